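# Genotype, expression, phenotype and DRP simulators against their
# construction targets.

test_that("simulated genotype frequencies track the sampled frequencies", {
  g <- simulate_genotypes(1000, 100, seed = 51)
  p_gen <- g$report$p_gen
  realized <- g$freq
  expect_gte(mean(abs(realized - p_gen) <= 0.05), 0.95)
  # symmetric binomial at p = 0.5
  g5 <- simulate_genotypes(2000, 10, maf_low = 0.5, maf_high = 0.5,
                           seed = 52)
  expect_lt(max(abs(colMeans(g5$dosages) - 1)), 0.08)
  # determinism and map layout
  expect_identical(simulate_genotypes(50, 20, seed = 53)$dosages,
                   simulate_genotypes(50, 20, seed = 53)$dosages)
  expect_equal(g$pos_bp[1:3], c(1L, 1001L, 2001L))
  expect_error(simulate_genotypes(10, 10, maf_low = 0), "maf_low")
})

test_that("block-correlated mode induces within-block LD", {
  g <- simulate_genotypes(800, 40, seed = 54, ld_rho = 0.9, ld_block = 20)
  r_adj <- mean(abs(diag(cor(g$dosages)[-1, -40])[1:18]))
  expect_gt(r_adj, 0.4)
  expect_true(all(g$dosages %in% 0:2))
})

test_that("qtl_effect evaluates the allele-substitution formula", {
  expect_equal(qtl_effect(0.5, 0.8, 1, 100),
               (2 * 0.5 * 0.5)^(-0.5) * sqrt(0.8) / sqrt(100),
               tolerance = 1e-12)
  expect_equal(qtl_effect(0.5, 0.8, 1, 100), 0.126491, tolerance = 1e-6)
  expect_equal(qtl_effect(0.3, 0, 1, 100), 0)
  expect_equal(qtl_effect(0.1, 0.8, 1, 100) / qtl_effect(0.5, 0.8, 1, 100),
               sqrt(0.5 / 0.18), tolerance = 1e-12)
  expect_error(qtl_effect(0, 0.8, 1, 100), "strictly")
  expect_error(qtl_effect(1, 0.8, 1, 100), "strictly")
})

test_that("phenotype simulator honours its architecture and ground truth", {
  g <- simulate_genotypes(300, 800, seed = 55)
  sims <- simulate_phenotypes(g, h2 = 0.8, m = 100, n_replicates = 3,
                              seed = 56)
  for (s in sims) {
    expect_length(unique(s$truth$qtl_indices), 100)
    expect_equal(s$pheno$y, s$truth$tbv + s$truth$resid)
    # effects recomputable from realized frequencies
    expect_equal(s$truth$a,
                 qtl_effect(g$freq[s$truth$qtl_indices], 0.8, 1, 100))
    # TBV recomputable from dosages and effects
    expect_equal(s$truth$tbv,
                 as.numeric(g$dosages[, s$truth$qtl_indices] %*% s$truth$a))
  }
  # distinct replicates use distinct QTL draws; same master seed repeats
  expect_false(identical(sims[[1]]$truth$qtl_indices,
                         sims[[2]]$truth$qtl_indices))
  sims2 <- simulate_phenotypes(g, h2 = 0.8, m = 100, n_replicates = 3,
                               seed = 56)
  expect_identical(sims[[2]]$pheno$y, sims2[[2]]$pheno$y)
  # h2 = 1: phenotype is exactly the TBV
  s1 <- simulate_phenotypes(g, h2 = 1, m = 50, n_replicates = 1,
                            seed = 57)[[1]]
  expect_equal(s1$pheno$y, s1$truth$tbv)
  expect_error(simulate_phenotypes(g, eligible_snps = 1:10, m = 100),
               "eligible")
})

test_that("expression simulator realizes its nominal cis-h2", {
  g <- simulate_genotypes(500, 200, seed = 58)
  ex <- simulate_expression(g, n_genes = 10, cis_snps_per_gene = 10,
                            cis_h2 = 0.6, seed = 59)
  expect_equal(ncol(ex$expr$values), 10)
  expect_true(all(abs(ex$truth$cis_h2_realized - 0.6) < 0.1))
  # cis_h2 = 1 -> exact linear function of cis dosages
  ex1 <- simulate_expression(g, n_genes = 2, cis_snps_per_gene = 10,
                             cis_h2 = 1, seed = 60)
  b <- ex1$effects[[1]]
  rebuilt <- as.numeric(g$dosages[, names(b)] %*% b)
  expect_equal(unname(ex1$expr$values[, 1]), rebuilt, tolerance = 1e-10)
  # cis_h2 = 0 -> no association with cis dosages
  ex0 <- simulate_expression(g, n_genes = 10, cis_snps_per_gene = 10,
                             cis_h2 = 0, seed = 61)
  cors <- vapply(seq_len(10), function(j) {
    idx <- ex0$truth$snp_lo[j]:ex0$truth$snp_hi[j]
    max(abs(suppressWarnings(cor(ex0$expr$values[, j],
                                 g$dosages[, idx]))), na.rm = TRUE)
  }, 0)
  expect_gte(mean(cors < 0.15), 0.9)
})

test_that("elastic-net expression prediction recovers cis signal", {
  g <- simulate_genotypes(300, 60, seed = 62)
  tr <- 1:200; ta <- 201:300
  gtr <- geno_matrix(g$dosages[tr, ], chrom = g$chrom, pos_bp = g$pos_bp)
  gta <- geno_matrix(g$dosages[ta, ], chrom = g$chrom, pos_bp = g$pos_bp)
  # gene that is an exact linear function of one cis SNP
  yv <- 2 * g$dosages[, 5]
  etr <- expr_matrix(cbind(gene1 = yv[tr]),
                     individual_ids = gtr$individual_ids,
                     state = "log2p1", gene_chrom = "1",
                     gene_start = 4001L, gene_end = 4001L)
  pred <- predict_expression_enet(gtr, etr, gta, seed = 63,
                                  window_bp = 5000)
  expect_gte(spearman(pred$values[, 1], yv[ta]), 0.95)
  # target = train reproduces the fit
  pred_tr <- predict_expression_enet(gtr, etr, gtr, seed = 63,
                                     window_bp = 5000)
  expect_gt(cor(pred_tr$values[, 1], yv[tr]), 0.99)
  # constant gene falls back to the training mean and is flagged
  etc <- expr_matrix(cbind(gene1 = rep(2, 200)),
                     individual_ids = gtr$individual_ids,
                     state = "log2p1", gene_chrom = "1",
                     gene_start = 4001L, gene_end = 4001L)
  predc <- predict_expression_enet(gtr, etc, gta, seed = 63,
                                   window_bp = 5000)
  expect_true(all(predc$values == 2))
  expect_equal(attr(predc, "mean_predicted"), "gene1")
})

test_that("null genes predict at chance level", {
  g <- simulate_genotypes(300, 40, seed = 64)
  tr <- 1:200; ta <- 201:300
  gtr <- geno_matrix(g$dosages[tr, ], chrom = g$chrom, pos_bp = g$pos_bp)
  gta <- geno_matrix(g$dosages[ta, ], chrom = g$chrom, pos_bp = g$pos_bp)
  set.seed(65)
  Y <- matrix(rnorm(300 * 5), 300, 5,
              dimnames = list(NULL, paste0("gene", 1:5)))
  etr <- expr_matrix(Y[tr, ], individual_ids = gtr$individual_ids,
                     state = "log2p1",
                     gene_chrom = rep("1", 5),
                     gene_start = rep(1L, 5), gene_end = rep(39001L, 5))
  pred <- predict_expression_enet(gtr, etr, gta, seed = 66)
  rho <- vapply(1:5, function(j)
    if (sd(pred$values[, j]) == 0) 0
    else suppressWarnings(spearman(pred$values[, j], Y[ta, j])), 0)
  expect_gte(mean(abs(rho) < 0.2), 0.8)
})

test_that("DRP pseudo-phenotypes realize their target reliability", {
  g <- simulate_genotypes(2000, 300, seed = 67)
  s <- simulate_phenotypes(g, n_replicates = 1, seed = 68)[[1]]
  drp_hi <- simulate_drp(s$truth$tbv, rel = 0.999,
                         ids = g$individual_ids, seed = 69)
  expect_gte(cor(drp_hi$y, s$truth$tbv), 0.99)
  drp_mid <- simulate_drp(s$truth$tbv, rel = 0.5,
                          ids = g$individual_ids, seed = 70)
  expect_lt(abs(cor(drp_mid$y, s$truth$tbv)^2 - 0.5), 0.07)
  expect_equal(drp_mid$rel, rep(0.5, 2000))
  expect_identical(drp_mid$y,
                   simulate_drp(s$truth$tbv, 0.5, g$individual_ids,
                                seed = 70)$y)
  expect_error(simulate_drp(s$truth$tbv, rel = 1), "rel")
})
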