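# AI-REML variance components, BLUP prediction against the direct GLS
# oracle, and cis-heritability estimation.

test_that("REML recovers heritability on a single replicate", {
  gn <- simulate_genotypes(400, 1500, seed = 41)
  G <- vanraden_g(gn)
  set.seed(42)
  L <- t(chol(as.matrix(G) + diag(1e-6, 400)))
  g <- as.numeric(L %*% rnorm(400)) * sqrt(0.5)
  y <- g + rnorm(400, 0, sqrt(0.5))
  vc <- estimate_variance_components(y, list(G))
  expect_true(vc$converged)
  h2 <- unname(vc$sigma2[1] / sum(vc$sigma2))
  expect_gt(h2, 0.35)
  expect_lt(h2, 0.65)
})

test_that("REML pushes the genetic variance to the boundary under the null", {
  gn <- simulate_genotypes(150, 600, seed = 43)
  G <- vanraden_g(gn)
  at_boundary <- 0
  for (s in 1:5) {
    set.seed(200 + s)
    y <- rnorm(150)
    vc <- suppressWarnings(estimate_variance_components(y, list(G)))
    if (vc$sigma2[1] / sum(vc$sigma2) < 0.1) at_boundary <- at_boundary + 1
  }
  expect_gte(at_boundary, 4)
})

test_that("identity kernel triggers the non-identifiability warning", {
  set.seed(44)
  y <- rnorm(30)
  expect_warning(
    estimate_variance_components(y, list(diag(30))),
    "non-identifiable")
})

test_that("BLUP equals the direct V-inverse GLS oracle (1 and 2 kernels)", {
  set.seed(45)
  n <- 30
  gn <- simulate_genotypes(n, 200, seed = 45)
  G <- as.matrix(vanraden_g(gn))
  E <- tcrossprod(matrix(rnorm(n * 50), n, 50)) / 50
  dimnames(E) <- dimnames(G)
  y <- rnorm(n)
  obs <- 1:20
  # one kernel
  s2 <- c(k1 = 0.7, e = 0.5)
  bl <- blup_predict(y[obs], list(sigma2 = s2), list(G), observed = obs)
  Vi <- solve(0.7 * G[obs, obs] + 0.5 * diag(20))
  mu <- sum(Vi %*% y[obs]) / sum(Vi)
  ghat <- as.numeric(0.7 * G[, obs] %*% Vi %*% (y[obs] - mu))
  expect_equal(bl$mu_hat, mu, tolerance = 1e-6)
  expect_equal(bl$g_hat, ghat, tolerance = 1e-6)
  expect_equal(bl$pred, mu + ghat, tolerance = 1e-6)
  # two kernels (GTBLUP layout)
  s2b <- c(k1 = 0.6, k2 = 0.3, e = 0.4)
  bl2 <- blup_predict(y[obs], list(sigma2 = s2b), list(G, E),
                      observed = obs)
  Vi2 <- solve(0.6 * G[obs, obs] + 0.3 * E[obs, obs] + 0.4 * diag(20))
  mu2 <- sum(Vi2 %*% y[obs]) / sum(Vi2)
  r2 <- Vi2 %*% (y[obs] - mu2)
  expect_equal(bl2$g_hat, as.numeric(0.6 * G[, obs] %*% r2),
               tolerance = 1e-6)
  expect_equal(bl2$t_hat, as.numeric(0.3 * E[, obs] %*% r2),
               tolerance = 1e-6)
})

test_that("3-individual example matches the explicit MME/V solve", {
  G <- matrix(c(1, 0.5, 0.25,
                0.5, 1, 0.5,
                0.25, 0.5, 1), 3, 3)
  y <- c(1.2, -0.4)
  bl <- blup_predict(y, list(sigma2 = c(k1 = 1, e = 1)), list(G),
                     observed = 1:2)
  V <- G[1:2, 1:2] + diag(2)
  Vi <- solve(V)
  mu <- sum(Vi %*% y) / sum(Vi)
  ghat <- as.numeric(G[, 1:2] %*% Vi %*% (y - mu))
  expect_equal(bl$g_hat, ghat, tolerance = 1e-10)
})

test_that("BLUP degenerate and invariance properties hold", {
  set.seed(46)
  n <- 25
  gn <- simulate_genotypes(n, 150, seed = 46)
  G <- as.matrix(vanraden_g(gn))
  y <- rnorm(15, mean = 3)
  obs <- 1:15
  # vanishing genetic variance: predictions collapse to the mean
  bl0 <- blup_predict(y, list(sigma2 = c(k1 = 1e-12, e = 1)), list(G),
                      observed = obs)
  expect_lt(max(abs(bl0$g_hat)), 1e-10)
  expect_equal(bl0$pred, rep(mean(y), n), tolerance = 1e-8)
  # duplicated G row -> identical genetic value
  G2 <- rbind(cbind(G, G[, 3]), c(G[3, ], G[3, 3]))
  bl2 <- blup_predict(y, list(sigma2 = c(k1 = 0.5, e = 0.5)), list(G2),
                      observed = obs)
  expect_equal(bl2$g_hat[n + 1], bl2$g_hat[3], tolerance = 1e-10)
  # shifting y by a constant shifts predictions by exactly that constant
  bl_a <- blup_predict(y, list(sigma2 = c(k1 = 0.5, e = 0.5)), list(G),
                       observed = obs)
  bl_b <- blup_predict(y + 10, list(sigma2 = c(k1 = 0.5, e = 0.5)),
                       list(G), observed = obs)
  expect_equal(bl_b$pred, bl_a$pred + 10, tolerance = 1e-8)
  expect_error(blup_predict(y, list(sigma2 = c(k1 = 1, e = 1)), list(G),
                            observed = integer(0)), "no observed")
})

test_that("cis-heritability estimation separates signal from noise", {
  gn <- simulate_genotypes(300, 60, seed = 47)
  ex <- simulate_expression(gn, n_genes = 3, cis_snps_per_gene = 10,
                            cis_h2 = 1, seed = 48)
  # gene 2 occupies SNPs 11-20, positions 10001..19001
  h2_hi <- estimate_cis_h2(ex$expr$values[, 2], gn,
                           gene_chrom = "1",
                           gene_start = ex$expr$gene_start[2],
                           gene_end = ex$expr$gene_end[2],
                           window_bp = 5000, n_pcs = 2)
  expect_gt(h2_hi, 0.9)
  # same replicate scored with a window that excludes the causal SNPs
  h2_out <- estimate_cis_h2(ex$expr$values[, 2], gn,
                            gene_chrom = "1", gene_start = 45001,
                            gene_end = 50001, window_bp = 4000, n_pcs = 2)
  expect_lt(h2_out, h2_hi)
  # pure-noise expression estimates near zero
  low <- 0
  for (s in 1:4) {
    set.seed(300 + s)
    h2_null <- estimate_cis_h2(rnorm(300), gn, gene_chrom = "1",
                               gene_start = 10001, gene_end = 19001,
                               window_bp = 5000, n_pcs = 2)
    if (h2_null <= 0.1) low <- low + 1
  }
  expect_gte(low, 3)
  # no cis-SNPs in window -> NA with warning
  expect_warning(
    out <- estimate_cis_h2(rnorm(300), gn, gene_chrom = "2",
                           gene_start = 1, gene_end = 2,
                           window_bp = 10),
    "cis-SNP")
  expect_true(is.na(out))
})
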