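# Synthetic genotypes, cis-heritable gene expression, QTL phenotypes with
# full ground truth, genetically predicted expression (elastic net), and
# DRP-like pseudo-phenotypes with known reliability.

#' Simulate unlinked SNP genotypes
#'
#' Per-SNP allele frequencies are drawn from `Uniform(maf_low, maf_high)`
#' and dosages as independent `Binomial(2, p)` (Hardy-Weinberg, no linkage
#' by default).  Positions are laid out on one synthetic chromosome at
#' fixed spacing.  An optional block mode induces within-block genotype
#' correlation through a Gaussian copula with AR(1) structure, since
#' kernel methods are sensitive to linkage disequilibrium.
#'
#' @param n individuals.
#' @param p SNPs.
#' @param maf_low,maf_high allele-frequency bounds, `0 < maf_low <=
#'   maf_high <= 0.5`.
#' @param seed integer seed.
#' @param chrom chromosome label for the synthetic map.
#' @param spacing_bp distance between adjacent SNPs (1-based positions).
#' @param ld_rho optional AR(1) correlation of the latent haplotype
#'   Gaussians within blocks (`NULL` = independent SNPs).
#' @param ld_block block size when `ld_rho` is set.
#' @return a [geno_matrix()] with synthetic map and generative frequencies
#'   recorded in `report$p_gen`.
#' @export
simulate_genotypes <- function(n, p, maf_low = 0.05, maf_high = 0.5,
                               seed = NULL, chrom = "1", spacing_bp = 1000,
                               ld_rho = NULL, ld_block = 50) {
  if (!(maf_low > 0 && maf_low <= maf_high && maf_high <= 0.5))
    stop("need 0 < maf_low <= maf_high <= 0.5")
  with_seed(seed, {
    pf <- stats::runif(p, maf_low, maf_high)
    if (is.null(ld_rho)) {
      X <- matrix(stats::rbinom(n * p, 2, rep(pf, each = n)), n, p)
    } else {
      stopifnot(ld_rho > -1, ld_rho < 1)
      X <- matrix(0, n, p)
      thr <- stats::qnorm(pf)
      for (start in seq(1, p, by = ld_block)) {
        idx <- start:min(start + ld_block - 1, p)
        b <- length(idx)
        for (hap in 1:2) {  # two independent haplotypes per individual
          Zl <- matrix(stats::rnorm(n * b), n, b)
          if (b > 1) for (j in 2:b)
            Zl[, j] <- ld_rho * Zl[, j - 1] +
              sqrt(1 - ld_rho^2) * Zl[, j]
          X[, idx] <- X[, idx] + (Zl < rep(thr[idx], each = n))
        }
      }
    }
    geno_matrix(X,
                individual_ids = sprintf("ind%05d", seq_len(n)),
                snp_ids = sprintf("snp%06d", seq_len(p)),
                chrom = rep(chrom, p),
                pos_bp = as.integer(seq_len(p) - 1) * as.integer(spacing_bp) + 1L,
                report = list(p_gen = pf))
  })
}

#' Allele-substitution effect of a QTL
#'
#' `a_i = (2 p_i (1 - p_i))^(-1/2) * sigma_g / sqrt(m)` with
#' `sigma_g = sqrt(sigma2_p * h2)`, so that each of the `m` QTL contributes
#' variance `sigma_g^2 / m` under Hardy-Weinberg.  `p_i` is the realized
#' allele frequency of the QTL in the marker data.
#'
#' @param p_i allele frequency (vectorized), strictly inside `(0, 1)`.
#' @param h2 trait heritability.
#' @param sigma2_p phenotypic variance.
#' @param m total QTL count.
#' @return numeric effect(s).
#' @export
qtl_effect <- function(p_i, h2, sigma2_p, m) {
  stopifnot(m >= 1, h2 >= 0, h2 <= 1, sigma2_p >= 0)
  if (any(p_i <= 0 | p_i >= 1))
    stop("QTL allele frequency must lie strictly in (0, 1)")
  sigma_g <- sqrt(sigma2_p * h2)
  (2 * p_i * (1 - p_i))^(-1 / 2) * sigma_g / sqrt(m)
}

#' Simulate QTL phenotypes with full ground truth
#'
#' Per replicate: `m` QTL are sampled without replacement from the
#' eligible SNPs; effects come from [qtl_effect()] using each QTL's
#' realized frequency; the true breeding value is the dosage-weighted sum
#' of effects; residuals are `N(0, (1 - h2) * sigma2_p)`; the phenotype is
#' TBV + residual.  Defaults realize the reference architecture
#' (`h2 = 0.8`, `m = 100`, `sigma2_p = 1`).  Replicates use seeds derived
#' independently from `seed`.
#'
#' @param geno a [geno_matrix()].
#' @param eligible_snps integer indices of SNPs eligible as QTL; defaults
#'   to all polymorphic SNPs.
#' @param h2 heritability.
#' @param m QTL count.
#' @param sigma2_p phenotypic variance.
#' @param n_replicates replicates.
#' @param seed master seed.
#' @return list of length `n_replicates`; each element has `pheno`
#'   (a [pheno_table()]) and `truth` (class `sim_truth`: `qtl_indices`,
#'   `a`, `tbv`, `resid`, `h2`, `sigma2_p`, `seed`).
#' @export
simulate_phenotypes <- function(geno, eligible_snps = NULL, h2 = 0.8,
                                m = 100, sigma2_p = 1, n_replicates = 10,
                                seed = NULL) {
  stopifnot(inherits(geno, "geno_matrix"))
  eligible <- eligible_snps %||% which(geno$freq > 0 & geno$freq < 1)
  if (length(eligible) < m)
    stop("only ", length(eligible), " eligible SNPs for m = ", m, " QTL")
  n <- nrow(geno$dosages)
  lapply(seq_len(n_replicates), function(r) {
    rs <- derive_seed(seed %||% 0L, "phenotype", r)
    with_seed(rs, {
      qtl <- sort(sample(eligible, m, replace = FALSE))
      a <- qtl_effect(geno$freq[qtl], h2, sigma2_p, m)
      tbv <- as.numeric(geno$dosages[, qtl, drop = FALSE] %*% a)
      resid <- stats::rnorm(n, 0, sqrt((1 - h2) * sigma2_p))
      list(pheno = pheno_table(geno$individual_ids, tbv + resid),
           truth = structure(list(qtl_indices = qtl, a = a, tbv = tbv,
                                  resid = resid, h2 = h2,
                                  sigma2_p = sigma2_p, seed = rs),
                             class = "sim_truth"))
    })
  })
}

#' Write per-replicate ground truth as TSV files
#'
#' Emits `<prefix>_qtl.tsv` (replicate, QTL index, SNP id, effect) and
#' `<prefix>_tbv.tsv` (replicate, individual, TBV, residual).
#'
#' @param sims output of [simulate_phenotypes()].
#' @param geno the genotypes the simulation ran on.
#' @param prefix output path prefix.
#' @export
write_sim_truth <- function(sims, geno, prefix) {
  qtl <- do.call(rbind, lapply(seq_along(sims), function(r) {
    tr <- sims[[r]]$truth
    data.frame(replicate = r, qtl_index = tr$qtl_indices,
               snp_id = geno$snp_ids[tr$qtl_indices], effect = tr$a)
  }))
  tbv <- do.call(rbind, lapply(seq_along(sims), function(r) {
    tr <- sims[[r]]$truth
    data.frame(replicate = r, id = geno$individual_ids, tbv = tr$tbv,
               resid = tr$resid)
  }))
  utils::write.table(qtl, paste0(prefix, "_qtl.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(tbv, paste0(prefix, "_tbv.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' Simulate cis-heritable gene expression
#'
#' Genes are placed on consecutive windows of the SNP map.  For each gene,
#' effects of its cis-SNPs are drawn `N(0, 1)`, the genetic value is
#' rescaled so its variance fraction equals the gene's `cis_h2`, and
#' Gaussian noise supplies the remainder (total variance approximately 1).
#' Genes whose window carries no polymorphic SNP are skipped with a
#' warning.
#'
#' @param geno a [geno_matrix()] with a populated map.
#' @param n_genes gene count.
#' @param cis_snps_per_gene SNPs per gene window.
#' @param cis_h2 scalar or per-gene vector in `[0, 1]`.
#' @param seed integer seed.
#' @return list with `expr` (an [expr_matrix()] with gene coordinates,
#'   state `"log2p1"`) and `truth` (data.frame: gene, causal window,
#'   realized cis-h2) plus `effects` (list of per-gene cis effects).
#' @export
simulate_expression <- function(geno, n_genes, cis_snps_per_gene = 10,
                                cis_h2 = 0.3, seed = NULL) {
  stopifnot(inherits(geno, "geno_matrix"))
  p <- ncol(geno$dosages)
  n <- nrow(geno$dosages)
  if (n_genes * cis_snps_per_gene > p)
    stop("map too short: need ", n_genes * cis_snps_per_gene, " SNPs")
  h2v <- rep_len(cis_h2, n_genes)
  if (any(h2v < 0 | h2v > 1)) stop("cis_h2 outside [0,1]")
  with_seed(seed, {
    vals <- matrix(NA_real_, n, n_genes)
    truth <- data.frame(gene_id = sprintf("gene%04d", seq_len(n_genes)),
                        snp_lo = NA_integer_, snp_hi = NA_integer_,
                        cis_h2_nominal = h2v, cis_h2_realized = NA_real_)
    effects <- vector("list", n_genes)
    keep <- logical(n_genes)
    for (g in seq_len(n_genes)) {
      lo <- (g - 1) * cis_snps_per_gene + 1
      hi <- g * cis_snps_per_gene
      idx <- lo:hi
      poly <- idx[geno$freq[idx] > 0 & geno$freq[idx] < 1]
      if (!length(poly)) {
        warning("gene ", g, ": no polymorphic SNP in window; skipped")
        next
      }
      b <- stats::rnorm(length(poly))
      gv <- as.numeric(geno$dosages[, poly, drop = FALSE] %*% b)
      sg <- stats::sd(gv)
      if (sg == 0) {
        warning("gene ", g, ": constant genetic value; skipped")
        next
      }
      gv <- gv / sg * sqrt(h2v[g])
      noise <- stats::rnorm(n, 0, sqrt(1 - h2v[g]))
      vals[, g] <- gv + noise
      v <- stats::var(gv + noise)
      truth$snp_lo[g] <- lo; truth$snp_hi[g] <- hi
      truth$cis_h2_realized[g] <- stats::var(gv) / v
      effects[[g]] <- stats::setNames(b / sg * sqrt(h2v[g]),
                                      geno$snp_ids[poly])
      keep[g] <- TRUE
    }
    expr <- expr_matrix(vals[, keep, drop = FALSE],
                        individual_ids = geno$individual_ids,
                        gene_ids = truth$gene_id[keep],
                        state = "log2p1",
                        gene_chrom = geno$chrom[truth$snp_lo[keep]],
                        gene_start = geno$pos_bp[truth$snp_lo[keep]],
                        gene_end = geno$pos_bp[truth$snp_hi[keep]])
    list(expr = expr, truth = truth[keep, , drop = FALSE],
         effects = effects[keep])
  })
}

#' Genetically predicted gene expression by elastic net
#'
#' Per gene, fits an elastic net of expression on the gene's cis-SNP
#' dosages (falling back to all SNPs when coordinates are absent), with
#' the penalty chosen by `inner_k`-fold cross-validation, and predicts
#' expression for the target individuals.  Genes with no expression
#' variance or an all-zero coefficient path are predicted as the training
#' mean and flagged.
#'
#' @param geno_train,geno_target [geno_matrix()] objects sharing SNP
#'   columns.
#' @param expr_train an [expr_matrix()] over the training individuals.
#' @param l1_ratio elastic-net mixing (`glmnet` alpha; 0.5 = balanced).
#' @param inner_k folds for penalty selection.
#' @param seed integer seed (fold assignment).
#' @param window_bp cis window around the gene body.
#' @return an [expr_matrix()] of predicted expression for the target
#'   individuals, same state as `expr_train`, with attribute
#'   `"mean_predicted"` naming genes that fell back to the mean.
#' @export
predict_expression_enet <- function(geno_train, expr_train, geno_target,
                                    l1_ratio = 0.5, inner_k = 5,
                                    seed = NULL, window_bp = 1e6) {
  stopifnot(inherits(geno_train, "geno_matrix"),
            inherits(geno_target, "geno_matrix"),
            inherits(expr_train, "expr_matrix"))
  if (!identical(geno_train$snp_ids, geno_target$snp_ids))
    stop("train and target SNP sets differ")
  n_tr <- nrow(geno_train$dosages)
  if (n_tr < 30) stop("need at least 30 training individuals")
  m <- ncol(expr_train$values)
  preds <- matrix(NA_real_, nrow(geno_target$dosages), m)
  mean_pred <- character(0)
  has_coords <- !is.null(expr_train$gene_start)
  foldid <- with_seed(seed, sample(rep_len(seq_len(inner_k), n_tr)))
  for (j in seq_len(m)) {
    yj <- expr_train$values[, j]
    if (has_coords) {
      cis <- which(!is.na(geno_train$pos_bp) &
                     geno_train$chrom == expr_train$gene_chrom[j] &
                     geno_train$pos_bp >= expr_train$gene_start[j] - window_bp &
                     geno_train$pos_bp <= expr_train$gene_end[j] + window_bp)
    } else {
      cis <- seq_len(ncol(geno_train$dosages))
    }
    if (stats::sd(yj) == 0 || length(cis) == 0) {
      preds[, j] <- mean(yj)
      mean_pred <- c(mean_pred, expr_train$gene_ids[j])
      next
    }
    Xtr <- geno_train$dosages[, cis, drop = FALSE]
    Xta <- geno_target$dosages[, cis, drop = FALSE]
    if (length(cis) == 1 || all(apply(Xtr, 2, stats::sd) == 0)) {
      # too few predictors for glmnet; ordinary least squares
      df <- data.frame(y = yj, x = Xtr[, 1])
      fit <- stats::lm(y ~ x, data = df)
      preds[, j] <- stats::predict(fit, data.frame(x = Xta[, 1]))
      next
    }
    cvfit <- glmnet::cv.glmnet(Xtr, yj, alpha = l1_ratio, foldid = foldid,
                               standardize = TRUE)
    cf <- as.numeric(stats::coef(cvfit, s = "lambda.min"))
    if (all(cf[-1] == 0)) {
      preds[, j] <- mean(yj)
      mean_pred <- c(mean_pred, expr_train$gene_ids[j])
    } else {
      preds[, j] <- as.numeric(
        stats::predict(cvfit, newx = Xta, s = "lambda.min"))
    }
  }
  if (expr_train$state == "tpm") preds[preds < 0] <- 0
  out <- expr_matrix(preds, individual_ids = geno_target$individual_ids,
                     gene_ids = expr_train$gene_ids,
                     state = if (expr_train$state == "standardized")
                       "log2p1" else expr_train$state,
                     gene_chrom = expr_train$gene_chrom,
                     gene_start = expr_train$gene_start,
                     gene_end = expr_train$gene_end)
  attr(out, "mean_predicted") <- mean_pred
  out
}

#' Simulate DRP-like pseudo-phenotypes with known reliability
#'
#' `DRP_i = TBV_i + e_i` with `var(e_i) = var(TBV) * (1 - rel_i) / rel_i`,
#' so that the squared correlation between DRP and TBV approaches `rel`
#' in expectation.  The reliabilities are stored in the returned table for
#' DRP-mode evaluation.
#'
#' @param tbv true breeding values.
#' @param rel target reliability per individual (scalar recycled), in
#'   `(0, 1)`.
#' @param ids individual ids (defaults to names of `tbv` or `ind...`).
#' @param seed integer seed.
#' @return a [pheno_table()] with a `rel` column.
#' @export
simulate_drp <- function(tbv, rel, ids = NULL, seed = NULL) {
  relv <- rep_len(rel, length(tbv))
  if (any(relv <= 0 | relv >= 1)) stop("rel outside (0,1)")
  ids <- ids %||% names(tbv) %||% sprintf("ind%05d", seq_along(tbv))
  vt <- stats::var(tbv)
  with_seed(seed, {
    e <- stats::rnorm(length(tbv), 0, sqrt(vt * (1 - relv) / relv))
    pheno_table(ids, tbv + e, rel = relv)
  })
}
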