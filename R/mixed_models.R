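# GBLUP / GTBLUP machinery: REML variance components by the
# average-information algorithm with EM fallback, BLUP prediction of
# unphenotyped individuals, and cis-heritability of gene expression.

#' Estimate variance components by AI-REML
#'
#' Fits `y = 1 mu + sum_r u_r + e` with `u_r ~ N(0, K_r sigma_r^2)` and
#' `e ~ N(0, I sigma_e^2)` for one or two kernels (GBLUP: the genomic
#' relationship matrix; GTBLUP: genomic plus expression relationship
#' matrices).  Updates are average-information Newton steps with step
#' halving; if an AI step cannot improve the restricted likelihood an
#' EM-REML step is taken instead.  Components are clamped at
#' `1e-8 * var(y)`.
#'
#' @param y named numeric response over the observed individuals.
#' @param kernels list of 1-2 [kernel_matrix()] (or plain symmetric
#'   matrices) over the same individuals, in the same order as `y`.
#' @param tol convergence tolerance on the change in restricted
#'   log-likelihood.
#' @param max_iter iteration cap; non-convergence is reported via
#'   `converged = FALSE`, not an error.
#' @param init optional numeric vector of starting values
#'   `(sigma_1^2, ..., sigma_e^2)`.
#' @return object of class `varcomp`: `sigma2` (named vector, last element
#'   `e`), `h2` (per-kernel variance ratios), `loglik`, `converged`,
#'   `n_iter`, `ai_rcond`.
#' @export
estimate_variance_components <- function(y, kernels, tol = 1e-8,
                                         max_iter = 200, init = NULL) {
  Ks <- lapply(kernels, function(K)
    if (inherits(K, "kernel_matrix")) K$values else as.matrix(K))
  n <- length(y)
  if (n < 10) stop("need at least 10 observations")
  for (K in Ks) {
    if (nrow(K) != n) stop("kernel/response dimension mismatch")
  }
  if (!is.null(names(y)) && !is.null(rownames(Ks[[1]])) &&
      !identical(names(y), rownames(Ks[[1]])))
    stop("kernel/response id mismatch")
  nk <- length(Ks)
  vy <- stats::var(y)
  clamp <- 1e-8 * vy
  theta <- init %||% rep(vy / (nk + 1), nk + 1)  # kernels..., residual
  ones <- matrix(1, n, 1)

  reml_parts <- function(theta) {
    V <- diag(theta[nk + 1], n)
    for (r in seq_len(nk)) V <- V + theta[r] * Ks[[r]]
    R <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(R)) return(NULL)
    Vinv <- chol2inv(R)
    Vi1 <- Vinv %*% ones
    xvx <- as.numeric(crossprod(ones, Vi1))
    P <- Vinv - tcrossprod(Vi1) / xvx
    Py <- as.numeric(P %*% y)
    ll <- -0.5 * (chol_logdet(R) + log(xvx) + sum(y * Py))
    list(P = P, Py = Py, ll = ll)
  }

  parts <- reml_parts(theta)
  if (is.null(parts)) stop("initial variance matrix not positive definite")
  converged <- FALSE
  ai_rcond <- NA_real_
  it <- 0
  for (it in seq_len(max_iter)) {
    # score and AI matrix over (sigma_1^2, ..., sigma_e^2); K_e = I
    Kall <- c(Ks, list(diag(1, n)))
    PK <- lapply(Kall, function(K) parts$P %*% K)
    KPy <- lapply(Kall, function(K) as.numeric(K %*% parts$Py))
    score <- vapply(seq_len(nk + 1), function(r)
      -0.5 * (sum(diag(PK[[r]])) - sum(parts$Py * KPy[[r]])), 0)
    AI <- matrix(0, nk + 1, nk + 1)
    PKPy <- lapply(KPy, function(v) as.numeric(parts$P %*% v))
    for (r in seq_len(nk + 1)) for (s in r:(nk + 1)) {
      AI[r, s] <- AI[s, r] <- 0.5 * sum(KPy[[r]] * PKPy[[s]])
    }
    ai_rcond <- tryCatch(1 / kappa(AI, exact = FALSE),
                         error = function(e) 0)
    if (is.finite(ai_rcond) && ai_rcond < 1e-12)
      warning("near-singular AI matrix: variance split may be ",
              "non-identifiable")
    delta <- tryCatch(solve(AI, score), error = function(e) NULL)
    new_parts <- NULL
    if (!is.null(delta)) {
      step <- 1
      for (h in 1:10) {  # step halving
        cand <- pmax(theta + step * delta, clamp)
        p2 <- reml_parts(cand)
        if (!is.null(p2) && p2$ll >= parts$ll - 1e-10) {
          new_parts <- p2; new_theta <- cand; break
        }
        step <- step / 2
      }
    }
    if (is.null(new_parts)) {  # EM fallback (always ascends)
      new_theta <- pmax(vapply(seq_len(nk + 1), function(r)
        theta[r] + theta[r]^2 * (sum(parts$Py * KPy[[r]]) -
                                   sum(diag(PK[[r]]))) / n, 0), clamp)
      new_parts <- reml_parts(new_theta)
      if (is.null(new_parts)) break
    }
    dll <- new_parts$ll - parts$ll
    theta <- new_theta
    parts <- new_parts
    if (abs(dll) < tol) { converged <- TRUE; break }
  }
  names(theta) <- c(paste0("k", seq_len(nk)), "e")
  h2 <- theta[seq_len(nk)] / sum(theta)
  structure(list(sigma2 = theta, h2 = h2, loglik = parts$ll,
                 converged = converged, n_iter = it,
                 ai_rcond = ai_rcond),
            class = "varcomp")
}

#' @export
print.varcomp <- function(x, ...) {
  cat("REML variance components:\n")
  print(round(x$sigma2, 6))
  cat(sprintf("  loglik=%.4f, converged=%s (%d iterations)\n",
              x$loglik, x$converged, x$n_iter))
  invisible(x)
}

#' BLUP prediction for all individuals, including unphenotyped ones
#'
#' Solves the mixed model at the supplied variance components via the
#' variance projection equivalent to the all-individual mixed-model
#' equations with missing records: `mu = (1'V^-1 1)^-1 1'V^-1 y` on the
#' observed block, then `u_r = sigma_r^2 K_r[, obs] V^-1 (y - 1 mu)` for
#' every individual.  The predicted value of a validation individual is
#' `g` (plus `t` for the two-kernel model), plus `mu` when comparing on the
#' response scale.
#'
#' @param y_ref response of the observed individuals.
#' @param components a `varcomp` (or list with `sigma2` laid out the same
#'   way).
#' @param kernels list of 1-2 kernels over ALL individuals (reference and
#'   validation).
#' @param observed integer or logical index of the observed individuals
#'   within the kernel ordering, aligned with `y_ref`.
#' @return object of class `blup_solution`: `mu_hat`, `g_hat` (first
#'   kernel, all individuals), `t_hat` (second kernel or `NULL`), `pred`
#'   (`mu_hat + g_hat [+ t_hat]`), `ids`.
#' @export
blup_predict <- function(y_ref, components, kernels, observed) {
  Ks <- lapply(kernels, function(K)
    if (inherits(K, "kernel_matrix")) K$values else as.matrix(K))
  ids <- if (inherits(kernels[[1]], "kernel_matrix"))
    kernels[[1]]$individual_ids else rownames(Ks[[1]])
  n_all <- nrow(Ks[[1]])
  obs <- if (is.logical(observed)) which(observed) else as.integer(observed)
  if (length(obs) == 0) stop("no observed individuals")
  if (length(y_ref) != length(obs))
    stop("y_ref length must match the observed index")
  nk <- length(Ks)
  s2 <- components$sigma2
  Voo <- diag(s2[nk + 1], length(obs))
  for (r in seq_len(nk))
    Voo <- Voo + s2[r] * Ks[[r]][obs, obs, drop = FALSE]
  sol <- chol_solve_sym(Voo, cbind(y_ref, 1))
  Viy <- sol$x[, 1]; Vi1 <- sol$x[, 2]
  mu_hat <- sum(Viy) / sum(Vi1)
  resid_proj <- Viy - Vi1 * mu_hat  # V^-1 (y - 1 mu)
  u <- lapply(seq_len(nk), function(r)
    as.numeric(s2[r] * Ks[[r]][, obs, drop = FALSE] %*% resid_proj))
  pred <- mu_hat + Reduce(`+`, u)
  structure(list(mu_hat = mu_hat, g_hat = u[[1]],
                 t_hat = if (nk > 1) u[[2]] else NULL,
                 pred = pred, ids = ids %||% seq_len(n_all),
                 observed = obs),
            class = "blup_solution")
}

#' Cis-heritability of one gene's expression
#'
#' Builds a VanRaden relationship matrix from the SNPs within `window_bp`
#' of the gene body, residualizes the expression on an intercept plus the
#' leading genotype principal components (and any user-supplied
#' covariates), and returns `sigma_g^2 / (sigma_g^2 + sigma_e^2)` from a
#' single-kernel REML fit.
#'
#' @param expr_gene numeric expression vector for one gene, aligned with
#'   the genotype rows.
#' @param geno a [geno_matrix()] with `chrom`/`pos_bp` populated.
#' @param gene_chrom,gene_start,gene_end gene coordinates (1-based,
#'   inclusive).
#' @param window_bp cis window on each side of the gene body (default
#'   1 Mb).
#' @param n_pcs number of genotype principal components used as
#'   covariates (default 5).
#' @param covariates optional numeric matrix of extra covariates (e.g.
#'   externally computed expression factors).
#' @return estimated cis-h2 in `[0, 1]`, or `NA` with a warning when
#'   fewer than 2 cis-SNPs fall in the window.
#' @export
estimate_cis_h2 <- function(expr_gene, geno, gene_chrom, gene_start,
                            gene_end, window_bp = 1e6, n_pcs = 5,
                            covariates = NULL) {
  stopifnot(inherits(geno, "geno_matrix"))
  n <- nrow(geno$dosages)
  stopifnot(length(expr_gene) == n)
  cis <- which(!is.na(geno$pos_bp) & geno$chrom == gene_chrom &
                 geno$pos_bp >= gene_start - window_bp &
                 geno$pos_bp <= gene_end + window_bp)
  cis <- cis[geno$freq[cis] > 0 & geno$freq[cis] < 1]
  if (length(cis) < 2) {
    warning("fewer than 2 polymorphic cis-SNPs in window; returning NA")
    return(NA_real_)
  }
  cis_geno <- geno_matrix(geno$dosages[, cis, drop = FALSE],
                          individual_ids = geno$individual_ids,
                          snp_ids = geno$snp_ids[cis])
  Gc <- vanraden_g(cis_geno)
  X <- matrix(1, n, 1)
  if (n_pcs > 0) {
    Zc <- scale(geno$dosages, center = TRUE, scale = FALSE)
    pc <- stats::prcomp(Zc, center = FALSE, rank. = min(n_pcs, n - 1))
    X <- cbind(X, pc$x)
  }
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  resid <- stats::lm.fit(X, expr_gene)$residuals
  vc <- estimate_variance_components(resid, list(Gc))
  unname(vc$sigma2[1] / sum(vc$sigma2))
}
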