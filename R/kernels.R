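# Similarity matrices: VanRaden G, expression E, linear and Gaussian
# kernels, train-test cross-kernels and the weighted fusion
# K = w1 * Ka + (1 - w1) * Kb.

#' Construct a kernel matrix object
#'
#' Symmetric n x n similarity with the individual ordering that produced it.
#' Input is symmetrized (tolerance 1e-10) at construction; a Gaussian kernel
#' must have unit diagonal.
#'
#' @param values n x n numeric matrix.
#' @param individual_ids ordered identifiers.
#' @param kind one of `"vanraden_g"`, `"expression_e"`, `"linear"`,
#'   `"gaussian"`, `"fused"`.
#' @param params named list of parameters that produced the kernel
#'   (e.g. `theta`, `w1`, source labels).
#' @param jitter_applied diagonal jitter added for positive-definiteness.
#' @return an object of class `kernel_matrix`.
#' @export
kernel_matrix <- function(values, individual_ids = rownames(values),
                          kind = c("vanraden_g", "expression_e", "linear",
                                   "gaussian", "fused"),
                          params = list(), jitter_applied = 0) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("kernel must be square")
  if (is.null(individual_ids))
    individual_ids <- paste0("ind", seq_len(nrow(values)))
  stop_if_not_ids(individual_ids, "individual")
  if (max(abs(values - t(values))) > 1e-10)
    stop("kernel asymmetric beyond 1e-10")
  values <- (values + t(values)) / 2
  if (kind == "gaussian" && max(abs(diag(values) - 1)) > 0)
    stop("gaussian kernel must have unit diagonal")
  if (kind == "fused") {
    w1 <- params$w1
    if (is.null(w1) || w1 < 0 || w1 > 1) stop("fused kernel needs w1 in [0,1]")
  }
  dimnames(values) <- list(individual_ids, individual_ids)
  structure(list(individual_ids = individual_ids, values = values,
                 kind = kind, params = params,
                 jitter_applied = jitter_applied),
            class = "kernel_matrix")
}

#' @export
as.matrix.kernel_matrix <- function(x, ...) x$values

#' @export
dim.kernel_matrix <- function(x) dim(x$values)

#' @export
print.kernel_matrix <- function(x, ...) {
  cat(sprintf("kernel_matrix (%s): %d x %d\n", x$kind, nrow(x$values),
              ncol(x$values)))
  invisible(x)
}

# ---- relationship matrices ----------------------------------------------

#' VanRaden genomic relationship matrix
#'
#' `G = Z Z' / (2 * sum(p_i * (1 - p_i)))` where `Z` is the dosage matrix
#' with column `i` centered by `2 * p_i`, i.e. genotype codes 0/1/2 become
#' `(0 - 2p_i)`, `(1 - 2p_i)`, `(2 - 2p_i)`.  When `p` is computed from the
#' data the columns of `Z` sum to zero, hence the rows of `G` sum to zero.
#' Monomorphic SNPs (freq 0 or 1) contribute nothing and are dropped; the
#' count dropped is recorded in `params$n_monomorphic_dropped`.
#'
#' @param geno a [geno_matrix()].
#' @param freq optional per-SNP allele frequencies overriding `geno$freq`.
#' @return a [kernel_matrix()] of kind `"vanraden_g"`.
#' @export
vanraden_g <- function(geno, freq = NULL) {
  stopifnot(inherits(geno, "geno_matrix"))
  p <- freq %||% geno$freq
  stopifnot(length(p) == ncol(geno$dosages))
  keep <- p > 0 & p < 1
  if (!any(keep)) stop("zero denominator: all SNPs monomorphic")
  X <- geno$dosages[, keep, drop = FALSE]
  p <- p[keep]
  Z <- sweep(X, 2, 2 * p)
  denom <- 2 * sum(p * (1 - p))
  G <- tcrossprod(Z) / denom
  kernel_matrix(G, individual_ids = geno$individual_ids, kind = "vanraden_g",
                params = list(n_snps = sum(keep),
                              n_monomorphic_dropped = sum(!keep),
                              freq_from_data = is.null(freq)))
}

#' Standardize gene-expression columns
#'
#' Per gene `j`: `r_ij = (x_ij - mean_j) / sd_j` with the sample (n-1
#' divisor) standard deviation.  Genes with zero variance are excluded and
#' counted.
#'
#' @param expr an [expr_matrix()] in state `"tpm"` or `"log2p1"`.
#' @return list with `r` (n x m standardized matrix), `means`, `sds`,
#'   `n_dropped`.
#' @export
standardize_expression <- function(expr) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (expr$state == "standardized")
    stop("expression already standardized")
  X <- expr$values
  mu <- colMeans(X)
  s <- apply(X, 2, stats::sd)
  keep <- s > 0
  R <- sweep(sweep(X[, keep, drop = FALSE], 2, mu[keep]), 2, s[keep], "/")
  list(r = R, means = mu[keep], sds = s[keep], n_dropped = sum(!keep))
}

#' Gene-expression relationship matrix
#'
#' `E = R R' / m` where `R` holds per-gene standardized expression and `m`
#' is the number of retained (non-constant) genes.
#'
#' @param expr an [expr_matrix()] in state `"tpm"` or `"log2p1"`;
#'   standardization is performed internally.
#' @return a [kernel_matrix()] of kind `"expression_e"`.
#' @export
expression_e <- function(expr) {
  st <- standardize_expression(expr)
  m <- ncol(st$r)
  if (m == 0) stop("no genes left after dropping zero-variance genes")
  E <- tcrossprod(st$r) / m
  kernel_matrix(E, individual_ids = expr$individual_ids,
                kind = "expression_e",
                params = list(m = m, n_dropped = st$n_dropped))
}

# ---- generic kernels -----------------------------------------------------

#' Linear kernel `K = X X'`
#'
#' @param X numeric feature matrix (rows = individuals).
#' @param ids optional identifiers (defaults to rownames).
#' @param scale_by_p divide by the number of features so entries stay O(1)
#'   regardless of dimension (default `FALSE`).
#' @return a [kernel_matrix()] of kind `"linear"`.
#' @export
linear_kernel <- function(X, ids = rownames(X), scale_by_p = FALSE) {
  X <- as.matrix(X)
  K <- tcrossprod(X)
  if (scale_by_p) K <- K / ncol(X)
  kernel_matrix(K, individual_ids = ids, kind = "linear",
                params = list(scale_by_p = scale_by_p, p = ncol(X)))
}

#' Gaussian (RBF) kernel
#'
#' `K_ij = prod_k exp(-theta * (x_ik - x_jk)^2) = exp(-theta * ||x_i -
#' x_j||^2)`, computed through squared Euclidean distances (the product
#' form is algebraically identical).  The diagonal is exactly 1.
#'
#' @param X numeric feature matrix (rows = individuals).
#' @param theta positive bandwidth parameter.
#' @param ids optional identifiers.
#' @return a [kernel_matrix()] of kind `"gaussian"`.
#' @export
gaussian_kernel <- function(X, theta, ids = rownames(X)) {
  if (!is.numeric(theta) || length(theta) != 1 || theta <= 0)
    stop("theta must be a positive scalar")
  D2 <- sq_dist(as.matrix(X))
  K <- exp(-theta * D2)
  diag(K) <- 1
  kernel_matrix(K, individual_ids = ids, kind = "gaussian",
                params = list(theta = theta))
}

# pairwise squared Euclidean distances, rows of A vs rows of B
sq_dist <- function(A, B = A) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  D2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  D2[D2 < 0] <- 0
  D2
}

#' Train-test cross-kernel rows
#'
#' One row per test sample holding its similarities `k'` to all training
#' samples, with the same kernel form and `theta` as the training kernel.
#'
#' @param X_train,X_test feature matrices with matching columns.
#' @param kind `"linear"` or `"gaussian"`.
#' @param theta bandwidth (Gaussian only).
#' @param scale_by_p match the training linear kernel's feature-count
#'   scaling.
#' @return an `n_test x n_train` numeric matrix.
#' @export
cross_kernel <- function(X_train, X_test, kind = c("linear", "gaussian"),
                         theta = NULL, scale_by_p = FALSE) {
  kind <- match.arg(kind)
  X_train <- as.matrix(X_train)
  X_test <- as.matrix(X_test)
  if (ncol(X_train) != ncol(X_test))
    stop("feature-dimension mismatch: train has ", ncol(X_train),
         ", test has ", ncol(X_test))
  if (kind == "linear") {
    K <- tcrossprod(X_test, X_train)
    if (scale_by_p) K <- K / ncol(X_train)
    K
  } else {
    if (is.null(theta) || theta <= 0) stop("theta must be a positive scalar")
    exp(-theta * sq_dist(X_test, X_train))
  }
}

#' Weighted fusion of two kernels
#'
#' `K = w1 * Ka + (1 - w1) * Kb`, elementwise, over an identical individual
#' ordering.  Only `w1` is stored; `w2 = 1 - w1` by construction.
#'
#' @param Ka,Kb [kernel_matrix()] objects with identical id order.
#' @param w1 weight of `Ka`, in `[0, 1]`.
#' @return a [kernel_matrix()] of kind `"fused"`.
#' @export
combine_kernels <- function(Ka, Kb, w1) {
  stopifnot(inherits(Ka, "kernel_matrix"), inherits(Kb, "kernel_matrix"))
  if (!is.numeric(w1) || length(w1) != 1 || w1 < 0 || w1 > 1)
    stop("w1 must be a scalar in [0,1]")
  if (!identical(Ka$individual_ids, Kb$individual_ids)) {
    bad <- which(Ka$individual_ids != Kb$individual_ids)[1]
    stop(sprintf("kernel id mismatch at position %d: '%s' vs '%s'",
                 bad %||% length(Ka$individual_ids),
                 Ka$individual_ids[bad], Kb$individual_ids[bad]))
  }
  K <- w1 * Ka$values + (1 - w1) * Kb$values
  kernel_matrix(K, individual_ids = Ka$individual_ids, kind = "fused",
                params = list(w1 = w1, kind_a = Ka$kind, kind_b = Kb$kind,
                              theta_a = Ka$params$theta,
                              theta_b = Kb$params$theta))
}

# ---- feature scaling (shared by WMKRR workflows) -------------------------

#' Column standardization learned on a training set
#'
#' Returns centers/scales from the training rows; apply with
#' [apply_standardization()] to both training and test rows so that test
#' samples are scaled with training statistics.  Zero-variance columns get
#' scale 1 (they become constant zero after centering).
#'
#' @param X training feature matrix.
#' @return list with `center`, `scale`.
#' @export
standardize_features <- function(X) {
  X <- as.matrix(X)
  ctr <- colMeans(X)
  sc <- apply(X, 2, stats::sd)
  sc[sc == 0 | !is.finite(sc)] <- 1
  list(center = ctr, scale = sc)
}

#' Apply a learned column standardization
#' @param X feature matrix.
#' @param sf output of [standardize_features()].
#' @export
apply_standardization <- function(X, sf) {
  sweep(sweep(as.matrix(X), 2, sf$center), 2, sf$scale, "/")
}
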