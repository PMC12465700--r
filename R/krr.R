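# Kernel ridge regression in the dual: alpha = (K + lambda I)^-1 y,
# prediction y(x) = k' (K + lambda I)^-1 y (+ training mean when the
# response is centered).

#' Fit kernel ridge regression in the dual
#'
#' Solves `(K + lambda I) alpha = y~` by Cholesky factorization (never by
#' explicit inversion), where `y~` is the response centered by its training
#' mean when `center_y = TRUE`.  Centering reconciles the interceptless
#' ridge objective with mixed-model comparators that carry an overall mean.
#'
#' @param K a [kernel_matrix()] or plain symmetric matrix over the training
#'   individuals.
#' @param y numeric response aligned with the rows of `K`.
#' @param lambda_reg positive ridge penalty.
#' @param center_y center `y` by its mean before solving (default `TRUE`);
#'   the stored `y_mean` is added back at prediction time.
#' @return an object of class `wmkrr_fit` with elements `alpha`,
#'   `lambda_reg`, `y_mean`, `kernel_spec`, `train_ids`,
#'   `jitter_applied`.
#' @export
fit_krr <- function(K, y, lambda_reg, center_y = TRUE) {
  if (!is.numeric(lambda_reg) || length(lambda_reg) != 1 || lambda_reg <= 0)
    stop("lambda_reg must be a positive scalar")
  spec <- list(kind = "unknown")
  ids <- NULL
  if (inherits(K, "kernel_matrix")) {
    spec <- c(list(kind = K$kind), K$params)
    ids <- K$individual_ids
    K <- K$values
  }
  K <- as.matrix(K)
  n <- nrow(K)
  if (ncol(K) != n) stop("K must be square")
  if (length(y) != n) stop("length(y) must match nrow(K)")
  ids <- ids %||% rownames(K) %||% paste0("ind", seq_len(n))
  y_mean <- if (center_y) mean(y) else 0
  sol <- chol_solve_sym(K + diag(lambda_reg, n), as.numeric(y) - y_mean)
  structure(list(alpha = as.numeric(sol$x), lambda_reg = lambda_reg,
                 y_mean = y_mean, kernel_spec = spec, train_ids = ids,
                 jitter_applied = sol$jitter),
            class = "wmkrr_fit")
}

#' @export
print.wmkrr_fit <- function(x, ...) {
  cat(sprintf("wmkrr_fit: n_train=%d, lambda=%.4g, y_mean=%.4g, kernel=%s\n",
              length(x$alpha), x$lambda_reg, x$y_mean, x$kernel_spec$kind))
  invisible(x)
}

#' Predict from a fitted kernel ridge regression
#'
#' @param model a `wmkrr_fit` from [fit_krr()].
#' @param k_rows `n_test x n_train` cross-kernel matrix whose rows are the
#'   `k'` similarity vectors of the test samples to all training samples,
#'   built with the model's kernel kind, `theta`, `w1` and training feature
#'   scaling.
#' @return numeric vector `k_rows %*% alpha + y_mean`.
#' @export
predict_krr <- function(model, k_rows) {
  stopifnot(inherits(model, "wmkrr_fit"))
  if (!is.matrix(k_rows)) k_rows <- matrix(as.numeric(k_rows), nrow = 1)
  if (ncol(k_rows) != length(model$alpha))
    stop("k_rows has ", ncol(k_rows), " columns but model has ",
         length(model$alpha), " training samples")
  as.numeric(k_rows %*% model$alpha + model$y_mean)
}

#' Serialize a fitted model to a versioned JSON file
#' @param model a `wmkrr_fit`.
#' @param path output path.
#' @export
save_krr <- function(model, path) {
  stopifnot(inherits(model, "wmkrr_fit"))
  obj <- list(format = "wmkrr_fit", version = 1L,
              alpha = model$alpha, lambda_reg = model$lambda_reg,
              y_mean = model$y_mean, kernel_spec = model$kernel_spec,
              train_ids = model$train_ids,
              jitter_applied = model$jitter_applied)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a serialized fitted model
#' @param path file written by [save_krr()].
#' @export
load_krr <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "wmkrr_fit"))
    stop("not a wmkrr_fit file: ", path)
  structure(list(alpha = as.numeric(obj$alpha),
                 lambda_reg = obj$lambda_reg, y_mean = obj$y_mean,
                 kernel_spec = as.list(obj$kernel_spec),
                 train_ids = obj$train_ids,
                 jitter_applied = obj$jitter_applied %||% 0),
            class = "wmkrr_fit")
}
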