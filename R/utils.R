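# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a master seed
#'
#' All stochastic operations in the package draw their seed from a single
#' master seed through this function, so that partial reruns of a pipeline
#' (e.g. re-simulating only phenotypes) stay consistent with the full run.
#' The derivation is a 31-bit multiplicative hash of the label characters
#' and an index, so distinct labels/indices give effectively independent
#' streams.
#'
#' @param master integer master seed.
#' @param label character tag naming the consumer (e.g. `"phenotype"`).
#' @param index integer stream index within the label (e.g. replicate).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, label, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  h <- abs(as.double(master)) %% 2147483647
  for (ch in utf8ToInt(as.character(label))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  h <- (h * 31 + abs(as.double(index))) %% 2147483647
  as.integer(h)
}

# Evaluate expr with a locally-set RNG seed, restoring the caller's RNG
# state afterwards. seed = NULL leaves the global stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Cholesky solve of A x = b for symmetric A, escalating diagonal jitter
# (relative to mean(diag)) when the factorization fails.  Returns x plus
# the jitter actually applied so callers can record it.
chol_solve_sym <- function(A, b, jitter_base = 1e-8) {
  R <- tryCatch(chol(A), error = function(e) NULL)
  jit <- 0
  if (is.null(R)) {
    sc <- mean(diag(A))
    if (!is.finite(sc) || sc <= 0) sc <- 1
    for (f in c(1, 1e2, 1e4, 1e6)) {
      jit <- jitter_base * sc * f
      R <- tryCatch(chol(A + diag(jit, nrow(A))), error = function(e) NULL)
      if (!is.null(R)) break
    }
    if (is.null(R)) stop("symmetric factorization failed even after jitter")
  }
  x <- backsolve(R, forwardsolve(t(R), b))
  if (is.matrix(b)) dimnames(x) <- dimnames(b) else names(x) <- names(b)
  list(x = x, jitter = jit, chol = R)
}

# log-determinant from an upper-triangular Cholesky factor
chol_logdet <- function(R) 2 * sum(log(diag(R)))

stop_if_not_ids <- function(ids, what) {
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicated %s ids: %s", what,
                 paste(unique(ids[duplicated(ids)])[1:3], collapse = ", ")))
  }
  invisible(ids)
}
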