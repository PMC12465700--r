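# Bayesian optimization of the WMKRR hyperparameters (w1, lambda, theta):
# random initial design, Gaussian-process surrogate, expected-improvement
# acquisition, inner cross-validated Pearson correlation as the objective.

#' Expected improvement acquisition value
#'
#' `EI = (mu - best - xi) * Phi(z) + sigma * phi(z)` with
#' `z = (mu - best - xi) / sigma`; when `sigma = 0` it degenerates to
#' `max(0, mu - best - xi)`.  Used for maximization.
#'
#' @param mu surrogate posterior mean at the candidate.
#' @param sigma surrogate posterior standard deviation (non-negative).
#' @param best incumbent (best objective value so far).
#' @param xi non-negative exploration margin.
#' @return non-negative expected improvement (vectorized over
#'   `mu`/`sigma`).
#' @export
expected_improvement <- function(mu, sigma, best, xi = 0) {
  stopifnot(all(sigma >= 0), xi >= 0)
  d <- mu - best - xi
  ei <- pmax(d, 0)
  pos <- sigma > 0
  if (any(pos)) {
    z <- d[pos] / sigma[pos]
    ei[pos] <- d[pos] * stats::pnorm(z) + sigma[pos] * stats::dnorm(z)
  }
  pmax(ei, 0)
}

#' Inner cross-validated Pearson objective for one hyperparameter point
#'
#' Fuses the two precomputed kernels at `w1`, and for each inner fold fits
#' KRR on the in-fold training block and predicts the held-out block from
#' its cross-kernel rows.  Returns the Pearson correlation between the
#' concatenated held-out predictions and observations.  The same `folds`
#' must be reused for every candidate point of a tuning run so that all
#' points are scored on identical partitions.
#'
#' @param w1 kernel-a weight in `[0, 1]`.
#' @param lambda ridge penalty.
#' @param Ka,Kb n x n kernel matrices (plain matrices or
#'   [kernel_matrix()]) over the training individuals.
#' @param y response.
#' @param folds integer fold labels partitioning the training individuals.
#' @param center_y passed to [fit_krr()].
#' @return Pearson correlation (0 with a warning if the predictions are
#'   constant).
#' @export
inner_cv_objective <- function(w1, lambda, Ka, Kb, y, folds,
                               center_y = TRUE) {
  if (inherits(Ka, "kernel_matrix")) Ka <- Ka$values
  if (inherits(Kb, "kernel_matrix")) Kb <- Kb$values
  n <- length(y)
  stopifnot(nrow(Ka) == n, nrow(Kb) == n, length(folds) == n)
  K <- w1 * Ka + (1 - w1) * Kb
  pred <- numeric(n)
  for (f in unique(folds)) {
    te <- which(folds == f)
    tr <- which(folds != f)
    fit <- fit_krr(K[tr, tr, drop = FALSE], y[tr], lambda_reg = lambda,
                   center_y = center_y)
    pred[te] <- predict_krr(fit, K[te, tr, drop = FALSE])
  }
  if (stats::sd(pred) < 1e-14) {
    warning("constant held-out predictions; objective set to 0")
    return(0)
  }
  stats::cor(pred, y)
}

#' Tune WMKRR hyperparameters by Bayesian optimization
#'
#' Implements the five-step loop: (i) evaluate `n_initial` random points;
#' (ii) fit a Gaussian-process surrogate to all evaluations; (iii) choose
#' the next point by maximizing expected improvement over a random
#' candidate set; (iv) repeat for `n_iterations` iterations; (v) return the
#' best-scoring point of the whole trace.  The objective is the inner
#' cross-validated Pearson correlation of [inner_cv_objective()].
#'
#' In linear mode `Ka`/`Kb` are fixed kernels and the search space is
#' `(w1, log10 lambda)`.  In Gaussian mode `D2a`/`D2b` are squared-distance
#' matrices and the kernels are rebuilt per candidate as
#' `exp(-theta * D2)`, adding `log10 theta` to the space (a single `theta`
#' shared by both kernels by default; pass `share_theta = FALSE` for
#' per-kernel bandwidths).
#'
#' @param y response over the training individuals.
#' @param Ka,Kb precomputed kernels (linear mode).
#' @param D2a,D2b precomputed squared Euclidean distance matrices
#'   (Gaussian mode).
#' @param kind `"linear"` or `"gaussian"`.
#' @param bounds named list of 2-vectors for `w1`, `log10_lambda` and (for
#'   Gaussian) `log10_theta`.
#' @param n_initial random points in the initial design.
#' @param n_iterations surrogate-guided evaluations after the initial
#'   design (the package default matches the 200-iteration budget used for
#'   the method's published configuration).
#' @param inner_k inner CV fold count; folds are drawn once per call.
#' @param seed integer seed; the whole trace is reproducible given the
#'   seed.
#' @param share_theta share one bandwidth between both Gaussian kernels.
#' @param ei_xi exploration margin of the EI acquisition.
#' @param n_candidates size of the random candidate set scanned for the
#'   EI argmax each iteration.
#' @return list with `best` (named list `w1`, `lambda`, `theta`,
#'   `objective`), `trace` (data.frame of all evaluations in order),
#'   `best_index`, `folds`, `seed`.
#' @export
tune_wmkrr <- function(y, Ka = NULL, Kb = NULL, D2a = NULL, D2b = NULL,
                       kind = c("linear", "gaussian"),
                       bounds = list(w1 = c(0, 1),
                                     log10_lambda = c(-3, 3),
                                     log10_theta = c(-6, 1)),
                       n_initial = 10, n_iterations = 200, inner_k = 5,
                       seed = NULL, share_theta = TRUE, ei_xi = 0.01,
                       n_candidates = 1024) {
  kind <- match.arg(kind)
  stopifnot(n_iterations >= 1, n_initial >= 1)
  n <- length(y)
  if (kind == "linear") {
    if (inherits(Ka, "kernel_matrix")) Ka <- Ka$values
    if (inherits(Kb, "kernel_matrix")) Kb <- Kb$values
    stopifnot(!is.null(Ka), !is.null(Kb))
    dims <- c("w1", "log10_lambda")
  } else {
    stopifnot(!is.null(D2a), !is.null(D2b))
    dims <- if (share_theta) c("w1", "log10_lambda", "log10_theta")
            else c("w1", "log10_lambda", "log10_theta_a", "log10_theta_b")
  }
  lo <- vapply(dims, function(d) {
    b <- bounds[[sub("_[ab]$", "", d)]]
    if (is.null(b)) stop("bounds missing for ", d)
    b[1]
  }, 0)
  hi <- vapply(dims, function(d) bounds[[sub("_[ab]$", "", d)]][2], 0)
  d <- length(dims)

  eval_point <- function(u) {
    # u in [0,1]^d -> native scale
    x <- lo + u * (hi - lo)
    names(x) <- dims
    w1 <- x[["w1"]]
    lambda <- 10^x[["log10_lambda"]]
    if (kind == "linear") {
      Kaf <- Ka; Kbf <- Kb; th <- c(NA_real_, NA_real_)
    } else {
      th_a <- 10^x[[if (share_theta) "log10_theta" else "log10_theta_a"]]
      th_b <- 10^x[[if (share_theta) "log10_theta" else "log10_theta_b"]]
      Kaf <- exp(-th_a * D2a); diag(Kaf) <- 1
      Kbf <- exp(-th_b * D2b); diag(Kbf) <- 1
      th <- c(th_a, th_b)
    }
    obj <- suppressWarnings(
      inner_cv_objective(w1, lambda, Kaf, Kbf, y, folds))
    list(x = x, w1 = w1, lambda = lambda, theta = th, objective = obj)
  }

  with_seed(seed, {
    folds <- sample(rep_len(seq_len(inner_k), n))
    U <- matrix(stats::runif(n_initial * d), n_initial, d)
    evals <- apply(U, 1, eval_point)
    for (it in seq_len(n_iterations)) {
      obj_seen <- vapply(evals, `[[`, 0, "objective")
      ok <- is.finite(obj_seen)
      if (!any(ok)) stop("all hyperparameter evaluations non-finite")
      cand <- matrix(stats::runif(n_candidates * d), n_candidates, d)
      gp <- tryCatch(gp_fit(U[ok, , drop = FALSE], obj_seen[ok]),
                     error = function(e) NULL)
      if (is.null(gp)) {
        u_next <- cand[1, ]
      } else {
        post <- gp_predict(gp, cand)
        ei <- expected_improvement(post$mean, post$sd, max(obj_seen[ok]),
                                   xi = ei_xi)
        u_next <- cand[which.max(ei), ]
      }
      U <- rbind(U, u_next)
      evals[[length(evals) + 1]] <- eval_point(u_next)
    }
  })

  obj_all <- vapply(evals, `[[`, 0, "objective")
  trace <- data.frame(
    iter = seq_along(evals),
    phase = rep(c("initial", "bo"), c(n_initial, n_iterations)),
    w1 = vapply(evals, `[[`, 0, "w1"),
    lambda = vapply(evals, `[[`, 0, "lambda"),
    theta_a = vapply(evals, function(e) e$theta[1], 0),
    theta_b = vapply(evals, function(e) e$theta[2], 0),
    objective = obj_all)
  best_index <- which.max(ifelse(is.finite(obj_all), obj_all, -Inf))
  be <- evals[[best_index]]
  list(best = list(w1 = be$w1, lambda = be$lambda,
                   theta = if (kind == "gaussian") be$theta[1] else NA_real_,
                   theta_b = if (kind == "gaussian" && !share_theta)
                     be$theta[2] else NULL,
                   objective = be$objective),
       trace = trace, best_index = best_index, folds = folds, seed = seed)
}
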