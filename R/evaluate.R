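# Cross-validation / forward-validation orchestration and all evaluation
# metrics: predictive ability (optionally corrected by mean DRP accuracy),
# unbiasedness, centered RMSE, DRP reliability arithmetic, Spearman
# accuracy.

#' Repeated k-fold cross-validation plan
#'
#' Uniform random partitions with fold sizes differing by at most one.
#' The same plan must be reused by every method compared within a repeat,
#' so that reference and validation populations stay constant across
#' methods.
#'
#' @param ids individual identifiers.
#' @param k folds per repeat.
#' @param repeats repeats.
#' @param seed integer seed.
#' @return object of class `fold_plan`: `ids`, `k`, `repeats`,
#'   `assignments` (n x repeats integer matrix), `seed`.
#' @export
make_cv_folds <- function(ids, k = 10, repeats = 5, seed = NULL) {
  n <- length(ids)
  if (n < k) stop("fewer individuals (", n, ") than folds (", k, ")")
  A <- with_seed(seed, {
    vapply(seq_len(repeats),
           function(r) sample(rep_len(seq_len(k), n)), integer(n))
  })
  structure(list(ids = as.character(ids), k = k, repeats = repeats,
                 assignments = A, seed = seed),
            class = "fold_plan")
}

#' Forward-validation split by birth year
#'
#' Training on older animals, validating on the youngest cohort:
#' individuals with `birth_year >= cutoff_year` form the validation set.
#'
#' @param ids individual identifiers.
#' @param birth_year integer birth years aligned with `ids`.
#' @param cutoff_year first validation birth year.
#' @return list with `reference` and `validation` id vectors.
#' @export
forward_split <- function(ids, birth_year, cutoff_year) {
  stopifnot(length(ids) == length(birth_year))
  val <- !is.na(birth_year) & birth_year >= cutoff_year
  if (!any(val)) stop("no individuals at or after the cutoff year")
  if (all(val)) stop("no reference individuals before the cutoff year")
  list(reference = as.character(ids[!val]),
       validation = as.character(ids[val]))
}

#' Predictive ability
#'
#' Pearson correlation between observations and predictions, divided by
#' the mean DRP accuracy `r_bar` of the validation individuals (the mean
#' of the square roots of their DRP reliabilities) in DRP mode, or by 1
#' for simulated phenotypes.
#'
#' @param obs,pred aligned numeric vectors (at least 3 pairs).
#' @param mean_acc `r_bar`, or 1 when the response is a simulated
#'   phenotype.
#' @return numeric; `NA` with a warning when either vector is constant.
#' @export
predictive_ability <- function(obs, pred, mean_acc = 1) {
  stopifnot(length(obs) == length(pred), length(obs) >= 3, mean_acc > 0)
  if (stats::sd(obs) == 0 || stats::sd(pred) == 0) {
    warning("constant vector: predictive ability undefined")
    return(NA_real_)
  }
  stats::cor(obs, pred) / mean_acc
}

#' Unbiasedness (regression slope of observations on predictions)
#'
#' OLS slope of `obs` on `pred`; 1 indicates neither inflation nor
#' deflation of the predictions.
#'
#' @param obs,pred aligned numeric vectors.
#' @return slope; `NA` with a warning when `pred` is constant.
#' @export
unbiasedness <- function(obs, pred) {
  stopifnot(length(obs) == length(pred))
  if (stats::var(pred) == 0) {
    warning("constant predictions: slope undefined")
    return(NA_real_)
  }
  stats::cov(obs, pred) / stats::var(pred)
}

#' Centered root-mean-square error
#'
#' Both vectors are mean-centered before the root-mean-square difference,
#' so the metric is invariant to a constant shift of either vector.
#'
#' @param obs,pred aligned numeric vectors (at least 2 pairs).
#' @return non-negative RMSE.
#' @export
rmse_centered <- function(obs, pred) {
  stopifnot(length(obs) == length(pred), length(obs) >= 2)
  sqrt(mean(((pred - mean(pred)) - (obs - mean(obs)))^2))
}

#' DRP reliability arithmetic
#'
#' From an EBV reliability `REL` and trait heritability `h2`:
#' `lambda_h = (1 - h2) / h2`, effective record contribution
#' `ERC = lambda_h * REL / (1 - REL)`, and DRP reliability
#' `r2_DRP = ERC / (ERC + lambda_h)`.  As printed, the two formulas
#' compose to `r2_DRP = REL`; both intermediate quantities are exposed.
#'
#' @param rel EBV reliability in `[0, 1)` (vectorized).
#' @param h2_trait trait heritability in `(0, 1)`.
#' @return data.frame with columns `rel`, `h2`, `lambda_h`, `erc`,
#'   `r2_drp`.
#' @export
drp_reliability <- function(rel, h2_trait) {
  stopifnot(h2_trait > 0, h2_trait < 1)
  if (any(rel < 0 | rel >= 1)) stop("rel must lie in [0,1) (rel = 1 gives infinite ERC)")
  lambda_h <- (1 - h2_trait) / h2_trait
  erc <- lambda_h * rel / (1 - rel)
  data.frame(rel = rel, h2 = h2_trait, lambda_h = lambda_h, erc = erc,
             r2_drp = erc / (erc + lambda_h))
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ties); the accuracy measure
#' for predicted gene expression.
#'
#' @param x,y aligned numeric vectors (at least 3 pairs).
#' @return correlation in `[-1, 1]`; `NA` with a warning for constant
#'   input.
#' @export
spearman <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

# ---- method runners ------------------------------------------------------

# Fit/predict one method on one train/validation split.  Returns the
# validation predictions on the response scale.
run_method_fold <- function(method, geno, expr, y, train_idx, val_idx,
                            kernel_kind, fs_k, tune_cfg, seed) {
  snps <- seq_len(ncol(geno$dosages))
  if (!is.null(fs_k)) {
    sc <- univariate_scores(geno$dosages[train_idx, , drop = FALSE],
                            y[train_idx])
    snps <- select_top_k(sc, fs_k)
  }
  Xg <- geno$dosages[, snps, drop = FALSE]
  freq <- colMeans(Xg) / 2

  if (method == "GBLUP" || method == "GTBLUP") {
    gsub <- geno_matrix(Xg, individual_ids = geno$individual_ids,
                        snp_ids = geno$snp_ids[snps], freq = freq)
    G <- vanraden_g(gsub)
    kerns <- list(G)
    if (method == "GTBLUP") {
      if (is.null(expr)) stop("GTBLUP requires expression data")
      kerns <- c(kerns, list(expression_e(expr)))
    }
    kerns_tr <- lapply(kerns, function(K)
      K$values[train_idx, train_idx, drop = FALSE])
    vc <- estimate_variance_components(y[train_idx], kerns_tr)
    bl <- blup_predict(y[train_idx], vc, kerns, observed = train_idx)
    return(bl$pred[val_idx])
  }

  if (method != "WMKRR") stop("unknown method: ", method)
  # WMKRR: train-scaled features, tuned (w1, lambda[, theta])
  sfa <- standardize_features(Xg[train_idx, , drop = FALSE])
  Xa <- apply_standardization(Xg, sfa)
  if (is.null(expr)) stop("WMKRR requires expression data")
  Xe <- expr$values
  sfb <- standardize_features(Xe[train_idx, , drop = FALSE])
  Xb <- apply_standardization(Xe, sfb)
  if (kernel_kind == "linear") {
    Ka <- tcrossprod(Xa) / ncol(Xa)
    Kb <- tcrossprod(Xb) / ncol(Xb)
    tn <- tune_wmkrr(y[train_idx],
                     Ka = Ka[train_idx, train_idx, drop = FALSE],
                     Kb = Kb[train_idx, train_idx, drop = FALSE],
                     kind = "linear",
                     n_initial = tune_cfg$n_initial,
                     n_iterations = tune_cfg$n_iterations,
                     inner_k = tune_cfg$inner_k, seed = seed)
    Kfull <- tn$best$w1 * Ka + (1 - tn$best$w1) * Kb
  } else {
    D2a <- sq_dist(Xa) / ncol(Xa)  # per-feature scaling keeps theta O(1)
    D2b <- sq_dist(Xb) / ncol(Xb)
    tn <- tune_wmkrr(y[train_idx],
                     D2a = D2a[train_idx, train_idx, drop = FALSE],
                     D2b = D2b[train_idx, train_idx, drop = FALSE],
                     kind = "gaussian",
                     n_initial = tune_cfg$n_initial,
                     n_iterations = tune_cfg$n_iterations,
                     inner_k = tune_cfg$inner_k, seed = seed)
    Kaf <- exp(-tn$best$theta * D2a)
    Kbf <- exp(-(tn$best$theta_b %||% tn$best$theta) * D2b)
    Kfull <- tn$best$w1 * Kaf + (1 - tn$best$w1) * Kbf
  }
  fit <- fit_krr(Kfull[train_idx, train_idx, drop = FALSE], y[train_idx],
                 lambda_reg = tn$best$lambda)
  predict_krr(fit, Kfull[val_idx, train_idx, drop = FALSE])
}

#' Run a multi-method comparison under a shared validation plan
#'
#' Executes the configured methods over repeated k-fold cross-validation
#' (or a forward split) with a byte-identical fold plan for every method,
#' per-fold feature selection restricted to training rows, and per-repeat
#' metrics aggregated by averaging over repeats.
#'
#' @param config list with elements:
#'   \describe{
#'     \item{geno}{a [geno_matrix()].}
#'     \item{pheno}{a [pheno_table()] aligned with `geno` (matched by id).}
#'     \item{expr}{an [expr_matrix()] (required for GTBLUP/WMKRR).}
#'     \item{methods}{character subset of `GBLUP`, `GTBLUP`, `WMKRR`.}
#'     \item{kernel_kind}{`"linear"` or `"gaussian"` (WMKRR).}
#'     \item{fs_k}{top-k SNP count for per-fold feature selection, or
#'       `NULL` to use all SNPs.}
#'     \item{cv}{list `k`, `repeats` — or `forward = list(cutoff_year=)`.}
#'     \item{tune}{list `n_initial`, `n_iterations`, `inner_k`.}
#'     \item{drp_mode}{if `TRUE`, divide predictive ability by the mean
#'       DRP accuracy computed from `pheno$rel`.}
#'     \item{seed}{master seed.}
#'   }
#' @return object of class `metric_report`: `per_repeat` (data.frame:
#'   method, repeat, predictive_ability, unbiasedness, rmse),
#'   `aggregated` (mean over repeats), `failures` (data.frame of caught
#'   per-fold errors), `plan`.
#' @export
run_comparison <- function(config) {
  geno <- config$geno
  pheno <- config$pheno
  expr <- config$expr %||% NULL
  methods <- config$methods %||% "GBLUP"
  kernel_kind <- config$kernel_kind %||% "linear"
  fs_k <- config$fs_k %||% NULL
  tune_cfg <- utils::modifyList(
    list(n_initial = 10, n_iterations = 200, inner_k = 5),
    config$tune %||% list())
  seed <- config$seed %||% 1L
  stopifnot(inherits(geno, "geno_matrix"), inherits(pheno, "pheno_table"))
  idx <- match(geno$individual_ids, pheno$id)
  if (anyNA(idx)) stop("phenotype missing for some genotyped individuals")
  y <- pheno$y[idx]
  rel <- if ("rel" %in% names(pheno)) pheno$rel[idx] else NULL
  n <- length(y)

  if (!is.null(config$forward)) {
    by <- pheno$birth_year[idx]
    sp <- forward_split(geno$individual_ids, by,
                        config$forward$cutoff_year)
    splits <- list(list(repeat_id = 1L, folds = list(
      match(sp$validation, geno$individual_ids))))
    plan <- sp
  } else {
    cv <- utils::modifyList(list(k = 10, repeats = 5), config$cv %||% list())
    plan <- make_cv_folds(geno$individual_ids, k = cv$k,
                          repeats = cv$repeats,
                          seed = derive_seed(seed, "folds"))
    splits <- lapply(seq_len(cv$repeats), function(r) {
      list(repeat_id = r,
           folds = lapply(seq_len(cv$k),
                          function(f) which(plan$assignments[, r] == f)))
    })
  }

  per_repeat <- list()
  failures <- list()
  for (sp in splits) {
    for (method in methods) {
      pred <- rep(NA_real_, n)
      for (fi in seq_along(sp$folds)) {
        val_idx <- sp$folds[[fi]]
        train_idx <- setdiff(seq_len(n), val_idx)
        fseed <- derive_seed(seed, paste0("tune_", method),
                             sp$repeat_id * 1000 + fi)
        res <- tryCatch(
          run_method_fold(method, geno, expr, y, train_idx, val_idx,
                          kernel_kind, fs_k, tune_cfg, fseed),
          error = function(e) e)
        if (inherits(res, "error")) {
          failures[[length(failures) + 1]] <-
            data.frame(method = method, repeat_id = sp$repeat_id,
                       fold = fi, message = conditionMessage(res))
        } else {
          pred[val_idx] <- res
        }
      }
      got <- which(!is.na(pred))
      mean_acc <- if (isTRUE(config$drp_mode) && !is.null(rel))
        mean(sqrt(rel[got])) else 1
      per_repeat[[length(per_repeat) + 1]] <- data.frame(
        method = method, repeat_id = sp$repeat_id,
        predictive_ability =
          predictive_ability(y[got], pred[got], mean_acc),
        unbiasedness = unbiasedness(y[got], pred[got]),
        rmse = rmse_centered(y[got], pred[got]),
        n_predicted = length(got))
    }
  }
  per_repeat <- do.call(rbind, per_repeat)
  agg <- stats::aggregate(
    per_repeat[c("predictive_ability", "unbiasedness", "rmse")],
    by = list(method = per_repeat$method), FUN = mean)
  structure(list(per_repeat = per_repeat, aggregated = agg,
                 failures = if (length(failures)) do.call(rbind, failures)
                 else NULL,
                 plan = plan),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Aggregated metrics (mean over repeats):\n")
  print(x$aggregated, row.names = FALSE)
  if (!is.null(x$failures))
    cat(nrow(x$failures), "fold-level failures recorded\n")
  invisible(x)
}
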