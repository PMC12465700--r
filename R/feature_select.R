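# Univariate SNP feature selection: per-SNP regression F statistic with
# the response, top-k selection with stable tie-breaking.  Always applied
# to training rows only so that marker selection never sees validation
# responses.

#' Univariate association scores for every SNP
#'
#' Score of SNP `j` is the F statistic of the simple linear regression of
#' `y` on its dosage, `F = (n - 2) r^2 / (1 - r^2)` — a monotone transform
#' of the squared correlation, so the induced ranking is the squared
#' correlation ranking.  Constant SNPs score 0.
#'
#' @param geno a [geno_matrix()] or plain dosage matrix (training rows
#'   only).
#' @param y training response.
#' @return object of class `feature_scores`: `snp_ids`, `scores`, `rank`
#'   (permutation; rank 1 = highest score, ties broken by original SNP
#'   order).
#' @export
univariate_scores <- function(geno, y) {
  X <- if (inherits(geno, "geno_matrix")) geno$dosages else as.matrix(geno)
  n <- nrow(X)
  if (n < 3) stop("need at least 3 training individuals")
  if (stats::sd(y) == 0) stop("zero-variance response")
  if (length(y) != n) stop("response length mismatch")
  yc <- y - mean(y)
  Xc <- sweep(X, 2, colMeans(X))
  sx2 <- colSums(Xc^2)
  r2 <- ifelse(sx2 > 0,
               (as.numeric(crossprod(Xc, yc)))^2 / (sx2 * sum(yc^2)), 0)
  r2 <- pmin(r2, 1 - 1e-12)
  scores <- ifelse(sx2 > 0, (n - 2) * r2 / (1 - r2), 0)
  ord <- order(-scores, seq_along(scores))
  structure(list(snp_ids = colnames(X) %||% paste0("snp", seq_len(ncol(X))),
                 scores = unname(scores), rank = order(ord)),
            class = "feature_scores")
}

#' Select the top-k scoring SNPs
#'
#' Returns the indices of the `k` highest-scoring SNPs (all SNPs when
#' `k >= p`), with ties at the boundary broken in favour of the
#' earlier-indexed SNP for reproducibility.  The default `k` matches the
#' 30,000-SNP selection used in the reference workflow.
#'
#' @param scores a `feature_scores` from [univariate_scores()].
#' @param k number of SNPs to keep.
#' @return sorted integer vector of selected SNP indices.
#' @export
select_top_k <- function(scores, k = 30000) {
  stopifnot(inherits(scores, "feature_scores"), k >= 1)
  p <- length(scores$scores)
  ord <- order(-scores$scores, seq_len(p))
  sort(ord[seq_len(min(k, p))])
}
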