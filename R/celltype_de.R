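#' Marker-signature score per spot
#'
#' The mean normalised expression of a marker list (e.g. a keratinocyte
#' panel) in each spot.
#'
#' @param norm Normalised features x spots matrix from
#'   [lognormalize()].
#' @param markers Character vector of feature ids; every marker must be
#'   present in the matrix.
#' @return Named numeric vector of per-spot scores.
#' @export
signature_score <- function(norm, markers) {
  missing <- setdiff(markers, rownames(norm))
  if (length(missing))
    abort("markers absent from the matrix: ",
          paste(missing, collapse = ", "))
  Matrix::colMeans(norm[markers, , drop = FALSE])
}

#' Label spots by signature score
#'
#' A spot is positive iff its score is strictly greater than the given
#' quantile of all scores (strict, so a constant score vector labels no
#' spot).
#'
#' @param scores Numeric vector from [signature_score()].
#' @param quantile Quantile threshold in `[0, 1)` (default 0.75).
#' @return Logical vector, same names/order as `scores`.
#' @export
label_spots <- function(scores, quantile = 0.75) {
  scores > stats::quantile(scores, quantile)
}

#' Wilcoxon rank-sum differential expression between spot groups
#'
#' Tests every sufficiently detected feature for a difference in
#' normalised expression between labelled and unlabelled spots with a
#' two-sided Wilcoxon rank-sum test (mid-ranks for ties; the exact null
#' distribution when both groups have at most 8 spots and there are no
#' ties, otherwise the normal approximation with tie and continuity
#' correction). P-values are Benjamini-Hochberg adjusted across the
#' tested features. A feature whose values are identical in both groups
#' gets p = 1 by convention.
#'
#' @param norm Normalised features x spots matrix.
#' @param labels Logical vector over the matrix columns (group 1 =
#'   `TRUE`).
#' @param min_detect_frac Features detected (value > 0) in fewer than
#'   this fraction of spots are not tested.
#' @return data.frame with one row per tested feature: `feature`,
#'   `n1`, `n2`, `U` (rank-sum statistic of group 1), `p`, `q`,
#'   `log2fc` (log2 ratio of group means with pseudocount 1) and
#'   `direction` (`"up"` = higher in labelled spots).
#' @export
wilcoxon_de <- function(norm, labels, min_detect_frac = 0.05) {
  stopifnot(length(labels) == ncol(norm))
  n1 <- sum(labels); n2 <- sum(!labels)
  if (n1 == 0L || n2 == 0L)
    abort("both spot groups must be non-empty")
  detected <- Matrix::rowMeans(norm > 0) >= min_detect_frac
  feats <- rownames(norm)[detected]
  if (!length(feats))
    abort("no feature passes the detection filter")
  m <- as.matrix(norm[detected, , drop = FALSE])

  res <- lapply(seq_len(nrow(m)), function(i) {
    x <- m[i, labels]; y <- m[i, !labels]
    if (all(x == x[1]) && all(y == y[1]) && x[1] == y[1]) {
      return(c(U = n1 * n2 / 2, p = 1))
    }
    exact <- n1 <= 8L && n2 <= 8L && !anyDuplicated(c(x, y))
    wt <- suppressWarnings(
      wilcox.test(x, y, exact = exact, correct = TRUE))
    c(U = unname(wt$statistic), p = wt$p.value)
  })
  res <- do.call(rbind, res)
  mean1 <- rowMeans(m[, labels, drop = FALSE])
  mean2 <- rowMeans(m[, !labels, drop = FALSE])
  log2fc <- log2((mean1 + 1) / (mean2 + 1))
  data.frame(
    feature = feats, n1 = n1, n2 = n2,
    U = res[, "U"], p = res[, "p"], q = bh_adjust(res[, "p"]),
    log2fc = log2fc,
    direction = ifelse(log2fc >= 0, "up", "down"),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; input order is preserved.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0) || any(pvals > 1))
    abort("p-values must lie in [0, 1] and not be NA")
  p.adjust(pvals, method = "BH")
}

#' Spatial concordance between a signature and a feature
#'
#' Spearman rank correlation (mid-ranks) between the per-spot signature
#' score and a feature's per-spot values, with a two-sided p-value from
#' the t approximation. Quantifies whether a uTAR's spatial expression
#' pattern follows a marker signature.
#'
#' @param scores,values Equal-length per-spot numeric vectors
#'   (n >= 5).
#' @return List with `rho`, `p`, `n` and `ok` (`FALSE`, with `rho`/`p`
#'   `NA`, when either vector has zero variance).
#' @export
spatial_concordance <- function(scores, values) {
  if (length(scores) != length(values))
    abort("scores and values must have equal length")
  n <- length(scores)
  if (n < 5L) abort("concordance requires at least 5 spots")
  if (var(scores) == 0 || var(values) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n, ok = FALSE))
  ct <- suppressWarnings(
    cor.test(scores, values, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = n, ok = TRUE)
}
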