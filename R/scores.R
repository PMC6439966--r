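#' Raw-count reactivity score
#'
#' The simplest reactivity index: the mean raw truncation count across one
#' condition's replicates at each position.
#'
#' @param x a [count_table].
#' @param condition `"case"` or `"cont"`.
#' @return Numeric vector of length `L` with attribute `method = "count"`.
#' @export
score_count <- function(x, condition = "case") {
  stopifnot(inherits(x, "count_table"))
  cols <- which(x$condition == condition)
  if (!length(cols)) stop("no '", condition, "' samples present")
  structure(rowMeans(x$counts[, cols, drop = FALSE]), method = "count")
}

#' Coverage-ratio reactivity score
#'
#' Truncation count at a position divided by the number of reads passing
#' through it. With truncation (5'-end) counts, a read truncated at any
#' position `j >= i` of the same transcript passed through `i`, so the
#' pass-through coverage is the within-transcript suffix sum of counts. The
#' per-replicate ratios `c_i / T_i` are averaged across the condition's
#' replicates; positions with zero pass-through coverage are missing (`NA`).
#'
#' @inheritParams score_count
#' @return Numeric vector in `[0, 1]` (or `NA`), attribute `method = "ratio"`.
#' @export
score_ratio <- function(x, condition = "case") {
  stopifnot(inherits(x, "count_table"))
  cols <- which(x$condition == condition)
  if (!length(cols)) stop("no '", condition, "' samples present")
  ratios <- vapply(cols, function(k) {
    r <- rep(NA_real_, nrow(x$counts))
    for (tx in unique(x$transcript)) {
      idx <- which(x$transcript == tx)
      c_k <- x$counts[idx, k]
      suffix <- rev(cumsum(rev(c_k)))
      r[idx] <- ifelse(suffix > 0, c_k / suffix, NA_real_)
    }
    r
  }, numeric(nrow(x$counts)))
  ratios <- matrix(ratios, nrow = nrow(x$counts))
  out <- rowMeans(ratios, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  structure(out, method = "ratio")
}

#' ROC curve and AUROC against reference labels
#'
#' Threshold-sweep receiver operating characteristic with midrank handling of
#' tied scores; the AUC equals the (normalized) Mann-Whitney U statistic, i.e.
#' the probability that a random positive outscores a random negative, counting
#' ties as one half. Positions labelled `unknown`/`unmapped` and positions with
#' missing scores are excluded.
#'
#' @param scores numeric score vector (higher = more confident positive).
#' @param labels per-position labels; `loop`/`stem` (or `stem_bg`) are used,
#'   everything else is excluded.
#' @param positive which label counts as positive, `"loop"` or `"stem"`.
#' @return List with `auc`, `curve` (`data.frame` of `fpr`, `tpr`), `n_pos`,
#'   `n_neg`, `n_excluded`.
#' @export
roc_auc <- function(scores, labels, positive = c("loop", "stem")) {
  positive <- match.arg(positive)
  labels <- as.character(labels)
  labels[labels == "stem_bg"] <- "stem"
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length")
  keep <- labels %in% c("loop", "stem") & !is.na(scores)
  n_excluded <- sum(!keep)
  y <- labels[keep] == positive
  s <- scores[keep]
  n_pos <- sum(y); n_neg <- sum(!y)
  if (n_pos == 0L || n_neg == 0L)
    stop("ROC needs at least one positive and one negative labelled position")
  r <- rank(s)  # midranks
  auc <- (sum(r[y]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  # threshold sweep over unique scores, descending; ties enter together
  ord <- order(s, decreasing = TRUE)
  tp <- cumsum(y[ord]); fp <- cumsum(!y[ord])
  last <- !duplicated(s[ord], fromLast = TRUE)  # last index of each tie group
  curve <- data.frame(fpr = c(0, fp[last] / n_neg), tpr = c(0, tp[last] / n_pos))
  list(auc = auc, curve = curve, n_pos = n_pos, n_neg = n_neg,
       n_excluded = n_excluded)
}
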