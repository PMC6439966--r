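#' Rank-normalize a count table to (0, 1)
#'
#' Converts raw truncation counts to scaled ascending ranks: within each sample
#' column, every count is replaced by `rank / (N + 1)` where `N` is the number
#' of ranked positions, so larger counts map to larger values and all values lie
#' strictly inside (0, 1). These scaled ranks are treated as realizations of the
#' marginal cumulative distribution of the mixture copula model.
#'
#' Ties are broken by midranks (average rank) by default, which is deterministic
#' and standard rank-copula practice; `ties = "random"` breaks ties uniformly at
#' random under `seed`.
#'
#' @param x a [count_table].
#' @param global logical; if `TRUE` (default) ranks are computed across the full
#'   concatenated position axis, otherwise per transcript.
#' @param ties `"midrank"` (default) or `"random"`.
#' @param seed integer seed used only when `ties = "random"`.
#' @return An object of class `rank_data`: list with `v` (matrix in (0,1), same
#'   shape as the counts), and the `condition`, `transcript`, `position`,
#'   `boundaries` metadata carried over from `x`.
#' @export
rank_normalize <- function(x, global = TRUE, ties = c("midrank", "random"),
                           seed = NULL) {
  stopifnot(inherits(x, "count_table"))
  ties <- match.arg(ties)
  ties.method <- if (ties == "midrank") "average" else "random"
  rank_col <- function(col) {
    n <- length(col)
    if (length(unique(col)) == 1L)
      message("degenerate sample column: all ", n, " counts equal")
    rank(col, ties.method = ties.method) / (n + 1)
  }
  if (ties == "random" && !is.null(seed)) set.seed(seed)
  if (global) {
    v <- apply(x$counts, 2L, rank_col)
  } else {
    v <- x$counts
    for (tx in unique(x$transcript)) {
      idx <- which(x$transcript == tx)
      v[idx, ] <- apply(x$counts[idx, , drop = FALSE], 2L, rank_col)
    }
  }
  dimnames(v) <- dimnames(x$counts)
  structure(
    list(v = v, condition = x$condition, transcript = x$transcript,
         position = x$position, boundaries = x$boundaries),
    class = "rank_data")
}

#' @export
print.rank_data <- function(x, ...) {
  cat(sprintf("rank_data: %d positions x %d samples (%d case, %d cont)\n",
              nrow(x$v), ncol(x$v), sum(x$condition == "case"),
              sum(x$condition == "cont")))
  invisible(x)
}

# Column indices of one condition's replicates.
condition_cols <- function(rd, condition) {
  idx <- which(rd$condition == condition)
  if (!length(idx)) stop("no '", condition, "' samples present")
  idx
}
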