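#' Per-position truncation count table
#'
#' Container for the observable data of a structure-probing experiment: one row
#' per transcript position, one column per sequencing sample, holding 5'-end
#' (truncation) read counts. Each sample belongs to either the `case` (probed)
#' or `cont` (control) condition; control samples are optional for
#' single-condition designs such as case-only icSHAPE.
#'
#' Transcript boundaries are tracked as 0-based offsets into the concatenated
#' position axis (`{0, L1, L1+L2, ..., L}`), so downstream hidden Markov model
#' fits can force the unmapped state at every transcript junction.
#'
#' @param counts integer matrix, `L x K`, non-negative truncation counts.
#' @param condition character vector of length `K`, each `"case"` or `"cont"`.
#' @param transcript transcript identifier(s): a single string, or a length-`L`
#'   vector assigning each row to a transcript (rows of one transcript must be
#'   contiguous).
#' @param position optional length-`L` integer vector of original 1-based
#'   coordinates (defaults to `1..L_t` within each transcript).
#' @return An object of class `count_table` with elements `counts`, `condition`,
#'   `transcript`, `position` and `boundaries`.
#' @export
count_table <- function(counts, condition, transcript = "tx", position = NULL) {
  counts <- as.matrix(counts)
  if (length(counts) == 0L) stop("empty count table")
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "double"
  K <- ncol(counts)
  L <- nrow(counts)
  condition <- as.character(condition)
  if (length(condition) != K) stop("condition must name each of the ", K, " samples")
  if (!all(condition %in% c("case", "cont")))
    stop("condition entries must be 'case' or 'cont'")
  if (!any(condition == "case")) stop("at least one case sample is required")
  if (is.null(colnames(counts))) {
    colnames(counts) <- stats::ave(condition, condition,
      FUN = function(x) paste0(x, "_", seq_along(x)))
  }
  if (length(transcript) == 1L) transcript <- rep(transcript, L)
  if (length(transcript) != L) stop("transcript must have length 1 or L")
  rle_tx <- rle(transcript)
  if (anyDuplicated(rle_tx$values)) stop("rows of one transcript must be contiguous")
  if (is.null(position)) {
    position <- unlist(lapply(rle_tx$lengths, seq_len), use.names = FALSE)
  }
  if (length(position) != L) stop("position must have length L")
  structure(
    list(counts = counts, condition = condition,
         transcript = transcript, position = as.integer(position),
         boundaries = cumsum(c(0L, rle_tx$lengths))),
    class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d positions, %d transcript(s), %d sample(s) [%s]\n",
              nrow(x$counts), length(unique(x$transcript)), ncol(x$counts),
              paste(colnames(x$counts), collapse = ", ")))
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

#' Trim transcript ends
#'
#' Removes the first and last `n_trim` positions of every transcript. Read
#' mapping is unreliable at the very ends of transcripts, so end positions are
#' often excluded before model fitting. Original 1-based coordinates are kept
#' in `$position` so output can be mapped back.
#'
#' @param x a [count_table].
#' @param n_trim non-negative integer; `2 * n_trim` must be smaller than each
#'   transcript length.
#' @return A trimmed [count_table].
#' @export
trim_ends <- function(x, n_trim) {
  stopifnot(inherits(x, "count_table"), n_trim >= 0, n_trim == round(n_trim))
  if (n_trim == 0L) return(x)
  keep <- unlist(lapply(split(seq_along(x$transcript), factor(x$transcript, unique(x$transcript))),
    function(idx) {
      L <- length(idx)
      if (2 * n_trim >= L)
        stop("transcript too short to trim ", n_trim, " positions from each end (L=", L, ")")
      idx[(n_trim + 1L):(L - n_trim)]
    }), use.names = FALSE)
  count_table(x$counts[keep, , drop = FALSE], x$condition,
              transcript = x$transcript[keep], position = x$position[keep])
}

#' Concatenate count tables of multiple transcripts
#'
#' Stacks several transcripts into one table with a shared position axis, so a
#' single model can be fitted across transcripts (ranks are then computed
#' globally). Transcript junctions are recorded in `$boundaries` and are forced
#' into the unmapped state during HMM fits.
#'
#' @param tables list of [count_table] objects sharing identical sample columns
#'   and condition assignment.
#' @return One [count_table] of total length `sum(L_i)`.
#' @export
concatenate_transcripts <- function(tables) {
  stopifnot(length(tables) >= 1L, all(vapply(tables, inherits, TRUE, "count_table")))
  ref <- tables[[1L]]
  for (t in tables[-1L]) {
    if (!identical(colnames(t$counts), colnames(ref$counts)) ||
        !identical(t$condition, ref$condition))
      stop("all tables must share sample columns and condition assignment")
  }
  tx <- unlist(lapply(tables, `[[`, "transcript"), use.names = FALSE)
  if (anyDuplicated(unique(unlist(lapply(tables, function(t) unique(t$transcript))))))
    stop("duplicated transcript ids across tables")
  count_table(do.call(rbind, lapply(tables, `[[`, "counts")), ref$condition,
              transcript = tx,
              position = unlist(lapply(tables, `[[`, "position"), use.names = FALSE))
}

#' Read a count table from a tab-delimited file
#'
#' Expected columns: `transcript`, `position` (1-based), then one column per
#' sample named `<condition>_<replicate>` (e.g. `case_1`, `case_2`, `cont_1`).
#' Control columns may be absent.
#'
#' @param path file path.
#' @return A [count_table].
#' @export
read_count_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("transcript", "position") %in% names(df)))
    stop("count file must have 'transcript' and 'position' columns: ", path)
  samp <- setdiff(names(df), c("transcript", "position"))
  cond <- sub("_.*$", "", samp)
  if (!all(cond %in% c("case", "cont")))
    stop("sample columns must be named case_<r> or cont_<r>; got: ",
         paste(samp, collapse = ", "))
  m <- as.matrix(df[samp])
  count_table(m, cond, transcript = df$transcript, position = df$position)
}

#' Write a count table to a tab-delimited file
#'
#' @param x a [count_table].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path) {
  df <- data.frame(transcript = x$transcript, position = x$position,
                   x$counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
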