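#' Parse a reference secondary structure into per-base labels
#'
#' Converts a dot-bracket string or a two-column label file into per-base
#' labels over `{loop, stem, unmapped, unknown}`, used for supervised training
#' (hidden states restricted to match the reference) and for AUROC evaluation.
#'
#' In dot-bracket dialect, bracket characters `()`, `[]`, `{}`, `<>` and
#' upper/lower-case letter pairs (pseudoknots, `A`..`Z` opening and `a`..`z`
#' closing) map to `stem`; `.` maps to `loop`; `-` and `x` map to `unmapped`;
#' any other character maps to `unknown`. Brackets must balance; the first
#' unmatched position is reported otherwise.
#'
#' The label-file dialect is a two-column TSV (position, label) whose labels
#' must be in `{loop, stem, unmapped, unknown}`; listed positions must cover a
#' contiguous 1..L range.
#'
#' @param text a dot-bracket string, or a path to a file. Files in dot-bracket
#'   dialect may be FASTA-like (`>` header lines are skipped and structure lines
#'   concatenated).
#' @param dialect `"dot_bracket"` or `"label_file"`.
#' @return Character vector of per-base labels with class `reference_labels`
#'   and attribute `source` naming the dialect.
#' @export
parse_reference <- function(text, dialect = c("dot_bracket", "label_file")) {
  dialect <- match.arg(dialect)
  if (dialect == "label_file") {
    df <- utils::read.delim(text, header = FALSE, stringsAsFactors = FALSE,
                            col.names = c("position", "label"))
    if (any(sort(df$position) != seq_len(nrow(df))))
      stop("label file positions must cover a contiguous 1..L range")
    lab <- df$label[order(df$position)]
    lab[!lab %in% c("loop", "stem", "unmapped")] <- "unknown"
    return(structure(lab, class = "reference_labels", source = "label_file"))
  }
  if (length(text) == 1L && file.exists(text)) {
    lines <- readLines(text)
    text <- paste(lines[!startsWith(lines, ">")], collapse = "")
  }
  if (!nzchar(text)) stop("empty reference structure")
  chars <- strsplit(text, "")[[1L]]
  # 'x' marks unmapped bases, so the X/x letter pair is not a pseudoknot
  open  <- c("(", "[", "{", "<", setdiff(LETTERS, "X"))
  close <- c(")", "]", "}", ">", setdiff(letters, "x"))
  lab <- rep("unknown", length(chars))
  lab[chars == "."] <- "loop"
  lab[chars %in% c("-", "x")] <- "unmapped"
  lab[chars %in% c(open, close)] <- "stem"
  # balance check per bracket family
  for (f in seq_along(open)) {
    depth <- 0L; first_open <- NA_integer_
    for (i in seq_along(chars)) {
      if (chars[i] == open[f]) {
        if (depth == 0L) first_open <- i
        depth <- depth + 1L
      } else if (chars[i] == close[f]) {
        depth <- depth - 1L
        if (depth < 0L) stop("unbalanced brackets: unmatched '", close[f],
                             "' at position ", i)
      }
    }
    if (depth > 0L) stop("unbalanced brackets: unmatched '", open[f],
                         "' at position ", first_open)
  }
  structure(lab, class = "reference_labels", source = "dot_bracket")
}
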