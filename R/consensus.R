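#' Column-wise consensus sequence with BLOSUM62 tie resolution
#'
#' Per column the most frequent residue wins. When two or more residues share
#' the maximal count, the winner among them maximizes the summed BLOSUM62
#' similarity to the column's observed residues; residual exact ties are
#' broken alphabetically. Columns in which the gap is the most common
#' character are omitted from the output sequence (still recorded in the
#' per-column table).
#'
#' @param alignment A [protein_alignment()].
#' @param gap_policy `"omit"` (default) drops gap-majority columns from the
#'   sequence; `"emit"` writes `-` for them.
#' @param tie_scope Score tied candidates against the whole column
#'   (`"column"`, default) or only against the tied residues themselves
#'   (`"tied"`).
#' @return An object of class `consensus_result`: `sequence` and a
#'   per-column data.frame `table` (winner, count, tie flag, gap-majority
#'   flag).
#' @examples
#' aln <- protein_alignment(c(a = "KA", b = "KA", c = "WA", d = "WV"))
#' consensus_sequence(aln)$sequence
#' @export
consensus_sequence <- function(alignment,
                               gap_policy = c("omit", "emit"),
                               tie_scope = c("column", "tied")) {
  gap_policy <- match.arg(gap_policy)
  tie_scope <- match.arg(tie_scope)
  stopifnot(inherits(alignment, "protein_alignment"))
  m <- as.matrix(alignment)
  B <- blosum62()
  nc <- alignment$ncol
  winner <- character(nc)
  count <- integer(nc)
  tie <- logical(nc)
  gap_major <- logical(nc)

  for (j in seq_len(nc)) {
    col <- m[, j]
    res <- col[col %in% AA_STATES]     # ambiguity codes don't vote
    ngap <- sum(col == "-")
    if (length(res) == 0L) {
      gap_major[j] <- TRUE
      winner[j] <- "-"
      if (ngap == length(col)) warning("column ", j, " is entirely gaps")
      next
    }
    tab <- table(res)
    topn <- max(tab)
    if (ngap > topn) {                 # gap is the most common character
      gap_major[j] <- TRUE
      winner[j] <- "-"
      count[j] <- ngap
      next
    }
    cand <- names(tab)[tab == topn]
    count[j] <- topn
    tie[j] <- length(cand) > 1L
    if (tie[j]) {
      against <- if (tie_scope == "column") res else res[res %in% cand]
      score <- vapply(cand, function(r) sum(B[r, against]), 0)
      cand <- cand[score >= max(score) - 1e-9]
      cand <- sort(cand)               # alphabetical residual tie-break
    }
    winner[j] <- cand[1]
  }

  seq_cols <- if (gap_policy == "omit") which(!gap_major) else seq_len(nc)
  structure(list(
    sequence = paste(winner[seq_cols], collapse = ""),
    table = data.frame(column = seq_len(nc), winner = winner, count = count,
                       tie = tie, gap_majority = gap_major),
    gap_policy = gap_policy, tie_scope = tie_scope),
    class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("consensus_result: %d columns, %d ties, %d gap-majority\n",
              nrow(x$table), sum(x$table$tie), sum(x$table$gap_majority)))
  invisible(x)
}
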