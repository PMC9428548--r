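## Amino-acid alphabet used throughout (PAML/WAG state order).
AA_STATES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
               "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

## Ambiguity codes expand to state sets; gap and X carry no information.
AA_AMBIGUITY <- list(B = c("N", "D"), Z = c("Q", "E"), X = AA_STATES, "-" = AA_STATES)

#' Gapped protein alignment
#'
#' A light container for a protein multiple sequence alignment: a named set of
#' equal-length gapped amino-acid strings over the 20-letter alphabet plus
#' `-` (gap) and the ambiguity codes `B`, `Z`, `X`.
#'
#' @param seqs Named character vector of aligned sequences.
#' @param strict If `TRUE`, only the 20 canonical residues and `-` are
#'   accepted; if `FALSE` (default for in-memory construction) the
#'   ambiguity codes `B`/`Z`/`X` are also allowed and are treated as
#'   residue sets by the likelihood machinery.
#' @return An object of class `protein_alignment` with elements `names`,
#'   `seqs` (uppercase, gaps normalized to `-`) and `ncol`.
#' @examples
#' aln <- protein_alignment(c(s1 = "MKV-", s2 = "MK-A"))
#' aln$ncol
#' @export
protein_alignment <- function(seqs, strict = FALSE) {
  if (length(seqs) == 0L) stop("alignment is empty")
  nm <- names(seqs)
  if (is.null(nm) || anyNA(nm) || any(nm == ""))
    stop("all sequences must be named")
  if (anyDuplicated(nm)) stop("duplicate sequence names: ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  seqs <- toupper(seqs)
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  wid <- nchar(seqs)
  if (length(unique(wid)) != 1L)
    stop("alignment error: sequences have unequal lengths (",
         paste(range(wid), collapse = "-"), ")")
  ok <- if (strict) c(AA_STATES, "-") else c(AA_STATES, "-", "B", "Z", "X")
  for (i in seq_along(seqs)) {
    ch <- strsplit(seqs[[i]], "")[[1]]
    bad <- which(!(ch %in% ok))
    if (length(bad))
      stop(sprintf("parse error: invalid residue '%s' in sequence '%s' at column %d",
                   ch[bad[1]], nm[i], bad[1]))
  }
  structure(list(names = nm, seqs = unname(seqs), ncol = unname(wid[1])),
            class = "protein_alignment")
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat(sprintf("protein_alignment: %d sequences x %d columns\n",
              length(x$names), x$ncol))
  invisible(x)
}

#' @export
as.matrix.protein_alignment <- function(x, ...) {
  m <- do.call(rbind, strsplit(x$seqs, ""))
  rownames(m) <- x$names
  m
}

#' Read an aligned protein FASTA file
#'
#' Records must have equal lengths; `.` gaps are normalized to `-`. By
#' default only the 20-letter alphabet plus gaps is accepted on read; pass
#' `strict = FALSE` to admit the `B`/`Z`/`X` ambiguity codes.
#'
#' @param path Path to a FASTA file of aligned protein sequences.
#' @param strict Reject ambiguity codes (default `TRUE`).
#' @return A [protein_alignment()].
#' @export
read_alignment <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- tryCatch(Biostrings::readBStringSet(path),
                 error = function(e) stop("FASTA parse error in ", path, ": ",
                                          conditionMessage(e)))
  if (length(ss) == 0L) stop("alignment error: no sequences in ", path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  protein_alignment(seqs, strict = strict)
}

#' Write an alignment to FASTA
#'
#' @param aln A [protein_alignment()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "protein_alignment"))
  ss <- Biostrings::BStringSet(aln$seqs)
  names(ss) <- aln$names
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Percent identity between two ungapped-comparable sequences
#'
#' Identity is computed over columns where both sequences have a residue
#' (pair gaps are skipped); sequences of unequal length are compared after a
#' simple global check and must be pre-aligned.
#'
#' @param a,b Protein sequence strings (may contain `-`).
#' @return Percent identity in `[0, 100]`.
#' @export
sequence_identity <- function(a, b) {
  x <- strsplit(toupper(a), "")[[1]]
  y <- strsplit(toupper(b), "")[[1]]
  if (length(x) != length(y))
    stop("sequences must be aligned (equal length) for identity")
  keep <- x != "-" & y != "-"
  if (!any(keep)) stop("no comparable columns")
  100 * mean(x[keep] == y[keep])
}

## residue characters -> list of state-index vectors (NULL carries no info)
aa_state_sets <- function(chars) {
  lapply(chars, function(ch) {
    i <- match(ch, AA_STATES)
    if (!is.na(i)) return(i)
    set <- AA_AMBIGUITY[[ch]]
    if (is.null(set)) stop("unknown residue code: ", ch)
    match(set, AA_STATES)
  })
}
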