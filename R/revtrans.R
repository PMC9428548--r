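#' Read a codon-usage table
#'
#' Expects a tab-separated file with columns `codon`, `amino_acid`
#' (one-letter code, `*` for stop) and `fraction`; `#` lines are comments.
#' Codons are validated against the standard genetic code and fractions must
#' sum to 1 within each amino acid.
#'
#' @param path Path to the table; default is the packaged synthetic
#'   Sf9-style table.
#' @return An object of class `codon_usage_table`.
#' @export
read_codon_table <- function(path = system.file("extdata",
                                                "sf9_codon_usage_synthetic.tsv",
                                                package = "kinesin13",
                                                mustWork = TRUE)) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("codon", "amino_acid", "fraction") %in% names(df)))
  df$codon <- toupper(gsub("U", "T", df$codon))
  if (any(!grepl("^[ACGT]{3}$", df$codon)))
    stop("invalid codon in table: ",
         paste(df$codon[!grepl("^[ACGT]{3}$", df$codon)], collapse = ", "))
  if (anyDuplicated(df$codon)) stop("duplicate codons in table")
  gc <- Biostrings::GENETIC_CODE
  exp_aa <- as.character(gc[df$codon])
  bad <- df$amino_acid != exp_aa
  if (any(bad))
    stop("codon/amino-acid mismatch with the standard genetic code: ",
         paste(df$codon[bad], collapse = ", "))
  sense <- df[df$amino_acid != "*", ]
  if (nrow(sense) != 61) stop("table must cover all 61 sense codons, has ",
                              nrow(sense))
  sums <- tapply(df$fraction, df$amino_acid, sum)
  if (any(abs(sums - 1) > 1e-6))
    stop("usage fractions do not sum to 1 for: ",
         paste(names(sums)[abs(sums - 1) > 1e-6], collapse = ", "))
  structure(list(table = df), class = "codon_usage_table")
}

#' @export
print.codon_usage_table <- function(x, ...) {
  cat(sprintf("codon_usage_table: %d codons, %d amino acids\n",
              nrow(x$table), length(unique(x$table$amino_acid)) - 1L))
  invisible(x)
}

#' Reverse translate a protein into a coding DNA sequence
#'
#' `mode = "top"` deterministically takes each residue's most frequent codon;
#' `mode = "sample"` draws a codon per residue with probability equal to its
#' usage fraction (reproducible under `seed`). Translating the output back
#' with the standard genetic code yields the input protein.
#'
#' @param protein Protein sequence string over the 20-residue alphabet.
#' @param table A `codon_usage_table` (default: packaged Sf9-style table).
#' @param mode `"top"` or `"sample"`.
#' @param seed Optional integer seed for sampling mode.
#' @return A DNA sequence string of length `3 * nchar(protein)`.
#' @examples
#' reverse_translate("MW")
#' @export
reverse_translate <- function(protein, table = read_codon_table(),
                              mode = c("top", "sample"), seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(table, "codon_usage_table"))
  res <- strsplit(toupper(protein), "")[[1]]
  if (length(res) == 0L) stop("empty protein sequence")
  bad <- setdiff(unique(res), AA_STATES)
  if (length(bad))
    stop("cannot reverse translate residue(s): ", paste(bad, collapse = ", "))
  df <- table$table[table$table$amino_acid != "*", ]
  by_aa <- split(df, df$amino_acid)
  if (!is.null(seed)) set.seed(seed)
  codons <- vapply(res, function(a) {
    rows <- by_aa[[a]]
    if (is.null(rows)) stop("residue absent from codon table: ", a)
    if (mode == "top") {
      rows$codon[which.max(rows$fraction)]
    } else {
      sample(rows$codon, 1L, prob = rows$fraction)
    }
  }, "")
  paste(codons, collapse = "")
}
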