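#' Read an NCBI-format scoring matrix
#'
#' Parses the standard NCBI text layout (header row of residue codes, one
#' labelled row per residue). Only the 20 canonical residues are retained.
#'
#' @param path Path to a matrix file such as the packaged `BLOSUM62.txt`.
#' @return A symmetric 20x20 integer matrix indexed by residue.
#' @export
read_scoring_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- strsplit(trimws(lines[-1]), "\\s+")
  m <- matrix(NA_integer_, length(rows), length(hdr),
              dimnames = list(vapply(rows, `[`, "", 1), hdr))
  for (i in seq_along(rows))
    m[i, ] <- as.integer(rows[[i]][-1])
  m <- m[AA_STATES, AA_STATES]
  if (!isTRUE(all.equal(m, t(m)))) stop("scoring matrix is not symmetric")
  m
}

#' The BLOSUM62 substitution scoring matrix
#'
#' Published BLOSUM62 scores, shipped as a packaged NCBI-format text file.
#' Used only for tie resolution in [consensus_sequence()].
#'
#' @return A symmetric 20x20 integer matrix.
#' @export
blosum62 <- function() {
  cache_get("blosum62", read_scoring_matrix(
    system.file("extdata", "BLOSUM62.txt", package = "kinesin13",
                mustWork = TRUE)))
}

## Parse a PAML-layout amino-acid model file: 19 lower-triangle rows of
## exchangeabilities followed by a row of 20 equilibrium frequencies.
read_paml_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  vals <- lapply(strsplit(trimws(lines), "\\s+"), as.numeric)
  if (length(vals) < 20) stop("malformed PAML matrix file: ", path)
  S <- matrix(0, 20, 20, dimnames = list(AA_STATES, AA_STATES))
  for (i in 2:20) {
    row <- vals[[i - 1]]
    if (length(row) != i - 1) stop("bad exchangeability row ", i, " in ", path)
    S[i, 1:(i - 1)] <- row
  }
  S <- S + t(S)
  pi <- vals[[20]]
  if (length(pi) != 20 || any(pi <= 0)) stop("bad frequency row in ", path)
  list(exchangeabilities = S, pi = pi / sum(pi))
}

## tiny package-local cache for parsed data files
.k13_cache <- new.env(parent = emptyenv())
cache_get <- function(key, value) {
  if (!exists(key, envir = .k13_cache)) assign(key, value, envir = .k13_cache)
  get(key, envir = .k13_cache)
}
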