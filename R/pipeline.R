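#' Validate a resurrection run configuration
#'
#' A run configuration is a plain list (or a path to a JSON file holding
#' one) with fields: `alignment` and `tree` (paths), optional `keep` (taxa
#' to prune to), `outdir`, `seed`, `presence_threshold`, `frequencies`
#' (`"model"`/`"empirical"`), optional `gamma` (`list(k =, alpha =)`),
#' `codon_table` (path; default packaged table) and `codon_mode`.
#'
#' @param config List or JSON file path.
#' @return The validated config list with defaults filled in.
#' @export
run_config <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  defaults <- list(keep = NULL, outdir = ".", seed = 1,
                   presence_threshold = 0.5, frequencies = "model",
                   gamma = NULL, codon_table = NULL, codon_mode = "top")
  for (f in names(defaults))
    if (is.null(config[[f]])) config[[f]] <- defaults[[f]]
  for (f in c("alignment", "tree"))
    if (is.null(config[[f]]) || !file.exists(config[[f]]))
      stop("config error: missing or nonexistent ", f, " file")
  if (!is.null(config$codon_table) && !file.exists(config$codon_table))
    stop("config error: codon table file not found")
  config
}

#' Run the full sequence-resurrection pipeline
#'
#' Reads the family alignment and tree, optionally prunes to a taxon set,
#' infers the consensus and the maximum-likelihood ancestral (root) motor
#' sequence, reverse-translates both for expression, and writes all
#' artifacts plus a run log.
#'
#' @param config See [run_config()].
#' @return Invisibly, a named list of output file paths plus the in-memory
#'   results (`consensus`, `reconstruction`, `ancestral_seq`).
#' @export
run_resurrection <- function(config) {
  config <- run_config(config)
  aln <- read_alignment(config$alignment)
  tree <- read_tree(config$tree)
  if (!is.null(config$keep)) {
    tree <- prune_to_taxa(tree, config$keep)
    aln <- protein_alignment(stats::setNames(
      aln$seqs[match(tree$tip.label, aln$names)], tree$tip.label))
  }
  set.seed(config$seed)
  model <- build_wag(config$frequencies, alignment = aln)
  cons <- consensus_sequence(aln)
  rec <- asr(aln, tree, model, gamma = config$gamma)
  anc <- ancestral_sequence(rec, "root", config$presence_threshold)
  ct <- if (is.null(config$codon_table)) read_codon_table()
        else read_codon_table(config$codon_table)
  dna_anc <- reverse_translate(anc, ct, mode = config$codon_mode,
                               seed = config$seed)
  dna_con <- reverse_translate(cons$sequence, ct, mode = config$codon_mode,
                               seed = config$seed)

  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$outdir, f)
  write_fasta <- function(seqs, path) {
    ss <- Biostrings::BStringSet(seqs)
    Biostrings::writeXStringSet(ss, path)
    path
  }
  paths <- list(
    consensus_fasta = write_fasta(c(Con13 = cons$sequence), p("consensus.fasta")),
    ancestral_fasta = write_fasta(c(Anc13 = anc), p("ancestral.fasta")),
    coding_dna_fasta = write_fasta(c(Anc13_cds = dna_anc, Con13_cds = dna_con),
                                   p("coding_dna.fasta")),
    posterior_tsv = p("posteriors.tsv"),
    run_log = p("run.log"))
  utils::write.table(posterior_table(rec), paths$posterior_tsv,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(c(
    sprintf("kinesin13 %s", as.character(utils::packageVersion("kinesin13"))),
    sprintf("alignment: %s (%d x %d)", config$alignment, length(aln$names), aln$ncol),
    sprintf("tree: %s (%d leaves)", config$tree, length(tree$tip.label)),
    sprintf("model: WAG, frequencies=%s, gamma=%s", config$frequencies,
            if (is.null(config$gamma)) "none"
            else sprintf("k=%d alpha=%g", config$gamma$k, config$gamma$alpha)),
    sprintf("log-likelihood: %.6f", rec$loglik),
    sprintf("presence threshold: %g", config$presence_threshold),
    sprintf("seed: %d", config$seed),
    sprintf("ancestral length: %d", nchar(anc)),
    sprintf("consensus length: %d", nchar(cons$sequence)),
    sprintf("identity Anc vs Con: %.1f%%",
            if (nchar(anc) == nchar(cons$sequence))
              sequence_identity(anc, cons$sequence) else NA)),
    paths$run_log)
  invisible(c(paths, list(consensus = cons, reconstruction = rec,
                          ancestral_seq = anc)))
}

#' Comparative report of derived fold-changes and ratios
#'
#' Computes every derived comparison the rate table supports: fold-changes
#' between constructs and conditions, percent comparisons, off-rate
#' lattice/end ratios, the on-rate fold, ATPase stimulation folds and the
#' ATP-coupling stoichiometry under both comparators. Pairs whose labels
#' are absent are listed and skipped; the report is still emitted.
#'
#' @param rates A [rate_table()]; defaults to the published measurements
#'   ([kinesin13_rates()]).
#' @param path Optional TSV output path.
#' @return A data.frame with columns `id`, `kind`, `value`, `se`.
#' @export
run_comparison_report <- function(rates = kinesin13_rates(), path = NULL) {
  out <- list()
  missing <- character(0)
  add <- function(id, kind, fn) {
    r <- tryCatch(fn(), error = function(e) {
      missing <<- c(missing, paste0(id, " (", conditionMessage(e), ")"))
      NULL
    })
    if (!is.null(r)) out[[length(out) + 1L]] <<- data.frame(
      id = id, kind = kind, value = r$value, se = r$se)
  }
  fc <- function(a, b, q, scale = 1) function() {
    x <- fold_change(rates, a, b, q)
    list(value = x$ratio * scale, se = x$se * scale)
  }
  ratio2 <- function(lab) function() {
    x <- fold_change(rbind(
      rate_table(paste0(lab, ".lat"), "koff", rt_row(rates, lab, "koff_lattice")$value,
                 rt_row(rates, lab, "koff_lattice")$sd),
      rate_table(paste0(lab, ".end"), "koff", rt_row(rates, lab, "koff_end")$value,
                 rt_row(rates, lab, "koff_end")$sd)),
      paste0(lab, ".lat"), paste0(lab, ".end"), "koff")
    list(value = x$ratio, se = x$se)
  }
  add("depol_fold_anc13_vs_mcak", "fold", fc("Anc13", "MCAK", "depolymerization"))
  add("depol_fold_anc13_vs_mcak_egfp", "fold", fc("Anc13", "MCAK-EGFP", "depolymerization"))
  add("depol_fold_mcak_anc13_vs_mcak", "fold", fc("MCAK-Anc13", "MCAK", "depolymerization"))
  add("depol_fold_anc13_taxol_vs_basal", "fold", fc("Anc13+taxol", "basal", "depolymerization"))
  add("depol_pct_anc13_taxol_vs_mcak", "percent", fc("Anc13+taxol", "MCAK", "depolymerization", 100))
  add("depol_fold_anc13_vs_anc13_adp", "fold", fc("Anc13", "Anc13+ADP", "depolymerization"))
  add("depol_fold_mcak_vs_anc13_adp", "fold", fc("MCAK", "Anc13+ADP", "depolymerization"))
  add("depol_pct_con13_vs_mcak", "percent", fc("Con13", "MCAK", "depolymerization", 100))
  add("depol_pct_con13_vs_mcak_egfp", "percent", fc("Con13", "MCAK-EGFP", "depolymerization", 100))
  add("koff_ratio_mcak_lattice_end", "ratio", ratio2("MCAK"))
  add("koff_ratio_anc13_lattice_end", "ratio", ratio2("Anc13"))
  add("kon_fold_anc13_vs_mcak", "fold", fc("Anc13", "MCAK", "kon"))
  add("atpase_fold_anc13_basal_vs_mcak_basal", "fold", fc("Anc13", "MCAK", "atpase_basal"))
  add("atpase_fold_anc13_mt_vs_mcak_mt", "fold", fc("Anc13", "MCAK", "atpase_mt"))
  add("atpase_stim_fold_anc13", "fold", function() {
    x <- rt_row(rates, "Anc13", "atpase_mt")$value /
      rt_row(rates, "Anc13", "atpase_basal")$value
    list(value = x, se = NA_real_)
  })
  add("atpase_stim_fold_mcak", "fold", function() {
    x <- rt_row(rates, "MCAK", "atpase_mt")$value /
      rt_row(rates, "MCAK", "atpase_basal")$value
    list(value = x, se = NA_real_)
  })
  add("atpase_tubulin_fold_anc13", "fold", function() {
    x <- rt_row(rates, "Anc13", "atpase_tubulin")$value /
      rt_row(rates, "Anc13", "atpase_basal")$value
    list(value = x, se = NA_real_)
  })
  add("tubulins_per_atp_vs_mcak", "stoichiometry", function() {
    s <- tubulins_per_atp(rates, "Anc13", "MCAK")
    list(value = s$stoichiometry, se = s$se)
  })
  add("tubulins_per_atp_vs_mcak_egfp", "stoichiometry", function() {
    r2 <- rates
    i <- which(r2$label == "MCAK-EGFP" & r2$quantity == "depolymerization")
    j <- which(r2$label == "MCAK" & r2$quantity == "atpase_mt")
    r2 <- rbind(r2, rate_table("MCAK-EGFP", "atpase_mt",
                               r2$value[j], r2$sd[j], r2$n[j], r2$units[j]))
    s <- tubulins_per_atp(r2, "Anc13", "MCAK-EGFP")
    list(value = s$stoichiometry, se = s$se)
  })
  rep <- if (length(out)) do.call(rbind, out)
         else data.frame(id = character(), kind = character(),
                         value = numeric(), se = numeric())
  attr(rep, "missing") <- missing
  if (length(missing))
    message("skipped comparisons: ", paste(missing, collapse = "; "))
  if (!is.null(path))
    utils::write.table(rep, path, sep = "\t", quote = FALSE, row.names = FALSE)
  rep
}
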