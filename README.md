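# kinesin13

Inference of **reference motor-domain sequences** for the kinesin-13 family
of microtubule depolymerases, plus the **kinetic analysis** used to
characterize the resulting "resurrected" motors.

Kinesin-13s (e.g. MCAK/KIF2C) do not walk along microtubules — they take
them apart, and they are essential regulators of microtubule length in the
spindle and in cilia. Given a gapped protein alignment of family motor
domains and a rooted phylogeny with branch lengths, this package infers:

* the **ancestral** motor domain — the maximum-likelihood marginal estimate
  of the root sequence under the WAG substitution model, computed by
  Felsenstein pruning with a separate two-state (presence/absence) indel
  reconstruction over gap blocks:
  posterior at the root for state $x$, column $c$:
  $\;p(x \mid D_c) \propto \pi_x L_{\mathrm{root}}(x)$,
  with $Q_{ij} = s_{ij}\pi_j$ scaled to one expected substitution per site
  per unit branch length;
* the **consensus** motor domain — the most common residue per column, with
  count ties resolved by maximal summed BLOSUM62 similarity to the column;
* a **coding DNA sequence** for either, via a host codon-usage table.

On the measurement side it provides estimators with calibrated
uncertainties for the assays used on such motors:

* microtubule depolymerization rates from length-vs-time traces
  (OLS with time-based truncation at the resolution floor; µm/min);
* single-molecule detachment rates from censored dwell times,
  $\hat k_{\mathrm{off}} = U / \sum_i (d_i - \Delta)$ with frame-interval
  correction $\Delta = 1/8.7$ s, and attachment rates
  $k_{\mathrm{on}} = N/(T \cdot L \cdot c)$ (nM⁻¹ s⁻¹ µm⁻¹);
* ATPase turnover per active site from HPLC or NADH-coupled progress
  curves;
* derived comparisons: fold-changes with log-scale error propagation,
  lattice/end off-rate ratios, and the ATP-coupling stoichiometry
  $S = S_{\mathrm{comp}} (v_t/v_c)(k_c/k_t)$ (tubulin dimers removed per
  ATP hydrolyzed).

Seeded synthetic-data generators (`evolve_alignment()`,
`simulate_dwells()`, `simulate_length_traces()`, `simulate_atpase()`)
emulate each assay with known ground truth so that every estimator is
validated end-to-end without any external data.

## Worked example

```r
library(kinesin13)

## a synthetic 16-taxon family with a known 120-residue root
sim <- evolve_alignment(sim_config(seed = 1, n_leaves = 16, depth = 0.5,
                                   length = 120, indel_rate = 0.05))
rec <- asr(sim$alignment, sim$tree)        # WAG + indel reconstruction
anc <- ancestral_sequence(rec)
rec$loglik
#> [1] -2115.935
sequence_identity(anc, sim$root_seq)       # % of the true root recovered
#> [1] 89.2
substr(anc, 1, 40)
#> [1] "CSEFGYHIDAGGPNRTPWSNHGIIVTASQSTDTGFINLPK"

## reverse-translate for expression (packaged Sf9-style table)
substr(reverse_translate(anc), 1, 30)
#> [1] "TGCTCTGAGTTCGGTTACCATATTGATGCT"

## censored dwell-time kinetics at 8.7 Hz on a 23 s movie
d <- simulate_dwells(sim_config(seed = 2, concentration = 0.05,
                                end_fraction = 1))
k <- koff_mle(d, "end")
sprintf("k_off = %.3f +/- %.3f 1/s (n = %d)", k$k_off, k$se, k$n_events)
#> [1] "k_off = 1.217 +/- 0.053 1/s (n = 526)"

## derived comparative report from the published rate tables
rep <- run_comparison_report()
subset(rep, id %in% c("depol_fold_anc13_vs_mcak",
                      "koff_ratio_anc13_lattice_end",
                      "tubulins_per_atp_vs_mcak"))
#>                            id          kind  value     se
#>      depol_fold_anc13_vs_mcak          fold 10.873 0.7412
#>  koff_ratio_anc13_lattice_end         ratio  1.106 0.1023
#>      tubulins_per_atp_vs_mcak stoichiometry  4.972 0.4802
```

The report says: the ancestral construct depolymerizes ~11× faster than
full-length MCAK, detaches from the microtubule lattice and end at
essentially the same rate (ratio 1.11 — unlike MCAK, it does not
discriminate the end), and removes ~5 tubulin dimers per ATP when anchored
to MCAK's 1:1 stoichiometry.

## Layout

* `R/` — alignment/tree I/O (`read_alignment`, `read_tree`,
  `prune_to_taxa`), WAG model (`build_wag`, `transition_matrix`), ASR
  (`asr`, `ancestral_sequence`, `reconstruct_indels`, `resolve_polytomy`),
  consensus, reverse translation, kinetics, generators, pipeline
  (`run_resurrection`, `run_comparison_report`).
* `inst/extdata/` — WAG (PAML layout), BLOSUM62 (NCBI layout), synthetic
  Sf9-style codon table.
* `inst/cli/kinesin13` — command-line front end (`consensus`, `asr`,
  `revtrans`, `prune`, `compare`, `run-all`).
* `vignettes/kinesin13-methods.Rmd` — models, assumptions, design choices.
* `tests/testthat/` — unit, property and acceptance suites with independent
  enumeration oracles.
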