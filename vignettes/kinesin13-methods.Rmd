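---
title: "Resurrecting a kinesin-13 motor domain: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resurrecting a kinesin-13 motor domain: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinesin13)
```

# Scope

The kinesin-13 family are microtubule depolymerases. Two "reference" motor
domains can be inferred from a family alignment and tree: a **consensus**
sequence (most common residue per column) and an **ancestral** sequence (the
maximum-likelihood estimate of the root state of the family). This package
implements that inference, the reverse translation of the result for
heterologous expression, and the analysis of the kinetic assays used to
characterize such motors — microtubule depolymerization traces,
single-molecule dwell times, ATPase progress curves — together with the
derived comparative statistics (fold-changes, off-rate ratios,
ATP-per-tubulin coupling stoichiometry).

Wet-lab quantities (absolute rates) are *inputs*: the package ships the
published means, s.d. and n as `kinesin13_rates()` and computes every derived
ratio from them at run time. Nothing in the package claims to reproduce a
measurement computationally; the synthetic-data generators exist so that
every estimator can be validated against known ground truth.

# Ancestral reconstruction model

## Substitution model

Residues evolve under a reversible continuous-time Markov chain with the WAG
amino-acid model: rate matrix $Q_{ij} = s_{ij}\pi_j$ from the published
exchangeabilities $s_{ij}$ and equilibrium frequencies $\pi$, normalized so
$-\sum_i \pi_i Q_{ii} = 1$, i.e. branch lengths are expected substitutions
per site. Transition probabilities $P(t) = e^{Qt}$ are computed by symmetric
eigendecomposition of $\Pi^{1/2} Q \Pi^{-1/2}$, which is numerically stable
for every branch length used here; no Padé fallback is needed at these
scales. $P(0)$ is returned as an exact identity matrix.

Defaults follow the stated reconstruction protocol: WAG's own frequencies
(no `+F`) and a rate-homogeneous model, because the original tool invocation
requested neither empirical frequencies nor gamma rates. Both remain
available (`build_wag("empirical", aln)`; `gamma = list(k = 4, alpha = ...)`
with mean-of-class discretization).

## Likelihood and marginal posteriors

`alignment_loglik()` runs Felsenstein pruning over the rooted input tree,
with per-node rescaling of partial likelihoods (75-taxon alignments would
otherwise underflow), multiplying three or more child messages at
multifurcations. Gaps and `X` contribute all-ones partials (missing data);
`B`/`Z` contribute their residue sets. Branch lengths are taken from the
input tree as fixed; re-optimization is out of scope.

Marginal posteriors at any internal node use the standard up–down
(inside–outside) recursion: the posterior of state $x$ at a node is
proportional to the product of the inside messages from all subtrees around
that node with the root closed by $\pi$. Because the model is reversible and
the chain starts at stationarity, the likelihood is invariant to sliding the
root along a branch (the pulley principle) — a property the test suite
checks, along with agreement to $10^{-10}$ with exhaustive enumeration over
all internal-state assignments on trees of up to 5 leaves.

## Indels

Gap structure is modelled separately from residues, mirroring the two-pass
design of the original reconstruction tool. Maximal runs of consecutive
columns with an identical leaf gap pattern form one binary
(absent/present) character each; characters evolve under a two-state
reversible CTMC whose stationary frequencies come from the observed leaf
states (pseudocount 0.5) and whose single exchange rate is optimized by
maximum likelihood across all blocks. Presence posteriors at internal nodes
use the same up–down machinery on two states.

`ancestral_sequence()` emits, per column with presence posterior at least
the threshold (default 0.5, configurable), the argmax-posterior residue;
exact ties break first to the higher equilibrium frequency, then
alphabetically — a deterministic rule, so reruns are byte-identical.

## Polytomies

A multifurcation can be resolved with `resolve_polytomy()` by grouping a
subset of its children under a new zero-length branch. A zero-length branch
has $P(0) = I$, so the likelihood and all posteriors are unchanged — asserted
in the tests rather than assumed.

# Consensus inference

Per column the most frequent residue wins (`consensus_sequence()`). When
several residues tie on count, the winner among them maximizes the summed
BLOSUM62 similarity to *all* residues observed in the column. Scoring
against the whole column (rather than only the tied residues) was a genuine
design choice: it is the only reading in which both the tie set and the
column context matter; the tied-only variant is available behind
`tie_scope = "tied"`. Residual exact ties (e.g. a perfect I/L tie) resolve
alphabetically. Columns where the gap is the most common character are
omitted from the output protein — a consensus is a sequence, not an
alignment row — with `gap_policy = "emit"` available to keep them as `-`.

# Reverse translation

`reverse_translate()` maps each residue to a codon from a host codon-usage
table, either deterministically (most frequent codon, the default) or by
sampling with the usage fractions under a seed. The original work used a
commercial optimizer whose algorithm is proprietary; the deterministic rule
is the reproducible stand-in. The packaged Sf9-style table is **synthetic**
(representative lepidopteran preferences, labelled as such in the filename);
correctness — translating the output back yields the input protein for every
mode — is independent of the fractions and is tested against the standard
genetic code implementation in Biostrings.

# Kinetic estimators

* **Depolymerization** (`depolymerization_rate()`): OLS line on length vs
  time from the protein-addition time to the end of shrinkage. The end of
  shrinkage is found iteratively as the time where the *fitted line* crosses
  the resolution floor (default 0.5 µm): truncating on fitted rather than
  observed values avoids selecting on measurement noise, which otherwise
  biases the slope slightly toward zero. Rates are total length loss per
  minute (both ends combined), matching kymograph length measurement; a
  Theil–Sen option exists for traces with pauses.
* **Off-rates** (`koff_mle()`): right-censored exponential MLE,
  $\hat k = U / \sum_i (d_i - \Delta)$ with $U$ uncensored events and
  $\Delta$ one frame interval (1/8.7 s). The $\Delta$ subtraction matches
  how kymograph durations are read: an event overlapping $m$ frames is
  recorded as $m\Delta$, which for uniform phase carries exactly one extra
  frame interval in expectation. Profile-likelihood confidence intervals.
* **On-rate** (`kon_rate()`): events per (time × microtubule length ×
  concentration), with a Poisson standard error.
* **ATPase** (`atpase_rate()`): slope of [ADP] vs time divided by active-site
  concentration (HPLC mode), or the absorbance slope converted through the
  NADH extinction coefficient (default 6220 M⁻¹cm⁻¹, a standard constant not
  printed in the source work) in coupled mode.
* **Coupling stoichiometry** (`tubulins_per_atp()`): relative route
  $S = S_{\mathrm{comp}} \cdot (v_t/v_c) \cdot (k_c/k_t)$ anchored to a
  comparator of known stoichiometry (full-length MCAK removes ~1 tubulin per
  ATP on GMPCPP-stabilized microtubules). From the published tables this
  gives 4.97 against full-length MCAK and 7.64 against the EGFP fusion; the
  published value of 5.8 ± 1.4 lies between, and the exact computation
  behind it is not described — so the comparator is an explicit parameter
  and no test pins 5.8. An absolute route via lattice geometry
  (8 nm rise × 13 protofilaments = 1625 dimers/µm) is exposed for when a
  per-microtubule motor count is available.

`fold_change()` propagates uncertainty on the log scale from `sd/sqrt(n)`;
rows without a reported n (the single-molecule table prints none) fall back
to using sd directly, which is conservative.

# Synthetic data: what it emulates, and what a green test means

Generator defaults are the stated experimental world: 350-residue motor
domain, a two-clade (13A/13B-like) 16-leaf tree with mean root-to-tip 1.0
substitutions/site (75-leaf variant available), 8.7 Hz movies of 200 frames,
40 pM motor on ~8 µm microtubules, 40 nM motor for depolymerization imaged
every 5 s (2 s for fast constructs), and the measured rates as generating
parameters. Length-trace noise is σ = 0.2 µm (≈2–3 pixels; chosen, not from
the source). Sequence evolution is site-independent with single-block
deletions (no insertions, no heterotachy); dwell observation reproduces
frame-overlap quantization and movie-end censoring, but not point-spread
functions or photobleaching.

A green recovery test therefore establishes that each estimator is unbiased
and correctly calibrated *for data with the assumed statistical structure*
— exponential dwells, linear shrinkage, Gaussian noise. It cannot establish
anything about image segmentation, non-exponential dwell mixtures, or
pausing, which are outside the generators. Two numbers the recovery suite
deliberately does not assert: the published long-event fractions (23%/20%
above 2 s) exceed the single-exponential prediction $e^{-2k}$ at the fitted
off-rates, an unreconciled feature of the source data; and sequence-identity
figures for the real family (81% ancestral-vs-consensus) depend on
unpublished upstream settings — on the packaged synthetic family the same
statistic computes to ~73–79%, reported but not asserted.

# Numerical choices

* Per-column partials rescaled by their maximum, log-accumulated; impossible
  columns return `-Inf` cleanly.
* Enumeration-oracle agreement asserted to 1e-10; round-trips to 1e-9.
* Posterior ties broken by equilibrium frequency then alphabet (exact-tie
  tolerance 1e-12); consensus ties as above (score tolerance 1e-9).
* Indel rate optimized on a log grid over [1e-4, 1e3] by Brent search.
* Recovery acceptance runs use the per-condition replicate counts the
  published tables report (12/18 traces, 4 basal assays fit jointly):
  with single short traces a ±3 s.e. band has too few residual degrees of
  freedom to reach its nominal coverage, which is a property of small-sample
  t statistics, not of the estimators.

# Known limitations

* No branch-length or topology optimization; the tree is trusted.
* Marginal (not joint) reconstruction only; no posterior sampling of
  ancestral sequences.
* The consensus is unweighted; tree-based sequence weighting is out of scope.
* The Sf9 codon table is a labelled synthetic stand-in.
* Diffusion coefficients, image processing and drug-binding models are out
  of scope.

# A worked example

```{r example}
sim <- evolve_alignment(sim_config(seed = 1, n_leaves = 16, depth = 0.5,
                                   length = 120, indel_rate = 0.05))
rec <- asr(sim$alignment, sim$tree)
anc <- ancestral_sequence(rec)
round(sequence_identity(anc, sim$root_seq), 1)   # % of the true root recovered

rep <- run_comparison_report()
subset(rep, id %in% c("depol_fold_anc13_vs_mcak", "tubulins_per_atp_vs_mcak"))
```
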