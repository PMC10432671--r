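---
title: "From somatic variants to validated neoantigens: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From somatic variants to validated neoantigens: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neovax)
```

# Scope

`neovax` implements the computational spine of a personalized neoantigen
vaccine workflow for triple-negative breast cancer: post-call somatic
variant filtering, enumeration of mutant MHC class I epitope candidates,
allele- and anchor-aware selection on predicted binding, quantification of
cell-based binding assays (EC50/IC50), IFN-γ T-cell responder calling,
31-mer long-peptide design, immunopeptidome matching, and candidate-funnel
summary tables. Upstream sequence processing (alignment, variant calling,
annotation, HLA typing) and the external binding predictor itself are out
of scope; the package consumes their outputs as files and bundles a
deterministic mock predictor for offline use.

Every numeric threshold lives in a single `neovax_config()` object, and a
synthetic-data module generates each input format with known ground truth
so the whole pipeline is testable without patient data.

# The model and procedure

## Somatic variant filtering

A missense call is retained when all six rules hold, each relative to a
configurable threshold (defaults in parentheses):

1. tumor coverage strictly above `coverage_min` (10 reads);
2. normal coverage strictly above `coverage_min` (10 reads);
3. normal-tissue variant allele fraction strictly below `normal_vaf_max`
   (1%);
4. tumor variant allele fraction strictly above `tumor_vaf_min` (15%);
5. variant reads on both strands (≥ 1 forward and ≥ 1 reverse);
6. population minor allele frequency at most `pop_maf_max` (1%); variants
   absent from population databases are treated as MAF 0.

`apply_somatic_filters()` returns the retained set plus an audit table
naming, for each rejected variant, the first rule (in the order above)
that failed. VAFs are read-count ratios; zero-depth rows raise an error
rather than silently dividing by zero.

## Epitope enumeration

For each retained variant the mutant protein is formed by a single
residue substitution (the reference residue is checked against the
protein, and synonymous "mutations" are rejected). A mutation-centered
context of up to 21 residues (`flank_len` = 10 on each side, truncated at
the protein termini, never padded) supports enumeration of every window
of the configured lengths that contains the mutated position — 9-mers for
the human arm, 8/9/10-mers for the murine arm. For a mutation at protein
position *p* in a protein of *n* residues, the number of length-*L*
windows is

$$\min(p,\; n - L + 1) - \max(1,\; p - L + 1) + 1,$$

which is *L* for interior sites (so 27 candidates per variant over
lengths 8–10). Each mutant window is paired with its wild-type
counterpart, which differs at exactly the mutant offset; windows touching
non-standard residues (`X`) are dropped.

## Selection rules

Human candidates are scored per allele against predicted affinity in nM
(from a file produced by an external predictor, or the bundled mock).
Anchor positions are 1, 2 and the C-terminus. With the allele threshold
`thr` (`HLA-A*02:01` 1000 nM, `HLA-A*03:01` 1500 nM, `HLA-A*24:02`
2500 nM) and wild-type minimum `wt_min`, the decision cascade per
candidate is:

* mutant affinity not below `thr` → rejected (`rejected_affinity`);
* wild-type affinity above `wt_min` → **selected**
  (`anchor_differential`: the mutation changes binding, typically at an
  anchor);
* both bind similarly (wild type below `thr` and affinity ratio within
  `similar_affinity_fold` = 3) at a TCR-facing position → **selected**
  (`nonanchor_similar`: the mutation is presented to the T-cell
  receptor);
* similar binding at an anchor position → rejected
  (`rejected_position`);
* otherwise → rejected (`rejected_wt`).

Murine candidates are selected when their best percentile rank over
H2-D^b^ and H2-K^b^ is at most `mouse_rank_max` = 1.0 (inclusive).

## Binding assays

Stabilization assays titrate peptide from `top_concentration` (100 µM)
in `n_dilutions` (8) serial `dilution_factor`-fold (3×) steps and report
MFI. `fit_ec50()` fits a four-parameter logistic in log~10~
concentration; the EC50 is the concentration at the midpoint of baseline
and plateau. If the nonlinear fit fails, a monotone log-linear
interpolation between the two points bracketing half-max is used; flat
curves (signal range below 10% of scale) yield no EC50. Competition
assays convert signal to inhibition relative to the no-competitor FITC
reference; the IC50 is the fitted concentration at 50% inhibition. A
peptide is called a binder only when the EC50/IC50 is determinate within
the tested range **and** the plateau reaches `binder_plateau_fold` (1.5×)
the no-peptide control (stabilization) or maximal inhibition reaches 50%
(competition).

A subject responds to a peptide when the stimulated %IFN-γ^+^ of CD8^+^
is at least `responder_fold` (2×) the unstimulated background,
inclusively; zero backgrounds are floored at `zero_floor_pct` (0.1%) so
trace signals do not auto-qualify.

## Long peptides and immunopeptidome matching

`design_31mer()` builds a vaccine long peptide as a native `lp_len`
(31)-residue window of the mutated protein that contains one H2-D^b^ and
one H2-K^b^ minimal epitope from the same variant plus the mutant
residue, centered on the mutation as nearly as the termini and epitope
coverage allow (ties toward the N-terminus). No linkers or concatenation:
pairs whose union cannot fit a native window are an error.
`match_candidates()` queries an MS-eluted ligand list by exact string
identity, with an optional isoleucine/leucine-equivalent mode (off by
default) because mass spectrometry cannot distinguish the two.

## Summary tables

`summarize_counts()` tallies, per sample and allele, predicted binders,
assay-confirmed binders, immunogenic peptides (confirmed binders with at
least one responding subject) and tumor-displayed peptides, with a totals
row. Rates are percentages **truncated** (not rounded) to one decimal —
the convention under which 44/66 prints as 66.6% — implemented as
`floor(10·pct + 1e-9)/10`, the tiny nudge guarding against binary
floating-point representation error. The bundled
`tnbc_funnel_counts()` table reproduces the published study funnel
(93 predicted, 66 tested in patients, 44 bound, 66.6%, 30 immunogenic)
when re-tallied through the same code path via
`expand_counts_to_records()`.

# Synthetic data: scope and limits

Generators are pure functions of their parameters and a seed (the
caller's RNG stream is untouched) and plant the downstream answer by
construction:

* `gen_variants()` plants passing variants and, per filter rule, decoys
  failing **that rule alone** (single-fault construction), with protein
  sequences consistent with each call;
* `gen_affinity_table()` plants the selected set via the
  differential-binding route;
* `gen_binding_curves()` draws the 4PL with Hill slope 1 (the paper gives
  no curve shape; the half-maximal EC50 definition is slope-invariant)
  and multiplicative Gaussian noise, because flow-cytometry MFI error
  scales with signal;
* `gen_tcell_assays()` separates responders (≥ 2.5× effective background)
  from non-responders (≤ 1.5×) so the 2× rule recovers them exactly;
* `gen_ms_peptides()` draws background 9-mers that never collide with
  planted peptides — composition realism is irrelevant since matching is
  exact-string.

`simulate_bundle()` wires these into one coherent study whose truth sets
are nested (responders ⊆ binders ⊆ selected) and recoverable end to end
at zero noise. The generators model none of: predictor error structure,
inter-replicate assay variance, HLA typing uncertainty, or peptide
synthesis failures.

# Numerical notes

* **4PL fitting** uses Levenberg–Marquardt with box constraints, falling
  back to an unconstrained fit when the constrained one fails (observed
  on exact inhibition-scale data), and sanity-checks the coefficients
  (finite; Hill slope in (0.05, 20]; log~10~ EC50 in [−6, 6]) before
  accepting.
* **Unsaturated curves bias EC50 upward slightly.** With 5%
  multiplicative noise, curves whose true EC50 (10–32 µM) approaches the
  100 µM top concentration have an extrapolated plateau, and the
  plateau/EC50 trade-off under noise yields a mean log-EC50 bias of
  about +0.04 (≈ 4%) with a heavy upper tail. The Monte-Carlo recovery
  check therefore asserts a 10% geometric-mean tolerance; this is a
  property of fitting unsaturated dose-response data, not of the
  implementation.
* **Truncated rates** use the `floor` + half-ulp-nudge formula above;
  naive `floor(pct*10)/10` misprints exact ratios such as 50% whose
  binary representation falls just below the decimal.
* **Seed hygiene**: all generators run under a saved-and-restored RNG
  state; `simulate_bundle()` derives independent per-stage seeds from the
  master seed so stage outputs are individually reproducible.

# Design decisions

* The wild-type minimum of the differential rule is stated in the source
  protocol only for HLA-A\*02:01 (1000 nM); for the other alleles it
  mirrors their own mutant threshold, preserving the differential-binding
  intent. Override via `neovax_config(wt_affinity_min = ...)`.
* "Similar" binding of mutant and wild type means an affinity ratio
  within 3-fold, both below the allele threshold.
* Long peptides are native protein windows (never concatenated epitopes
  with linkers), matching the vaccine design they model.
* The binder call's plateau requirement (1.5× control) operationalizes an
  under-specified "MFI taken as measure for the stabilizing effect":
  a formal half-max crossing on a barely-elevated curve is not binding.

# Problem sizes

The default simulated study (`simulate_bundle()`) uses 6 true somatic
variants plus 12 single-fault decoys (2 per rule), 9-mer enumeration
(typically 54 candidates), 2 planted selections per variant, ~8 binders
with EC50s log-uniform in 1–31.6 µM, 3 subjects, and a 200-peptide
background ligandome. The acceptance checks additionally fit 100 noisy
curves and evaluate a 64-cell filter boundary grid and a 108-cell
selection grid against independent oracles.
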