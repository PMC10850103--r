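---
title: "Models and methods behind splicescope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind splicescope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicescope)
```

## The scientific problem

The 20S proteasome degrades proteins by peptide hydrolysis, but it can also
ligate two non-contiguous fragments of its substrate — splice-reactants —
into spliced peptides. When a single purified protein is digested in vitro,
a spliced product can arise from one molecule (cis-spliced, in forward or
reverse order) or from two molecules of the same protein (homologous
trans-spliced, modeled as overlapping substrate intervals). Identifying
these products by mass spectrometry is statistically hard because the
spliced search space of a protein is several orders of magnitude larger
than the non-spliced one, which inflates the risk of false spliced
assignments. splicescope implements the computational side of this problem:
the combinatorics of the search space, origin-aware rescoring of candidate
peptide-spectrum matches (PSMs) with stratified error control, filtering of
label-free kinetic quantification, and downstream sequence-preference
analytics, all exercisable end to end on synthetic data.

## Coordinate model and search-space combinatorics

A product is located by 1-based inclusive indices: the first splice-reactant
spans `(i, j)`, the second `(k, n)`; the P1 residue (forming the
acyl-enzyme intermediate with the catalytic threonine) is at `j`. The
classes partition all coordinate tuples:

* forward cis: `k >= j + 2`, so the intervening sequence has length at
  least one;
* reverse cis: `i >= n + 1`, disjoint reactants with the first product
  reactant downstream (a zero-length gap is allowed because the reversed
  concatenation differs from the contiguous substring);
* homologous trans: overlapping intervals, `max(i, k) <= min(j, n)`, which
  forces two substrate molecules;
* forward-adjacent tuples (`k = j + 1`) are never spliced products — their
  sequence equals a non-spliced peptide.

Closed-form counts (`count_nonspliced()`, `count_forward_cis()`,
`count_reverse_cis()`, `count_trans()`) are paired with an independent
brute-force enumerator (`brute_force_counts()`) that classifies every tuple
explicitly; the test suite checks exact agreement for all substrate lengths
up to 30, product lengths up to 15 and minimal reactant lengths 1 and 2.
This dual route is the package's oracle for the gap conventions above: the
partition used here is the one consistent with all three closed forms.

`map_peptide()` inverts the construction: exact string matching first, then
all two-fragment splits, with leucine/isoleucine treated as equivalent
(equal monoisotopic mass). Resolution precedence is non-spliced > cis >
trans, and a sequence explainable by both forward and reverse cis locations
is a cis multi-mapper. All locations of the resolved class are kept;
`n_origins` is their count and downstream quantities are divided by it
(`multi_mapper_adjust()`), which conserves total intensity exactly.

## Spectrum similarity and the predictor interface

Rescoring uses three similarity features plus the origin flag:

* the normalized spectral contrast angle
  `SA = 1 - 2 acos(cos(v1, v2)) / pi` on L2-normalized intensity vectors
  (1 = identical, 0 = orthogonal);
* the Spearman rank correlation of matched fragment intensities (undefined
  for constant vectors; imputed with the origin-stratum median);
* the absolute error between the observed retention time and a linear map
  of the predicted indexed retention time (iRT).

The spectrum predictor is an interface: any function returning annotated
fragment m/z, normalized intensities and a predicted iRT can plug in. The
shipped implementation, `mock_predict()`, is deterministic — fragment m/z
from monoisotopic residue masses (cysteine carried as carbamidomethylated),
intensities from a fixed string hash, iRT from a fixed hydropathy scale —
so every test and simulation is reproducible without a trained model or a
network connection.

Fragment matching uses a 0.02 Th tolerance by default (a 20 ppm mode is
available), each predicted fragment taking its nearest observed peak within
tolerance; the nearest-m/z tie-break is our choice where the underlying
procedure is not specified. The iRT calibration is fitted by least squares
on the high-confidence subset (non-spliced PSMs with spectral angle above
0.9, falling back to all non-spliced PSMs below 20 points), and its
"10-fold cross-validation" is implemented as deterministic out-of-fold
residual reporting: the folds diagnose the fit, they select nothing.

## Origin-aware rescoring and stratified error control

The rescorer is a percolator-style iterative linear scheme, re-implemented
here because only its behavior, not its internals, is fixed by the
method it emulates: initialize the score with the spectral angle; per
iteration compute target-decoy q-values, take targets at q <= 0.01 as
positives, fit an L2-regularized linear discriminant (ridge, lambda = 1,
z-scored features, 5 iterations) of positives versus decoys, and rescore.
The q-value estimator is the monotonized `(#decoys >= s + 1)/(#targets >= s)`;
peptide-level reports collapse to the best PSM per distinct sequence before
estimation. Posterior error probabilities come from an isotonic regression
of the local decoy fraction in score order, converted by `p/(1 - p)` under
the standard equal-null-mass assumption and clamped to [0, 1]; the group
FDR of a stratum is the mean PEP over its accepted members. Because the
spliced origin flag is a feature, a null-heavy spliced stratum drives its
weight negative and the spliced group FDR above the non-spliced one — the
automatic penalization the stratified design is meant to produce.

Identification-stage filters follow fixed rules: PSMs whose peptides carry
deamidation or N-terminal acetylation are removed (whole spectra are
removed when such a non-spliced PSM scores within 30% of the best spliced
PSM for that spectrum — we read "within 30%" as a base score of at least
0.7 times the best spliced score); accepted spliced peptides are re-scored
against every isobaric non-spliced substring (6 ppm precursor tolerance)
with the frozen model weights and removed only when a competitor scores
strictly higher; contaminant candidates displace an assignment only with a
strictly higher spectral angle. Both ties retain the already-accepted
hypothesis — the conservative direction.

## Kinetic quantification filtering

Per-peptide MS1 intensities over the digestion time course (0, 1, 2, 4 and
24 h by default, in biological x technical replicates) are processed in
fixed order: substrate-contaminant removal (spliced peptides keyed on the
splice-site junction `(j, k)`; control-detected non-spliced peptides
removed only when their 0 h intensity exceeds every later time point), then
background-noise filtering — the peptide background is its maximum 0 h
intensity across replicates, the global cut-off is the median of those
backgrounds, and every measurement is censored below and reduced by
`max(peptide background, global cut-off)` — then averaging of available
technical replicates, then the reference-time rule: peptides with no
positive intensity at the reference time (4 h by default, configurable for
faster-digesting substrates) are dropped. Two choices the source procedure
leaves open are fixed here: the reference-time rule is evaluated per
biological replicate (presence in one replicate retains the peptide, which
keeps the most data), and the global cut-off is computed over peptides with
at least one 0 h measurement, peptides never measured at 0 h receiving a
background of 0. The background filter consumes raw tables only and marks
its output, so accidental double subtraction is refused rather than
silently compounded.

## Sequence-preference analytics

* **SCS-P1 / PSP-P1** (`compute_scs_psp()`): per-residue summed
  reference-time intensities of products with that residue at P1
  (hydrolysis: non-spliced C-termini; splicing: C-termini of N-terminal
  splice-reactants), normalized within a 29-residue window truncated at the
  termini — truncation rather than padding keeps the percentages
  well-defined.
* **Background databases** (`simulate_background_qualitative()`): the
  spliced background repeatedly samples the four coordinates uniformly with
  replacement and accepts only valid spliced tuples within the
  identification length window, until it holds 50 times the identified
  spliced set; the non-spliced background samples from the enumerated
  non-spliced space. Accepted tuples are uniform over the valid set by
  construction, and all sampled sequences are re-mapped for multi-mapping.
  The quantitative variant assigns intensities uniformly within the
  observed range of the same product class.
* **Divergence logos** (`build_pwm()`, `quantitative_logo()`): position
  weight matrices over the 12-position junction window (P6..P1 before the
  site, P1'..P6' after it — the next substrate residues for non-spliced
  peptides, the second reactant onward for spliced ones) are built from
  log10-transformed intensities summed per amino acid and position and
  column-normalized. Intensities below 10 are clamped to weight 0 so the
  matrices stay non-negative. Letter heights are the per-position
  Jensen-Shannon divergence in bits (base-2 logs; the intensity transform
  stays log10) times the normalized column difference, zero where the
  columns are equal.
* **Coverage and hotspots** (`coverage_profile()`, `hotspot_split()`):
  per-residue summed log10 intensities of all covering peptides are min/max
  scaled, smoothed with `smooth.spline()` under generalized
  cross-validation (the smoothing parameter is recorded by that choice, not
  hand-set), and min/max scaled again. Detected P1 residues are split at
  the coverage median: ties at the threshold and the odd residue go to the
  hotspot side, deterministically; if all coverages are equal the split is
  refused as ambiguous rather than guessed. The hotspot sequence stretch is
  every residue at or above the lowest hotspot coverage. Conditional motifs
  follow Bayes' rule, `P(R|H) = P(H|R) P(R) / P(H)` with `P(H) = 0.5` by
  construction; `P(H|R)` is the ratio of summed coverages inside hotspots
  over all regions (kept as a raw conditional-probability matrix), `P(R)`
  and the resulting conditional matrices are column-normalized. Randomized
  backgrounds permute the coverage values along the substrate 100 times
  under a seed. For splicing, only N-terminal splice-reactants enter the
  hotspot analyses, matching the acyl-intermediate logic.
* **Generation efficacy** (`generation_efficacy()`): identified unique
  products divided by the type's own theoretical space summed over the
  identification window.

## The synthetic-data generator

`simulate_substrate()`, `simulate_digestion()` and `simulate_psm_table()`
emulate the statistical structure the pipeline assumes, not the physics of
fragmentation or chromatography. Defaults are fixed once as the study
conditions: spliced peptides are ~12.5% of unique products and
trans-spliced a few percent of those; hydrolysis P1 propensities favor
hydrophobic and acidic residues and splicing P1 propensities small polar
ones; N-terminal splice-reactants are short (geometric length, parameter
0.45); abundances follow saturating accumulation `A0 (1 - exp(-rate t))`
with multiplicative lognormal noise (CV 0.25) plus a small additive 0 h
background floor, over 2 biological x 2 technical replicates. Observed
spectra are mock predictions with 0.004 Th m/z jitter; retention times
follow a fixed linear iRT map with 0.4 min jitter. A configured fraction of
assignments is swapped to a wrong peptide of the same origin class, so the
emitted truth table supports exact empirical-FDR and precision-recall
computation.

Decoy candidates are drawn from the reversed substrate, one per spectrum,
with the decoy's stratum sampled at the substrate's theoretical
search-space ratio (capped to [0.05, 0.95] so both strata stay populated):
in any two-database search the spliced decoy space dwarfs the non-spliced
one, and this imbalance is precisely what lets the origin feature learn to
penalize spliced matches. All randomness flows from the single config seed
through fixed offsets, so every artifact is bit-reproducible.

What the generator does not emulate — correlated fragment noise, isotope
envelopes, chimeric spectra, charge-state heterogeneity, retention-time
drift between runs — bounds what passing tests show: they validate the
statistical machinery (error control, filters, analytics) under the stated
assumptions, not instrument-level behavior on real data.

## Problem sizes and numerical choices

The test suite runs the combinatorics oracle to substrate length 30, the
rescoring calibration at 5,000 targets + 5,000 decoys over 10 seeds, the
spliced-free benchmark with ~300 embedded peptides over 10 seeds, and the
background-sampler uniformity check with 50,000 tuples on a length-8
substrate — sizes chosen so each property is measured with real statistical
power on a single CPU. Ties in q-value computation are handled by
evaluating counts at score thresholds (ties share the threshold);
standardization guards constant features by leaving them inert; PWM columns
with no observations become uniform; degenerate min/max scalings return
all-zero profiles rather than NaN.

## Known limitations

Three-fragment splicing and heterologous trans-splicing across different
proteins are representable in the location type but not enumerated.
The generation-efficacy denominators use the closed forms, which describe
products no longer than the substrate — products longer than the substrate
(possible for trans splicing on very short substrates) are outside the
identification window in any realistic setting. The PEP estimator assumes
the decoy set carries the null mass of the target set; with very few decoys
its group FDRs are noisy. The mock predictor shares none of a trained
model's sequence-specific intensity structure, so absolute spectral-angle
distributions on real data will differ from the synthetic ones.
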