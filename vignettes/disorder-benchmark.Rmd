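---
title: "Benchmarking structure-derived and sequence-based disorder predictors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking structure-derived and sequence-based disorder predictors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idrbench)
```

## The problem

Intrinsically disordered regions (IDRs) lack a fixed equilibrium structure;
predicting which residues of a sequence are disordered is a long-standing
sequence-analysis task. Structure prediction offers two indirect routes to
the same per-residue quantity: the model's own confidence (pLDDT, 0–100,
low where the structure is unreliable — often because there is no structure
to predict) and the solvent accessibility of the predicted structure
(disordered regions expose far more surface than folded ones). `idrbench`
is the evaluation machinery needed to compare such structure-derived scores
with dedicated disorder predictors on a common reference: calibrated binary
evaluation, protein-set stratification, resampling significance tests, and
a marker analysis that asks *for which proteins* the structure-derived
route is competitive.

## Score transforms

**pLDDT route.** `plddt_to_disorder()` maps confidence to propensity as
$s_i = 1 - \mathrm{pLDDT}_i/100$, a strictly order-reversing transform, so
ROC-based evaluation is unaffected by any further monotone rescaling.
pLDDT is read from the temperature-factor column of the PDB-format model
(`read_plddt_from_model()`), taking the alpha-carbon value per residue and
falling back to the residue's first atom when no CA exists (logged).

**RSA route.** Accessible surface area is normalized by the maximum
accessibility of each residue type in an extended Gly-X-Gly tripeptide
(`asa_to_rsa()`, capped at 1) and smoothed with a sliding arithmetic mean of
width 25 (`smooth_rsa()`). The packaged Gly-X-Gly maxima are the
theoretical values of Tien et al. (2013); the table is data, not code, and
can be swapped via `max_asa_table(path)`. Because published normalization
tables differ by a few percent, exact numerical agreement with any given
external RSA pipeline requires using that pipeline's table. At the termini
the window is truncated to its in-range part rather than padded: padding
with zeros would bias terminal residues toward order, and truncation keeps
the output inside the data range (tested as an invariant).

**Optimized rank.** Structure predictors emit several ranked models;
`select_best_model()` picks, per protein, the model whose derived profile
maximizes per-protein ROC AUC, breaking ties toward the native rank. AUC is
used as the selection criterion because it is the headline residue-level
metric of the whole pipeline; the choice is isolated in one function and
swappable. By construction this optimized-rank scenario can only improve on
the rank-1 model, and the pipeline verifies that direction.

## Calibration and metrics

Binary calls are not taken from each method's own cut-off. Instead
`calibrate_threshold()` chooses, per method, the threshold at which the
number of pooled residues scoring *strictly above* it best matches the
native number of disordered residues in the same pool. This removes the
between-method confound of systematically over- or under-calling disorder.
Candidates are the observed scores plus 0; with heavy ties the target can
be unattainable, in which case the objective |achieved − target| is
minimized and ties are broken toward fewer predicted disordered residues
(the conservative side). On tie-free pools the match is exact, which the
tests assert.

Residue-level metrics are micro-averaged over the pooled residues of a
protein set: ROC AUC in the Mann–Whitney form with ties counted 1/2, AUPRC
as uninterpolated average precision, and MCC / F1 / sensitivity from the
confusion counts at the calibrated threshold. Zero denominators return 0
with a degeneracy flag rather than an error, so a dataset-level aggregation
over many methods never aborts on an edge case; callers that need to treat
undefined values differently can inspect the flag. Per-protein AUC
(`per_protein_auc()`) is kept separate and returns `NA` for single-class
proteins — fully disordered proteins have no ordered residues and no
defined AUC, and are excluded from per-protein analyses.

Protein-level content is evaluated with MAE (mean absolute error between
predicted and native content fractions) and Spearman correlation with
average ranks for ties, which equals the classical
$1 - 6\sum d_i^2/(n(n^2-1))$ formula on tie-free inputs. Fully disordered
protein (FDP) classification uses strict content cut-offs — a protein is
native-FDP when its native content exceeds the cut-off and predicted-FDP
when its predicted content exceeds the same cut-off. Applying the same
cut-off to predictions is a design decision: it keeps the declaration rule
symmetric and parameter-free, and the three cut-offs (0.99, 0.90, 0.80)
give nested predicted sets by construction.

## Stratification

IDRs are maximal runs of disorder labels (`extract_idrs()`), so segment
lengths conserve the label count exactly and painting segments back
reproduces the series — both tested as invariants. The protein sets are:
shortIDR (has IDRs, all ≤ 30 residues), longIDR (≥ 1 IDR > 30; the
conventional long-IDR threshold), bindingIDR (≥ 1 IDR carrying any binding
annotation — binding is a region-level property, so one annotated residue
flags the whole IDR), non-terminusIDR (has IDRs, none containing residue 1
or L; "at the terminus" means strict contact, with no tolerance margin,
the simplest defensible rule), and FDP99/90/80. Dataset summaries count the
*qualifying* IDRs of each set — the short IDRs for shortIDR, the binding
IDRs for bindingIDR, all member IDRs otherwise — which is what makes the
per-set median IDR lengths diverge.

## Significance testing

Method comparisons are repeated over random protein subsets: 20 disjoint
5% slices for residue-level and content metrics, and 20 independently
sampled 20% subsets for the FDP sets, whose few dozen positives would make
5% slices uninformative (20 subsets of 20% cannot be disjoint; independent
draws give the small expected overlap). The paired per-subset differences
are screened with the Anderson–Darling test at p = 0.05; normality not
rejected leads to a paired t-test, otherwise the Wilcoxon signed-rank test.
Normality is tested on the *differences* because that is what the paired
t-test assumes. Constant non-zero differences or fewer than 8 observations
route directly to the Wilcoxon branch (the Anderson–Darling statistic needs
8 points, and a constant sample is maximally non-normal); all-zero
differences return `=` with p = 1. Verdicts are two-sided at α = 0.05 with
no multiple-testing correction — each cell of a report table is an
individual comparison, which is the convention in this benchmarking
literature and is flagged here as a caveat for anyone scanning a whole
table for significant entries. Orientation is explicit: MAE is
lower-is-better and its symbols invert. A type-I-error test (two
exchangeable synthetic methods, 200 replicates) keeps the realized
false-positive rate of the whole scheme near the nominal level.

## Sequence markers and the competitive split

The marker analysis asks which proteins a structure-derived predictor
handles as well as the dedicated predictors. Per protein, eight markers are
computed from binary profiles: sequence length; putative disorder content;
putative binding-region content; number and maximal length of putative IDRs
(runs of ≥ 4 consecutive predicted-disordered residues — the ≥ 4 rule
applies only to counting IDRs); putative coiled-coil content; minimal
terminus distance of putative-IDR residues (distance of residue $i$ is
$\min(i-1, L-i)$, so terminal residues score 0; sentinel $L+1$ when no
putative IDR exists); and the composite score
$\sum_{i\,\text{pred.\ disordered}} \min(i-1, L-i)\, /\, L$, which is low
when disorder is scarce and/or terminal. The composite deliberately sums
over *all* predicted-disordered residues, not only those inside ≥ 4-runs,
reading "putative disordered residues" literally.

A protein is *competitive* when the structure-derived per-protein AUC
clears a floor (typically the best predictor's dataset-level AUC) and is
not below the lower bound of a 95% normal-approximation interval,
$\bar a - 1.96\, s/\sqrt{k}$, over the protein's $k$ panel AUCs. The
interval construction is one possible reading of "within the confidence
interval of the panel"; it is isolated in `competitive_split()` so
alternates can be swapped in. Marker distributions between the two groups
are compared with two-sided Wilcoxon rank-sum tests — the markers are
counts and bounded fractions, far from normal, and the rank test matches
the box-plot style summaries such analyses report. The selection rule then
keeps proteins strictly below the competitive-group medians on all active
(significant) markers; strictness at the median and monotonicity under
relaxed medians are both tested.

## The synthetic generator

`gen_reference()` produces proteins as alternating ordered/disordered runs
with geometric lengths, log-normal sequence lengths, region-level binding
painting, and a `p_terminus` probability that the first/last run is
disordered. The defaults describe a CAID-like cohort: 646 proteins, mean
length ≈ 520 residues, ≈ 16% disordered residues, mean disordered-run
length 65, 31% binding IDRs, and about half of the disordered proteins
touching a terminus. `gen_predictor()` draws residue scores from a latent
binormal model squashed to [0,1] by the logistic; since ROC AUC is
invariant under the strictly increasing squash, the expected AUC is exactly
$\Phi((\mu_1-\mu_0)/(\sigma\sqrt2))$, giving the test suite a closed-form
target. The default separation of 1.2 yields AUC ≈ 0.80, the level of
strong disorder predictors. `gen_af2_series()` adds spatially
autocorrelated noise (moving-average of white noise, rescaled to unit
marginal variance) to a class signal, producing pLDDT anti-correlated with
disorder and RSA elevated inside disordered runs. Seeds are threaded by
stable hashing of (seed, stream label, id), so generation is reproducible
independently of iteration order, and the global RNG state is restored
afterwards.

What the generator does **not** emulate: amino-acid composition biases of
real IDRs (sequences are uniform letters); the spatial coherence of real
*sequence-based* predictor errors — `gen_predictor()` noise is independent
per residue, which makes protein-level FDP classification much harder for
generated sequence predictors than for real ones (real predictors call
whole regions); and any structural realism in the pLDDT/RSA series beyond
autocorrelation. Passing tests therefore demonstrate the correctness of the
evaluation machinery, not the real-data ranking of any method.

## Numerical and scale choices

Strict `>` is used for binarization, FDP content cut-offs and the
below-median rule, with boundary cases pinned by tests. Scores marginally
outside [0,1] in third-party prediction files (excess ≤ 0.05) are clamped
with a warning — tolerant of rounding, while larger excursions remain hard
errors. AUC and MCC arithmetic is done in double precision throughout;
pooled benchmarks reach ~3.5×10^5 residues, where integer products would
overflow. The test suite validates the ROC implementation against
exhaustive pairwise enumeration up to length 12 and against an independent
ROC package; MCC against the point-biserial correlation identity on random
confusion tables; and the binormal recovery at 10^5 residues within ±0.01
of the closed form. Resampling checks use cohorts of 100–650 proteins and
200 replicates, sizes at which the whole suite runs in well under a minute
while keeping Monte-Carlo error small relative to the asserted bands.

## Known limitations

- Real-data benchmark tables depend on third-party prediction files and
  structure models; the pipeline recomputes them when those inputs are
  supplied but ships none of them.
- The terminus rule, the predicted-FDP declaration rule, the
  optimized-rank selection metric and the competitive-interval construction
  are each a single documented choice among defensible alternatives, kept
  behind one function each.
- No multiple-testing correction across verdict grids (by design, see
  above).
- mmCIF models are not parsed; PDB format only.
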