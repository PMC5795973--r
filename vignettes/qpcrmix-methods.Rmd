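---
title: "Methods: joint mixed-model qPCR quantification and adipose fatty-acid analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint mixed-model qPCR quantification and adipose fatty-acid analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

`qpcrmix` implements the statistical core of a nutrigenomic feeding
trial in growing pigs: two breeds (a fat Mediterranean breed, Iberian,
and a lean cosmopolitan breed, Duroc), two isocaloric diets differing in
energy source (HO, high-oleic sunflower oil, versus CH, carbohydrate),
and two feeding statuses per animal (a 24 h fast versus 3 h
postprandial), giving an eight-cell treatment structure. Gene expression
of 13 lipid-metabolism candidates is measured by qPCR in adipose biopsies;
carcass adipose composition is measured as fatty-acid percentage
profiles. This vignette records the models, the defaults and the
numerical choices, and what the simulators do and do not emulate.

## The transformation

A qPCR thermocycler reports a quantification cycle `Cp`; expression on a
log2 scale is recovered through the per-gene amplification efficiency
`E` (2 = perfect doubling, estimated from standard-curve dilution
series and supplied as a percentage, `E = 1 + pct/100`):

    y = -log2(E^-Cp) = Cp * log2(E).

`y` rises with `Cp`, so **larger y means lower expression**. The product
form avoids underflow of `E^-Cp` at late cycles; it is exact, not an
approximation. Efficiencies at or below 1 (non-amplifying reactions)
are rejected rather than clamped.

## The joint mixed model

All genes — targets and normalisers — enter one linear mixed model on
the transformed scale:

    y_gijklr = TG_gi + P_gj + B_gk + A_gl + D_ijkl + e_gijklr

with `TG_gi` the fixed mean of gene `g` in treatment cell `i`
(cell-mean coding, 15 genes x 8 cells), and independent random effects
for plate-within-gene `P`, housing-box-within-gene `B`,
animal-within-gene `A`, the biopsy sample `D` (animal x status, shared
across all genes — this is what carries sample loading and
reverse-transcription variation), and the well residual `e`. Technical
replicates enter as individual wells; the residual is well noise.

Design readings worth making explicit:

* One variance per grouping, shared across genes. The model notation
  gives one symbol per grouping; gene-specific variances per grouping
  are deliberately not fitted (see Limitations).
* Estimation is REML through `lmerTest::lmer()`; variance components
  whose unconstrained optimum would be negative are pinned at 0 by the
  optimiser's boundary. Random groupings observed at a single level are
  dropped and reported with variance 0.
* An empty gene-by-cell combination makes the cell-mean design rank
  deficient; `fit_expression_model()` refuses and names the empty cells
  instead of silently dropping columns.

The package also ships an *independent* evaluator of the restricted
log-likelihood, `reml_loglik()`, plus `gls_beta()` and
`reml_brute_force()` (multiplicative grid plus Nelder--Mead polish on
the log-variance scale). These exist so the optimiser can be audited on
small instances without trusting its own criterion; the test suite
requires the fitted criterion to be within 1e-6 of the brute-force
maximum on instances of up to 40 observations.

## Contrasts, normalisation and fold changes

Each effect is a zero-sum weight vector over the eight cells
(`effect_contrasts()`): main effects average the four first-named-class
cells (Iberian, fed, HO) against the other four; interactions are
differences of differences. For a target gene the contrast applies to
its own cell means; with reference-anchored normalisation (the default)
the same contrast averaged over the reference genes is subtracted, and
the standard error is computed from the combined weight vector. Both
routes to normalisation are present in the model — the shared sample
effect `D` absorbs sample loading even with `normalize = FALSE` — and the
flag exposes the `D`-only variant because flat reference genes make the
two asymptotically equivalent.

Inference per contrast: `t = diff/se` with Satterthwaite denominator
degrees of freedom (via `lmerTest`), two-sided. Satterthwaite was
adopted because it yields fractional, contrast-specific df — at the
study scale the breed contrasts (between animals) land in the tens
while residual-dominated status contrasts can reach the thousands —
consistent with the wide df spread such analyses report. No
Kenward--Roger correction is offered.

Back-transformation (`to_fold_change()`):

    FC = 2^-diff,  SE(FC) = 2^-se,
    95% CI = [ 2^-(diff + t(df,.975) se), 2^-(diff - t(df,.975) se) ].

The interval is asymmetric around FC on the ratio scale but symmetric in
log2; the geometric mean of the bounds equals FC to numerical precision,
which the tests assert at 1e-9 and which also holds for the published
fold-change tables this package reproduces. FC > 1 means higher
expression in the first-named class (diff < 0 on the y scale because y
is inverted).

## Reference-gene stability

Two published stability notions are implemented from their method
descriptions, as deterministic contracts:

* **geNorm M**: for candidate `j`, the mean over other candidates `k` of
  the SD (denominator n-1) across samples of `y_j - y_k`;
  `genorm_rank()` excludes the largest-M gene stepwise until two remain,
  with ties broken by excluding the lexicographically later identifier.
  The pairwise-variation criterion for choosing the *number* of
  references is not implemented; the count is a user parameter (the
  motivating study fixed it at 2).
* **NormFinder-style stability**: samples are centred by their
  across-gene mean; per group the bias `d` (group mean minus overall
  mean) and within-group variance `s^2` combine as
  `sqrt(d^2 + s^2/n)`, averaged over groups. With a single group the
  measure is defined as the SD of the centred values (the general
  formula would degenerate to `s/sqrt(n)`; the SD convention is fixed
  here as the contract — rankings agree either way). The sample
  grouping is a required argument with no default, because the choice
  (breed, status, or their crossing) is an analysis decision.

`select_references()` combines the two rankings by their mean and
breaks ties by identifier. Wells are collapsed to one mean per gene and
biopsy sample first: stability is about biological samples, not
technical replicates.

## Multiplicity

The inter-gene correlation matrix is computed from per-sample gene
means anchored on the references, and the effective number of tests is

    m_eff = 1 + (M - 1) (1 - Var(lambda)/M),

with `Var` over the eigenvalues using denominator M-1 (the classical
eigenvalue-dispersion convention; variants differ and this one is fixed
deliberately), clipped to [1, M]. Benjamini--Hochberg step-up then uses
`m_eff` as the multiplier while keeping observed ranks:
`q_(i) = m_eff p_(i) / i`, monotonicity enforced from the top rank,
clipped at 1, and floored at the nominal p so an "adjusted" value never
undercuts it. Adjustment is applied per effect family (all genes within
one effect), not globally — the families answer different questions and
the per-family reading is recorded here as the package's choice. The
matrix feeding `m_eff` (which genes, which normalisation) is likewise a
package decision, not a reconstruction of the original analysis.

## Fatty-acid composition

`compute_indices()` sums percentage columns into SFA, MUFA, PUFA, n-6
and n-3, and computes the n-6/n-3 ratio per sample (LS means of
per-sample ratios are not ratios of summed LS means; the per-sample
route is the only arithmetic consistent with the published tables).
The default memberships reproduce the published index rows exactly at
two decimals; notably C17:1 is excluded from MUFA and C20:2 from PUFA
because the printed index rows only sum without them. Whether those
exclusions were intentional upstream cannot be determined; they are the
defaults here, flagged, and overridable.

Each fatty acid or index is modelled separately:
breed, diet and breed x diet fixed (cell-mean coding), litter and box
random. LS means average cell means over the other factor. On balanced
designs GLS equals OLS, so LS means are then exactly linear in the
response — the property the index/member consistency tests exploit. The
layer screen (run within each breed before pooling layers) augments the
model with layer and layer x diet and adds an animal random intercept,
because both layers are measured on the same animal and omitting the
pairing term would miscalibrate the layer test.

## The simulators

`simulate_qpcr()` is the generative reading of the joint model: draw
every random component from its zero-mean normal, add the true cell
means, and invert the transformation per gene (`Cp = y / log2(E)`).
Defaults emulate the study conditions:

* 30 Iberian / 19 Duroc males; diets 17/13 and 10/9 (HO/CH) as in the
  trial; both statuses biopsied per animal; 13 targets + ACTB and PPIA
  with the trial's amplification efficiencies; triplicate wells.
* 19 litters split 10 Iberian / 9 Duroc (litters cannot cross breeds),
  allocated round-robin within breed; two housing boxes per
  breed-by-diet cell.
* Plates hold ~4 animals (both statuses, all genes) and are filled
  *stratified across treatment cells*. The true layout is unknown;
  balanced plating is standard practice, keeps the components
  identifiable, and keeps plate noise out of the breed contrast, which
  block-by-animal plating would confound.
* Variance components (squared log2 units):
  plate 0.04, box 0.005, animal 0.05, sample 0.08, residual 0.02 —
  i.e. SDs of 0.20, 0.07, 0.22, 0.28 and 0.14. These are unstated
  upstream and were chosen once from typical qPCR magnitudes: a well
  replicate SD of ~0.14 cycles-equivalents, reverse-transcription and
  loading variation a bit under 0.3, and modest between-animal
  biological noise for well-regulated adipose genes. All are config
  fields, not constants.
* Baseline cell means of 25 log2 units put Cp in the 26--29 cycle
  range. `inject_effect()` adds `w * diff / sum(w^2)` of a contrast's
  weight pattern so the contrast evaluates exactly to `diff`.

`simulate_fa()` perturbs breed-by-diet cell mean vectors
multiplicatively (equivalently, on the centred log-ratio scale) with
per-fatty-acid litter, box and residual draws, then closes each profile
to 100%. Zero mean entries stay exactly zero. The cell means are built
from the published marginal LS means additively
(`cell = breed + diet - diet average`), so the breed marginals
reproduce the published breed columns exactly, and an unreported
`other` component absorbs the remainder to 100 so closure and the
published values coexist. Log-scale SDs (litter 0.03, box 0.02,
residual 0.05) reproduce between-animal SDs of about one percentage
point on a 20% fatty acid, in line with the published SEMs.

The two simulators seed independent streams; generating one never
perturbs the other.

What the simulators do **not** emulate: heavy-tailed or skewed well
noise, gene-specific variance components, amplification-curve artefacts
or Cp-calling error beyond the residual, real (unknown) plate and box
layouts, within-profile correlation between fatty acids beyond what the
multiplicative noise and closure induce, and any genotype-by-diet
structure in the composition. Passing calibration and recovery tests on
these simulations therefore validates the estimation machinery under
the model's own assumptions, not the model's adequacy for real data.

## Numerical choices and degenerate inputs

* REML convergence is delegated to `lme4` defaults; the audit route
  (grid + polish of the standalone likelihood, tolerance 1e-6) is the
  package's check that the optimum is real.
* Noise-free data (all variances 0) is accepted: the fit interpolates
  the cell means exactly and all components collapse to ~0; the
  optimiser warns, the estimates are still exact.
* Ties in stability rankings break lexicographically; zero-information
  contrasts (all-zero weights, weights not summing to zero) and
  correlation matrices that are asymmetric or lack a unit diagonal are
  errors, not warnings. A gene constant across samples gets correlation
  0 with a warning.
* Percentages are validated non-negative and summing to at most 100
  plus a 0.5 rounding allowance; fatty-acid headers are normalised to
  canonical spellings, unknown columns kept with a warning.

## Problem sizes used by the tests

Simulation-based checks use sizes chosen to keep the default suite
around a quarter of an hour end to end: the null-calibration check runs
13 study-scale fits (1014 contrast draws), fold-change recovery 40
study-scale replicates, interval coverage 120 replicates on a reduced
five-gene panel, and the stability-selection check 200 seeded panels.
The acceptance script repeats the same computations at somewhat smaller
sizes. Thresholds (type-I error in [0.03, 0.07], recovery within 15% in
at least 90% of replicates, coverage 95% +/- 2.5%) are properties of
the method, not of the replicate counts.

## Known limitations

* Shared (not gene-specific) variance components can misstate
  gene-level uncertainty when a few genes are far noisier than the
  rest; the published breed intervals suggest real heterogeneity of
  exactly that kind, so absolute interval widths from this model should
  be read accordingly.
* Satterthwaite is the only df method offered.
* The effective-tests matrix construction and the per-family adjustment
  scope are package decisions where the upstream analysis is silent.
* `geNorm`'s optimal-reference-count criterion V(n/n+1) is out of scope.
* No chromatogram or fluorescence-curve processing: Cp values and
  fatty-acid percentages are taken as given.
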