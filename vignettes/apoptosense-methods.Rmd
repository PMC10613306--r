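---
title: "Methods: pathway-informed apoptosis-sensitivity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pathway-informed apoptosis-sensitivity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apoptosense)
```

## The problem

Most chemotherapeutics kill tumour cells through the intrinsic apoptosis
pathway. Whether a medulloblastoma cell commits to apoptosis is not decided
by any single protein but by the balance of interacting BCL-2 family
members upstream of mitochondrial outer-membrane permeabilisation (MOMP)
and of the caspase machinery downstream of it. `apoptosense` implements a
systems-level analysis of that balance: it takes the expression of 14
apoptosis-regulatory proteins, measured relative to a common HeLa
reference, and asks (i) whether the profile predicts sensitivity to
cisplatin-induced apoptosis, (ii) what fraction of a patient cohort looks
sensitive when protein levels are inferred from tumour mRNA, and (iii)
which anti-apoptotic protein a given state depends on, via an equilibrium
stress-dose score with in-silico BH3-mimetic dosing and a reduced
caspase-execution model.

## Functional groups

Raw expression enters as a sample-by-14 table relative to HeLa (linear
scale; the HeLa profile is all ones by construction). Nine derived
features — *functional groups* — encode pathway structure through
arithmetic that mirrors the protein interactions:

| group | definition | rationale |
|---|---|---|
| `BAX_BAK` | BAX + BAK | redundant pore-forming effectors |
| `ANTIAPOPTOTIC` | BCL2 + BCLXL + MCL1 | redundant guardians sequestering effectors |
| `APAF_C9` | APAF1 × CASP9 | apoptosome formation requires both |
| `XIAP_over_C3` | XIAP / CASP3 | stoichiometric inhibition of executioner caspase |
| `SMAC`, `BID`, `BIM`, `PUMA`, `NOXA` | pass-through | independent regulators |

Groups are computed on the linear relative-expression scale. `XIAP/CASP3`
is undefined at `CASP3 = 0`, which is reported as an error naming the
sample rather than propagated as `Inf`.

Group values are z-scored across the training panel using the sample
standard deviation (n−1 denominator; appropriate for the small panels this
analysis is designed for, and the default of common statistical software).
The convention is recorded inside the fitted object so either convention
can be reproduced downstream.

## PCA, component retention, and the discriminant

PCA is performed on the z-scored group matrix via the covariance of the
standardised data — equivalent to correlation PCA — so the Kaiser rule
"retain eigenvalues > 1" keeps components that carry more variance than any
single standardised input. Eigenvector sign is made reproducible by
orienting every loading column so that its largest-magnitude entry is
positive.

Classification of high- versus reduced-sensitivity samples uses a
two-class Fisher discriminant with pooled within-class covariance and
equal priors, fitted on the scores of all Kaiser-retained components (a
`pcs` argument restricts to user-chosen components when only a sub-plane
is of interest). Numerical choices:

* A pooled covariance with reciprocal condition number below 1e−10 is
  shrunk toward the identity, `(1−λ)S + λ·mean(diag(S))·I` with λ = 0.1,
  and the coefficient is reported. With six training samples this is a
  realistic contingency.
* The discriminant is required to separate the training set whenever it is
  linearly separable in the retained-PC space. Fisher's direction does not
  guarantee this (a single outlying sample can sit on the wrong side even
  of a separable set), so when Fisher leaves training errors a
  deterministic perceptron pass is attempted and kept only if it achieves
  perfect separation; the method used is recorded in the model.
* Samples exactly on the plane are assigned `reduced_sensitivity`. For a
  tool whose downstream use is deciding whether treatment escalation is
  warranted, the conservative tie is the reduced-sensitivity call.

Biplot contributions are reported as the raw orthonormal loadings of the
two requested components, with the scaling convention recorded in the
output, so magnitudes are comparable across runs.

## Patient inference from cohort mRNA

Patient tumours contribute mRNA, not western blots. Protein profiles are
inferred by interquartile mapping: per protein, the cohort mRNA
interquartile range [Q1, Q3] is mapped linearly onto the interquartile
range of the cell-line protein values, using type-7 (linear interpolation)
quantiles — the convention is stored in the fitted map. Patients older
than 18 years, or of unknown age, are removed first (paediatric focus);
removals are counted by reason.

Values outside the mRNA IQR follow a configurable policy: `"linear"`
continues the same affine map into the tails, `"clamp"` pins them at the
mapped Q1/Q3. The module default is `"linear"` (the mapping statement
constrains only the interquartile region, and extrapolation preserves
ordering information in the tails); the orchestrated pipeline
(`run_full()`) defaults to `"clamp"` because unbounded extrapolation can
drive an inferred `CASP3` to the zero clip and make the `XIAP/CASP3` ratio
undefined for individual patients, aborting an otherwise valid cohort run.
Negative inferred values are clipped to zero with a warning in either
policy.

Projected patients are z-scored with the **cell-line training
parameters** — not cohort-refitted ones — then projected with the stored
loadings and classified with the stored discriminant. This keeps the
patient positions on the same scale as the training panel, which is the
point of anchoring mRNA to the protein IQRs in the first place. Feeding
panel-derived pseudo-patients through the full chain reproduces the
training classification exactly; this end-to-end consistency is enforced
by tests.

## Equilibrium stress-dose surrogate

The packaged model of BCL-2 family buffering is a deliberately small
equilibrium surrogate, not a reproduction of any published kinetic model.
Each anti-apoptotic protein (BCL-2, BCL-XL, MCL-1) binds each ligand
(BAX, BAK, a generic promiscuous stress-induced BH3 activator, and any
administered mimetic) by mass action with configured dissociation
constants. Free concentrations solve the coupled binding equations by
damped fixed-point iteration (damping 0.5, tolerance 1e−8 µM); every
conservation law is satisfied at the returned point, and the solver is
checked in tests against the closed-form 1:1 binding quadratic and a
brute-force grid oracle.

The **stress dose** of a state is the minimal activator dose at which the
free fraction of the BAX+BAK pool reaches the MOMP threshold θ (default
0.1, configurable), found by bisection (upper bound 1000 µM, width
1e−4 µM at termination). Lower stress dose = more apoptosis-primed. An
unreachable threshold is flagged in the result, not thrown. The score is
monotone non-decreasing in each anti-apoptotic total and non-increasing in
each mimetic dose; both properties are exercised over a thousand seeded
random states in the acceptance tests.

Modelling the stress as a single promiscuous BH3 species matches the
interpretation of the score as a generic BH3-only dose. All dissociation
constants live in a versioned YAML file
(`inst/extdata/surrogate_config.yaml`). Protein–protein Kds default to the
low-nanomolar magnitude of measured BCL-2-family interactions, with mild
selectivity structure (BCL-2 preferring BAX, MCL-1 preferring BAK, BCL-XL
binding both); mimetic Kds follow the published sub-nanomolar selectivity
of ABT-199, WEHI-539 and S63845 for BCL-2, BCL-XL and MCL-1 respectively.
These are documented placeholder defaults: users with measured affinities
should override the file. With the defaults, dosing WEHI-539 collapses the
stress dose of a BCL-XL-dominated state and ABT-199 that of a
BCL-2-dominated state, the qualitative behaviour the score exists to
expose.

## Reduced caspase-execution model

Downstream competence is simulated with a five-reaction mass-action ODE:
apoptosome assembly (APAF-1 + pro-caspase 9), catalytic caspase-3
activation by the apoptosome, reversible XIAP inhibition of active
caspase 3, SMAC sequestration of XIAP, and substrate cleavage by free
active caspase 3. Integration uses `deSolve::lsoda` (rtol 1e−8, atol
1e−10). Total caspase-3 and total XIAP pools are conserved along
trajectories (tested), cleavage starts at zero, is non-decreasing and
bounded by one. A profile is **execution-competent** when cleavage reaches
80% within 60 minutes of MOMP (time 0 of the simulation). Rate constants
are placeholder defaults in the same YAML config, chosen so that a
HeLa-magnitude input executes comfortably within the hour while a
XIAP-saturated, SMAC-depleted state stalls — the two regimes the
competence rule distinguishes. Relative expression is converted to µM
through reference HeLa concentrations
(`inst/extdata/hela_concentrations.yaml`), again documented placeholders
intended to be overridden with measured values.

## Pharmacology utilities

* **Viability normalisation.** (A450 − A620) per well divided by the mean
  background-corrected vehicle signal; vehicle mean is 1 by construction.
* **IC50.** Four-parameter log-logistic ("variable slope") fit by
  Levenberg–Marquardt, with the top free rather than fixed at 1, matching
  the common plate-assay default. The fit is parameterised in log(IC50)
  with data-derived start points, so it is deterministic. Non-convergence
  yields a flagged result with diagnostics; a monotone increasing
  dose–viability trend warns.
* **Synergy.** Webb's fractional product: `score = fAB / (fA·fB)`;
  `< 0.8` strong synergy, `[0.8, 1)` weak synergy, `= 1` additive (within
  1e−9), `> 1` antagonism. Replicate-level scores are averaged after the
  ratio.
* **BH3 profiling.** Each JC-1 590 nm trace is summarised by its area
  under the curve over the 3 h window (trapezoid; an endpoint mode is
  available since the choice of summary is not canonical), then anchored
  between DMSO (0% depolarisation) and FCCP (100%). Values are *not*
  clamped to [0, 100]: out-of-range responses are real signals of anchor
  noise and are reported as-is. Dynamic profiling (Δ-priming) is the
  per-peptide difference treated − baseline.

## Synthetic data: what it emulates, and what it does not

Every input has a generator with recorded ground truth, so each stage is
testable without external downloads:

* **Panels**: per-protein log-normal baselines (relative expression is
  positive and right-skewed; unit median, σ_log = 0.5). Reduced-sensitivity
  samples receive the planted class effect — anti-apoptotic proteins up,
  SMAC and BID down — shifted on the log scale by `separation` within-class
  standard deviations. A fixed-seed six-sample stand-in panel
  (`synthetic_cellline_panel()`) carries the cell-line names used in the
  documentation; it is synthetic and labelled as such.
* **Cohorts**: latent protein truth drawn around the panel medians, mRNA
  coupled through a Gaussian copula with the normal-scores correlation set
  to `2·sin(π·ρ/6)` so the *Spearman* correlation hits the requested ρ.
  Ages include adult and unknown entries to exercise the paediatric filter.
* **Plates**: exponential-decay fluorescence with per-condition true
  depolarisation fraction and multiplicative noise.
* **Dose–response**: log-spaced doses bracketing the true IC50 two decades
  either side, multiplicative Gaussian noise.

The generators deliberately omit batch and plate effects, molecular
subgroup structure, censored/limit-of-detection values, and
platform-specific mRNA distributions. Tests passing on synthetic data
therefore demonstrate correctness of the computations and the recovery
behaviour of the estimators under the stated noise models — not
performance on real cohort data, which additionally depends on those
unmodelled features.

## Problem sizes and runtime choices

The test-suite defaults are sized for a desk run: six-sample training
panels; 200-seed recovery studies at 20+20 samples per class; 1,000-state
stress-dose monotonicity scans; 266-patient synthetic cohorts; 2 × 10^6
point grids for the brute-force binding oracle. These sizes make the full
suite complete in about two minutes on one core while leaving every
statistical check well-powered.

## Known limitations

* The classifier is a two-class linear discriminant by design; no
  cross-validation, multi-class or nonlinear extension is provided.
* The equilibrium and caspase surrogates preserve input/output contracts
  and qualitative orderings of the full kinetic treatments they stand in
  for; their absolute scores depend on the placeholder constants and
  should not be compared across differently-configured runs.
* Quantile mapping assumes the cohort's mRNA ranks reflect protein ranks;
  genes with strong post-transcriptional regulation will violate this.
* A cohort projection is only as comparable as its platform scale; the
  interquartile anchoring removes location/scale but not distribution-shape
  differences.
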