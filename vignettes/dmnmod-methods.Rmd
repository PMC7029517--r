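---
title: "Models and methods behind dmnmod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dmnmod}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmnmod)
```

## The scientific question

Older African Americans develop Alzheimer's disease (AD) at roughly twice
the rate of older non-Hispanic Caucasians, and cohort studies have reported
race-dependent trajectories of CSF tau biomarkers despite similar amyloid
changes. `dmnmod` implements a moderation analysis asking whether race
changes the relationship between default-mode-network (DMN) functional
connectivity and three AD severity measures — a composite cognitive
Z-score, CSF A&beta;42, and CSF total tau — and a bootstrap *enrichment*
test asking whether those race-dependent connectivity changes concentrate
in one particular subsystem block (midline core &harr; dorsomedial) rather
than being scattered across the network.

Because the human data this design emulates are protected, the package
ships a synthetic cohort generator as a first-class, tested module. Every
statistical claim the package makes is assessed against data it generated
itself under known truth; what that does and does not establish about real
data is discussed at the end.

## The node model

Eleven ICA-derived DMN components are modeled as abstract labeled nodes in
the three Andrews-Hanna subsystems: dorsomedial (TP, vlTC, dlTC, dmPFC,
TPJ), medial temporal (pHG, HIP, pIPL), and midline core (PCU, PCC,
vmPFC). All $\binom{11}{2} = 55$ unordered node pairs are enumerated in a
deterministic canonical order (node ids assigned lexicographically by
abbreviation; pairs ordered lexicographically on the id pair). Every pair
belongs to exactly one of six blocks; the three inter-subsystem blocks
have sizes $3\times5 = 15$ (midline-dorsomedial), $3\times3 = 9$
(midline-temporal) and $5\times3 = 15$ (dorsomedial-temporal). The
lateral temporal cortex is kept as two distinct nodes (ventrolateral and
dorsolateral) because the component taxonomy distinguishes them. No
spatial information (coordinates, masks) is attached: the source design
derived its components empirically and published no coordinates, so
spatial reproduction is out of scope by construction.

## The synthetic cohort generator

`generate_cohort()` draws a two-race, three-diagnosis cohort whose default
cell sizes (Caucasian NC/MCI/AD = 31/25/16; African American = 27/28/10;
n = 137 total) and biomarker distributions reproduce the demographic table
of the emulated study at the race &times; diagnosis cell level. Choices
that matter:

* **Truncated normals, not log-normals.** Cohort tables report arithmetic
  mean (SD); drawing from a normal truncated at zero keeps that pair as
  the parameterization. For variables whose mean is several SDs above
  zero (age, education) the truncation is immaterial and sample moments
  converge to the configured values; for skewed CSF markers in small
  cells (e.g. AD-stage A&beta;42) truncation shifts the realized mean
  upward slightly — a deliberate trade for parameter transparency.
* **Composite cognition by diagnosis.** Cognitive Z is drawn per diagnosis
  from normals with means (0, −0.8, −2.3) and SD 0.7, matching the
  reported cognitive Z rows to the first decimal and preserving the
  NC &gt; MCI &gt; AD ordering in expectation.
* **APOE &epsilon;4 carrier rates** are not printed in the emulated
  demographic table; defaults of 0.30 (Caucasian) and 0.37 (African
  American) are typical of AD-spectrum research cohorts. All binary risk
  traits are Bernoulli at race-specific prevalences taken from the table.
* **Head motion.** Mean framewise displacement is drawn from a truncated
  normal (mean 0.30 mm, SD 0.15 mm, floor 0.02 mm). The default cohort
  emulates the *post-QC* sample, so essentially no subject exceeds the
  3 mm exclusion threshold; QC behavior is exercised by configuring a
  high-motion cohort explicitly.

### Planting effects

Connectivity truth is expressed per subject as an 11&times;11 target
correlation matrix. A baseline structure (0.4 within subsystems, 0.15
between, positive definite by construction) is modified by *effect
specifications*: for a planted pair,

$$r = \tanh\!\big(\operatorname{atanh}(r_0) + \beta_{\text{main}} x +
\beta_{\text{race}} I + \beta_{\text{int}}\, I x\big),$$

where $x$ is the subject's biomarker value on its raw scale (Z units for
cognition, pg/mL for CSF markers), $I$ indicates African American race,
and $r_0$ is the pair's baseline. Working on the Fisher (atanh) scale
keeps targets inside (−1, 1) while staying nearly linear at the
$|r| \le 0.5$ magnitudes of reported connectivity coefficients. Raw-scale
betas were chosen (over standardized ones) so a planted coefficient lives
on exactly the scale the downstream regression estimates: the reported
tables print per-pg/mL slopes of order 0.003, which is only consistent
with raw-scale modeling. Planting can break positive definiteness; the
matrix is then repaired deterministically by eigenvalue clipping at
$10^{-6}$ and rescaling to unit diagonal.

The default effect set plants the reported coefficient magnitudes:
baseline race offsets (−0.19, −0.31, −0.15) on three pairs, and
race &times; biomarker interactions concentrated in the
midline-dorsomedial block (cognition 0.14–0.20; A&beta;42 −0.001 to
−0.002 per pg/mL; t-Tau 0.003–0.004 per pg/mL) plus one medial
temporal-midline pair. One printed t-Tau interaction (0.02) contradicts
its own confidence interval and is planted at 0.003, the magnitude of its
table's other t-Tau rows.

### Time courses and motion

Component time courses are 124 volumes at TR = 3 s of i.i.d. draws from a
zero-mean unit-variance multivariate normal realized through the Cholesky
factor of the subject's target matrix — no hemodynamic model, no temporal
autocorrelation, no scanner noise spectrum. Motion traces are random
walks over the six rigid-body parameters whose increments are rescaled so
the trace's mean framewise displacement equals the subject's record
exactly.

## The connectivity chain

The package implements only the *temporal* tail of a resting-state
preprocessing chain (everything spatial — realignment regression,
nuisance covariates, normalization, smoothing — precedes its entry point
and is out of scope):

1. **Discard** the first 10 volumes (magnetization equilibrium).
2. **Band-pass 0.01–0.08 Hz**: an ideal rectangular frequency-domain
   filter. DFT bins outside the band (including DC) are zeroed and the
   series inverse-transformed. The ideal filter was chosen over an IIR
   design because it is deterministic, exactly idempotent, and trivially
   testable against a direct DFT oracle; it matches the convention of the
   standard preprocessing toolboxes. Detrending beyond DC removal is off
   by default.
3. **Pairwise Pearson correlation** over the 55 enumerated pairs. Raw
   $r$ is the primary measure (the emulated analysis correlated component
   time courses with no stated transform); a Fisher-z option
   (`fisher = TRUE`) is exposed for sensitivity analyses and for
   parameter-recovery simulations (below).

Framewise displacement is the summed absolute volume-to-volume change of
the six parameters with rotations mapped to arc length on a 50 mm sphere;
the QC rule excludes subjects with mean FD &ge; 3 mm (inclusive, per the
stated wording "3 mm and higher"). The FD convention is recorded in the
function signature so alternatives remain pluggable.

## The statistical engine

Each node pair is analyzed with ordinary least squares:
connectivity ~ covariates + biomarker + race + race&times;biomarker, with
race coded 0 = Caucasian (reference) / 1 = African American, covariates
age, sex, mean FD and APOE &epsilon;4 by default, and listwise deletion.
Although the emulated analysis is described as MANCOVA, every reported
quantity is a per-pair coefficient with CI and unadjusted p — which
univariate models produce — so per-pair OLS is the engine and no
multivariate omnibus statistic is attempted. The scan over 55 pairs
shares one QR decomposition across outcomes (tested identical to
`stats::lm` per pair). Three scans make up the standard design:
cognition and A&beta;42 in all subjects, t-Tau only in the
amyloid-positive stratum (A&beta;42 strictly &lt; 192 pg/mL).

Multiple testing is controlled within each scan's 55 p-values (matching
the per-table correction of the source design, never across scans):
Benjamini-Hochberg step-up at FDR 10% via `stats::p.adjust`, plus Storey
q-values with $\pi_0$ estimated at fixed $\lambda = 0.5$ — the spline
$\pi_0$ estimator is unstable at m = 55, so the fixed-&lambda; form is
used and recorded. With $\pi_0$ capped at 1 the q-values reduce exactly
to BH-adjusted p-values, which the tests assert.

The confirmatory ANCOVA averages each subject's inter-subsystem entries
(15/9/15 pairs) and tests the race term by a type-II F (race dropped from
the main-effects model race + diagnosis + age + sex).

## The enrichment bootstrap

The package's core novel procedure: pool the 165 interaction p-values
(55 pairs &times; 3 biomarkers), and separately the 45 from the
midline-dorsomedial block; from each pool draw 1500 simulated 3&times;5
matrices of p-values with replacement; count matrices containing &ge; 3
entries with p &lt; 0.05; compare the two counts with a 2&times;2 Pearson
chi-squared (df = 1, no continuity correction). Cells are sampled
ignoring the (pair, biomarker) labels, exactly as the source workflow
describes; stratified sampling by biomarker is available behind a flag.
The two bootstraps use independent RNG streams derived from the master
seed. The per-entry threshold 0.05 inside the counting rule is a config
field (the source text never states it).

Because matrix cells are i.i.d. draws, the count divided by 1500
converges to the closed-form binomial tail
$P(\mathrm{Bin}(15, f) \ge 3)$ at the pool's significant fraction $f$ —
the package carries this as `binomial_expectation()` and uses it as the
analytic oracle for the sampler.

Two documented divergences from the published numbers:

* The published statistic "X²(2, N = 3000) = 487.53" is not reproducible
  from its own counts (791/1500 vs 192/1500) under any standard
  2&times;2 chi-squared variant, and df = 2 is inconsistent with a
  2&times;2 table. The package computes the textbook df = 1 statistic
  and treats printed counts as data, not as an oracle.
* **The test is anticonservative under the null by construction.** The
  block pool (45 values) and global pool (165) are finite samples; their
  empirical significant fractions differ by sampling noise alone, and the
  chi-squared then compares 1500-draw bootstrap proportions as if they
  were independent observations. Simulation at the study conditions shows
  the null rejection rate at &alpha; = 0.05 is far above nominal
  (roughly three in four null cohorts). The package implements the
  procedure faithfully and exposes the binomial oracle so users can see
  both pools' conditional expectations; interpreting the chi-squared
  p-value as a calibrated error rate is not supported.

## Numerical and design choices

* **Determinism.** Every random stage derives a 32-bit sub-seed from the
  master seed by an exact integer congruence; fixed config + seed
  reproduces byte-identical CSVs and manifests (manifests therefore carry
  no timestamps).
* **Degenerate inputs.** Zero-variance outcome columns fail a scan pair
  (recorded, non-fatal) but are an error in a single-pair fit;
  rank-deficient designs name the collinear columns; empty pass bands,
  empty pools, zero-margin 2&times;2 tables and missing cognitive domains
  are all explicit errors or defined degenerate results rather than NaN
  propagation.
* **Parameter-recovery scale.** Effects are planted on the Fisher scale,
  so coverage simulations fit the model with the `fisher = TRUE` option:
  on the matched scale the estimator is unbiased and 95% CIs attain
  nominal coverage. Fitting raw $r$ against an atanh-planted truth
  instead incurs a small, predictable tanh-attenuation (~5% of the
  coefficient at these magnitudes) — a property of the scale mismatch,
  not of the estimator.
* **Problem sizes in the test suite.** The acceptance checks run 200
  all-null cohorts (calibration), 500 cohorts per coverage target, and
  100 end-to-end enrichment replicates, all at the full study geometry
  (137 subjects, 124 volumes); structural and hand-worked checks are
  exact. These sizes give Monte-Carlo standard errors comfortably inside
  the asserted bands while keeping the suite fast.

## What passing tests do and do not show

The generator produces Gaussian, temporally white component signals with
exactly the planted correlation structure, biomarkers independent of
connectivity except through planted effects, and motion that never
corrupts the signal. Passing calibration and recovery tests therefore
establishes that the *pipeline* is correct: type-I error control, CI
coverage, FDR behavior and enrichment power hold when the model is true.
They do not establish robustness to hemodynamic autocorrelation,
non-Gaussian noise, motion-signal coupling, atrophy-driven component
misidentification, or unmodeled confounding between race and scanner
factors — none of which the generator emulates. Real-data claims about
the midline-dorsomedial concentration additionally inherit the
anticonservatism of the enrichment chi-squared discussed above.
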