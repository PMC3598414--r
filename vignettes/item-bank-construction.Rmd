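---
title: "Constructing a delirium screening item bank: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing a delirium screening item bank: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(delbank)
```

`delbank` reduces a large pool of dichotomous delirium indicators to a
small, screening-optimal set per Confusion Assessment Method (CAM)
feature. This vignette is the package's own account of the statistical
machinery: the models, their assumptions, every tunable parameter with its
default and rationale, what the synthetic-data generator does and does not
emulate, and the numerical choices made where the design was open.

## The measurement model

Responses are modeled with the two-parameter logistic (2PL) item response
model. For person $i$ with latent trait $\theta_i$ and indicator $j$ with
discrimination $a_j$ and difficulty (symptom severity) $b_j$,

$$P_j(\theta_i) = \Pr(y_{ij} = 1 \mid \theta_i) =
  \frac{1}{1 + \exp\{-D\,a_j(\theta_i - b_j)\}},$$

with $\theta \sim N(0,1)$ fixing the scale. The scaling constant $D$
defaults to 1.7, which makes the logistic curve approximate the normal
ogive, so reported parameters are near the probit metric that
tetrachoric-correlation-based estimators imply; all outputs record the
metric (`link`, `D`) rather than leaving it implicit. Item information is

$$I_j(\theta) = (D a_j)^2 P_j(\theta)\{1 - P_j(\theta)\},$$

which peaks at $\theta = b_j$ with value $(D a_j)^2/4$ and is additive
over locally independent items. The workflow's two standing assumptions —
unidimensionality and local independence — are not taken on faith: local
dependence is screened out empirically and dimensionality is assessed and
enforced by splitting before any 2PL is fit.

## Stage 1: tetrachoric correlations and local-dependency screening

Dichotomous indicators are correlated on the latent scale via the
tetrachoric model: each pair is assumed to dichotomize a bivariate normal
at thresholds fixed by the margins, and $\hat\rho$ solves the
upper-quadrant probability equation by safeguarded Newton iteration on a
Gauss–Legendre evaluation of the bivariate normal integral (compiled
code; the test suite checks it against an independent brute-force
bisection oracle to $10^{-4}$). Empty cells receive a 0.5 continuity
correction before estimation, the standard practice for sparse tables;
without it, permuted-data correlations of rare indicators jump to the
$\pm 1$ boundary and inflate the permutation-null eigenvalues that Stage 2
depends on. Estimability flags always use the raw counts.

A pair is *inestimable* when (a) an off-diagonal cell of its 2×2 table is
zero — the structural void a logically dependent pair produces — (b) a
margin has fewer than `min_margin = 5` positive or negative responses, or
(c) $|\hat\rho| >$ `boundary = 0.995`. The original signal for such pairs
was estimation-software error messages, which is not a portable criterion;
these three rules are its operational counterpart.

`iterative_screen()` repeatedly drops the indicator involved in the most
inestimable pairs until none remain, with a deterministic tie-break
(larger distance of the marginal proportion from 0.5, then lexicographic
id) chosen so that better-targeted indicators survive ties and results
are invariant to column order. Clinically essential indicators can be
forced to stay via `forced_retain`; if only forced indicators remain in
conflict the log records an unresolved status rather than dropping them.
Missing responses are handled pairwise (complete cases per pair)
throughout this stage.

Non-positive-semidefinite tetrachoric matrices are repaired by eigenvalue
clipping at $10^{-6}$ and rescaling to unit diagonal; the repair is used
only for eigen-analysis and factoring, and the raw matrix is retained.

## Stage 2: dimensionality

**Permuted parallel analysis.** Each of `n_permutations = 100`
permutations shuffles every indicator's responses independently across
persons, which preserves each margin exactly while destroying
inter-indicator association, then recomputes the tetrachoric matrix and
its spectrum. Root $j$ is significant when the observed eigenvalue
exceeds the 97.5th percentile of the permuted root-$j$ values; $m$ counts
leading significant roots and stops at the first failure (the behaviour
for non-contiguous significant roots is thereby defined, a case the
procedure's description leaves open). One hundred permutations resolve
the 97.5th percentile adequately (at least 40 are required); the
per-root false-positive rate on independent data measures ≈ 2.8% in the
package's own 500-replication calibration test, inside the 1–5% band
around the nominal 2.5%.

**Factor models.** The single-factor CFA is always fit; when $m > 1$, an
$m$-factor EFA (minimum-residual extraction, promax rotation, factor
signs normalized majority-positive) supplies the simple-structure pattern
— each indicator to its largest-absolute-loading factor, ties to the
lower index — for an $m$-factor correlated CFA and an orthogonal bifactor
model. All are fit by unweighted least squares on the repaired
tetrachoric matrix with the unit-diagonal (categorical) constraint, so
uniquenesses are implied by communalities. The fit chi-square is
approximated as $(n-1) F_{\min}$ from the least-squares discrepancy; this
is deliberately documented as an approximation — the mean-and-variance
adjusted chi-square of commercial categorical-data estimators is out of
scope — and CFI/RMSEA computed from it are used comparatively, not as
formal tests:

$$\mathrm{CFI} = 1 - \frac{\max(\chi^2 - df,\,0)}
 {\max(\chi^2_B - df_B,\,0)}, \qquad
\mathrm{RMSEA} = \sqrt{\frac{\max(\chi^2 - df,\,0)}{df\,(n-1)}}.$$

**Adjudication.** One dimension is retained when parallel analysis finds
a single significant root. Otherwise $m > 1$ is retained when at least
two of three signs hold: multiple significant roots; CFI improvement of
the $m$-factor CFA over the single-factor model of at least
`cfi_improvement = 0.01`; bifactor *large secondary loadings* (some
indicator's specific loading exceeds its general loading — one indicator
suffices, the minimal reading of an unquantified criterion). The
published procedure invoked an unquantified "preponderance of the
evidence" plus expert judgment; the two-of-three rule with a 0.01 CFI
threshold is its computational analogue, and expert overrides remain
available through the configuration. On a split, sub-sets with fewer
than `min_subset = 4` indicators are reported but not IRT-modeled,
mirroring the handling of a three-indicator secondary factor in the
motivating analysis.

## Stage 3: 2PL estimation and scoring

`fit_2pl()` maximizes the marginal likelihood by EM. The latent
distribution is integrated over `n_quad = 49` Gauss–Hermite nodes
transformed to the $N(0,1)$ measure (weights renormalized to sum to one;
the effective support is about $\pm 6$ trait units and estimates change
by under $10^{-3}$ between 49 and 101 nodes). The E-step computes
posterior node weights per person — missing responses simply contribute
nothing to the person likelihood, which is the estimator's natural
treatment of item-level missingness — and the M-step solves each item's
weighted logistic likelihood by full Newton iteration, so the marginal
log-likelihood is non-decreasing and is asserted so at every iteration.
Convergence is a maximum absolute parameter change below `tol = 1e-4`
(at most 500 iterations; indicator sets containing nearly degenerate
items with difficulties beyond 4 can sit on a likelihood ridge and
converge slowly, which is reported as a warning, not an error). The
trait scale is identified by the prior; if the data are inversely coded
the trait is reflected so that discriminations are majority-positive.
This full-information MML-EM estimator intentionally replaces the
limited-information weighted-least-squares estimator used in the
motivating analysis: it is portable, handles missingness without
imputation, and agrees with it asymptotically under the model.

EAP scores are posterior means under the $N(0,1)$ prior on a 201-node
Gauss–Hermite grid (denser than the EM grid because scores are compared
against a $10^{-5}$-level brute-force oracle in the tests); persons with
no observed responses receive the prior ($\hat\theta = 0$, SD 1).

## Stage 4: anchored selection

The screening anchor $\theta^{+}_{50}$ is the 50th percentile
(linear-interpolation type-7 quantile — the convention had to be fixed
somewhere and this is R's default) of EAP scores among persons rated
positive on the CAM feature. Indicators are ranked by $I_j(\theta^\ast)$,
descending, ties broken by $|b_j - \theta^\ast|$ then id, and the top
`k = 5` are retained (configurable 1–10; five follows the
diminishing-returns rationale for indicators per latent trait). The
rationale is explicitly a screening one: a severe symptom with a high
$b_j$ may discriminate superbly at trait levels far above the anchor yet
carry almost no information where feature-positive and feature-negative
persons actually separate.

When every indicator's information at $\theta^{+}_{50}$ falls below
`fallback_floor = 0.25` — the peak information of an item with
discrimination ≈ 0.59 at $D = 1.7$, a concrete reading of "very low
information content" — the anchor moves to the 75th percentile and the
selection is redone there, flagged as a fallback. A sensitivity block
re-ranks at the 25th/50th/75th percentiles and reports pairwise top-$k$
overlaps and Kendall's τ over full rankings (both, because it is not
recorded whether the original stability claim considered all indicators
or only the top five); `stable` means every pairwise top-5 overlap is at
least 4. Marginal reliability at the anchor is
$\mathrm{TI}(\theta^\ast) / \{\mathrm{TI}(\theta^\ast) + 1\}$, one minus
the error variance of the trait estimate under the unit-variance prior.

## The synthetic-data generator

No deposited cohort exists, so every stage is exercised against
synthetic cohorts whose generative structure matches what the analysis
assumes. `default_cohort_spec()` encodes the packaged default: ten latent
dimensions organised into seven CAM-feature-by-mode indicator sets (15,
11, 8+7, 8, 13, 10+5, 9+5 indicators — the feature-4 direct-interview
set is omitted, as it was judged redundant with inattention in the
motivating analysis), traits correlated 0.6 within a feature and 0.5
across features, discriminations uniform on $[0.5, 3.5]$ and difficulties
on $[-1.0, 4.5]$ (the span of published estimates, with one extreme
discrimination of 9.7 treated as a boundary artifact and capped — it
destabilizes recovery tests without changing any selection), 2%
missingness completely at random, and two parent–child dependency pairs
that create structural voids for the screening stage to find.

Feature-positive labels are produced by thresholding the true latent
trait of each feature's labeling dimension, optionally flipped with a
symmetric misclassification probability (`positivity_noise`, default 0):
the original feature ratings were clinician judgments, and thresholding
preserves their essential property that positives sit higher on
$\theta$. The common threshold 0.50961 was solved numerically (once,
against the multivariate-normal orthant probabilities) so that the CAM
rule $f_1 \wedge f_2 \wedge (f_3 \vee f_4)$ labels 13.3% of persons
delirium-positive under the 0.5 cross-feature trait correlation, the
prevalence of the motivating screening cohort; each feature is then
positive in ≈ 30% of persons.

What the generator deliberately does not emulate: longitudinal
fluctuation of symptoms, interviewer behaviour, polytomous responses,
informative missingness, and clinician rating processes beyond the
noisy-threshold model. Passing recovery tests therefore demonstrates
that the pipeline inverts its own generative assumptions at realistic
sample sizes — not that those assumptions hold in any particular
clinical data set.

## Numerical choices and degenerate inputs

* Tetrachoric solves are bracketed in $[-0.9999, 0.9999]$ with Newton
  steps falling back to bisection; boundary solutions are clamped, kept
  in the matrix for spectral work, and flagged inestimable.
* Permutations whose tetrachoric matrix contains an incomputable entry
  (a fully degenerate pairwise margin) are redrawn, up to ten times, and
  counted.
* Factor-model optimizations use `L-BFGS-B` with loadings bounded by
  ±0.999 and factor correlations by ±0.95; Heywood cases in EFA are
  clipped to unit communality with a warning.
* The bifactor model with only two specific factors is not globally
  identified for noiseless block-equicorrelated inputs; with real
  (noisy, heterogeneous) data the ULS minimum is effectively unique, and
  the large-secondary flag is read from the fitted minimum.
* Degenerate indicators (one observed category) are refused by name in
  `fit_2pl()`; upstream screening removes them in the pipeline.
* All randomness is seed-controlled; the pipeline derives one child seed
  per indicator set from the mandatory configuration seed, so a report
  is bit-reproducible given `(inputs, config)`.

## Scale of the packaged simulations

The test suite's simulation studies use the cohort size of the
motivating study, n = 4,598, for parameter-recovery (50 replications of
a 10-item set), dimensionality recovery (50 one-factor and 50 two-factor
sets), and end-to-end selection recovery (50 replications of a 12-item
set under well-populated item banks, plus 50 under the full
published-span banks for the anchor-percentile stability check);
parallel-analysis null calibration uses 500 replications at n = 1,000,
k = 10. These sizes were chosen to make Monte Carlo error small relative
to the thresholds being checked while keeping the whole suite
desk-scale.

## Known limitations

* No differential item functioning analysis (age, sex, race), no
  1PL/3PL/graded-response models, no multidimensional IRT estimation
  (multidimensionality is handled by splitting), and no
  computerized-adaptive-testing engine.
* CFI/RMSEA from $(n-1)F_{\min}$ are comparative indices here, not
  calibrated test statistics.
* The screening stage, faithful to its empirical signal, removes very
  rare indicators whose pairwise tables contain sampling zeros; on
  near-Guttman data (highly discriminating items spanning a wide
  severity range) this can be aggressive, which matches the behaviour of
  the original error-message-driven procedure.
* Selection quality is bounded by anchor estimation: EAP shrinkage pulls
  $\theta^{+}_{50}$ slightly toward zero relative to the true positive
  median, which can reorder items whose information curves cross near
  the anchor.
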