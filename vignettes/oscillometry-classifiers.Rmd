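---
title: "Explainable classifiers for respiratory oscillometry: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Explainable classifiers for respiratory oscillometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`oscml` builds classifiers of respiratory disease from forced oscillation
technique (FOT) impedance spectra, with a deliberate emphasis on models a
clinician can read: evolved arithmetic expressions, fuzzy pattern trees,
and shallow decision trees, evaluated side by side with the usual
black-box learners under a leakage-safe nested cross-validation harness.
This vignette explains the science inside each stage, the tunable
parameters and their defaults, the design decisions that were genuinely
open, and what the synthetic-data results do and do not establish.

## The eRIC circuit model

Respiratory impedance `Zrs(f)` is the complex ratio of oscillatory
pressure to flow at the airway opening; its real part is resistance and
its imaginary part reactance (both cmH2O·s/L here). The extended RIC
(eRIC) model interprets a spectrum with four mechanical analogs: central
resistance `R` in series with inertance `I` (cmH2O·s²/L), feeding a
parallel block of peripheral resistance `Rp` and compliance `C`
(L/cmH2O). The input impedance is

$$Z(\omega) = R + \frac{R_p}{1+(\omega R_p C)^2}
 + j\!\left(\omega I - \frac{\omega R_p^2 C}{1+(\omega R_p C)^2}\right),
 \qquad \omega = 2\pi f .$$

Total resistance is `Rt = R + Rp`. Two consequences drive the test
oracles: the real part decreases monotonically from `Rt` to `R`, and the
reactance crosses zero at the closed-form resonant frequency

$$f_r = \frac{1}{2\pi}\sqrt{\frac{R_p^2 C - I}{I\,R_p^2 C^2}},$$

which exists exactly when `Rp²C > I`. Two textbook-looking invariants are
*not* exactly true and are tested in corrected form: the 4–16 Hz
regression intercept `R0` can overshoot `Rt` by a few percent when the
band sits on the concave low-frequency shoulder of the resistance curve,
and the relative deviation of the reactance from its inertance asymptote
at `k·f_r` is `Rp²C/(k²Rp²C − (k²−1)I)`, which is slightly *above*
`1/k²` — about 1% one decade above resonance, not below it.

## Oscillometric indexes

Eleven standard indexes summarize a spectrum measured at multiples of
2 Hz in 4–32 Hz: the intercept `R0`, slope `S` and mean `Rm` of the
resistance-versus-frequency line over 4–16 Hz (both boundaries
inclusive); point resistances `R4`, `R20` and their difference `R4_R20`
(small-airway heterogeneity); mean reactance `Xm` over the full band;
resonant frequency `Fr`; dynamic compliance `Cdyn = −1/(2π·4·X4)`;
reactance area `Ax` (trapezoidal integral of the negative reactance from
4 Hz to the crossing); and the 4-Hz impedance modulus `Z4`.

Numerical choices where the definitions underdetermine the computation:

* `Fr` is the linearly interpolated zero crossing between the bracketing
  grid points. If the reactance never crosses within the band, the
  crossing is linearly extrapolated from the last two grid points and
  capped at 64 Hz — the cap keeps `Ax` and `Fr` bounded in severe
  obstruction.
* `Ax` integrates only measured signal: the integral stops at 32 Hz even
  when the crossing is extrapolated beyond it; the interpolated crossing
  is added as a node when it falls inside the band.
* `Cdyn` is undefined when `X4 ≥ 0` (resonance below the measured band,
  a very compliant extreme). `fot_features()` reports `NA`;
  `cohort_features()` by default caps the value at `X4 = −0.01`
  (≈0.40 L/cmH2O) so classifier tables stay complete. This affects about
  1% of synthetic subjects.
* Appending frequencies above 32 Hz never changes any index.

## Inverting the model

`fit_eric()` estimates `(R, Rp, I, C)` by bounded Levenberg–Marquardt
least squares (via `minpack.lm`) on the stacked real and imaginary
residuals, weighted equally — the data offer no reason to privilege one
part. The loss surface has mirror local minima in `(Rp, C)`, so the
solver restarts from a fixed heuristic grid: split fractions {0.3, 0.6,
0.9} of the low-frequency resistance allocated to `R`, crossed with
compliance guesses {0.005, 0.02, 0.08} and inertance guesses from the
top-of-band reactance. The best residual wins; the procedure is
deterministic for a fixed spectrum. Bounds (all parameters ≥ 0, `C`
floored at 1e−6) replace unconstrained damped least squares to keep the
compliance physical. Noiseless spectra are recovered to ~1e−15 relative;
with 1% multiplicative noise the median per-parameter error stays below
5% (the compliance is the least identifiable, ~1.5%).

## Fuzzification

Each of the 16 features (11 indexes + `R`, `Rp`, `I`, `C`, `Rt`) maps to
three triangular linguistic sets — low, medium, high — supported on
`[min, mid]`, `[min, max]` and `[mid, max]`, where min and max come from
the *training rows only* and mid is their average. Test values outside
the training support are clipped to it before evaluation (equivalent to
clipping memberships for this triangle family, and easier to reason
about); ties with the training extremes get the exact vertex memberships,
no epsilon nudging. Inside the support the three memberships sum to 1 to
machine precision. On a 72-row feature with all-distinct values exactly
70 rows keep a non-zero medium membership — only the extreme rows are
fully low or high.

## Evolved classifiers

Two engines synthesize readable expressions in two dialects.

**Dialects.** Arithmetic trees combine crisp (z-scored) features and
constants with `add`, `sub`, `mul` and protected `div` (|denominator| <
1e−6 returns 1); the classifier score is `sigmoid(tree value)`. Fuzzy
pattern trees combine membership features with `max`, `min`, weighted
and ordered-weighted averages `WA/OWA(a, b, r)` with constant weight
`r ∈ {0.1, …, 0.9}`, and the unary `dilator` (square root) and
`concentrator` (square); the operator set is closed on [0, 1], so the
tree output is itself the score.

**Tree GP** (`evolve_gp()`): ramped half-and-half initialization over a
(2, 6) depth range, tournament selection (default size 7), subtree
crossover (0.9) on copies of the parents, subtree mutation (0.1) by the
grow method within the remaining depth budget. Offspring exceeding the
depth cap (default 6 — small caps keep expressions legible) revert to the
corresponding parent. Fitness is the training AUC of the scores; the
best-ever individual is tracked across generations even if lost from the
population. Crossover/mutation rates and the AUC fitness are classical
defaults; the source framework for such systems often uses log-loss, and
both choices are exposed through the configuration.

**Grammatical evolution** (`evolve_ge()`): integer-codon genomes (8-bit,
length 100) decoded by leftmost derivation through a BNF grammar — at
each rule with two or more productions the next codon picks
`codon mod n`; single-production rules consume nothing; the codon stream
wraps at most 3 times; a derivation-depth cap of 12 bounds phenotype
size before the wrap budget. Undecodable genomes are *invalid values*,
assigned the worst fitness — with the bundled grammars fewer than half
of a random initial population is invalid. The GA uses tournament size
2, variable one-point crossover (0.9) and per-codon mutation (0.01).
The two bundled grammars were reconstructed to generate exactly the
expression families above (the structure of the original grammar is
known only through its products); `make_grammar()` rebuilds them over
any terminal subset. Grammars ship as plain BNF text files under
`inst/grammars/`.

Whether pattern trees should be evolved by GP, GE, or both was an open
call; both engines support both dialects here, selected by a `dialect`
argument.

## Baselines

Eight off-the-shelf families sit behind one `fit_score()` contract
(continuous disease score per test row; adapters never see test labels):
KNN (`class`), RBF-SVM (`e1071`, raw decision values, orientation fixed
on training scores — probability calibration was not used), random
forest (`ranger`), XGBoost, ridge-penalized logistic regression
(`glmnet`, with `lambda = 1/(nC)` mapping the conventional `C` grid),
and decision trees (`rpart`). Two slots deserve a note: **ADAB** is a
discrete AdaBoost (SAMME) implemented in-package on depth-limited
`rpart` base learners, and **LGBM** denotes a leaf-wise ("lossguide")
histogram gradient-boosting adapter backed by `xgboost` — leaf-wise
growth being the defining LightGBM strategy. The decision-tree criterion
grid collapses to `rpart`'s {gini, information}, and the boosting grids
are exposed in a corrected orientation by default (estimator counts
10–400, depths 1–60; the transposed orientation is available via
`default_grids(corrected = FALSE)`).

## Evaluation harness

`nested_cv()` estimates generalization with stratified 10-fold outer
cross-validation: preprocessing (z-score or fuzzification scheme) is
fitted on each outer-training fold only; an exhaustive inner stratified
5-fold grid search selects hyperparameters by pooled inner AUC (the
inner fold count and metric are our choice — the procedure itself does
not fix them); the winner is refit on the full outer-training rows and
scores the outer-test rows; the ten test folds pool into a single ROC
and AUC. Grid ties break toward the first listed option. The
no-leakage property is asserted by recomputation in the tests: every
fold's stored preprocessing parameters must equal those refit from the
training rows alone.

Recursive feature elimination (`rfe_path()`/`rfe_select()`) removes, at
each round, the feature whose removal least degrades the inner-CV AUC —
a model-agnostic signal chosen because KNN and SVM have no native
importances; ties drop the later column. The subset size is a grid
hyperparameter (1–15 crisp, 1–47 fuzzy; coarse triples {4, 8, 12} /
{12, 24, 36} for the evolutionary engines, whose fits dominate run
time). Selection frequencies over (algorithm × outer fold)
sub-experiments — 90 per analysis with the nine default families — rank
features by how often the data ask for them.

Experiment drivers mirror a three-part design: univariate
orientation-corrected AUC per feature (computed on the full dataset — a
raw feature has no fitted parameters to leak); the nested-CV comparison
of all classifiers on normalized and fuzzified data (180 sub-experiments
per representation); and the same with feature selection.
`group_compare()` adds the descriptive statistics: Shapiro–Wilk
normality per group, then two-sided Mann–Whitney per feature at p ≤
0.05, deliberately without multiple-testing correction to match
conventional reporting of such screens; zero-variance features are
flagged with p = 1 rather than erroring.

## The synthetic cohort

No clinical data ship with the package; `simulate_cohort()` emulates a
three-group study (25 controls, 24 disease-with-normal-spirometry, 23
disease-with-altered-spirometry). Per-subject eRIC parameters are drawn
from log-normal distributions — positivity plus the right-skewed,
outlier-prone shape typical of clinical oscillometry — with disease
encoded as a multiplicative shift of the group median. Three replicate
spectra per subject receive independent multiplicative Gaussian noise
(5% by default; the within-subject variability of the instrument is a
free knob, not a claim) and are averaged, mirroring the
three-measurement protocol.

Defaults, frozen after a one-time calibration: control medians `R` = 2.0,
`Rp` = 1.1 cmH2O·s/L, `I` = 0.006 cmH2O·s²/L, `C` = 0.022 L/cmH2O;
median shifts ×(1.10, 1.35, 1.00, 0.70) for the normal-spirometry group
and ×(1.15, 1.55, 1.05, 0.58) for the altered group; log-scale spread
0.25 (control) / 0.30 (disease). Raising `Rp` and lowering `C` with
disease raises `Rt`, `Fr`, `Ax` and `Z4` and lowers `Cdyn` — the
clinically expected directions — and the calibration placed the
best-feature univariate AUCs near 0.8 (normal-spirometry analysis) and
0.9 (altered), moderate rather than trivial separability. The control
inertance was set low enough that ~99% of subjects have a negative 4-Hz
reactance, as a real adult cohort does.

What the generator does *not* emulate: demographic confounding,
instrument drift, frequency-correlated measurement error, model
misspecification (every synthetic spectrum is exactly eRIC plus noise),
and any disease physiology beyond a median shift. Passing tests
therefore show that the pipeline recovers known structure under its own
generative assumptions — they are evidence about the software, not about
sarcoidosis.

## Problem sizes and reproducibility

Every stochastic stage derives its seed from one global seed via stage
hashing, so runs are reproducible end to end and stages can be rerun in
isolation; the shipped default seed is 7. The test-suite and acceptance
runs use desk-scale problem sizes chosen to finish in minutes: 100
random draws for noiseless inversion, 200 Monte-Carlo repeats at 1%
noise, 10,000 points for the partition-of-unity check, 20 label
shuffles for the permutation null, reduced hyperparameter grids (e.g.
`C ∈ {0.1, 1, 10}`, GP population 100 × 10 generations) and the reduced
algorithm set LR + DT + GP for the end-to-end experiment. The full
default grids reproduce the complete comparison and simply take
proportionally longer.

## Known limitations

* The eRIC inversion assumes the eRIC topology; alternative circuit
  models (RIC, Mead, DuBois) are out of scope.
* The multi-start list is a substitute for the undocumented
  initialization of the original estimation software, not a
  reproduction of it.
* Evolutionary-engine hyperparameters not fixed by the experimental
  grids (crossover/mutation rates, GE codon geometry) follow common
  practice and are configuration-exposed rather than validated choices.
* WA/OWA weights are constants; weighting one membership by another
  (which the expression family could in principle express) is not
  generated by these engines.
* `Fr` extrapolation beyond the band and the `Cdyn` cap are pragmatic
  conventions for degenerate spectra; results for subjects in those
  regimes carry the convention, not measurement.
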