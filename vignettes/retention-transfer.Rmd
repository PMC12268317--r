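---
title: "Transferring retention information between chromatographic systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transferring retention information between chromatographic systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtbridge)
```

## The problem

Suspect and non-target screening by LC/HRMS leans on retention time (RT) to
separate plausible candidate structures from implausible ones. The catch is
that reference retention data almost never come from the screening system
itself: they come from a library measured on some other reversed-phase
system (different column chemistry, mobile-phase additive, gradient
program, flow rate), or from a machine-learning model trained on a third
system. `rtbridge` implements the two standard routes for bridging that
gap — *projection* of experimentally measured retention indices through a
spline fitted on shared calibrants, and *prediction* from molecular
structure followed by recalibration — together with the similarity and
error statistics needed to decide, per pair of systems, which route is
more trustworthy.

## Retention time indices

Raw RTs are not comparable across systems. The package first converts them
to retention time indices (RTI) per *ordered pair* of systems, anchored on
the calibrants detected in **both** systems:

$$\mathrm{RTI}(x) = 1000\,\frac{RT_x - RT_\min}{RT_\max - RT_\min}$$

with $RT_\min$, $RT_\max$ the earliest and latest shared calibrant in that
system. Shared-calibrant indices span exactly $[0, 1000]$; suspects may
fall outside and are flagged. Because the transform is affine, it removes
flow-rate, dead-volume and column-length differences exactly (the test
suite asserts invariance under $RT \mapsto a\,RT + b$), but it cannot
remove gradient nonlinearity — that is the projection model's job.

Anchors are shared per pair rather than fixed per system because detection
differs between systems; a calibrant seen by only one member of a pair is
excluded from both anchor sets. The package also provides a per-system
index (`system_rti()`), anchored on all calibrants detected on that one
system, which is the natural scale when model predictions are calibrated
onto a single target.

## Spline projection

For each ordered pair, a generalized additive model — a univariate
penalized cubic regression spline with basis dimension $k = 6$, smoothing
parameter chosen by generalized cross-validation (`mgcv::gam`) — is fitted
on the shared calibrants, mapping source RTI to target RTI, and evaluated
on suspects. Decisions worth recording:

- **Basis dimension 6** is the method's defining parameter: small enough to
  be estimable from as few as eight calibrants, large enough to absorb the
  smooth nonlinearity that different gradient shapes induce.
- **`min_shared = 8`** calibrants per pair: a 6-dimensional basis needs
  more support points than basis functions; pairs below the floor are
  skipped and logged, never silently fitted.
- **No extrapolation.** The spline is evaluated on the closed calibration
  range $[0, 1000]$ only; suspects outside it in the source system are
  excluded with an explicit reason. Suspects out of range in the *target*
  system are retained but flagged (a switch excludes them too).
- **No monotonicity constraint** is imposed on the smooth; with eight or
  more reasonably spread calibrants and $k = 6$ the fitted maps are
  monotone in practice.
- **Asymmetry is intrinsic**: the smooth minimizes residuals in the target
  direction, so the A→B fit is not the inverse of the B→A fit and all
  ordered pairs are computed.
- The **pre-spline baseline** for a pair is the raw index difference
  `rti_source − rti_target`; comparing it with the post-spline residuals
  per pair quantifies what the spline adds.

## Retention order, clustering, and peak spacing

System similarity is summarized by Pearson correlation of RTs and Spearman
correlation of retention orders (average ranks for ties), computed on all
compounds detected by both systems; pairs with fewer than three shared
compounds or zero variance give missing values rather than numbers.
Clustering uses distance $1-\rho$ with average linkage — robust to
chaining — and a deterministic leaf order (lexical by system id under
ties). Whether to cluster on $1-\rho$ or some other transform is a design
choice of this package, not a property of the method.

Peak spacing normalizes RTs by the program length onto a 0–1000 axis
(plain division; no dead-time subtraction) and reports the sample (n−1)
standard deviation and the empirical CDF. Programs dominated by a long
gradient spread peaks (high SD); programs with long isocratic holds and a
short gradient compress them.

## The prediction arm

Where no shared measurements exist, an RT model is trained on an external
(structure, RT) table:

1. **Descriptors.** `compute_descriptors()` wraps ChemmineR/OpenBabel
   (salt-stripping by largest fragment, then the OpenBabel property set).
   The simulator's `simulate_descriptors()` is the first-class stand-in in
   tests, so no chemistry backend is ever required to validate the
   machinery.
2. **Cleaning**, in a fixed order: drop descriptors missing for more than
   15 compounds (a descriptor missing for exactly 15 is kept); drop
   compounds with remaining gaps; drop near-zero-variance columns
   (frequency ratio ≥ 19, unique fraction ≤ 10%); then, from every pair
   with $|r| > 0.7$, drop the member with the larger mean absolute
   correlation (`caret::findCorrelation`, exact mode — deterministic).
3. **Learner.** Gradient-boosted regression trees tuned by five-times
   repeated two-fold cross-validation over a declared grid (depth
   {3, 5, 7}, learning rate {0.05, 0.1, 0.3}, rounds {100, 300}, row
   subsampling 0.8), refit on all data with the winning setting. With one
   thread and a fixed seed the whole path is bit-reproducible.
4. **Recalibration.** Predicted RTs live on the training system's scale.
   The same spline machinery (k = 6, GCV) is fitted from predicted
   calibrant RT to the calibrants' *observed* target RTI and applied to
   suspects; suspects predicted outside the calibrant prediction range are
   excluded rather than extrapolated. A two-anchor linear variant is
   available behind a switch; the spline is the default for consistency
   with the projection arm.
5. **Local models.** Per system, the same learner can be trained on that
   system's calibrants alone (n ≥ 10). Local models share the external
   training set's retained descriptor space, so the comparison measures
   training-set size and chemistry match, not feature-selection luck.

Study compounds are always removed from any external training table before
fitting — the evaluation chemicals must never train the model.

## Comparing projection and prediction

Residual sets are summarized by RMSE, MAD (mean absolute deviation) and the
95th percentile of absolute deviations (linear interpolation between order
statistics). Two methods are compared on the suspects *both* could index,
by a variance-ratio test: $F = \mathrm{MSE}_{\text{larger}} /
\mathrm{MSE}_{\text{smaller}}$ with degrees of freedom equal to the
residual counts — no mean is subtracted, because prediction errors are
deviations from the observed value, not from a fitted mean — and a
two-sided p-value, uncorrected for multiplicity. Pairs with fewer than
three common suspects are excluded with a reason. The verdict
(`projection_better` / `prediction_better` / `indistinguishable`) follows
the test at $\alpha = 0.05$ and the sign of the RMSE difference.

## What the simulator emulates — and what it does not

The generator exists so that every stage can be validated against known
truth. Each compound has a latent elution coordinate $u \in (0,1)$ (a
one-dimensional hydrophobicity surrogate, uniform and tie-free); each
system turns $u$ into minutes through a strictly monotone warp built from
its gradient program. Design choices:

- **Warp construction.** Elution mass accrues at rate $|d\phi/dt| +
  \text{baseline}$ (baseline 0.05 per run) over the *active window*: from
  the end of any initial hold — nothing elutes during a low-organic hold —
  to the end of the last gradient segment. The inverse cumulative mass is
  smoothed by a monotone Hyman cubic through the segment knots, the way
  instrument dwell volume rounds gradient transitions in practice. A
  terminal isocratic plateau therefore compresses late eluters toward the
  gradient's end, and the warp's nonlinearity stays within what a
  6-dimensional smooth can represent — which is precisely the regime the
  projection method assumes. Random programs draw 15–54 min run times,
  optional initial holds (3–12% of the run), optional terminal holds
  (8–30%), and one- or two-slope gradients with moderate slope contrast.
- **Additive chemistry.** In ammonium-salt systems, basic compounds shift
  later and acidic compounds earlier by `delta_ion` (default 0.08) in
  latent space, so the shift interacts naturally with each system's warp.
  This reproduces the qualitative fingerprints of mobile-phase pH: perfect
  rank agreement within an additive class at zero noise, systematically
  elevated ranks for bases under ammonium additives, cross-class Spearman
  correlations that fall as the shift grows, and clustering that separates
  additive classes.
- **Noise and dropout.** Gaussian RT noise in minutes (default 0.13 min —
  about 10 index units on a 15-minute program, the scale used by the
  noisy-recovery checks) and independent Bernoulli non-detection per
  (compound, system) (default rate 0.15) emulate measurement error and
  patchy detectability.
- **Descriptors.** Informative columns are monotone transforms of $u$ plus
  noise (default 0.05); two columns encode acid/base character (the
  information a real descriptor set carries about charge state); the rest
  are pure noise, and defect columns (constant, duplicate,
  missing-polluted) can be planted to exercise the cleaning rules. The
  transforms are drawn from the seed alone, so training compounds and
  study compounds rendered with one seed share a descriptor space and
  models transfer between them. Because the informative columns are
  mutually redundant, the $|r| > 0.7$ filter keeps only part of the
  signal — which is exactly why an externally trained model at
  $n \approx 300$–500 beats calibrant-only local models at $n \approx 30$,
  mirroring the behaviour expected on real data.

What the simulator deliberately does **not** model: real retention
mechanisms (no LSER or gradient theory — the latent coordinate is
statistical), peak widths and co-elution, multi-dimensional chemistry
(a single $u$ cannot express column-chemistry selectivity differences
beyond the additive effect), matrix effects, or inter-batch column
variability. Passing tests therefore demonstrate that the *machinery* is
correct and that the method's direction-of-effect claims hold under the
stated generative assumptions — not that any particular accuracy will be
achieved on real interlaboratory data.

## Numerical choices and degenerate inputs

- Indices are computed ratio-first, so the anchor calibrants map to exactly
  0 and 1000 in floating point.
- Degenerate geometry raises typed errors rather than numbers: co-eluting
  anchors (`rt_max ≤ rt_min`), constant predictors, all-equal source
  indices, too few calibrants, too few residuals.
- The F-test is symmetric by construction (larger MSE in the numerator);
  two zero-MSE sets give $p = 1$, one zero-MSE set gives the $p = 0$
  limit, flagged degenerate.
- Percentiles interpolate linearly between order statistics (R's default
  quantile type 7).
- Ties in Spearman use average ranks; ties at an RTI anchor are harmless
  because the anchor is the value, not the compound.
- One global seed fans out to per-component seeds through a fixed counter
  scheme (`fan_seed`), so adding a stage never disturbs another stage's
  stream; all seeds stay below $2^{31}$.

## Problem sizes used in the test suite

The suite validates the analytic properties on small explicit fixtures and
the statistical properties on simulated studies: the default study is 20
systems (380 ordered pairs); noisy-recovery bands use 100 simulated pairs;
direction-of-effect comparisons for the prediction arm use 20 seeds of a
4-system, half-ammonium study with a 300-compound external training set
and a reduced tuning grid; F-test calibration uses 10^4 Gaussian null
replicates. These sizes give stable medians and proportions while keeping
a full run to a few minutes on one core.

## Known limitations

- Projection assumes a shared retention mechanism; non-reversed-phase
  systems are excluded up front, and nothing in the package will warn if
  two nominally reversed-phase systems in real data actually mix
  mechanisms.
- The k = 6 smooth cannot follow elution maps with sharper nonlinearity
  than its basis affords (e.g. severe mid-run plateaus between sparse
  calibrants); such pairs show elevated calibrant residuals, which is the
  practical diagnostic.
- Calibrant RMSE is reported separately from suspect RMSE and is *not* a
  reliable proxy for it; quality-control compounds independent of the
  fitted calibrants are the sound way to estimate projection uncertainty.
- The prediction arm's accuracy depends on chemical-space overlap between
  training and screening compounds; the simulator enforces overlap by
  construction, real applications must check it.
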