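---
title: "Classifying homing strategies from displaced-fish trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying homing strategies from displaced-fish trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homingtraj)
set.seed(1)
```

## The experiment and its geometry

A displacement experiment separates navigational strategies by making them
predict different return paths. A fish swims from its home shell through an
L-shaped tunnel (two equal 30 cm legs) into a reward chamber; the chamber is
then displaced — 50 cm laterally, or 50 cm right and 50 cm down — and the
fish released. From the displaced door, path integration (PI) predicts the
straight home vector (45°, 38.6 cm), allothetic place cues (APC) predict a
return to the shell's original arena position (135°/38.6 cm lateral,
180°/27.3 cm diagonal), and route recapitulation (RR) predicts retracing the
L-tunnel (first leg 90°, two equal legs totalling 54.5 cm, start–end chord
45°).

The coordinate frame puts the origin at the tank's top-left corner with x
rightward and y downward (the overhead-camera convention), so the two-branch
arccos angle formula used throughout equals `atan2(dy, dx)` in [0°, 360°).
Model trajectories are constructed *from the expectation constants*,
anchored at the displaced door — not re-derived from the shell and tunnel
coordinates — because only the constants, not the global angle convention of
the original apparatus drawings, are unambiguous. The shell and tunnel
geometry is retained for the synthetic generator's realism only.

```{r geometry}
strategy_expectations()
build_model_trajectory(arena_config(), "RR", "lateral")
```

## Trajectory scoring

**Cropping.** Analysis uses the first 60 s after the fish exits the chamber,
cut at the moment it "turns back": the first run of 2 consecutive 1 Hz steps
that head within 30° of the bearing to the chamber *and* decrease the
distance to it. The cone (30°), persistence (2 samples) and window (60 s)
are package parameters (`arena_config()`), since turn-back detection is a
judgement call rather than a published rule; the defaults are deliberately
permissive so that a genuine return triggers quickly.

**Interpolation.** Observed paths are digitised point sequences, so they are
resampled to 1000 points via a modified-Akima (makima) fit of x and y
against cumulative arc length, evaluated at equally spaced arc-length
stations. Makima is shape-preserving: it is exact on straight spans and
reduces to linear interpolation for two knots. Model paths are *exact
geometric predictions*, so they are resampled on the polyline itself with no
smoothing — passing the RR model's three vertices through a smoother would
round its defining right angle into a bulge of several centimetres and
distort every distance to it. For the two-vertex PI and APC models both
routes coincide exactly.

**Distance.** Both paths are first cut to the common arc length
min(L_obs, L_model); the score is the arithmetic mean of the 1000
index-paired Euclidean distances. It is exactly translation-equivariant;
rotation-equivariance is exact for straight paths and holds to sub-percent
accuracy otherwise (componentwise makima slopes are nonlinear in the
coordinates).

## The random-trajectory null and the decision rule

Each trial gets its own null: 10,000 straight trajectories from the trial's
start point, headings uniform on [0°, 180°), each of length
min(L_obs, L_PI), scored identically. Writing μ for the mean of the 10,000
mean distances and [a, b] for their range, the trial is assigned its closest
model strategy when the best model distance is below μ − SD_uniform with
SD_uniform = (b − a)/√12, and labelled RANDOM otherwise. The interval of the
fitted uniform is taken as the sample minimum and maximum — the natural
estimate, exposed as package behaviour rather than hidden. Two alternative
thresholds are provided: μ − SD_normal (sample SD) and the 20th percentile
of the empirical CDF.

Anchoring the random trajectories at the door mirrors how the model
trajectories are anchored, and makes the null a proper "random swimmer from
the same start" reference. Because a straight observed path is itself a
member of the null family, its null contains near-zero distances (a ≈ 0) —
a useful internal consistency check.

Two properties of this rule are worth knowing before interpreting labels:

* Under the uniform threshold, roughly the lowest fifth of null headings
  falls below μ − SD_uniform. With three model trajectories available, a
  *straight* random swimmer therefore gets captured by its nearest model in
  roughly 30% of trials; the rule's specificity for uniform-heading swimmers
  is intrinsically ≈ 70%, not a defect of any implementation.
* Specificity degrades further for slow fish: short analysed paths carry
  less geometric information, and both the model distances and the null
  contract together.

**Closest-model determination.** Strategies are ranked by mean distance
(exact ties, within 1e-9 cm, broken PI > APC > RR and logged). Because the
1000 interpolated distances are strongly serially dependent, the pairwise
contrasts use a moving-block bootstrap over the point index (block 50, 1000
resamples) rather than treating points as independent observations.

## Orientation angles and axial circular inference

The first straight angle accretes 1 Hz segments from the first sample while
each deviates ≤ 10° from the *immediately previous* segment (as the rule is
stated, not from a running mean), then applies the branch formula to the
chord; the start–end angle applies it to the first and last samples of the
cropped path. The y_end = y₁ tie takes the first branch (its continuous
limit). Angles live on [0°, 180°) and all circular machinery doubles them
onto the full circle first.

The orientation-modality question — uniform, unimodal or multimodal? — is
answered by maximum likelihood over a nested ten-model von Mises mixture
family (M1 uniform; M2A unimodal; M2B/M2C axial bimodal; M3A/M3B with a
uniform background; M4A/M4B/M5A/M5B bimodal with increasingly free modes,
concentrations and weights), each fitted from multiple random restarts of a
bounded quasi-Newton optimiser on the doubled circle.

Three numerical choices guard known pathologies:

* **κ ≤ 227.6** (mean resultant length ≈ 0.999): the mixture likelihood is
  unbounded as a component concentrates on a single point.
* **Mixing weights in [0.1, 0.9]** where free: without a floor, a
  "spike" component with κ at its cap and λ ≈ 0.05 wins on pure-uniform
  data in a sizeable fraction of samples. A mode carrying under 10% of
  trials is not usable evidence of orientation at these sample sizes.
* **Parsimony selection**: the reported best model is the *simplest* model
  within 2 AIC units of the AIC minimum (the AIC-minimal model always has
  ΔAIC = 0 in the table). Under a strict argmin, a richer nested model
  beats the true one whenever it gains more log-likelihood than its extra
  parameters cost, which happens by chance in a quarter or more of
  uniform-truth samples.

Even so, class selection is not perfect: at n = 200 and κ = 8, simulated
recovery is ≈ 82–85% for uniform truth, ≈ 85–90% for unimodal truth and
≈ 100% for bimodal truth. The residual errors are genuine — we verified
against an independent optimiser that the winning richer models really do
achieve their log-likelihoods on those samples — so they are a property of
AIC on nested mixtures, not of the optimiser. Mode recovery is excellent:
bias well under 1° and concentration within a few percent on average. The
likelihood-ratio statistic of the selected model against the uniform M1 is
reported as the multimodality evidence, with a χ² p-value (approximate:
mixture boundaries make the null distribution conservative).

## Group-level tests

Each labelled group (APC split by displacement, because its expectations
differ) is tested against its expectation constants for first angle,
start–end angle and full pre-turn-back distance. A Shapiro–Wilk gate (p >
0.05) chooses between a one-sample bootstrap *t* test — resampling the
μ₀-centred sample, 9999 replicates, p = (1 + #{|t*| ≥ |t|})/(reps + 1),
percentile CI — and a Wilcoxon signed-rank test. Groups with fewer than 3
trials report raw values only. Distances are compared across groups by
Kruskal–Wallis (five groups when all labels occur, hence df = 4) with a
Holm-adjusted pairwise Wilcoxon post-hoc.

The strategy-choice model is a multinomial logit (PI/APC/RR each versus
RANDOM) on age, swim speed, displacement and trial number. With at most two
trials per fish a fish-level random intercept is not identifiable, so
per-fish dependence is handled with cluster-robust sandwich errors — the
score and sandwich algebra is written out for the multinomial fit, and it
reduces to the standard HC0 logistic sandwich in the binary single-trial
case (a tested identity).

## The synthetic cohort generator

The generator emulates the study conditions: 40 fish, two counterbalanced
displacement trials each, 1 Hz samples from the displaced door for a 60 s
window, strategy frequencies at the observed cohort composition
(8:6:5:16 for PI:APC:RR:random over 35), per-fish swim speed ≈ Normal(3, 1)
cm/s and per-step speed jitter of 1 cm/s, heading noise von Mises with
κ = 50 (≈ 8° angular SD). Strategy swimmers aim, each second, at the point
their model path reaches after that step's arc progress — steps are capped
at polyline vertices, so the noiseless limit lies on the model polyline
exactly, corner sample included — and turn back toward the chamber after a
configurable fraction of the model length (scripted, so the turn-back index
is known ground truth for the cropping test). Random swimmers draw one
uniform heading and wander about it with the same noise. Walls reflect.

What the generator does *not* emulate: search loops, wall-following,
thigmotaxis, depth use, motivational dropout, or any interaction with the
(removed) tunnel and shell. Passing recovery tests on this cohort therefore
demonstrates that the pipeline recovers *its own* generative labels under
realistic noise — a necessary check of the machinery, not evidence about
real fish.

Age (uniform over roughly 1–4 years) and speed feed the optional
covariate-dependent strategy assignment (a multinomial logit with
user-supplied coefficients), used by the parameter-recovery tests of the
choice model.

## Numerical details and degenerate inputs

* Near-coincident consecutive samples (< 1e-9 cm apart) are dropped before
  interpolation; they destabilise the slope weights and carry no shape.
* Re-interpolating an already-interpolated path is exact on straight paths;
  on curves the chordal re-parameterisation moves stations by well under
  1e-3 cm — far below any scale the analysis uses.
* Noiseless RR recovery bottoms out at a mean distance ≈ 0.025 cm: makima
  necessarily rounds the right-angle corner over the two corner-adjacent
  1 Hz intervals. This is the floor of the observed-side interpolation, not
  a classification error (the label is always correct there, and the PI/APC
  floors are ≈ 1e-14).
* Zero-variance samples, coincident endpoints, stationary trajectories,
  sub-3-sample paths, out-of-tank coordinates and unknown
  strategies/displacements/rules all raise typed errors
  (`degenerate_trajectory`, `degenerate_angle`, `contract_error`,
  `config_error`, `validation_error`); the pipeline isolates the offending
  trial and continues.
* All stochastic stages derive their streams from one seed through an
  integer-hash scrambler; feeding arithmetic seed progressions straight to
  the RNG produced measurably correlated streams.

## Problem sizes

The test-suite and acceptance-script simulations use: an 80-trial cohort
with 10,000-trajectory nulls for recovery and specificity; 500 runs of the
bootstrap *t* calibration at n = 8 (999 replicates each); 20 replicates per
modality class for the circular family at n = 200, κ = 8; and 100 draws for
mode recovery. These sizes put Monte-Carlo error comfortably below each
check's tolerance while keeping a full run in minutes on one CPU.

## Limitations

The classifier inherits the decision rule's conservatism: its ≈ 70% ceiling
of specificity for straight random swimmers means a fraction of genuinely
unoriented trials will always carry a model label, and the rule-choice
sensitivity (uniform vs normal SD vs quantile thresholds) is reported per
trial for exactly that reason. The rule also carries a scale asymmetry: the
null is calibrated at the PI-model length, while each model's distance is
computed over the common length with *that* model, so the short
APC-diagonal prediction (27.3 cm) is compared on a shorter — hence
systematically smaller — distance scale and captures random diagonal trials
disproportionately. On synthetic cohorts, diagonal-trial specificity runs
some 25 points below lateral for exactly this reason, with APC the dominant
false label. The circular model family's class selection
carries irreducible AIC noise at realistic sample sizes. And all recovery
rates quoted here are properties of the synthetic cohort; applying the
pipeline to new recordings requires only a trajectory CSV and metadata
table, but the thresholds' behaviour on real swimming styles should be
examined with the per-trial null summaries the classifier emits.
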