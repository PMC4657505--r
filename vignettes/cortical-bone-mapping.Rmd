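---
title: "Cortical bone mapping for hip-fracture-type prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cortical bone mapping for hip-fracture-type prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbmfrax)
```

## The scientific problem

Hip fractures concentrate in two anatomically distinct patterns —
trochanteric and femoral neck — and the bone deficits that predispose to
each are focal, not global. Areal BMD from DXA summarises the whole hip in
one number and therefore discards exactly the spatial information that
separates the two fracture types. Cortical bone mapping (CBM) instead
measures cortical properties independently at thousands of points over the
proximal femoral surface from clinical CT, finds the surface patches
statistically associated with each fracture type, and feeds patch summaries
into survival and classification models.

`cbmfrax` implements this chain as reusable, tested components, together
with a synthetic-data generator that reproduces the statistical structure
of a prospective case-cohort study of men over 65, so that every stage can
be validated end to end without access to any clinical data set.

## The measurement model

At each surface vertex, the CT intensity profile along the inward surface
normal is modelled as a three-level step — soft tissue $y_0$, cortex $y_1$,
trabecular bone $y_2$, with the periosteal edge at $x_0$ and the
endocortical edge at $x_1$ — convolved with a Gaussian point-spread
function of width $\sigma$:

$$y(x) = y_0 + (y_1-y_0)\,\Phi\!\left(\frac{x-x_0}{\sigma}\right)
             + (y_2-y_1)\,\Phi\!\left(\frac{x-x_1}{\sigma}\right).$$

The Gaussian PSF is a modelling choice: CT blur is scanner-dependent, and a
Gaussian is the standard surrogate; $\sigma$ is fitted per profile. The
derived variables are cortical thickness CTh $= x_1-x_0$ (mm), cortical
density CBMD $= y_1$ (mg/cm³), cortical mass surface density
CM $= 0.1\,\mathrm{CTh}\cdot\mathrm{CBMD}$ (mg/cm²), and endocortical
trabecular density ECTD (mg/cm³). ECTD is reported under two conventions —
the fitted level $y_2$ (`point`, the default) or the mean fitted intensity
over a 3 mm band starting at $x_1+\sigma$ (`band`) — because the averaging
depth "close to the cortex" is not canonically defined; outputs record
which convention was used.

When the cortex is thinner than the blur, thickness and density trade off
along a nearly flat likelihood valley and the free six-parameter fit
becomes unreliable. The `constrained_density` mode fixes $y_1$ at a
subject-global cortical density (the median of free-mode $y_1$ over
profiles with CTh $> 2\hat\sigma$, `estimateGlobalDensity()`), which
restores identifiability of CM — the product $\mathrm{CTh}\cdot y_1$ —
even for sub-resolution cortices. This is the package's central
measurement property and is exercised directly in the test suite: on
noiseless profiles with $\sigma = 1.5$ mm and CTh from 0.3 to 1.5 mm the
constrained-mode CM error stays below 5 % while the free-mode thickness
error grows past 100 % at the thin end.

### Numerical choices

The fit is bounded Levenberg–Marquardt least squares (`minpack.lm`), with
parameter and function tolerances of $10^{-6}$ and at most 200 iterations
per start. Starting points combine three $x_0$ candidates around the
steepest ascent of a 5-point-smoothed profile, two blur starts (0.8 and
1.8 mm) and two width starts (a gradient-based guess and a sub-resolution
guess of $\sigma/2$); the lowest residual wins, with ties broken towards
the thinnest cortex. If the best residual still exceeds 2.5× a noise floor
estimated from the high-frequency residual, a coarse grid of additional
$x_0$ starts is tried. This richer start set exists because a single
heuristic start left roughly 3 % of noisy thin-cortex fits in a smeared
local minimum; it changes no aspect of the model, only the optimizer's
search. The fitted blur is capped at 3 mm (a generous ceiling for clinical
CT) so that noisy fits cannot drift to an arbitrarily smeared solution.
Monotone or constant profiles are rejected as degenerate rather than
fitted.

## The synthetic study

`makeCanonicalMesh()` builds a closed, sphere-topology surface — head
sphere, narrowed neck, flared trochanter, shaft stub — with six anatomical
region labels assigned parametrically. The default desk-scale mesh has
2,000 vertices (clinical meshes run 5,000–15,000; all operations scale
linearly in vertices, and the validation studies below use 500–1,000
vertices to keep replicate counts high).

`simulatePopulation()` draws covariates matching an elderly male cohort
(age Normal(74, 6) truncated at 65 years; weight Normal(84, 14) kg; height
Normal(174, 7) cm; six clinical sites), and builds per-vertex fields as

$$\text{field} = \text{baseline}\times(1 + \text{covariate terms}
  + \text{subject effect} + \text{planted deficit} + \text{spatial noise}),$$

with baselines CTh 1.6 mm, CBMD 1095 mg/cm³ (hence CM ≈ 175 mg/cm²) and
ECTD 170 mg/cm³. Spatial noise is white noise smoothed by k-ring
neighbourhood averaging (k = 2) — the field's spatial covariance is not
canonically specified anywhere, so a short-range smooth process is assumed
and configurable. Left and right hips share a common truth plus
independent noise; the analysis averages the two sides vertex-wise
(`averageLeftRight()`), passing through whichever hip is available when
one is missing. CM is never drawn independently: the identity
CM = 0.1·CTh·CBMD holds exactly at every vertex of every subject.

**Deficits are planted through risk, not labels.** Each subject carries
two latent standard-normal risk scores; the score scales a relative
deficit inside the trochanteric (superolateral trochanter) or neck
(superior neck) region, and *fracture outcomes are then generated from a
competing-risks proportional-hazards model driven by the realized patch
means* (`simulateFractureOutcomes()`): two constant-hazard processes with
log-hazard linear in standardized patch-mean CM, patch-mean ECTD and age;
the first event inside the 10-year horizon fixes the type and time,
otherwise the subject is censored at the horizon. Patch discovery
therefore faces a genuine inverse problem — the generator never writes
fracture labels into the fields. `effectFraction` is calibrated as the
field gap between the top and bottom deciles of the latent score (a 3.51
SD spread), so `effectFraction = -0.10` plants a 10 % decile contrast.

The standing validation configuration, `plantedPatchScenario()`, sets the
deficits and hazard coefficients so that incident cases show roughly a
10 % patch-mean CM deficit against the cohort with ~10 % spatial noise —
the regime in which surface statistics are expected to work at a few
hundred subjects — and uses elevated baseline rates (0.02/year per type)
so a desk-scale cohort contains enough cases; the cohort-realistic default
rates in `hazardSpec()` (≈0.1 %/year per type) reproduce the sparse
incidence of a real ageing cohort instead.

Global DXA-like and QCT-like BMD surrogates are generated as noisy
monotone functions of the whole-surface mean CM and ECTD — they carry
real, but spatially undifferentiated, signal, which is precisely the
contrast the prediction study needs. DXA physics is deliberately not
simulated; only this correlation structure matters for model comparison.

What the generator does **not** emulate: registration error (subjects
share the canonical topology, so mapping is a known correspondence;
`mapToCanonical()` supports permutations and partial correspondences, and
full non-rigid registration is out of scope as external tooling),
acetabulum-adjacent segmentation artefacts (representable only as elevated
noise), scanner calibration drift beyond a per-site offset, and
non-proportional hazards. Passing tests on synthetic data demonstrate the
statistical machinery under the stated generative model, not clinical
performance.

## Surface statistics

`fitVertexGlm()` fits, at every vertex, ordinary least squares of one CBM
variable on a fracture factor (trochanteric and neck indicators against
"none") plus nuisance covariates: age, weight, clinical site, and five
shape-mode scores. Weight is a confounder here, while the downstream
hazard and prediction models adjust for height instead — the two stages
deliberately use different anthropometric covariates, mirroring standard
practice in this analysis chain. Shape scores come from a size-excluded
principal decomposition (`computeShapeModes()`): every subject's
coordinates are translated to zero centroid and scaled to unit centroid
size *before* the decomposition, because overall size correlates with
fracture and must not absorb fracture-sensitive signal; centroid size is
the standard geometric-morphometrics normalizer. Effect sizes are
reported as percentages of the vertex-wise mean — with the caveat, flagged
on every ECTD map, that percentages are unstable where mean trabecular
density approaches zero.

Multiplicity is controlled by a permutation cluster-mass family-wise error
test: vertices with raw $p < 0.001$ form clusters on the mesh edge graph
(connected components via union-find), each cluster's mass (sum of $|t|$)
is compared with the null distribution of the maximum cluster mass under
subject-label permutation, and clusters with FWER-corrected $p < 0.05$
survive; the patch is their union. Permutation refits use Freedman–Lane
residualization against the fixed nuisance covariates, which is exact for
OLS (verified to $10^{-13}$ against the full refit) and two orders of
magnitude faster. Random-field theory, the classical alternative, is
intentionally not implemented: its thresholds depend on smoothness
estimates that the permutation test simply does not need. A Bonferroni
mode ($p < \alpha/V$) is provided as a cross-check and as the fast option
inside cross-validation folds.

Two degenerate situations get explicit handling. A vertex whose response
is *exactly* explained by the covariates has zero residual variance and
no usable evidence; its $t$ is reported as 0 rather than an exploding
ratio. And when no cluster survives correction, the patch falls back
first to the uncorrected cluster-forming mask and then to the top 1 % most
significant vertices, always flagged in the patch provenance —
cross-validation folds must produce a value for every subject, and a
silently empty patch would be worse than a flagged fallback.

Only CM and ECTD patches are carried into the hazard and prediction
models (a decision fixed before analysis in the study design this package
follows); CTh and CBMD patches are produced for reporting, and the
modelling functions refuse them unless explicitly overridden.

## Case-cohort survival modelling

The case-cohort design analyses all incident cases plus a random subcohort
drawn at fraction $\alpha$ from the full cohort. `fitWeightedCox()`
implements the Barlow weighting: subcohort members count as controls with
weight $1/\alpha$ while at risk, every case counts with weight 1 at its
own event, and a case inside the subcohort contributes both — implemented
as counting-process rows with the event row starting just before the
event time (offset $10^{-5}\times$ the longest follow-up, never crossing
zero). Ties use Breslow's method; all subjects enter at time zero
(baseline scan); competing fracture types are censored for type-specific
outcomes; variance is the sandwich estimator clustered on subject.
With $\alpha = 1$ this machinery reproduces a standard unadjusted Cox fit
exactly (coefficients agree to $10^{-6}$ in the test suite, and to
machine precision in practice) — the design's key internal consistency
check.

Exposures are standardized by their SD **in the subcohort** — the
population-representative sample; the full case-enriched analysis sample
would overweight cases — and hazard ratios are reported per 1 SD
*decrease* for imaging variables (so protective variables read as risks),
per 1 SD increase for height, and per 5-year increase for age, with age
and height fitted unadjusted and all imaging variables adjusted for
age + height + site. The per-SD-decrease and per-SD-increase ratios are
exact reciprocals, asserted numerically.

## Prediction and model comparison

Ten-year incidence models use binomial (any fracture) or trichotomous
multinomial (none/trochanteric/neck, reference "none") logistic
regression on age + height + site plus imaging variables; subjects
fracturing after the horizon count as non-fractured — the classifier asks
*whether*, not *when*. Logistic fits are unweighted on the analysis
sample; whether the original analyses weighted for case-cohort
over-sampling is not documented, so a weighted option exists
(`weights` argument) but is not the default, and the odds ratios should be
read as conditional on the case-enriched sample.

Cross-validation (`looPredict()`) holds each fold out of *everything*,
including patch discovery: when the model contains CBM variables, the
surface GLM and patch extraction are re-run on the fold's training
subjects, patch means recomputed from the fold's patches, and the
held-out subjects predicted from a model they never touched. Leave-one-out
is the default (`folds = n`); the replicate validation studies use 5–10
folds to keep a hundred replicates affordable, trading a little extra
pessimism for runtime. The permutation seed is fixed across folds so one
run's folds share a null — a documented knob (`spmSeed`).

AUC is computed by pair counting (ties half) with a subject-level
percentile bootstrap stratified by outcome; the trapezoidal ROC area
equals the pair-counting value, asserted in the tests. Nested models are
compared by the deviance $\chi^2$ test (DEV difference against the
parameter-count difference), refusing non-nested pairs, with the
conservative $p < 0.005$ reporting convention propagated to the output
tables.

## Precision

From paired repeat scans, the error variance at each vertex is estimated
as one half the variance of the within-pair differences (n − 1
denominator; 19 pairs is the default study size, giving 18 degrees of
freedom). The estimator is unbiased but blind to fixed between-scan
offsets, by construction. Reports show the SD in absolute units, as a
percentage of the cohort mean (CV %), and as a percentage of the
between-subject cohort SD — the most decision-relevant column, since
$1.96\sqrt{2}\,\mathrm{SD}$ is the minimum detectable single-subject
difference at 95 % confidence. Patch-level precision aggregates each scan
over the patch *before* differencing, which is why patch summaries are
far more repeatable than single vertices (independent noise shrinks
roughly as $\sqrt{k}$ over a k-vertex patch).

## Pipeline

`runPipeline()` chains the stages from one YAML configuration with an
explicit seed per stochastic stage, writes the four standard result
tables, per-vertex effect and precision maps as ASCII PLY scalar
properties, a structured stage log, and an md5 checksum manifest.
Identical configurations reproduce byte-identical outputs, and stages
whose cached state matches the stored config hash are not recomputed.
Measurement and mapping run before fracture labels are ever joined to the
data — the blinding mirror of the original processing order. The
measurement stage demonstrates the profile engine on a random vertex
subsample of one subject (full per-vertex re-measurement of every subject
is a cluster-scale computation; at desk scale the generator's fields
already stand in for measured ones, and the demonstration quantifies the
engine's recovery error on exactly the fields it would be measuring). The
thin `exec/cbmfrax` script exposes the same entry point from a shell.

## Validation-study problem sizes

The test suite and the acceptance script (`scripts/acceptance.R`) run the
package's validation studies at these sizes, chosen once for desk-scale
runtime: weighted-Cox oracle equivalence at n = 900; hazard-ratio recovery
(true HR 2.0 per SD decrease) over 60 case-cohort replicates at n = 1500,
α = 0.1; robust-CI coverage over 200 null replicates at n = 1000; SPM null
false-positive rate over 4 field realizations × 50 label draws at 1,000
vertices, n = 200, 500 permutations (several field blocks because the
conditional false-positive rate varies with the realized noise field);
planted-patch Dice over 5 replicates at n = 400; and the headline
CBM-vs-BMD contrast over 100 replicates at n = 260 with 5-fold
cross-validation and Bonferroni patches inside replicates. Larger sizes
sharpen the estimates but change no conclusion; every study is a plain
function of its seeds.

## Known limitations

Anatomical realism of the canonical surface is schematic; registration is
by construction exact; the hazard model is constant-rate within subject;
the BMD surrogates are correlational stand-ins, not physical simulations;
and the multinomial sample sizes in the replicate studies sit near the
lower end of what the model family needs, which is why separation is
detected and flagged rather than assumed away. Conclusions about clinical
data require clinical data.
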