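---
title: "Trait measurement error in depth-camera pig body weight: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trait measurement error in depth-camera pig body weight: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(pigtme)
```

## The question

A walk-in scale and a top-view depth camera give two measurements of the same
trait — pig body weight (BW) — with different error processes. Their absolute
difference per animal and occasion is the **trait measurement error** (TME).
If TME is random, image-based BW can replace scale BW in genetic evaluation;
if TME is partly *genetic* — for example because some sires transmit a
conformation that systematically fools the camera — then selection on
image-based phenotypes is selection on the error too. The package provides a
fully synthetic test bed for this question: a genotype/phenotype/depth-video
generator with known truth, the image-analysis and quantitative-genetics
pipeline, and report assembly, so that both the null world (TME is
non-genetic) and the failure world (heritable ventral clearance corrupts the
camera) can be simulated and analysed end to end.

## The simulated cohort

`sim_config()` fixes the study conditions. The defaults describe a commercial
finishing cohort: `n_individuals = 800` crossbred pigs genotyped at
`n_markers = 10000` biallelic SNPs with allele frequencies drawn from
U(0.05, 0.5), weighed at four visits (T1–T4) with mean BW 65/78/92/114 kg and
within-visit SD `sd_bw = 12` kg, under a depth camera `camera_height = 1.40`
m above the exit lane.

**Family structure.** Commercial finishing pigs are not unrelated: they are
full-sib litters nested within a limited set of sires. The generator's
default pedigree is 40 sires × 2 dams each × litters of ~10
(`n_sires`, `dams_per_sire`); founders are independent Binomial(2, p) draws
and offspring receive Mendelian alleles, so markers stay in linkage
equilibrium. This matters quantitatively: with 10,000 *independent* markers
and *unrelated* animals, the sampling SD of a GBLUP heritability estimate at
n = 800 is roughly `sqrt(2m)/n` ≈ 0.18, and a null trait would round to 0.00
in barely half of all replicates. The family design concentrates the
relationship matrix, which is what gives the REML estimates the precision a
study of this size reports (standard errors of a few hundredths for a
boundary trait). An unrelated mode (`n_sires = NULL`) is kept for the
sampling-theory checks. No linkage disequilibrium is simulated in either
mode; the analyses here need only additive architecture.

**Trait architecture.** Ten QTL (sampled among the markers) receive
equal-variance effects with random signs on the standardized scale, scaled so
that `var(u) = h2_bw * sd_bw^2` exactly; the residual is
N(0, (1 − h2_bw) sd_bw²) per visit, and small fixed effects (sex, birth
farm, pen density, age, dam parity — magnitudes set in `fixed_effects`,
defaults of order 1 kg) are added. Equal per-QTL variance (about 4% of
phenotypic variance each at the defaults) keeps all ten loci detectable,
which is what the top-10/top-100 marker-agreement statistic assumes.

**Ventral clearance.** The camera sees the pig's back; the gap between floor
and ventral abdomen (`clearance`, default mean 0.18 m) is invisible to it and
inflates the apparent height. In the null world clearance is pure environment
with `clearance_sd = 0.01` m — a uniform barn. The genetic-error scenario
posits that a minority of families carries belly-lifting genetics: clearance
then gets heritability `h2_clearance = 0.5` from a *single directional major
locus* drawn among markers with observed frequency 0.05–0.10 (disjoint from
the BW QTL), and `clearance_sd` widens to 0.04 m. The single skewed locus is
a deliberate choice, not a convenience: TME is an *absolute* difference, and
E[TME | g] is an even function of a symmetrically distributed clearance
breeding value, so a symmetric polygenic clearance architecture loses almost
all of its additive signal through the fold (we measured ĥ²_TME ≈ 0.1 at
true clearance h² = 0.5 under a normal architecture). A low-frequency
directional locus makes the clearance distribution right-skewed — most
animals sit near baseline, carriers sit above — so the fold is locally
monotone and the additive signal survives. This is also the most literal
reading of the scenario's premise ("some sires carry genetics that increase
the gap").

## Rendering and the image pipeline

`render_depth_video()` draws the pig as an ellipsoidal body with a
*flattened superelliptical* dorsal profile,
`z = clearance + c·sqrt(1 − q^k)` with `q` the normalized elliptical radius
and `k = dorsal_flatness = 3`. A literal half-ellipsoid (`k = 1`) has mean
height only ~2/3 of its maximum, which is a poor model of a finishing pig's
broad back and makes the mean-distance height definition (below)
systematically low; `k = 3` gives a mean/max ratio around 0.9. Floor pixels
sit at `camera_height`; pig pixels at `camera_height − (clearance + local
height)`. Per-frame pose jitter (`jitter_px`, `jitter_deg`) and randomly
varying head/tail protrusions emulate a restrained animal whose extremities
move; their distributions are nominal and configurable, since no
within-video pose statistics are available to match.

**Perspective.** The footprint is magnified by the thin-lens factor
`M = camera_height / (camera_height − (clearance + body_height/2))`. At 1.40
m working distance this is a ~35% linear magnification, and it is the channel
through which clearance corrupts *every* pixel feature coherently — a raised
body looks bigger, not just taller. Without it, clearance touches only the
height and volume features and any trained regression simply shifts weight
onto dorsal length and abdominal width, which erases the failure mode that
the genetic scenario exists to demonstrate.

**Pseudo-color encoding.** Hue is linear in distance,
`hue = hue_max · d / camera_height` with `hue_max = 240`°, so the floor is
the hottest hue and nearer surfaces are colder. The map is exactly invertible
in memory; through the 8-bit PNG round trip it is invertible to within one
quantization step (360/(6·255) ≈ 0.24°, i.e. ~1.4 mm at the default
geometry). Distance maps travel as plain CSV in metres and are exact.

**Segmentation.** `adaptive_hue_threshold()` binarizes the hue channel
starting 15° below the frame's mean hue (foreground = below threshold,
matching the encoding above), keeps the largest 8-connected component, and
raises the threshold 1° at a time — up to 5° above the mean — while the
component's bounding box comes within 5 px of the image border. Lower
thresholds are preferred: they capture the unambiguous core of the animal. A
threshold that turns more than half the frame white has found background and
is skipped; a uniform frame therefore reports "no pig" rather than a
spurious all-frame segmentation. Ties between equally sized components break
by scan order. `trim_head_tail()` removes a fraction
`min(trim_ratio · width/length, 0.25)` of the long axis at each end
(`trim_ratio = 1` by default; the ratio rule is stated by the source method
but its constant is not, so it is exposed as a parameter).
`extract_features()` then yields the four biometric features: dorsal length
and abdominal width (long/short sides of the minimum-area rotated rectangle,
in pixels, via a rotating-calipers search over the convex hull), height
(`camera_height −` mean masked distance, metres) and volume (sum of
`camera_height − distance` over the mask). Zero distances inside the mask —
missing depth readings — are replaced by the mean of the non-zero masked
distances before any statistic. Per-video features are the component-wise
medians over frames.

**Feature-space mode.** Rendering 800 × 4 videos is unnecessary to test the
genetics, so `simulate_features()` generates the per-video median features
directly from the same geometry (trimmed-ellipse area and mean-profile
integrals, the same magnification M) with multiplicative log-normal noise of
CV `feature_cv = 0.02` standing in for residual segmentation and pose
variability after median aggregation. The analytic geometry is calibrated
against one rendered reference frame passed through the actual segmentation
code, and `run_experiment(render_validation = k)` renders k animals' videos
to compare the two modes on the same shapes. Per-animal *conformation*
deviations (`shape_cv = 0.04`, log-scale, on length and width with height
balancing so that L·W·H stays proportional to mass) prevent body shape from
being a deterministic function of weight; without them dorsal length alone
would predict BW perfectly and the regression would ignore the very features
that clearance can corrupt. Pigs genuinely vary in condition at a given
weight, so this is realism, not tuning.

## Body-weight regression

`fit_bw_ols()` and `fit_bw_rf()` regress scale BW on the four median
features. The random forest uses 500 trees, minimum node size 5, and tunes
only the per-split feature-subset size by seeded 5-fold cross-validation
minimizing RMSE; everything is deterministic given the seed. Reported fit
metrics are `evaluate_bw()`'s R² (1 − SS_res/SS_tot) and MAPE
(100/n · Σ|y − ŷ|/y, absolute deviations, scale BW in the denominator).
Under cohort calibration (`fit_bw_holdout()`), each time point gets a seeded
random 80/20 split and both training and held-out metrics are reported —
whether published per-time-point fits are training or held-out is generally
unstated, so both are available.

**Calibration protocol and why it decides the outcome.** An important
structural finding of this implementation: when the regression is trained on
the *study cohort itself*, ordinary least squares learns to cancel the
clearance imprint — the height feature acts as a linear probe for clearance,
and the fitted coefficients discount exactly the corrupted directions. In
our experiments this caps the TME heritability near 0.1 even when clearance
is strongly heritable, which is a plausible mechanistic account of why a
study that trains and applies per cohort finds null TME heritability even
with its weakest regression. The failure mode emerges under *reference
calibration* (`calibration = "reference"`): the equation is fitted on a
separate uniform-clearance cohort (a factory-calibrated vision system) and
deployed unchanged, so nothing absorbs the clearance direction and the
corrupted predictions inherit its genetics. `experiment_config()` therefore
defaults to cohort calibration in the random scenario and reference
calibration in the genetic-clearance scenario, and exposes the switch.

## Quantitative genetics

Markers with minor allele frequency strictly below 0.05 are removed
(`maf_filter()`; a marker at exactly 0.05 is retained). `build_grm()` centres
each column by 2p and scales by sqrt(2p(1−p)) using observed frequencies,
then `G = WW′/m`. `reml_fit()` maximizes the restricted likelihood of the
one-random-effect GBLUP model `y = Xb + u + e`, `u ~ N(0, G σu²)`,
`e ~ N(0, I σe²)` by a single spectral decomposition of G followed by Brent
search of the profiled criterion over the log variance ratio in [−10, 10],
with an analytic-gradient root polish (golden-section search alone is
accurate only to ~√machine-epsilon, which fails an exact-invariance check).
The phenotype is standardized internally so the estimate is exactly invariant
to rescaling; an optimum at the search boundary is flagged. `h² =
σu²/(σu²+σe²)`; its standard error comes from the observed information of
(σu², σe²) (central finite differences) by the delta method, evaluated a
step inside the boundary when σu² has collapsed to zero. Degenerate inputs —
rank-deficient X, asymmetric or indefinite G, constant y — are refused with
informative errors.

`gwas_scan()` implements the single-marker mixed-model scan with the null
variance components held fixed across markers (the P3D/EMMAX approximation):
rotate into the eigenbasis of G, whiten by the null covariance, residualize
the centred marker dosages against the fixed effects once, and test each
marker by GLS with a t-statistic on n − p − 1 degrees of freedom. A test in
the suite bounds the approximation against exact per-marker refits. Markers
collinear with the fixed effects get effect 0 and p = 1, flagged. Rankings
are by −log10 p, ties broken by marker index; no multiple-testing correction
is applied because the downstream comparison is rank-based:
`topk_agreement()` counts how many of the top-10 markers of the scale-BW
scan appear in the top-100 of another scan.

## The experiment runner and the report

`run_experiment()` chains everything deterministically from one seed:
genotypes → trait and clearance → image BW (feature + regression, or direct
1.5%-of-mean i.i.d. noise via `image_mode = "noise"`) → TME → GRM/REML →
three GWAS per method and time point → `assemble_tme_report()`. The report
holds the fit-metric, heritability-triple (scale, image, TME) and
agreement/TME-overlap tables, the per-animal TME records, and the
consistently-extreme listing (animals in the top or bottom TME decile at two
or more time points; the decile and the minimum count are parameters, since
"consistently extreme" is not defined more precisely than "at least two time
points" anywhere we could anchor it). `autoplot()` methods draw the
TME-percentage distributions and Manhattan plots; artifacts persist as
CSV/TSV/JSON when `out_dir` is set, and a persisted feature table can be fed
back through `run_experiment(features = ...)` to resume identically.

```{r tiny-run, eval = FALSE}
cfg <- sim_config(n_individuals = 200, n_markers = 2000, n_sires = 10,
                  time_points = c("T1", "T2"), mean_bw = c(65, 78), seed = 1)
report <- run_experiment(experiment_config(cfg, methods = "ols"))
report
autoplot(report)
```

## Problem sizes, tolerances, and what the tests show

The test suite exercises the full study scale where the claims require it
(n = 800, m = 10,000 for the null-TME, parameter-recovery, calibration and
failure-mode checks; 20 seeded replicates for the replicate-fraction
claims) and smaller cohorts (n = 150–800, m = 300–2,000) for the
module-level oracles: normal-equation and grid-search likelihood references,
hand-computed GRMs, rendered-slab arithmetic, hypergeometric expectations.
The REML optimizer is required to match a 10⁴-point grid search within 10⁻³
in h²; segmentation geometry is required to match camera arithmetic at
machine precision on noiseless slabs; the hue codec must be exact in memory
and within one 8-bit quantization step through PNG.

What passing these tests shows is that the *pipeline* reproduces the
structural results under the stated generative model. It does not show that
real depth videos behave like the renderer: real data have occlusions,
multi-animal frames, depth dropout correlated with surface angle, motion
blur, and detector-level quality control, none of which are modelled. The
generator also omits linkage disequilibrium, dominance and epistasis,
genotype-environment correlation, and selection, so heritability recovery
here speaks to estimator correctness, not to robustness against real
population structure beyond the simulated sire-litter design.

## Known limitations

- TME's absolute value destroys additive signal under symmetric error
  genetics; the failure-mode demonstration depends on the directional
  major-locus architecture and on reference calibration, both documented
  above. With cohort-trained regressions the simulated ceiling for ĥ²_TME is
  far below the clearance heritability — a caution against over-reading
  null TME heritability as proof that no conformational genetics touch the
  camera.
- The perspective model is a single mid-body magnification factor, not a
  full pinhole projection with occlusion; it is exact enough for the
  footprint statistics used here.
- The feature-space generator matches the renderer through one calibrated
  reference shape; agreement degrades for shapes far from the cohort median
  (the `render_validation` table quantifies it per run).
- Variance-component standard errors use the observed information at (or
  just inside) the boundary; they are indicative, not exact, when ĥ² = 0.
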