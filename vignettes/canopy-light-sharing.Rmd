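---
title: "Light sharing in virtual wheat-pea mixtures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Light sharing in virtual wheat-pea mixtures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopymix)
```

## The scientific problem

In a cereal-legume intercrop, the two species compete for
photosynthetically active radiation, and the way light is partitioned
between them drives growth, biological nitrogen fixation and the final
balance of the mixture. For a *well-mixed* canopy, the turbid-medium
abstraction predicts the partition from just two descriptors per species:
leaf area index (LAI) and mean foliage inclination (through the extinction
coefficient $K$). Real canopies, however, are structured: plants stand in
rows, organs cluster around stems, and one species can overtop the other.

`canopymix` reproduces, as a fully synthetic and seeded pipeline, a
simulation experiment on this question: build explicit 3D mock-ups of six
winter pea cultivars of contrasting architecture (two leafy, four
semi-leafless) and of a wheat stand, mix them in virtual rows, compute each
species' interception of diffuse light by first-hit ray casting, and compare
the computed share with the well-mixed theoretical share. The deviation
between the two, and its relation to the wheat/pea height ratio, is the
quantity of scientific interest.

## Turbid-medium theory

For species $i$ with extinction coefficient $K_i$ and leaf area index
$\mathrm{LAI}_i$, the light interception efficiency (LIE) in a well-mixed
mixture is

$$\mathrm{LIE}_i \;=\; \frac{K_i\,\mathrm{LAI}_i}{\sum_j K_j\,\mathrm{LAI}_j}
\left(1 - e^{-\sum_j K_j \mathrm{LAI}_j}\right).$$

In the two-species share the exponential factor cancels: with
$\alpha = K_1/K_2$ and $p$ the relative LAI of species 1,

$$s(p) \;=\; \frac{\alpha p}{\alpha p + (1-p)},$$

the isoline family implemented by `share_theoretical()` and `isolines()`.
The identity between the share computed this way and the LIE ratio is
asserted to $10^{-12}$ in the test suite, which guards the algebraic
reconstruction.

Extinction coefficients come from mean foliage inclination through the
ellipsoidal leaf-angle distribution (`ellipsoidal_kbe()`): the distribution
parameter $x$ is inverted from the mean inclination, the directional
coefficient is $K(\theta) = G(\theta)/\cos\theta$, and a single
diffuse-effective $K$ is defined as the value that reproduces the
sky-integrated interception at a reference LAI. This mapping is isolated in
`extinction_from_inclination()` so an alternative convention can be swapped
in.

**Reference LAI.** The exported default is `ref_lai = 1`. Inside
`run_stage_experiment()` the reference is the scene's own total LAI instead.
The reason is quantitative: for erect wheat foliage $K(\theta)$ spans
roughly 0.4-2.7 across the sky vault, so the effective coefficient of a
sparse stand (total LAI near 0.25 at the first stage) is about 20 % larger
than the LAI-1 value, and using the latter systematically inflates the
theoretical shares against which the ray-cast shares are judged. Evaluating
$K$ at the stand's own optical depth makes the theoretical reference
internally consistent at every stage.

## Phytomer appearance: the Schnute model

Development is clocked in thermal time $t$ (degree-days above 0 °C since
emergence). The number of visible phytomers on the main stem follows the
Schnute form

$$Y(t) \;=\; y_{\max}
\left(\frac{1-e^{-A t}}{1-e^{-A t_{\max}}}\right)^{1/B},$$

with $Y(0) = 0$ and $Y(t_{\max}) = y_{\max}$; $t_{\max}$ is always the last
observation time, never a free parameter. Among the Schnute cases this
parameterization was selected because the times of maximal rate it implies
from the published per-cultivar parameter means land on the published values
(e.g. $t^\* = -\ln B / A \approx 353$ DD for the earliest cultivar against a
printed 350 DD); the form is kept behind `schnute_eval()` as a single
swappable strategy. Fitting (`schnute_fit()`) uses Levenberg-Marquardt least
squares via `minpack.lm::nlsLM`, with starting values $A_0 = 2/t_{\max}$,
$B_0 = 0.5$, $y_{\max,0} = \max(\text{counts})$ — inside the observed range
of all six cultivars — and refuses to return silently on non-convergence.
The maximal appearance rate (`schnute_rate()`) is closed form for $B < 1$;
when the maximiser falls outside $(0, t_{\max}]$ the result is flagged as a
boundary case, with the smallest-$t$ tie-break for plateaus.

Published rate values were plausibly obtained as means over eight per-plant
fits rather than from the mean parameters, so checks of $V_{\max}$ against
the printed table carry a 10 % tolerance (the Jensen gap between
mean-of-derivatives and derivative-at-means).

## The synthetic plant generator

The study's raw material — magnetically digitized plants — is not
available, so the generator is a first-class, tested module that emulates
the six cultivars from tabulated parameters:

* **Development**: main-stem phytomer count $= \operatorname{round} Y(t)$;
  phytomer $i$ appears when $Y$ crosses $i - 1/2$ (consistent with the
  rounding).
* **Organ expansion**: every organ grows linearly to its final length over
  75 DD after its phytomer appears. A 150 DD constant was considered and
  rejected: the reference stands at 300 DD carry LAI 0.06-0.13 and heights
  13-18 cm on only 3-5 visible phytomers, which is only attainable if
  organs approach final size within roughly one phyllochron.
* **Profiles**: stipule final length follows a triangular profile peaking
  (50 mm) between normalized ranks 0.6 and 0.8; leaflet length (leafy
  cultivars only) peaks (45 mm) at mid-stem; internode final lengths follow
  a per-cultivar profile over normalized rank. Leaves use an elliptical
  outline with a 2:1 length:width ratio; stems and internodes are thin
  vertical ribbons whose width is calibrated so stem area lands in the
  observed 5-11 % band of green area.
* **Geometry**: stipules attach in opposite pairs with a small petiole
  offset; leaflets sit on a rachis displaced from the stem, successive
  pairs staggered down the internode; azimuths are uniform (no azimuthal
  statistics were reported); organ inclinations follow per-cultivar
  piecewise-linear dynamics in thermal time with a mean-preserving jitter
  (sd 10°). Stems are staked upright; a short basal segment stands for the
  vestigial basal phytomers of winter pea.
* **Branching**: branch counts are drawn uniformly from the per-stage
  observed ranges, branch phytomer numbers from the observed means ± sd;
  insertion is basal (ranks 1-3) except for the cultivar whose branches
  arise at ranks 12-14. Branches lean 35° from vertical, reuse the
  main-stem profiles truncated to their phytomer count, and co-develop
  with the main-stem ranks above their insertion.
* **Wheat**: a stage-wise parametric generator (not a dynamic development
  model): per-plant green area, height and blade inclination are taken from
  the shipped stage table; blades are strips splayed off a thin pseudo-stem,
  sized so the green area matches the target exactly, including the green
  LAI decline at the last stage (area scaling, not a senescence model).

Calibration: the free geometric constants (internode scales and basal
multipliers, a per-cultivar leaf-size factor, stem widths) were fixed once
so that assembled stands at 300/600/1240/1560 DD reproduce the reference
LAI within ±20 %, foliage inclination within ±6° and organ-type area shares
within ±3 points; the shipped YAML files carry the calibrated values and the
test suite re-checks the bands. Leaflet count per leafy phytomer is a spec
field (`leaflet_pairs`), defaulting to one pair; the later leafy cultivar
uses two smaller pairs, which keeps its area while avoiding the unrealistic
single large leaflet discs.

What the generator does **not** emulate: tendrils (not digitized in the
source data), root systems, lodging or stem curvature, plastic responses to
neighbours, and any scattering organ optics. Tests passing on these
mock-ups therefore validate the pipeline's internal consistency and its
agreement with turbid-medium physics under the stated conditions — not
fidelity to any particular real canopy.

## Scene assembly and descriptors

`assemble_mixture()` lays plants on rows 0.17 m apart at 125 (wheat) and 45
(pea) plants m⁻², the species alternating within each row in proportion to
their densities, with ≤2 cm seeded placement jitter and a seeded rotation
of every mock-up. The scene is doubly periodic in x and y — an exact torus,
emulating an infinite stand without border plants. Descriptors
(`canopy_descriptors()`): LAI per species counts *all* green organs
including stems; mean foliage inclination is area-weighted over stipules,
leaflets and blades only (inclination measured from the horizontal — the
erect wheat habit at ~65° fixes the convention); plant height is the
highest organ vertex, averaged per species.

## Diffuse light interception

The sky is a Uniform Overcast Sky discretized into 20 sectors: five zenith
bands with boundaries every 18°, four azimuths each. Band weights follow
the cosine-weighted closed form $(\sin^2\theta_2 - \sin^2\theta_1)$,
normalized; the first band's weight is $\sin^2 18° \approx 0.0955$.
Directions sit at the band's upper boundary (18°, 36°, 54°, 72°, 90°), the
90° entry replaced by the band's flux-weighted mean zenith (≈78.1°) so no
ray is exactly grazing; a `band_mean` switch instead uses flux-weighted
means everywhere.

Interception is first-order: organs are opaque, with no transmission or
scattering. This replaces the radiosity treatment of the original study —
scattering redistributes a small fraction of PAR, and only intercepted
fractions are analyzed here — and it makes the energy bookkeeping exact:
per direction, species fractions plus the soil fraction sum to 1 in
counting measure.

Per direction, a stratified-jittered grid of parallel rays covers the
footprint. Shearing the scene by the ray direction turns the problem into
2D point-in-triangle tests with the first interception being the highest
hit; periodicity is exact, by replicating sheared triangles into every unit
tile their bounding box overlaps (capped at 10 plot widths, the path-length
cap). The kernel is C++ (Rcpp) with a uniform grid over the footprint;
default budget 10⁵ rays per sector. All jitter flows from R's RNG under a
single scene-level seed, fanned out to sectors and replicates by a
deterministic counter scheme, so results are bit-reproducible and adding
replicates never perturbs earlier ones. The Monte-Carlo standard error is
the weighted binomial error; it halves when the ray budget quadruples.

## The sharing analysis

`run_stage_experiment()` produces one record per (genotype, replicate):
descriptors, the ray-cast pea share `share_computed`, the theoretical share
from the record's *own* descriptors ($K$ from mean inclinations at the
scene's optical depth, $p$ from the LAIs), their deviation, and the
wheat/pea height ratio. `regress_shares()` compares computed with
theoretical shares. Both regression variants are always available; the
origin-constrained slope is reported as the headline number because both
axes are shares of the same total — the line is structurally pinned at
(0, 0) — and the published regression equations carry a slope only. The
free-intercept variant is written alongside in every summary.
`height_ratio_curve()` fits the saturating exponential
$d = a\,(1 - e^{-b(h-1)})$ to the deviations over height ratios $h \ge 1$,
reporting the saturation deviation $a$; "exponentially related" admits
several forms, and this bounded one matches the observation that the effect
of further pea height is constant beyond $h \approx 2$.

## Numerical choices and problem sizes

* Sparse-stage experiments run on a 0.68 m × 0.68 m torus (4 rows, 58
  wheat + 21 pea plants, 8 mock-up variants recycled per species); the
  analysis uses 24 mixtures (6 genotypes × 4 replicates) at 10⁵ rays per
  sector — a few minutes on one core.
* Schnute fits bound $A, B, y_{\max}$ away from zero; a constant series or
  fewer than five observations is an error, and noisy synthetic counts that
  dip locally produce a warning, not an error (phytomer number cannot truly
  decrease; observation noise can).
* Degenerate ray-cast inputs: a zero-area footprint is an error; an empty
  scene intercepts nothing; triangles seen edge-on under a direction are
  measure-zero and skipped.
* Zero-length organs are valid zero-area organs, so pre-emergence plants
  are empty mock-ups rather than errors.

## Known limitations

* First-order interception slightly underestimates absorption compared with
  a scattering treatment, uniformly across species.
* The mock-ups are more regular than digitized plants (exact profiles,
  independent jitters); residual within-plant clumping leaves the computed
  shares of the densest leafy mock-ups about 2-3 % below the well-mixed
  line even at the sparse stage, visible as a free-intercept slope below
  the origin-constrained one.
* The published mid- and late-stage regression slopes depend on the
  original digitized plants and are not reproduction targets; the pipeline
  reproduces the sparse-stage agreement and the qualitative height-ratio
  relation (taller pea mock-ups strictly increase the pea share, and
  deviations saturate with the height ratio).
* Inclination dynamics anchor points for the leafy cultivars are derived
  from the stand-level mean inclinations and the leaflet range endpoints,
  not digitized curves.
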