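---
title: "Friction at first touch: models, estimators, and synthetic benchmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Friction at first touch: models, estimators, and synthetic benchmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frictouch)
```

## The scientific question

When a fingertip presses on a plate, the skin inside the contact expands
radially, and the amount of expansion depends on the friction between skin
and plate: slippery surfaces let asperities slide outward as the pulp
flattens, high-friction surfaces pin them where they land. The mean
divergence of the in-contact micro-displacement field,
$$\overline{\nabla\cdot u} \;=\; \frac{1}{|S|}\int_S
  \frac{\partial u_x}{\partial x} + \frac{\partial u_y}{\partial y}\; dS,$$
taken over the apparent contact area $S$, is therefore a friction cue that
is available at initial contact, before any lateral loading. `frictouch`
implements the computational chain needed to study this effect: a
mechanical fingertip model, a kinematic strain model, displacement-field
analytics, a contact-image pipeline, a two-alternative forced-choice
(2AFC) analysis, and a fully seeded synthetic-data generator that makes
every stage testable without laboratory data.

## The geometric (hemisphere-flattening) model

`hemisphere_strain()` treats the fingertip as a quasihemisphere of radius
$R$ indented by $\delta$ against a plane. Material along the meridian arc
$R\theta$ (with $\theta = \arccos(1 - \delta/R)$) must fit onto the flat
chord $R\sin\theta$, giving the compressive strain
$1 - \sin\theta/\theta$. With the default $R = 10$ mm (a typical adult
index distal phalanx) and $\delta = 3$ mm this is about 10%:

```{r geometry}
hemisphere_strain(radius_mm = 10, indentation_mm = 3)
```

The strain definition is meridional (arc versus chord). Flattening also
stretches material circumferentially; a cap-averaged hoop strain is
reported alongside for completeness, but the headline number is the
meridional one. A volumetric definition would require assumptions about
the subsurface displacement field that this purely kinematic model does
not make.

## The mechanical fingertip model

`simulate_press()` integrates a cross-section of the fingertip: `n_nodes`
surface nodes on a circular arc (radius 8 mm, half-angle 60°), joined by
Kelvin–Voigt membrane elements, each connected to a rigid bone element by
a pulp spring acting along the node's *material* (initial radial)
direction. Pressing the bone ramps the load at the experimental force
rate (3.6 N/s) to the 3 N target; contact with the plate is a unilateral
penalty (clipped at zero force, so no adhesion), and the tangential
interaction is an elastoplastic stick spring: the anchor is dragged back
onto the Coulomb cone whenever $|f_t| > \mu f_n$ (radial return). The
integrator is semi-implicit Euler with an implicit per-node drag; the
default step is a tenth of the stiffest element's vibration period, so the
scheme is comfortably inside its stability region and the press is
quasi-static relative to every structural mode.

Model-design choices worth knowing about:

* **Material-direction pulp springs.** Pointing the pulp springs at the
  instantaneous bone position makes the model behave like a rigid
  expanding sphere, shovelling the skin outward and producing order-one
  spurious divergence. Springs along the fixed material direction
  compress the pulp without that artefact.
* **Engaged-contact divergence.** The contacted-skin divergence uses the
  axisymmetric form $\partial u_r/\partial r + u_r/r$ (limit
  $2\,\partial u_r/\partial r$ on the axis), area-weighted over contacted
  nodes, with each node's displacement referenced to its position at
  contact onset. Onset referencing makes the freshest rim nodes carry
  exactly zero displacement, and by the divergence theorem the strict
  area mean then collapses to the boundary flux of those nodes. Nodes
  carrying less than 10% of the peak interfacial pressure (the incipient
  rim, not yet mechanically engaged) are therefore excluded from the
  average.
* **Calibration.** The stiffness/damping/mass constants of the real
  fingertip are not identifiable from the printed endpoints alone, so the
  defaults were calibrated once to reproduce the divergence endpoints at
  3 N (about 0.04 at $\mu = 0.1$, about 0.02 at $\mu = 0.6$) while
  keeping the divergence strictly decreasing over
  $\mu \in \{0.1, 0.2, 0.4, 0.6\}$; they are all overridable through
  `finger_params()`.

```{r press, eval = FALSE}
sim <- simulate_press(finger_params(mu = 0.1))
sim$divergence          # ~0.043
glance(sim)
autoplot(sim)           # interfacial stress profiles
```

**Known limitation.** This is a 2D cross-section line model: there is no
hoop (azimuthal) elasticity coupling the meridional ring of nodes. With
the divergence-calibrated defaults, friction-dependent slip localises in
the low-pressure band near the contact rim, which makes the *peak
tangential stress* and the stick-spring elastic energy considerably more
friction-sensitive (about +76% and +198% between $\mu$ = 0.6 and 0.1)
than the full axisymmetric membrane would suggest (about +40%).
Calibrations that tame the stress ratio break the divergence ordering, so
the divergence — the quantity the perceptual claim rests on — was given
priority. The normal-stress profile is friction-invariant within a few
percent and integrates to the applied load within 1%, as it should.

## Displacement-field analytics

`grid_interpolate()` maps scattered tracked-feature displacements onto a
uniform grid with a local moving-least-squares plane fit over the
`k = 12` nearest features, masked to the convex hull (no extrapolation).
A plane fit reproduces affine fields exactly and converges at second
order on smooth fields; a Delaunay-based barycentric interpolant would
share those properties, but no triangulation backend is part of this
package's dependency footprint, and the MLS fit additionally tolerates
noisy, irregular feature clouds.

`mean_divergence()` applies central differences on interior masked cells
and one-sided differences at the mask boundary; cells with no masked
neighbour in some direction are excluded. The estimator is exact for
affine fields (so `u = k(x, y)` returns `2k` to rounding), vanishes on
rigid translations and rotations, and is invariant to adding a constant
field.

`decompose_field()` splits a field into constant + divergent +
rotational + residual. The constant part is the median vector (robust to
the asymmetric outliers produced by tracking failures); the divergent and
rotational parts are gradients of a scalar potential and a
streamfunction, both expanded in polynomials of total degree 8 and fitted
jointly by minimum-norm (SVD) least squares. Quadratic potentials are
represented exactly, so the canonical radial and rotational fields
separate to machine precision; what the degree-8 pair cannot represent
lands in the residual, and the reconstruction identity holds exactly by
construction. The harmonic gauge (fields that are simultaneously
curl-free and divergence-free) is fixed by the minimum-norm solution.

Strain summaries use the infinitesimal strain tensor from the same
differencing: the reported longitudinal strain is the largest principal
strain magnitude over the mask in percent (the component relevant to
mechanoreceptor thresholds of roughly 2–4% strain), the strain rate is
its central-difference time derivative (afferent threshold ~8%/s), and
`strain_energy()` integrates the plane-stress elastic energy density over
the masked area and a nominal skin thickness. Defaults $E = 0.1$ MPa,
$\nu = 0.4$, $t = 1.5$ mm are typical fingertip-skin values; only the
product matters for the reported millijoules, and all are configurable.

## The contact-image pipeline

The dual-illumination imaging scheme yields two channels per frame: a
ridge channel (grazing illumination, for feature tracking) and a contact
channel (coaxial illumination — only asperities in intimate contact light
up). The pipeline:

* `correct_illumination()` subtracts a heavily Gaussian-smoothed
  background (default $\sigma$ = 1/16 of the image size) and restores the
  mean, removing shading ramps while passing ridge-scale texture.
* `otsu_threshold()` maximises the between-class variance of the
  intensity histogram (exact histogram when the data take few distinct
  values, 256 bins otherwise; ties break toward the lower threshold).
  `real_contact_area()` counts above-threshold pixels times the squared
  pixel resolution.
* `detect_features()` scores corners by the smaller structure-tensor
  eigenvalue and keeps the strongest 700 with a minimum spacing;
  `track_features()` follows them with an iterative two-level pyramidal
  local optical-flow tracker. Each point's displacement is referenced to
  its contact onset — the first frame where the local contact brightness
  (10-pixel-radius disk) exceeds half of that point's trial maximum. A
  tight 2-pixel probe decides whether a point ever entered the contact at
  all; points that never did are dropped, as are ill-conditioned or
  divergent tracks (the count is recorded).
* `filter_force()` is the zero-lag second-order 50 Hz Butterworth
  low-pass, applied forward and backward with end-point detrending and
  mirror padding so that constants pass exactly and no start-up transient
  leaks into the window.
* `global_displacement()` implements the trial-exclusion rule: a trial
  whose median displacement vector exceeds 0.3 mm in magnitude is flagged,
  so that gross sliding of the whole contact cannot act as the cue.

## Psychophysics

`fit_psychometric()` fits the 2AFC performance curve by maximum
likelihood with a cumulative-Gaussian core, chance floor fixed at 0.5 and
a fixed 2% lapse:
$P(x) = \gamma + (1-\gamma-\lambda)\,\Phi((x - m)/s)$. The 75% threshold
is read off the lapse-corrected curve,
$x_{75} = m + s\,\Phi^{-1}\big((0.75-\gamma)/(1-\gamma-\lambda)\big)$.
The sigmoid family is a convention, not a claim: the recovery tests are
family-agnostic (they only require the generating curve to be recovered),
and the family, floor and lapse are arguments. Datasets with no usable
gradient — all-correct, all-chance, or flat — return
`converged = FALSE` rather than an arbitrary extrapolated threshold.
Group-level analyses can either pool trials across participants or fit
per participant (`by_participant` in `proportion_table()`); both
estimators are available because pooled and averaged thresholds answer
slightly different questions.

## The synthetic-data generator

`gen_press_trial()` emits what the real rig records — a synchronized
dual-channel image sequence plus a force trace — with the generating
truth attached, so that recovery can be asserted rather than assumed. The
generator emulates:

* **Trial kinematics.** Peak force, duration and force rate are drawn
  from the experimental distributions (5.5 ± 3.5 N, 1.47 ± 0.39 s,
  3.6 ± 3 N/s, truncated positive), or fixed by the caller. The force
  follows a smooth tanh ramp-plateau whose initial slope is the force
  rate.
* **Contact growth and acquisition trigger.** The apparent contact grows
  radially from the centre and is fully established at a small force
  (0.25 N by default — the gross footprint of a fingertip saturates
  within about a millimetre of indentation). Frame acquisition triggers
  at 0.3 N, above that saturation force, so every tracked feature's
  contact onset falls on the first frame and the generated
  onset-referenced field has a spatially constant true divergence — the
  simplest field against which the whole pipeline can be validated
  quantitatively. The default apparent-contact radius (7 mm) exceeds the
  camera field of view, as in a close-up view of the contact interior;
  shrinking it exposes contact-boundary effects instead.
* **Friction-dependent expansion.** In-contact skin displaces radially
  as $u_r = g_{\mathrm{eff}}\,F\,r$ with
  $g_{\mathrm{eff}} = g/(1 + c_\mu\,\mu)$, so lower friction means
  strictly larger divergence at equal force; $\mu$ comes from the
  vibration amplitude through `alpha_to_mu()`, an exponential decay
  pinned exactly to the measured anchors $\mu(10^{-3}\,\mu m) = 0.81$
  and $\mu(3\,\mu m) = 0.18$ (the shape between the anchors is a
  modelling choice; only monotonicity and the anchors are data). A
  saturating variant (expansion flattening above ~2 N, as pulp
  compression saturates) is available via `saturating = TRUE`.
* **Real-contact channel.** Asperity speckle inside the contact, its
  density scaled so that the real contact area at the maximal vibration
  amplitude is 38% below the reference amplitude by construction, growing
  mildly with force, with a radial density gradient whose sign
  (`brightness_sign`) sets whether local brightness correlates positively
  or negatively with displacement — the brightness convention of that
  correlation is genuinely ambiguous in the source analysis, so the
  generator exposes it as a parameter rather than resolving it.
* **Nuisances.** Additive Gaussian image noise, a per-frame linear
  illumination ramp (so the correction stage is exercised), force-channel
  noise, and 8-bit quantisation (which also makes the trial-directory
  round trip lossless).

Seeding: one master seed deterministically derives independent substreams
for the texture and the trial (`split_seed`), so every output is
byte-identical under a fixed configuration.

What the generator does *not* emulate: photorealistic fingerprints,
perspective or lens distortion, skin-tone variability, out-of-plane
motion, and the trial-to-trial physiological variability of real skin
(the within-participant divergence noise structure is not published, so
generator noise defaults are order-of-magnitude choices). Passing the
recovery tests therefore shows the estimators are correct on data with
the assumed structure, not that the structure captures everything about
real fingertips.

## Problem sizes used by the test-suite benchmarks

The packaged tests validate estimator exactness on 48–64 point grids,
track 250–500 features on 80–96 pixel frames over ~8–10 frames per trial
(100 replicate pairs for the ordering property), fit 500 simulated 2AFC
observers (6 levels × 10 trials), and run the press simulation at its
default 41 nodes. These sizes were chosen so the full statistical
batteries stay comfortably desk-scale while keeping every Monte-Carlo
margin (binomial or median-based) well away from its threshold.

## Numerical conventions and degenerate inputs

Image coordinates: x rightward (columns), y downward (rows), origin at
the top-left pixel centre; physical units enter only through the pixel
resolution, and the divergence is coordinate-convention independent.
Degenerate inputs fail loudly: collinear feature clouds, constant images
(no Otsu threshold), masks too small to difference, non-monotone
timestamps, non-physical elastic constants, and non-finite forces in the
integrator all raise informative errors rather than propagating NaNs.
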