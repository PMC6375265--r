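---
title: "A reduced-order model of drag shear stress in bent, bifurcating carotid trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A reduced-order model of drag shear stress in bent, bifurcating carotid trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carotidflow)
```

## The model

carotidflow implements a deliberately minimal, algebraic model of how blood
velocity and wall drag shear stress evolve along a bent, bifurcating
arterial tree, together with the analysis machinery needed to confront its
predictions with histological plaque measurements.

The model has three ingredients, each tied to one geometric feature of a
vessel segment:

* **Bends.** When the flow axis deviates by an angle $\theta$, only the
  axial component of the velocity vector survives, so the centre-line
  velocity is attenuated by $\cos\theta$. A tortuous, S-shaped vessel
  applies these attenuations in cascade: after bends
  $\theta_1, \dots, \theta_k$ the remaining fraction of the inflow velocity
  is $\prod_i \cos\theta_i$. The product is commutative, so the order in
  which the bends are met does not matter, only their angles. At
  $\theta = 30^\circ$ the single-bend reduction is $1-\cos 30^\circ = 13.4\%$,
  at $60^\circ$ it is $50\%$. The model is undefined at $\theta \ge 90^\circ$
  (the cosine would stop being a positive velocity fraction), and such
  angles are rejected rather than clamped.
* **Calibre.** With the driving force of the pumping heart fixed, the drag
  stress exerted on the endothelium scales as force over cross-sectional
  area. We report the *stress index*: the cumulative velocity factor
  divided by $\pi r^2$ with $r$ in cm, a dimensionless multiple of the
  cardiac driving force per cm². Wide vessels therefore sit at low stress
  even without bends.
* **Bifurcations.** A branch point divides the flow volume per second in
  the ratio of the daughter cross-sectional areas (`flow_split()`), and
  contributes *no* cosine factor — its hemodynamic effect enters only
  through the daughter calibres.

Low drag stress is the atherogenic exposure: sites whose stress index falls
below a baseline are flagged "prone" (`classify_sites()`). The default
baseline is relative — the median stress of the tree's straight segments —
because the source data calibrate no absolute force unit. An absolute mode
is available for users who can calibrate the stress-index unit in dynes/cm²;
it uses the conventional 5 dynes/cm² boundary between undisturbed arterial
shear (about 15 dynes/cm²) and disturbed low shear.

The model is intentionally not a fluid-dynamics solver: there is no
pulsatility, no viscosity-dependent resistance network, no Navier–Stokes.
It is an order-of-magnitude screening tool whose value lies in being
computable from a handful of calliper measurements.

## The carotid fixture

The package ships a fifteen-section fixture from the right carotid tree of
a seventy-year-old female cadaver: three common-carotid (CCA) sections,
nine external-carotid (ECA) sections spanning five bends (20°, 51°, 52°,
60°, 30°) and several branch points, and three internal-carotid (ICA)
sections spanning two bends (28°, 48°). Each record carries the lumen
radius, the bend angle where applicable, and the plaque-thickness range
read off magnified histological slides; one section (ECA-6) is plaque-free
and recorded as NIL.

Two encoding decisions deserve explanation:

* **The unsectioned 51° bend.** The ECA's second bend has no histological
  section of its own, but its cosine must enter the cascade for every
  section distal to it. Rather than invent a pseudo-section, the tree
  dialect carries it as `upstream_angle_deg` on ECA-3: the angle of an
  unsampled bend lying between a segment and its parent. This keeps one row
  per section while preserving the physics.
* **The ICA-2 radius override.** The reported stress at ICA-2 corresponds
  to a 5.5 mm radius (the calibre proximal to the bend), while its own
  section measures 5.0 mm. The tree dialect records this as an explicit
  `stress_radius_mm` override, used for the stress computation only; the
  measured radius stays in `radius_mm`. The override is visible in the data
  file, never silent.

`reproduce_reference()` recomputes every reported quantity from the fixture
and compares at the reported precision (two decimals for stress indices,
whole percent for the cascade percentages). Ten values reproduce exactly:
the 13.4% and 50% single-bend reductions, the 16% (ECA) and 59% (ICA)
remaining-velocity percentages, and the stress indices 0.44 (CCA-1), 0.32
(CCA-3), 1.20 (ECA-1), 0.72 (ECA-3), 0.93 (ICA-1) and 0.62 (ICA-2). Four
reported values do not follow from the stated formula with the recorded
geometry — 1.56 (ECA-2), 7.7 (the straight-part reference at 2 mm radius),
1.37 (ECA-5) and 1.2 (ECA-7); our formula-faithful values are 1.48, 7.96,
1.45 and 1.25. These are permanently flagged `discrepant`. We chose to
surface rather than reconcile them: no choice of convention we could find
reproduces all fourteen numbers simultaneously, and a reproduction report
that silently matched them would misrepresent the model.

## Concordance analysis

The source study's claim is qualitative — plaque was found where the model
predicts low stress. `concordance()` makes it quantitative two ways:

* a 2×2 table of predicted-prone against plaque presence, with sensitivity,
  specificity and the positive predictive value of the prone flag (on the
  fixture: every flagged site has plaque, PPV = 1, and the single
  plaque-free section ECA-6 sits well above the stress baseline);
* a Spearman rank correlation between stress index and plaque-thickness
  midpoint, with a permutation p-value. Thickness values are on-slide
  apparent magnitudes at mixed magnification, so they are treated as
  relative and used only through their ranks; NIL sections have no midpoint
  and are excluded from the ranks (observed absence and
  censored-below-detection cannot be distinguished in the source data),
  but NIL does count as plaque-negative in the 2×2 table.

The permutation null is enumerated exactly over all $n!$ orderings when
$n \le 8$ (the identity is included, so $p > 0$ always), and estimated by
Monte-Carlo with a fixed internal seed and the add-one correction
otherwise. The default alternative is one-sided (`"less"`): the model
predicts a *negative* stress–thickness association. With all-tied input the
coefficient is undefined and reported as `NA` rather than coerced.

## The synthetic generator

Because cadaveric data cannot be resampled, `generate_tree()` and
`generate_plaque()` emulate the fixture's statistical structure. Defaults
are fixed at the fixture's own conditions: 15 segments, bend fraction 6/15,
bifurcation fraction 5/15, bend angles uniform on [0°, 60°] (the fixture's
span), root radius 8.5 mm, taper factor 0.9 per generation with a 1.5 mm
floor — the narrowest vessel in the fixture; below that calibre the
differently regulated microcirculation begins and the model is out of its
regime.

Growth mimics anatomy: a new segment is either a *side branch* arising from
a uniformly chosen existing segment (whose section thereby sits at a branch
point), or a *continuation* of an open distal end, bend or straight. Side
branches attach anywhere along existing vessels, so tree depth grows
logarithmically with size and a 200-segment tree occupies the same stress
range as a 15-segment one — without this property, large synthetic studies
would concentrate almost all sections in a high-stress distal tail the
plaque model never touches.

Plaque follows a hinge with multiplicative lognormal noise: expected
thickness $a \cdot \max(0, s_0 - s)$ at stress index $s$, times
$e^{\varepsilon}$, $\varepsilon \sim N(0, \sigma^2)$, recorded NIL below a
0.5 mm detection floor (half the smallest measured thickness in the
fixture). Defaults $s_0 = 1$, $a = 10$, $\sigma = 0.1$ place the breakpoint
mid-tree and give fixture-like thickness spreads. This generator encodes
exactly one biological assumption — plaque accumulates monotonically with
stress deficit — and is clearly synthetic: passing recovery tests shows the
pipeline is self-consistent, not that real intima obeys a hinge law. Real
data differ in ways the generator does not emulate: measurement error in
radii and angles, spatial correlation of plaque along a vessel, systematic
slide-magnification effects, and inter-subject variation.

`recover_parameters()` inverts the generator by least squares on the log
scale ($\log T = \log a + \log(s_0 - s) + \varepsilon$ is exactly linear in
the noise), minimised by Nelder–Mead from a breakpoint initialised just
above the largest measured stress; percentile bootstrap intervals come from
refitting resampled sections. The fit requires at least 20 measured
sections — below that the breakpoint is barely identified. In our test
suite the estimator recovers $s_0 = 1$ to within a few thousandths at 200
segments and noise 0.1, and its bias shrinks monotonically with the noise
(averaged over 25 replicate seeds, keeping the replicates with enough
measured sections for the fit to be defined — feasibility is part of the
operation's contract, and a handful of degenerate deep-chain topologies per
25 fall below it).

## Numerical choices

* Angles enter through `cospi(theta/180)` for accuracy near round angles;
  radii are converted mm → cm once, in the area computation. Stress equals
  `cum_velocity_factor / area_cm2` exactly, by construction.
* `flow_split()` pins the last daughter's share to `inflow - sum(others)`
  so conservation is exact, not merely within rounding.
* Comparisons against reported values round to the reported precision
  first (2 d.p. for stress indices; CSV output is written at 4 d.p.).
* All randomness (generator, Monte-Carlo permutations, bootstrap) runs in
  `withr::with_seed()` scopes: results are reproducible from stated seeds
  and the caller's RNG stream is never disturbed. The plaque draws use a
  substream derived from the config seed by a multiplicative hash, so tree
  and plaque are independently reproducible from one seed.
* Exact permutation enumeration is capped at $n \le 10$ ($10! = 3.6$M
  coefficient evaluations) to keep worst-case memory and time bounded.

## Problem sizes

The shipped tests profile trees up to 100 segments against a brute-force
path-walking oracle, run 1000 randomized bend-monotonicity trials, and use
200-segment synthetic studies (25 replicate seeds per noise level) for
parameter recovery; the full suite completes in under two minutes on one
CPU. These sizes were chosen to exercise every code path at tight
tolerances while staying desk-scale; the model itself is $O(n)$ per tree
and comfortably handles much larger trees.

## Limitations

* The model is algebraic: it cannot represent oscillatory or secondary
  flow, pulsatility, or viscous losses, all of which matter in real
  carotid hemodynamics.
* The fixture is a single subject; its concordance is evidence of internal
  consistency, not population-level validity. The contralateral (plaque
  free) side carries no recorded geometry and stays outside the
  quantitative analysis.
* Plaque thicknesses are relative, slide-scale magnitudes; only their ranks
  are meaningful, which is why the concordance statistic is a rank
  correlation.
* The four discrepant reported stress values remain discrepant under every
  convention we examined; users comparing against the source tables should
  rely on the `repro_report` flags rather than eyeballing.
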