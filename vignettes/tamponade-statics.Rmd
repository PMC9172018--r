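---
title: "Silicone-oil tamponade statics and saccadic shear: model and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Silicone-oil tamponade statics and saccadic shear: model and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(SiOTamponade)
```

## The problem

After vitrectomy for retinal detachment, silicone oil (SiO) is injected into
the vitreous chamber as a tamponade: a buoyant, highly viscous fluid meant to
keep aqueous humour away from retinal breaks. How much of the retina the oil
actually touches depends on the fill fraction, the patient's posture, and
the shape of the chamber — which in high myopia carries a posterior
staphyloma and, after buckling surgery, an encircling-band indentation.
`SiOTamponade` models this system at desk scale: parametric chamber
geometry, regional segmentation of the wall, a static oil–aqueous
equilibrium solver with per-region contact reporting, saccade kinematics,
and a reduced-order wall-shear summary.

## Geometry

The emmetropic chamber is a sphere of diameter 24 mm truncated by a planar
lens cap (height 3 mm by default). Two radial deformations, both functions
of the pre-deformation polar angle $\psi$ (measured from the anterior pole),
generate the myopic variants:

* **staphyloma** — outward displacement
  $d(\psi) = D\,s\!\left(\frac{\psi-\psi_0}{180^\circ-\psi_0}\right)$ with the
  cubic smoothstep $s(u)=3u^2-2u^3$, depth $D = 3.5$ mm, onset
  $\psi_0 = 140^\circ$. The junction is $C^1$ and the posterior pole moves by
  exactly $D$.
* **cerclage** — inward displacement $c\,e^{-(a/\sigma)^2}$, where $a$ is the
  meridional arc distance from the equator, $c = 1.5$ mm and
  $\sigma = 2$ mm (band width 4 mm).

No published dimensions exist for the lens cap, staphyloma or band indent;
the defaults above are chosen to be anatomically typical (a crystalline-lens
vault into a 24 mm globe, a posterior pouch deep enough to contain the macula,
a 240-style band indent) and are all configurable through
`eyeGeometryParams()`. Results involving the deformed regions should be read
with this uncertainty in mind; the contact quantities reported by the
package are only mildly sensitive to them because the deformations are
small relative to the globe.

The mesh is a latitude/longitude triangulation whose vertex rings are
snapped to the lens rim and to every segmentation boundary (60°, 90°,
160°), so the planar cap shares vertices with the wall (watertight by
construction) and region areas converge at $O(h^2)$. All variants share one
connectivity: deformations move vertices only, which permits face-wise
comparison across geometries. An icosphere would serve equally well; the
ring construction was preferred because it makes the rim and boundary
snapping exact rather than approximate.

## Segmentation

Faces are labelled from their mean pre-deformation $\psi$: lens (cap faces),
pars plana (rim to 60°), pre-equatorial (60–90°), post-equatorial
(90–160°), macula ($\psi \ge 160^\circ$, a 20° cone about the posterior
pole). In the banded variant, faces whose indentation exceeds half the
maximum indent are relabelled `cerclage_band`. Each region splits into
superior/inferior hemifields by the sign of the face-centroid $y$; a
centroid exactly on $y=0$ counts as superior. Labelling on pre-deformation
angles makes it deformation-invariant, so the macula keeps its label inside
the staphyloma. "Retinal surface" denominators exclude the lens faces and
include everything else (pars plana and band); published reports rarely state their denominator, so this choice is explicit and uniform.

## Static equilibrium

Fluid properties: SiO 980 kg/m³ and 1000 mPa·s, aqueous 997 kg/m³ and
1 mPa·s, interfacial tension $\sigma = 0.044$ N/m, static contact angle
16.2° (advancing 21.2°, receding 11.2°). The capillary length
$\sqrt{\sigma/\Delta\rho g} \approx 16$ mm is comparable to the globe
radius, so interfacial tension shapes the bubble at eye scale (Bond number
$\approx 0.55$).

The configuration of the buoyant oil is obtained by minimising

$$E[\alpha] = \sigma A_{ow} + \sigma\cos\theta_w\,A_{wet}
  - \Delta\rho\, g \int_{oil} h\, dV$$

over a voxelised oil indicator $\alpha$ at fixed oil volume, where $A_{ow}$
is the oil–aqueous interface area, $A_{wet}$ the oil-covered wall area and
$h$ height against gravity. The solver is volume-conserving threshold
dynamics: each sweep convolves $\alpha$ with a Gaussian, adds a buoyancy
bias $\frac{s}{2\sqrt{2\pi}}\,h/\ell_c^2$ (this ratio reproduces the
Young–Laplace balance $\kappa + h/\ell_c^2 = \text{const}$ at the fixed
point), and rethresholds at the level that conserves the oil volume
exactly. The iteration order is fixed, so the solver is fully deterministic
— no RNG exists anywhere in the pipeline.

**Which phase wets the retina.** The 16.2° static angle is read as measured
*through the aqueous*: the retina is a hydrophilic surface that remains
coated by an aqueous film, and the oil is effectively non-wetting
(equivalent oil-side angle 163.8°). This reading is the only one consistent
with the reported tamponade behaviour the package reproduces — partial macular
wetting at 80% fill standing, near-zero posterior contact supine, inferior
contact below 40% even at 95% fill; an oil-wetting wall would put every one
of those quantities near its flat-interface value or above. The opposite
convention remains available via `fluidProperties(angleThrough = "oil")`.

**The film wall model.** A subtlety worth stating plainly: the *global*
minimiser of the energy above, for any contact angle short of 180°,
is a pooled configuration in which oil covers every wall not occupied by
the aqueous pool — wall contact at angle $\theta$ is always marginally
cheaper than carrying an oil–aqueous interface of the same area. The
observed tamponade states are instead *film-persistent*: the aqueous
wetting film on the wall does not drain on observational timescales except
where the bubble actively presses it out. The default wall treatment
(`wall = "film"`) therefore keeps a one-voxel aqueous shell on the wall,
imposed as a soft ranking penalty so that pressing can still claim shell
voxels, and accounts the shell at zero physical volume (the film is
micron-scale; charging a voxel-thick layer against the aqueous budget
would distort the phase split by several percent of chamber volume at
working resolutions). A ghost-value contact-angle wall without the shell is
available as `wall = "angle"`.

**Contact observable.** A face is SiO-wetted when the interpolated oil
fraction at depth (film + `probeGap`) beneath its centroid is at least 0.5
(ties wet). `probeGap` = 0.5 mm is the gap-collapse threshold: an aqueous
layer thinner than this counts as squeezed out. It is kept in physical
units so that reported percentages are consistent across grid resolutions;
a probe fixed in voxels would make "contact" a finer-and-finer criterion on
refinement and the percentages would not converge. Contact percentages
shift by roughly ±4 points when `probeGap` moves by ±0.25 mm, which is the
honest resolution limit of this observable — full CFD treatments are subject
to the same near-wall truncation at their own grid scales.

**Pinning and annealing.** Discrete threshold dynamics freezes once the
continuum interface motion per sweep falls below one voxel. The solver
anneals the kernel width over stages (default standard deviations 4, 2.5,
1.5 voxels): wide kernels move the interface quickly through large
rearrangements, narrow ones sharpen the frozen state. Each stage runs to
its own fixed point (zero flips, or interface displacement below 0.25
voxels per 10-sweep window); the narrow-kernel fixed point is the reported
state. Fine grids are warm-started from a converged half-resolution solve,
which typically cuts fine-grid sweeps to a few dozen.

**Degenerate inputs.** `fill = 0` and `fill = 1` bypass the dynamics
(empty/full chamber); zero interfacial tension reduces the solve to the
exact flat-interface ranking, which is also the analytic oracle used in the
tests; ties at the volume threshold are broken by voxel index, which is
what makes reruns byte-identical.

## Saccade kinematics

The saccade is a quintic $\theta(t)=\sum_k c_k t^k$ of amplitude 50° and
duration $T = 0.137$ s, observed for $2T$. The published coefficient table
for this law is internally inconsistent: evaluating its $c_0..c_4$ at $T$
gives $\theta(T) \approx 341^\circ$, not 50°, and the stated equation
includes a $c_5$ the table omits. The default `boundary_condition` mode
therefore keeps the table's initial acceleration ($c_2 = 2.01\times10^4$
deg/s², $c_0=c_1=0$) and solves the linear system
$\theta(T)=50,\ \theta'(T)=0,\ \theta''(T)=0$ for $c_3, c_4, c_5$, which
reproduces the physical saccade exactly; `table2_verbatim` keeps the
published set (with $c_5 = 0$) for transparency and is labelled diagnostic.
The peak angular velocity of the fitted law (~600 deg/s) sits in the
physiologic band for a 50° saccade.

## Reduced-order wall shear

The full moving-mesh two-phase solve is out of scope; the shear module is
an explicit surrogate that keeps the scaling drivers of the published
regional orderings and nothing more. Bulk fluid rotation lags the eye wall
by a rigid-lag law $d\Omega/dt = (\omega-\Omega)/\tau_r$ with
$\tau_r = R^2/(k\nu)$, $k = 10$ (configurable); wall shear per face is

$$\tau = \mu\,|\omega-\Omega|\,r_\perp/\delta(t)\cdot
  e^{-d_{pocket}/\delta}\,(1 + p_{ridge}/\delta),$$

with $\delta(t)=\min(\sqrt{\nu\,\max(t,1\,\text{ms})}, R)$ the Stokes-layer
depth and the geometry factor encoding the sheltering of the staphyloma
recess and the exposure of the band ridge. Faces use the oil properties
when SiO-wetted at the 90%-fill standing equilibrium (the reference shear
scenario) and the aqueous ones otherwise. Outputs are labelled
`reduced_order` and only orderings are meaningful — the staphyloma lowers
macular shear, the band concentrates the global maximum at its indentation
and relieves the pre-equatorial retina. No absolute pascal values should be
quoted from this module.

## What the geometry generator does and does not emulate

The generator reproduces the three idealised morphologies: axisymmetric,
sharp-edged lens plane, smooth axisymmetric staphyloma and band. Real eyes
deviate: staphylomas are rarely axisymmetric or centred on the pole, the
lens is curved, the chamber is not spherical, and the retinal surface is
rough at the scale of the wetting film. Passing tests therefore demonstrate
the mechanics of fill/posture/geometry interaction, not patient-specific
prediction. The same applies to the fluid pair: a single Newtonian
1000 mPa·s oil, no emulsification, no gas.

## Problem sizes and numerical defaults

Unit tests run the solver at 48³–64³, where a case takes a few seconds; the
study-condition sweep (3 geometries × 3 postures × 4 fills) runs at 96³
with half-resolution warm starts, about 10 s per case. Mesh subdivision 5
(~9k faces) keeps geometric discretisation error well under the voxel
error. The 0.25-voxel/10-sweep displacement tolerance, the 2000-sweep cap,
the 0.3 shell ranking penalty and the annealing schedule are all exposed
through the solver options and none is load-bearing for the qualitative
results: halving or doubling them moves contact percentages by under a
point.

## Known limitations

* Contact percentages carry an intrinsic ±(a few) point uncertainty from
  the gap-collapse threshold and the unreported reference geometry
  dimensions.
* The equilibrium is the film-persistent metastable state, by design; true
  long-time drainage (hours) would increase contact beyond it. Conversely,
  states reached by short time-marching from a horizontal initial interface
  retain *more* wall contact than this equilibrium in concave recesses: a
  non-wetting bubble gains no energy by entering the staphyloma pocket
  (spanning its mouth costs less interface than wrapping its wall), so the
  relaxed solution lines the pocket — and the macula inside it — with
  aqueous even in postures where a kinetically limited solve would leave
  the pocket oil-filled. Regional results inside the pocket are therefore
  conservative (lower bounds on contact).
* Contact-angle hysteresis is carried in `FluidProperties` but unused in
  statics; dynamic interface motion during the saccade is not modelled.
* The shear module is a scaling surrogate: regional orderings only.
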