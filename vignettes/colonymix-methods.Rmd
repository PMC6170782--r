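---
title: "Methods: simulating and measuring clonal mixing in adhesive bacterial colonies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and measuring clonal mixing in adhesive bacterial colonies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(colonymix)
```

# The model

`colonymix` simulates a monolayer of rod-shaped bacteria as rigid
two-dimensional capsules (spherocylinders): an axis segment of length
$L$ with hemispherical caps of radius $r$ (default $0.5\,\mu m$; one
simulation length unit is $1\,\mu m$, one time unit is $1\,h$).  Cells
elongate exponentially along their axis, $L \mapsto L\,e^{\mu\,dt}$,
and divide when they reach a noisy threshold length.  All motion is
generated by growth: overlapping capsules repel, and cells move in the
overdamped (inertia-free) regime where velocity is proportional to
force through a viscous drag, $v = F / (\gamma L_{\mathrm{eff}})$ and
$\omega = \tau / (\gamma_r L_{\mathrm{eff}}^3)$ with
$L_{\mathrm{eff}} = L + 2r$ (slender-body scaling of drag with size).

## Division geometry

A dividing cell is bisected into two equally sized daughters that
exactly tile the parent capsule: daughter axis length $L/2 - r$,
centres at $\pm (L + 2r)/4$ along the parent axis, so the facing caps
are tangent.  No material is created or displaced at division -- an
important property both physically (incompressible cells) and for the
ground-truth velocity fields described below.  Daughters inherit
orientation up to a small uniform angular jitter ($\pm 0.5^\circ$ by
default), which seeds the buckling instabilities seen in real
colonies; their growth rate and division length are resampled around
the population means with coefficients of variation of 0.05.  With the
default geometry (birth at $1\,\mu m$, division at $3\,\mu m$ axis
length) one generation takes $\ln 3 / \mu \approx 71$ min at the
default elongation rate, a typical pace for plasmid-carrying strains
on solid media at 37°C; the package's proliferation test verifies that
the population growth rate matches $\ln 2$ per generation.

## Intercellular adhesion

Adhesion is modelled after a self-recognizing surface adhesin that
binds through a protein-protein handshake: both partners must express
it, so the pairwise strength is $k_{\mathrm{pair}} =
\min(a_i, a_j)$ of the two per-cell levels -- a single scalar per
cell, as the protein is distributed uniformly over the cell surface.
The adhesive force acts as a *viscous drag on slippage*: for each
cell-cell contact the relative velocity of the two material points at
the contact is projected on the tangent (perpendicular to the contact
normal), and a force $F = k_{\mathrm{pair}} v_t$ drags each cell along
with its neighbour, applied at the contact points with the
corresponding torques.  Motion along the contact normal (approach or
separation) is *not* damped: adhesion opposes sliding, not detachment,
and a dedicated test verifies that the final normal separation of a
relaxing pair is independent of adhesion strength.

Numerically, the overdamped force balance is implicit in the adhesion
drag (the force depends on the velocity it helps determine).  Within
each relaxation sub-step the pairwise balance $F = k\,v_t(F)$ is
solved exactly, giving an effective coefficient
$k/(1 + k\mu)$ with $\mu$ the summed inverse drags of the pair.  This
is not a cap on the model -- it *is* the linear drag law, resolved
self-consistently -- and it is what makes the scheme stable at strong
adhesion ($k\mu > 1$), where a naive explicit evaluation oscillates.
As $k \to \infty$ contacts become rigid in the tangential direction,
which is how force chains propagate in the chain experiment.

## Constraint relaxation

Each time step is grow → relax → divide.  Relaxation iterates
overdamped sub-steps (default up to 600 of $0.004\,h$) until the worst
capsule overlap falls below `overlap_tol` ($0.01\,\mu m$); contacts
are redetected every sub-step with a uniform spatial grid, keeping the
cost near-linear in cell count.  If the budget is exhausted the state
is accepted (optionally with a warning) -- late in large colonies a
small residual overlap is tolerated rather than stalling the run.
Stability requires $k_{\mathrm{contact}}\,dt_{\mathrm{sub}}\,(1/d_i +
1/d_j) < 1$ for the stiffest pair; the defaults sit at about 0.6.
Degenerate coincident-centre contacts get the deterministic normal
$(1, 0)$.

External forces (used by the chain experiment) are persistent per-cell
forces added into every sub-step; with external forces present the
relaxation always runs its full budget, so it doubles as a time
integrator with `elapsed = iters * dt_sub`.

# The in-silico experiments

* **Microcolony morphology** (`run_microcolony`): one founder grown to
  200 cells; circularity ($4\pi A/P^2$ of the rasterized footprint) is
  recorded.  Rising adhesion suppresses the slippage that lets buckled
  cell files round the outline off, so circularity falls as adhesion
  rises from 0 through 0.05 to 10.
* **Two-domain colonies** (`run_two_domain`): two identical touching
  founders, one green, one red, uniform adhesion among all cells.  The
  interdomain contact ratio -- contacts between unlike labels over all
  contacts -- measures the interaction area between the lineages and
  rises several-fold from adhesion 0 to 5 at a few thousand cells.
* **Chain force propagation** (`run_chain`): ten identical non-growing
  cells side by side, touching along their long sides; antiparallel
  forces on the two end cells, directed along the cells' long axis
  (the force direction is not dictated by the underlying experiment's
  description; this shear geometry produces the lateral displacement
  profile of interest), run until each end cell has slid a fixed
  distance.  Without adhesion the ends slide off and interior cells
  stay put; with adhesion, motion propagates inward, monotonically in
  both adhesion strength and distance from the forced end.

Desk scales: the two-domain sweep in the original study design ran to
50 000 cells; the package defaults to 5 000 and its test suite asserts
the adhesion trend at 2 500 cells over three seeds, where it is
already unambiguous.  The acceptance script simulates 4 000 cells.

# Synthetic time-lapses and ground truth

`render_timelapse` rasterizes snapshot streams into confocal-like
movies: capsule interiors at a per-cell brightness (heritable with a
lognormal jitter at division, emulating cell-to-cell expression
variability and giving the images realistic texture), edge
anti-aliasing at 0.1 µm/px, Gaussian point-spread blur (2 px), and 2%
additive Gaussian noise, at one frame per 10 simulated minutes.

Every frame pair carries a known per-pixel displacement field.  Each
cell's motion over a step is recorded as (centre displacement,
rotation, axial stretch); a pixel is assigned to its nearest cell axis
and moved rigidly with it, with the axial coordinate stretched along
the axis (cap overhang rides with the pole).  Because divisions tile
the parent in place, daughters inherit the parent's displacement
record unchanged.  Truth for a 10-minute frame pair is *composed* from
the per-step mappings -- material points are tracked through every
intermediate snapshot -- which keeps the model exact across divisions
and large rotations; composing at the frame level instead leaves
visible reconstruction error around division waves.

What the generator does **not** emulate: intracellular intensity
structure (cells are flat-shaded), illumination drift, focus drift,
camera shot noise statistics, and any 3-D effects (the monolayer is
strictly planar).  Tests passing on these movies therefore validate
the pipeline's numerics, not its robustness to every real-microscopy
artefact.

# The image pipeline

Segmentation is Gaussian smoothing (2 px) followed by a per-channel
Otsu threshold -- parameter-free and standard.  The interdomain
boundary is the edge set of each domain mask minus the colony outline
(the edge of the hole-filled union, dilated 3 px to avoid rim
leakage), restricted to edge pixels within 3 px of the opposite domain
-- the restriction matters for rasterized colonies, which are slightly
porous between capsules, unlike saturated micrographs.  The result is
thinned to a single-pixel 8-connected skeleton with Guo-Hall thinning
plus a corner-pruning pass (the simpler Zhang-Suen scheme deletes
2-px-wide diagonal lines outright, which is why it is not used).

**Boundary length is a pixel count** -- the convention of the original
measurement -- and that convention is a chessboard metric: a straight
boundary at angle $\theta$ counts $L\max(|\cos\theta|, |\sin\theta|)$
pixels and an ideal digital circle counts $8R/\sqrt 2 \approx 5.66R$,
not $2\pi R$.  The tests assert these analytic predictions exactly
rather than pretending the convention measures Euclidean length.
Normalizing by the equivalent-circle colony radius
($\sqrt{A/\pi}$, robust to outline roughness and shared by the image
and simulation paths) gives the dimensionless mixing measure, which is
scale-invariant within ~2% across a doubling of resolution.

The fractal dimension uses Euclidean distance mapping: with $A(s)$ the
area within distance $s$ of the skeleton, $L(s) = A(s)/(2s+1)$ scales
as $s^{1-D}$; $D$ is one minus the least-squares slope of
$\log L$ vs $\log s$ over a log-spaced grid of integer scales (the
$2s+1$ band width and integer scales make a digital straight line give
exactly $D = 1$).  Defaults: 8 scales from 2 px to a quarter of the
skeleton's half-span, capped by the raster (the distance field is
clipped at borders).  For reference fractals the fit belongs inside
the scaling window -- a 4-iteration Koch curve is genuinely smooth
below its segment length, and measured from the segment length to
span/8 the estimator lands near the analytic $\log 4 / \log 3$, as
does an independent box-counting cross-check.

# The flow pipeline

`estimate_flow` is a pyramidal dense polynomial-expansion estimator:
each frame is locally fitted with a quadratic form over a Gaussian
applicability (via separable moment correlations and the precomputed
basis Gram matrix); equating the expansions of the two frames yields a
per-pixel linear constraint on the displacement, integrated over a
uniform window and solved coarse-to-fine with warping between
iterations.  Defaults (5 levels, 21-px window, 3 iterations, 7-px
expansion with $\sigma = 1.5$) were selected by the same calibration
the package ships: `calibrate_flow` ranks parameter sets by mean
per-pixel error against rendered ground truth,
$100 \cdot \overline{|v_{est}-v_{true}|} \; / \;
(\overline{|v_{true}|} + \varepsilon)$, over frame pairs taken from
the part of the movie where the colony is at the analysis scale (the
final third).  The calibration is deterministic, and a deliberately
degenerate tiny-window set in the default grid serves as a sanity
floor.

A known limitation, documented deliberately: on these fixtures the
calibrated error is far above the few-percent level one might hope
for, because the ground truth contains genuine cell-scale relative
motion (neighbouring capsules slide and rotate by a few tenths of a
micrometre per 10-minute frame) that is both below the integration
window and photometrically nearly invisible (a flat-shaded capsule
sliding along its own axis barely changes the image).  The estimated
field matches the *smooth* component of the truth well -- warping a
frame by the estimate explains the next frame about as well as the
truth itself does -- so downstream vorticity comparisons are
meaningful, but the per-pixel error metric pays for every invisible
degree of freedom.  The error falls with colony size (relative to the
mean speed, which grows with radius), which is why the validation is
run at the largest scale the time budget allows.

Vorticity is the curl by central differences with one-sided fallbacks
at mask borders (pixels without two masked neighbours in a direction
are excluded); RMS vorticity aggregates rotation sign-blindly.
Colonies are compared at equivalent colony area (mask pixel count) by
linear interpolation onto a 20-point log-spaced common grid.  Lineage
advection warps an integer label raster by successive fields using
inverse mapping with nearest-neighbour sampling (labels stay
discrete; forward splatting leaves holes).  Line-integral-convolution
rendering smears seeded white noise along streamlines
(bidirectional unit-speed Euler, 15 px each way).

# Reproducibility

Every runner takes a single integer seed, expanded deterministically
into independent streams for physics, rendering noise and LIC
textures, so modules can be tested in isolation; identical seeds and
parameters give bit-identical snapshot streams, and setting the
adhesion strength to zero reproduces the adhesion-free engine exactly
(a bitwise test guards the claim).  Runs write their fully resolved
configuration to a YAML manifest next to their outputs; snapshots
round-trip losslessly through tab-separated text at 15 significant
digits.
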