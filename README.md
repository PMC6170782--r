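# colonymix

Growing colonies of non-motile, rod-shaped bacteria develop internal
spatial structure purely through physics: cells elongate, push, buckle
and fold, and the boundaries between clonal lineages become
fractal-like. Intercellular adhesion — for example through a
self-recognizing surface adhesin expressed by both partners — changes
this process: it couples neighbouring cells, lets growth-generated
forces propagate further, increases rotational stirring during colony
expansion, and thereby *mixes* lineages, elongating the boundary
between them.

`colonymix` is an R package for studying this mechanism entirely in
silico. It is aimed at researchers in microbial biophysics and
synthetic biology who want a desk-scale, fully seeded sandbox for
adhesion-driven colony structure, plus the image-analysis tools used
to quantify it on either rendered simulations or real two-channel
micrographs.

It provides:

* **An agent-based monolayer simulator.** Cells are rigid 2-D capsules
  (spherocylinders) that grow exponentially along their axis and are
  bisected into equally sized daughters. Motion is overdamped
  (velocity ∝ force through viscous drag) and generated solely by
  growth via contact repulsion. Adhesion of strength *k* acts as a
  viscous drag opposing slippage transverse to each contact normal:
  `F = k · v_t`, with the pairwise strength `min(a_i, a_j)` of the two
  cells' adhesin levels (a handshake bond — one non-expressing partner
  disables it).
* **The three in-silico experiments** that probe the mechanism:
  microcolony morphology vs adhesion (`run_microcolony`), two-domain
  lineage colonies and their interdomain contact ratio
  (`run_two_domain`), and force propagation along a chain of ten
  non-growing cells (`run_chain`).
* **A boundary pipeline** for two-channel images: Otsu segmentation,
  interdomain-boundary skeletonization, normalized boundary length
  (skeleton pixels / colony radius), and fractal dimension by
  Euclidean distance mapping (`analyze_boundary`).
* **A time-lapse pipeline**: dense polynomial-expansion optical flow
  (`estimate_flow`) calibrated against rendered simulations with known
  per-pixel ground truth (`render_timelapse`, `calibrate_flow`),
  vorticity and RMS vorticity, comparison of colonies at equivalent
  area, lineage advection of falsely coloured initial frames, and
  line-integral-convolution rendering.

## A worked example

Force propagation along a chain of ten non-growing cells lying side by
side. Antiparallel forces act on the two end cells along their long
axes; each run stops when the ends have slid 2 µm:

```r
library(colonymix)
tab <- run_chain(n_cells = 10, adhesion_values = c(0, 1, 3),
                 displacement_target = 2)
round(matrix(tab$displacement, nrow = 10,
             dimnames = list(cell = 1:10, adhesion = c(0, 1, 3))), 3)
```

```
    adhesion
cell 0     1     3
  1  2 2.069 2.042
  2  0 0.224 0.363
  3  0 0.024 0.058
  4  0 0.003 0.017
  5  0 0.000 0.005
  6  0 0.000 0.005
  7  0 0.003 0.017
  8  0 0.024 0.058
  9  0 0.224 0.363
  10 2 2.069 2.042
```

Without adhesion the end cells slide off and the interior never moves;
with adhesion, motion propagates inward, increasing with strength and
decaying with distance from the forced ends — adhesion carries force
and motion to neighbours.

The mixing readout on a two-domain colony (two touching founder
cells, green and red, grown to 600 cells at adhesion 5):

```r
res <- run_two_domain(adhesion = 5, n_target = 600, seed = 1)
tail(res$metrics, 3)
```

```
     time n_cells interdomain_ratio colony_radius circularity
 6.250000      82         0.2272727      12.40558          NA
 8.333333     258         0.2671756      21.65610          NA
 9.750000     640         0.2262295      33.04258          NA
```

The interdomain contact ratio — contacts between unlike lineages over
all contacts — sits around 0.23 here; the same colony grown without
adhesion stays near 0.06: adhesion roughly quadruples the interaction
area between the lineages. `plot(res$colony)` draws the colony with
its two domains.

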