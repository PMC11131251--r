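---
title: "Spatio-temporal lineage trees of cellular clones: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatio-temporal lineage trees of cellular clones: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 5)
library(clonetree3d)
```

## The problem

Classical lineage trees and Muller ("jellyfish") plots show *when* cellular
clones arise and how abundant they become, but not *where* in the tissue
they live. Spatial context matters for tumor evolution: cells near vessels
see high drug concentrations and die or adapt, cells in low-drug niches
proliferate freely, and the clones that ultimately repopulate a treated
tumor are often those that happened to sit in protected regions.
`clonetree3d` draws lineage trees in three dimensions -- two tissue axes
plus one scaled time axis -- so each clone's trajectory shows the tissue
niche it occupied while it grew. Branches connect a mother cell's recorded
position at one sampled time point to its (or its daughter's) position at
the next.

Four trees can be drawn for any dataset:

* `tree3d_all()` -- every cell of every clone (the *full forest*);
* `tree3d_alive_all()` -- only lineages with a descendant alive at the end;
* `tree3d_clone()` -- every cell of one selected clone;
* `tree3d_alive_clone()` -- the surviving lineages of one clone.

## Input data model

A dataset is a directory with a `data/` subdirectory holding plain-text
files:

* `cell_history.txt` -- one row per cell:
  `cell_id clone_id mother_id birth_iter end_iter`. `mother_id = 0` marks
  the founder (real ids start at 1); `end_iter = 0` means alive and
  undivided, otherwise it is the iteration of division *or* death -- the
  format conflates the two, and the package classifies a terminated cell as
  divided exactly when it has daughters (`cell_fate()`). Clones are numbered
  from 0.
* `cellID_<k>.txt` / `cellXY_<k>.txt` -- for each saved iteration `k`, the
  ids and x-y coordinates of the cells present, in identical row order.
  That ordering is the only link between id and position, so a row-count
  mismatch is a hard error, not a warning. Empty files are legal: after a
  lethal treatment every cell may be gone.
* `drug.txt` (optional) -- a rectangular matrix of a microenvironmental
  factor over the tissue rectangle, rows along x.

The saved-iteration suffix is the raw simulation iteration at which the
snapshot was taken; a dataset therefore carries a *save stride* (the spacing
of its snapshot indices), which `read_snapshot_series()` infers. Whether a
cell left the computational domain cannot be encoded distinctly from death
in this format; the package records both identically (an `end_iter` with no
daughters).

On write, integer fields round-trip exactly and coordinates are written
with 6 significant digits -- far below cell-diameter scale, and enough that
re-read coordinates are visually identical.

## Tree construction

**Sampling.** Branches are drawn between consecutive *sampled* snapshots:
`tmin, tmin + file_step, ...`, with `tmax` always appended if the stride
does not land on it, so every tree reaches the final time. `file_step` must
be a multiple of the save stride. A large `file_step` skips intermediate
positions and straightens branches; a small one shows the full tortuosity
of each cell's path.

**Time scaling.** The time axis is scaled so all three axes are comparable:
`y = (file_index - tmin) * (xmax - xmin) / (tmax - tmin)`, anchoring
`y(tmin) = 0` and `y(tmax) = xmax - xmin`. When `(tmax - tmin)` is a
multiple of `file_step` this equals `(file_index - tmin)/file_step *
time_step` with `time_step = (xmax - xmin)/N` for `N` sampled intervals; we
chose the index-linear form because it keeps both anchors even when `tmax`
is appended off-stride.

**Branches.** For each sampled pair `(k, k')` and each member cell present
at `k'`, one segment runs from the cell's position at `k` to its position
at `k'`. A daughter born inside the window is not listed at `k`; the lookup
(`position_of()`) walks up mother links until it finds an ancestor present
at `k` and anchors the branch there. For a mutated clone this means the
clone's first segment starts at the mother's position in the parent clone;
we assign that boundary segment to the *daughter* clone, which makes
single-clone plots self-contained. Cells born and dead strictly inside one
sampling window leave no branch, by construction -- this is the expected
consequence of coarse sampling, not data loss.

**Survivor pruning.** `surviving_set()` walks mother links upward from
every cell alive in the final snapshot; the result is exactly the set of
cells with a surviving descendant (or themselves alive). For a single
clone the walk starts from that clone's own surviving leaves, so a clone
whose cells all died prunes to an empty tree even if some of its progeny
survived as *mutated* daughter clones -- the daughter clone's tree owns
those lineages. Pruned trees are always branch-subsets of their full
counterparts, and the all-clone forest is exactly the concatenation of the
single-clone trees; both invariants are property-tested against brute-force
descendant enumeration.

**Degenerate inputs.** A clone with no surviving cells yields an empty
branch set and renders as empty axes (with the backdrop, if requested) --
that picture *is* the result, not an error. Ties for a clone's root (equal
birth iterations) break toward the smallest cell id; in division-complete
histories the root is unique anyway.

## The gradient backdrop

With `is_gradient = 1` the drug matrix is quantized into four equal-width
bands over `[min, max]` (`quantize_field()`): value `v` maps to band
`floor(4 (v - min)/(max - min))`, clipped so `v = max` stays in the top
band; a constant field maps to the single lowest band. Colors are fixed,
lowest to highest: blue, cyan, yellow, red. Equal-width binning was chosen
over quantiles for determinism on spiky fields (a near-point-source field
would otherwise move its thresholds with every saved frame). The plane is
drawn at scaled time 0 -- the `tmin` face -- so the tree grows away from
its environment map; placing it at the `tmax` face would be an equally
defensible convention, and the choice is isolated in
`background_plane()`.

## Rendering

Scenes are drawn with base R's `persp()` projection: tissue x on the plot
x axis, scaled time on the depth axis, tissue y vertical. `theta` and `phi`
set the viewing angles, and re-rendering with new angles rotates the
figure; `export_jpeg()` renders to an off-screen JPEG device, so everything
works headless. Clone colors are deterministic functions of the clone id
(golden-angle-spaced HSV hues; clone 0 is fixed pink), so the same clone
has the same color in every figure of a dataset. Hues of very many clones
eventually pack closely -- with hundreds of clones, neighboring ids remain
distinguishable but distant ids may look similar.

## The bundled tumor simulator

`simulate_tumor()` is a first-class synthetic-data engine that emits
datasets in the exchange format, exercising every tree mode: growth from a
single founder, mutation-born clones, drug-induced extinction of the
sensitive founder clone, and repopulation by resistant survivors.

The model: off-lattice cells in a rectangle (default `[-100, 100]^2`,
matching the scale of the tree routines' examples). Each iteration,

1. the drug field takes one explicit finite-difference step
   (`update_drug()`): five-point diffusion with zero-flux boundaries,
   first-order decay, per-cell uptake at the nearest grid node, and a
   Dirichlet source at each vessel node once the drug is on. The stencil's
   stability bound `D/h^2 <= 0.25` is enforced at construction and at every
   step;
2. cells add the absorbed drug to an accumulated dose; *sensitive* cells
   (the founder clone's lineage) die when the dose passes
   `death_threshold`. Mutated clones are absolutely drug-resistant. All
   cells also die spontaneously with `random_death_prob`;
3. mature cells (age past an individually jittered `division_age`) divide
   if no neighbor sits within `crowding_radius`: the mother's record ends
   and two daughter records begin at her position, displaced to either
   side. Each daughter independently mutates with `p_mut`, founding the
   next unused clone id;
4. cells take a small random step (`motility_step`); cells leaving the
   rectangle are removed (recorded like deaths); overlapping pairs are
   relaxed apart (`resolve_crowding()`).

Snapshots are saved every `save_stride` iterations, including iteration 0.

### Default study conditions

Defaults are one coherent scenario, chosen once: 5,000 iterations with the
drug from iteration 3,000, a ~100-iteration cell cycle, a crowding radius
of 10 (the colony saturates at a few hundred cells in the default
rectangle), 5 vessels, and drug transport (`D = 5`, decay `5e-4`, uptake
`0.01`, threshold `0.1`) calibrated so the injected drug pervades the whole
tissue with a clear vessel-centered gradient and extinguishes the sensitive
founder clone while resistant clones repopulate -- the qualitative regime
the tree routines are designed to display. At `p_mut = 0.005` a run
typically produces a few tens of clones; at `p_mut = 0.05`, several
hundred: the low/high mutation contrast survives the reduced scale. These
sizes keep a full run under half a minute on one CPU; they are a scaled-down
analogue, not a reproduction, of long production simulations.

### What the generator does and does not emulate

It reproduces the *structure* real model output has (binary divisions,
sequentially numbered clones, continuous coordinates, gradient fields,
extinction and repopulation), so green tests certify the pipeline's
mechanics on faithful inputs. It does not attempt pharmacokinetic realism,
cell-cell adhesion, or calibrated kinetic rates, and experimental datasets
bring artifacts it never produces (tracking errors, cells entering the
field of view, missing frames). `validate_dataset()` exists precisely to
triage such external data before drawing.

## Numerical and testing notes

* Crowding uses an exact sweep over x-sorted positions to find all pairs
  closer than the radius; relaxation is a fixed number of symmetric
  half-overlap pushes (coincident cells separate along a random
  direction), i.e. soft repulsion rather than a strict packing solver.
* The diffusion stencil is mass-conserving by construction with zero-flux
  boundaries; tests require conservation to 1e-9 relative over 50 steps,
  and compare the steady single-vessel profile on the model grid against an
  independently stepped half-spacing grid (shape agreement within 10%
  after normalizing the source amplitude, radii 15-60).
* Tree construction contains no randomness: identical inputs give
  identical branch sets.
* Test problem sizes (histories up to ~200 cells, 200 random replicates for
  the pruning oracle, five simulator seeds per mutation rate) were chosen
  as the smallest sizes at which the checked properties are exercised in
  every regime; they run in a few minutes on one CPU.

## Known limitations

* Positions between saved snapshots are never interpolated; what you see at
  `file_step = s` is the polyline through every s-th recorded position.
* The history format cannot distinguish death from domain exit, so neither
  can any consumer of it.
* One figure per call; overlaying several selected clones in one figure is
  not supported.
* The JPEG export is the only file output; the scene object can of course
  be re-plotted on any R device.
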