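# clonetree3d

3D spatio-temporal lineage trees of cellular clones.

Tumors are spatially heterogeneous: a clone's fate depends on where its
cells sit — next to a vessel in a high-drug region, or in a protected
low-drug niche. Classical lineage trees and Muller plots show *when* clones
arise but not *where*. `clonetree3d` draws lineage trees in three
dimensions — tissue x, scaled time, tissue y — so each branch connects a
mother cell's recorded position at one time point to its (or its
daughter's) position at the next, and each clone's tree shows the tissue
niche it occupied while it grew. It is intended for output of agent-based
tumor-evolution simulations, and applies equally to tracked experimental
colonies recorded in the same format.

For a dataset directory with per-iteration cell snapshots
(`cellID_<k>.txt` / `cellXY_<k>.txt`), a genealogy table
(`cell_history.txt`: `cell_id clone_id mother_id birth_iter end_iter`) and
an optional microenvironment matrix (`drug.txt`), four trees can be drawn:

| routine | cells | clones |
|---|---|---|
| `tree3d_all()` | all ever recorded | all |
| `tree3d_alive_all()` | only lineages surviving at `tmax` | all |
| `tree3d_clone()` | all ever recorded | one |
| `tree3d_alive_clone()` | only surviving lineages | one |

Survivor pruning (`surviving_set()`) walks mother links back from every
cell alive at the final snapshot; per-clone trees trace back from that
clone's own leaves, so a clone wiped out by treatment prunes to an empty
tree. With `is_gradient = 1` the drug matrix is quantized into four
equal-width bands (blue–cyan–yellow–red, lowest to highest) and drawn as a
plane under the tree. The time axis is scaled so `y(tmin) = 0` and
`y(tmax) = xmax − xmin`, keeping all three axes comparable.

The package also bundles an off-lattice agent-based tumor simulator
(`simulate_tumor()`) that emits conforming datasets: proliferation gated by
crowding, random death, mutation-born drug-resistant clones
(probability `p_mut` per daughter), point vessels feeding an explicit
reaction–diffusion drug field, and dose-accumulation killing of sensitive
cells. See the methods vignette
(`vignettes/clonetree3d-methods.Rmd`) for the model and every default.

## Worked example

Simulate a treated tumor, write the dataset, and draw the founder clone:

```r
library(clonetree3d)

out <- simulate_tumor(sim_params(p_mut = 0.01, seed = 11))
out
#> <sim_output> 10819 cells total, 134 clones, 450 alive at iteration 5000

write_dataset(out$history, out$series, out$drug, "demo")

res <- tree3d_clone("demo", clone_num = 0, is_gradient = TRUE,
                    xmin = -100, xmax = 100, ymin = -100, ymax = 100,
                    tmin = 0, tmax = 5000, file_step = 250, to_print = TRUE)
res$branches
#> <branch_set> 4096 branches, mode=full, scope=single, clones: 0

resa <- tree3d_alive_clone("demo", clone_num = 0, is_gradient = TRUE,
                    xmin = -100, xmax = 100, ymin = -100, ymax = 100,
                    tmin = 0, tmax = 5000, file_step = 250, to_print = TRUE)
resa$branches
#> <branch_set> 0 branches, mode=alive, scope=single, clones:
```

The founder clone's full tree has 4096 branches — it grew for 3000
iterations before the drug arrived — but its survivor-pruned tree is
empty: every sensitive cell died, and the tissue was repopulated by
mutated, drug-resistant clones (here 134 clones arose in total). With
`to_print = TRUE` each call also writes a JPEG
(`demo/tree_clone_0.jpg`, `demo/tree_alive_clone_0.jpg`); `theta`/`phi`
set the viewing angles of the projection.

The same operations are available from a shell through the installed
script:

```sh
clonetree3d simulate --out demo --seed 11
clonetree3d clone --path-data demo --clone-num 0 --gradient --print \
  --xmin -100 --xmax 100 --ymin -100 --ymax 100 \
  --tmin 0 --tmax 5000 --file-step 250
clonetree3d validate --path-data demo --xmin -100 --xmax 100 \
  --ymin -100 --ymax 100 --tmin 0 --tmax 5000 --file-step 250
```

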