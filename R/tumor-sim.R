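#' Parameters of the agent-based tumor-evolution simulator
#'
#' The simulator grows a colony of off-lattice cells in a rectangular tissue
#' patch with point vessels. Cells age, divide when mature and uncrowded,
#' wander slightly, die at random, and their daughters mutate with
#' probability \code{p_mut}, each mutation founding a new, drug-resistant
#' clone. From \code{drug_start} on, a drug diffuses out of the vessels
#' (explicit finite-difference reaction-diffusion with decay and per-cell
#' uptake); sensitive cells (the founder clone's lineage) die once their
#' accumulated dose exceeds \code{death_threshold}.
#'
#' @param domain tissue rectangle \code{c(xmin, xmax, ymin, ymax)}.
#' @param n_vessels number of point vessels; positions are drawn
#'   non-uniformly inside the domain from the run's RNG unless
#'   \code{vessel_xy} is given.
#' @param vessel_xy optional n x 2 matrix of vessel coordinates.
#' @param p_mut mutation probability per daughter cell at division.
#' @param drug_start iteration at which the drug is switched on.
#' @param n_iters total simulation iterations.
#' @param save_stride iterations between saved snapshots (must divide
#'   \code{n_iters}).
#' @param diffusion_coeff drug diffusion coefficient (tissue units^2 per
#'   iteration); the explicit stencil requires
#'   \code{diffusion_coeff / h^2 <= 0.25} for grid spacing \code{h}.
#' @param decay_rate first-order drug decay per iteration.
#' @param uptake_rate fraction of the local drug a cell absorbs per
#'   iteration (absorbed drug is removed from the field and added to the
#'   cell's accumulated dose).
#' @param death_threshold accumulated dose that kills a sensitive cell.
#' @param division_age mean cell-cycle length in iterations (each cell's own
#'   threshold is jittered uniformly by +/-20\%).
#' @param crowding_radius minimum free distance: cells with a neighbor
#'   closer than this cannot divide, and overlapping pairs are pushed apart.
#' @param random_death_prob spontaneous death probability per iteration.
#' @param motility_step standard deviation of the random displacement per
#'   iteration; cells wandering outside the domain are removed.
#' @param grid_n drug-grid nodes per axis.
#' @param drug_source vessel concentration (Dirichlet value at vessel nodes
#'   while the drug is on).
#' @param seed RNG seed; a run is fully reproducible from its parameters.
#' @return A validated list of class \code{sim_params}.
#' @export
sim_params <- function(domain = c(-100, 100, -100, 100),
                       n_vessels = 5,
                       vessel_xy = NULL,
                       p_mut = 0.005,
                       drug_start = 3000,
                       n_iters = 5000,
                       save_stride = 50,
                       diffusion_coeff = 5,
                       decay_rate = 5e-4,
                       uptake_rate = 0.01,
                       death_threshold = 0.1,
                       division_age = 100,
                       crowding_radius = 10,
                       random_death_prob = 2e-4,
                       motility_step = 0.2,
                       grid_n = 41,
                       drug_source = 1,
                       seed = 1) {
  p <- list(domain = as.numeric(domain), n_vessels = as.integer(n_vessels),
            vessel_xy = vessel_xy, p_mut = p_mut,
            drug_start = as.integer(drug_start), n_iters = as.integer(n_iters),
            save_stride = as.integer(save_stride),
            diffusion_coeff = diffusion_coeff, decay_rate = decay_rate,
            uptake_rate = uptake_rate, death_threshold = death_threshold,
            division_age = division_age, crowding_radius = crowding_radius,
            random_death_prob = random_death_prob,
            motility_step = motility_step, grid_n = as.integer(grid_n),
            drug_source = drug_source, seed = as.integer(seed))
  if (length(p$domain) != 4 || p$domain[2] <= p$domain[1] ||
      p$domain[4] <= p$domain[3])
    stop("domain must be c(xmin, xmax, ymin, ymax)")
  for (nm in c("p_mut", "random_death_prob", "uptake_rate"))
    if (p[[nm]] < 0 || p[[nm]] > 1) stop(nm, " must be in [0, 1]")
  if (p$n_iters < 1) stop("n_iters must be >= 1")
  if (p$save_stride < 1 || p$n_iters %% p$save_stride != 0)
    stop("save_stride must divide n_iters")
  if (p$decay_rate < 0 || p$decay_rate >= 1) stop("decay_rate must be in [0, 1)")
  if (p$death_threshold < 0) stop("death_threshold must be >= 0")
  if (p$crowding_radius <= 0) stop("crowding_radius must be > 0")
  if (p$division_age <= 0) stop("division_age must be > 0")
  h <- (p$domain[2] - p$domain[1]) / (p$grid_n - 1)
  if (p$diffusion_coeff / h^2 > 0.25)
    stop(sprintf("explicit diffusion unstable: D/h^2 = %.3f > 0.25 (D = %g, h = %g)",
                 p$diffusion_coeff / h^2, p$diffusion_coeff, h))
  class(p) <- "sim_params"
  p
}

#' Read simulator parameters from a plain-text file
#'
#' The file uses Debian-control ("key: value") syntax, one parameter per
#' line, with the field names of \code{\link{sim_params}}; unknown keys are
#' an error, omitted keys take their defaults. \code{domain} and
#' \code{vessel_xy} are comma-separated number lists (vessel coordinates
#' x1,y1,x2,y2,...).
#'
#' @param path parameter file.
#' @param ... overrides applied after the file (e.g. \code{seed}).
#' @return A \code{\link{sim_params}}.
#' @export
read_sim_params <- function(path, ...) {
  dcf <- read.dcf(path)
  if (!nrow(dcf)) stop("empty simulator params file: ", path)
  vals <- as.list(dcf[1, ])
  known <- names(formals(sim_params))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown simulator parameter(s): ",
                        paste(bad, collapse = ", "))
  vals <- lapply(vals, function(v) as.numeric(strsplit(v, ",")[[1]]))
  if (!is.null(vals$vessel_xy))
    vals$vessel_xy <- matrix(vals$vessel_xy, ncol = 2, byrow = TRUE)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(sim_params, vals)
}

# Nearest-neighbor candidate pairs within `radius`, via a sweep over
# x-sorted positions (exact: every returned pair has distance < radius).
close_pairs <- function(pos, radius) {
  n <- nrow(pos)
  if (n < 2) return(matrix(integer(0), 0, 2))
  o <- order(pos[, 1])
  x <- pos[o, 1]; y <- pos[o, 2]
  ii <- integer(0); jj <- integer(0)
  d <- 1L
  while (d < n) {
    i <- seq_len(n - d); j <- i + d
    keep <- (x[j] - x[i]) < radius
    if (!any(keep)) break   # min x-gap is non-decreasing in the offset
    i <- i[keep]; j <- j[keep]
    dy <- y[j] - y[i]
    hit <- (x[j] - x[i])^2 + dy * dy < radius^2
    ii <- c(ii, i[hit]); jj <- c(jj, j[hit])
    d <- d + 1L
  }
  cbind(o[ii], o[jj])
}

#' Relax cell crowding by symmetric pairwise repulsion
#'
#' Every pair of cells closer than \code{radius} is pushed apart along the
#' line joining them, each cell moving half the overlap; coincident cells
#' separate along a random direction. The pass is iterated a fixed small
#' number of times (displacements from multiple neighbors add up), which
#' relaxes most overlaps without solving for a strict packing.
#'
#' @param pos n x 2 matrix of cell positions.
#' @param radius minimum separation (the crowding radius).
#' @param n_steps relaxation passes.
#' @return The updated position matrix.
#' @export
resolve_crowding <- function(pos, radius, n_steps = 5) {
  pos <- matrix(as.numeric(pos), ncol = 2)
  for (step in seq_len(n_steps)) {
    pr <- close_pairs(pos, radius)
    if (!nrow(pr)) break
    dx <- pos[pr[, 2], 1] - pos[pr[, 1], 1]
    dy <- pos[pr[, 2], 2] - pos[pr[, 1], 2]
    d <- sqrt(dx * dx + dy * dy)
    zero <- d < 1e-12
    if (any(zero)) {
      ang <- stats::runif(sum(zero), 0, 2 * pi)
      dx[zero] <- cos(ang) * 1e-6
      dy[zero] <- sin(ang) * 1e-6
      d[zero] <- 1e-6
    }
    push <- (radius - d) / 2
    ux <- dx / d * push; uy <- dy / d * push
    # accumulate displacements per cell (a cell may be in several pairs)
    ddx <- ddy <- numeric(nrow(pos))
    agg <- function(v, idx) {
      t <- tapply(v, idx, sum)
      out <- numeric(nrow(pos)); out[as.integer(names(t))] <- t; out
    }
    ddx <- agg(-ux, pr[, 1]) + agg(ux, pr[, 2])
    ddy <- agg(-uy, pr[, 1]) + agg(uy, pr[, 2])
    pos[, 1] <- pos[, 1] + ddx
    pos[, 2] <- pos[, 2] + ddy
  }
  pos
}

#' One explicit reaction-diffusion step of the drug field
#'
#' Updates the field by one iteration: five-point-stencil diffusion with
#' zero-flux boundaries (mass-conserving), first-order decay, per-cell
#' uptake at the nearest grid node, and a Dirichlet source at vessel nodes.
#' With no vessels, decay or uptake the total mass is conserved exactly.
#' The stability bound \code{D/h^2 <= 0.25} is checked, and any non-finite
#' value after the update is an error naming that bound.
#'
#' @param field a \code{\link{drug_field}} on a regular grid.
#' @param cells n x 2 matrix of cell positions (may be empty); each cell
#'   absorbs \code{uptake_rate} of the drug at its nearest node per step
#'   (co-located cells share the node's supply).
#' @param vessels v x 2 matrix of vessel positions (may be empty); vessel
#'   nodes are reset to \code{drug_source} after the step.
#' @param params a \code{\link{sim_params}} (supplies
#'   \code{diffusion_coeff}, \code{decay_rate}, \code{uptake_rate},
#'   \code{drug_source}).
#' @return List with the updated \code{field} and \code{dose}: the amount
#'   absorbed by each cell this step.
#' @export
update_drug <- function(field, cells, vessels, params) {
  f <- field$values
  nr <- nrow(f); nc <- ncol(f)
  ex <- field$extent
  h <- (ex[2] - ex[1]) / (nr - 1)
  alpha <- params$diffusion_coeff / h^2
  if (alpha > 0.25)
    stop(sprintf("explicit diffusion unstable: D/h^2 = %.3f exceeds the CFL bound 0.25", alpha))
  up <- f[c(1, seq_len(nr - 1)), ]
  dn <- f[c(seq_len(nr - 1) + 1, nr), ]
  lf <- f[, c(1, seq_len(nc - 1))]
  rt <- f[, c(seq_len(nc - 1) + 1, nc)]
  f <- f + alpha * (up + dn + lf + rt - 4 * f)
  f <- f * (1 - params$decay_rate)

  dose <- numeric(if (is.null(cells)) 0 else nrow(cells))
  if (length(dose) && params$uptake_rate > 0) {
    ix <- pmin(pmax(round((cells[, 1] - ex[1]) / h) + 1L, 1L), nr)
    iy <- pmin(pmax(round((cells[, 2] - ex[3]) / h) + 1L, 1L), nc)
    node <- (iy - 1L) * nr + ix
    cnt <- tabulate(node, nbins = nr * nc)
    occupied <- which(cnt > 0)
    # each of m co-located cells takes an equal share of the fraction
    # 1 - (1 - uptake_rate)^m removed from its node
    removed <- f[occupied] * (1 - (1 - params$uptake_rate)^cnt[occupied])
    share <- removed / cnt[occupied]
    dose <- share[match(node, occupied)]
    f[occupied] <- f[occupied] - removed
  }
  f[f < 0] <- 0
  if (!is.null(vessels) && nrow(vessels)) {
    ix <- pmin(pmax(round((vessels[, 1] - ex[1]) / h) + 1L, 1L), nr)
    iy <- pmin(pmax(round((vessels[, 2] - ex[3]) / h) + 1L, 1L), nc)
    f[(iy - 1L) * nr + ix] <- params$drug_source
  }
  if (!all(is.finite(f)))
    stop("drug field became non-finite; the explicit stencil requires D/h^2 <= 0.25")
  list(field = drug_field(f, ex), dose = dose)
}

#' Simulate tumor growth, drug response and clonal evolution
#'
#' Runs the off-lattice agent-based model from a single founder cell (clone
#' 0) at the domain center. Each iteration the drug field is updated (once
#' the drug is on), cells accumulate dose and sensitive cells die past the
#' dose threshold, cells die at random, mature uncrowded cells divide into
#' two daughters placed beside the mother (the mother's record ends --
#' division is two new records), each daughter mutates with \code{p_mut}
#' into a new drug-resistant clone, cells wander and those leaving the
#' domain are removed, and overlaps are relaxed. Snapshots are saved every
#' \code{save_stride} iterations (including iteration 0), so saved file
#' indices run 0, stride, ..., n_iters.
#'
#' @param params a \code{\link{sim_params}}.
#' @return An object of class \code{sim_output}: list with \code{history}
#'   (a \code{\link{cell_history}}), \code{series}
#'   (a \code{\link{snapshot_series}}), \code{drug} (the final
#'   \code{\link{drug_field}}), \code{vessel_xy}, \code{clone_count} and
#'   \code{params}.
#' @export
simulate_tumor <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  ex <- params$domain
  vessels <- params$vessel_xy
  if (is.null(vessels)) {
    # non-uniform layout: cluster-perturbed draws in the inner 80% of the domain
    cx <- stats::runif(params$n_vessels, ex[1] + 0.1 * (ex[2] - ex[1]),
                       ex[2] - 0.1 * (ex[2] - ex[1]))
    cy <- stats::runif(params$n_vessels, ex[3] + 0.1 * (ex[4] - ex[3]),
                       ex[4] - 0.1 * (ex[4] - ex[3]))
    vessels <- cbind(cx, cy)
  }
  field <- drug_field(matrix(0, params$grid_n, params$grid_n), ex)

  # history columns, indexed by cell id
  hclone <- 0L; hmother <- 0L; hbirth <- 0L; hend <- 0L
  n_cells <- 1L
  max_clone <- 0L

  # active-cell state
  act_id <- 1L
  pos <- matrix(c(mean(ex[1:2]), mean(ex[3:4])), 1, 2)
  dose <- 0
  div_at <- params$division_age * stats::runif(1, 0.8, 1.2)  # absolute iter of next division

  snaps <- list(snapshot(0L, act_id, pos))

  for (t in seq_len(params$n_iters)) {
    n <- length(act_id)

    # drug transport and uptake
    if (t >= params$drug_start && n > 0) {
      upd <- update_drug(field, pos, vessels, params)
      field <- upd$field
      dose <- dose + upd$dose
    } else if (t >= params$drug_start) {
      upd <- update_drug(field, NULL, vessels, params)
      field <- upd$field
    }

    if (n > 0) {
      # deaths: drug (sensitive = founder clone lineage) and random
      resistant <- hclone[act_id] > 0L
      dead <- (!resistant & dose > params$death_threshold) |
        (stats::runif(n) < params$random_death_prob)
      if (any(dead)) {
        hend[act_id[dead]] <- t
        act_id <- act_id[!dead]; pos <- pos[!dead, , drop = FALSE]
        dose <- dose[!dead]; div_at <- div_at[!dead]
        n <- length(act_id)
      }
    }

    if (n > 0) {
      # divisions: mature and uncrowded
      blocked <- logical(n)
      pr <- close_pairs(pos, params$crowding_radius)
      if (nrow(pr)) blocked[unique(c(pr[, 1], pr[, 2]))] <- TRUE
      dividing <- which(t >= div_at & !blocked)
      if (length(dividing)) {
        for (w in dividing) {
          mother <- act_id[w]
          hend[mother] <- t
          ang <- stats::runif(1, 0, 2 * pi)
          off <- 0.3 * params$crowding_radius * c(cos(ang), sin(ang))
          for (s in c(1, -1)) {
            n_cells <- n_cells + 1L
            mut <- stats::runif(1) < params$p_mut
            if (mut) max_clone <- max_clone + 1L
            hclone[n_cells] <- if (mut) max_clone else hclone[mother]
            hmother[n_cells] <- mother
            hbirth[n_cells] <- t
            hend[n_cells] <- 0L
            act_id <- c(act_id, n_cells)
            pos <- rbind(pos, pos[w, ] + s * off)
            dose <- c(dose, 0)
            div_at <- c(div_at, t + params$division_age * stats::runif(1, 0.8, 1.2))
          }
        }
        keep <- setdiff(seq_along(act_id), dividing)
        act_id <- act_id[keep]; pos <- pos[keep, , drop = FALSE]
        dose <- dose[keep]; div_at <- div_at[keep]
        n <- length(act_id)
      }
    }

    if (n > 0) {
      # motility and domain exit
      pos <- pos + matrix(stats::rnorm(2 * n, 0, params$motility_step), n, 2)
      pos <- resolve_crowding(pos, params$crowding_radius, n_steps = 1)
      out <- pos[, 1] < ex[1] | pos[, 1] > ex[2] |
        pos[, 2] < ex[3] | pos[, 2] > ex[4]
      if (any(out)) {
        hend[act_id[out]] <- t
        act_id <- act_id[!out]; pos <- pos[!out, , drop = FALSE]
        dose <- dose[!out]; div_at <- div_at[!out]
      }
    }

    if (t %% params$save_stride == 0)
      snaps[[length(snaps) + 1]] <- snapshot(t, act_id, pos)
  }

  history <- cell_history(seq_len(n_cells), hclone, hmother, hbirth, hend)
  structure(list(history = history,
                 series = snapshot_series(snaps, stride = params$save_stride),
                 drug = field, vessel_xy = vessels,
                 clone_count = length(unique(hclone)),
                 params = params),
            class = "sim_output")
}

#' @export
print.sim_output <- function(x, ...) {
  final <- x$series[[length(x$series)]]
  cat(sprintf("<sim_output> %d cells total, %d clones, %d alive at iteration %d\n",
              nrow(x$history), x$clone_count, length(final$ids),
              final$file_index))
  invisible(x)
}

#' Default configuration for drawing a simulated dataset
#'
#' @param out a \code{sim_output}.
#' @param path_data where the dataset was (or will be) written.
#' @param file_step sampling stride for drawing (defaults to 5 save strides).
#' @param ... further \code{\link{tree_config}} arguments.
#' @return A \code{\link{tree_config}} matching the simulation's domain and
#'   time range.
#' @export
sim_tree_config <- function(out, path_data = ".", file_step = NULL, ...) {
  p <- out$params
  tree_config(path_data,
              xmin = p$domain[1], xmax = p$domain[2],
              ymin = p$domain[3], ymax = p$domain[4],
              tmin = 0, tmax = p$n_iters,
              file_step = if (is.null(file_step)) 5L * p$save_stride else file_step,
              ...)
}
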