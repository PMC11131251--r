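# Shared test helpers: random dataset generation and brute-force oracles.

# Random binary-division history: starting from one founder, repeatedly pick
# an alive cell to divide (daughters may found new clones) or to die, at
# strictly increasing iterations. Returns a cell_history.
random_history <- function(n_events = 30, p_new_clone = 0.2, p_death = 0.25) {
  cell_id <- 1L; clone_id <- 0L; mother_id <- 0L
  birth <- 0L; end <- 0L
  alive <- 1L
  max_clone <- 0L
  n <- 1L
  for (t in seq_len(n_events)) {
    if (length(alive) == 0) break
    who <- if (length(alive) == 1) alive else sample(alive, 1)
    if (stats::runif(1) < p_death) {
      end[who] <- t
      alive <- setdiff(alive, who)
    } else {
      end[who] <- t
      for (k in 1:2) {
        n <- n + 1L
        new_clone <- stats::runif(1) < p_new_clone
        if (new_clone) max_clone <- max_clone + 1L
        cell_id[n] <- n
        clone_id[n] <- if (new_clone) max_clone else clone_id[who]
        mother_id[n] <- who
        birth[n] <- t
        end[n] <- 0L
        alive <- c(alive, n)
      }
      alive <- setdiff(alive, who)
    }
  }
  cell_history(cell_id, clone_id, mother_id, birth, end)
}

# A snapshot series consistent with a history: cells wander by a small
# random walk from their mother's last position; snapshots at every
# iteration 0..tmax (stride 1).
random_series <- function(history, tmax = max(c(history$birth_iter,
                                                history$end_iter)) + 1) {
  pos <- matrix(NA_real_, nrow(history), 2)
  pos[1, ] <- c(0, 0)
  ord <- order(history$birth_iter, history$cell_id)
  for (i in ord) {
    if (history$mother_id[i] != 0) {
      m <- match(history$mother_id[i], history$cell_id)
      pos[i, ] <- pos[m, ] + stats::rnorm(2, 0, 0.5)
    }
  }
  snaps <- lapply(0:tmax, function(k) {
    present <- which(history$birth_iter <= k &
                       (history$end_iter == 0 | history$end_iter > k))
    drift <- matrix(stats::rnorm(2 * length(present), 0, 0.2),
                    ncol = 2)
    snapshot(k, history$cell_id[present], pos[present, , drop = FALSE] + drift)
  })
  snapshot_series(snaps, stride = 1)
}

random_tree_config <- function(tmax, file_step = 1) {
  tree_config(".", xmin = -20, xmax = 20, ymin = -20, ymax = 20,
              tmin = 0, tmax = tmax, file_step = file_step)
}

# Brute-force pruning oracle: a cell survives iff its descendant set
# (computed by recursive enumeration) intersects the alive set, or it is
# itself alive. For single-clone scope the relevant leaves are the clone's
# own alive cells (a clone id is never re-entered along a lineage, so this
# matches the within-clone trace-back exactly), and the result is the
# clone's members.
brute_force_surviving <- function(history, alive_ids, clone_id = NULL) {
  if (!is.null(clone_id)) {
    alive_ids <- alive_ids[history$clone_id[match(alive_ids, history$cell_id)] ==
                             clone_id]
  }
  descendants <- function(id) {
    kids <- children_of(history, id)
    if (!length(kids)) return(integer(0))
    c(kids, unlist(lapply(kids, descendants)))
  }
  surv <- history$cell_id[vapply(history$cell_id, function(id) {
    id %in% alive_ids || length(intersect(descendants(id), alive_ids)) > 0
  }, logical(1))]
  if (!is.null(clone_id))
    surv <- surv[history$clone_id[match(surv, history$cell_id)] == clone_id]
  sort(surv)
}

# Canonical ordering for comparing branch sets as multisets (extra
# branch_set attributes are dropped so plain data frames compare equal).
sort_branches <- function(bs) {
  df <- data.frame(clone_id = bs$clone_id, x1 = bs$x1, y1 = bs$y1,
                   z1 = bs$z1, x2 = bs$x2, y2 = bs$y2, z2 = bs$z2)
  df <- df[do.call(order, df), , drop = FALSE]
  rownames(df) <- NULL
  df
}
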