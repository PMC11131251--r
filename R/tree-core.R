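#' Saved file indices sampled for drawing
#'
#' Branches are drawn between consecutive sampled snapshots. Sampling starts
#' at \code{tmin} and steps by \code{file_step}; the final index \code{tmax}
#' is always included, appended if the stride does not land on it exactly,
#' so the tree always reaches the last recorded time.
#'
#' @param tmin,tmax first and last saved iteration to draw.
#' @param file_step sampling stride (a positive multiple of the dataset's
#'   save stride).
#' @param stride the dataset's save stride.
#' @return Increasing integer vector of file indices.
#' @export
sampled_indices <- function(tmin, tmax, file_step, stride = 1L) {
  if (file_step < 1) stop("file_step must be >= 1")
  if (stride < 1) stop("stride must be >= 1")
  if (file_step %% stride != 0)
    stop(sprintf("file_step (%d) must be a multiple of the dataset save stride (%d)",
                 file_step, stride))
  if (tmax <= tmin) stop("tmax must be > tmin")
  s <- seq(as.integer(tmin), as.integer(tmax), by = as.integer(file_step))
  if (s[length(s)] != tmax) s <- c(s, as.integer(tmax))
  s
}

#' Time-axis scale of a tree
#'
#' The time axis is scaled so that the drawn tree spans exactly the x extent
#' of the tissue rectangle, giving all three axes comparable scale:
#' \code{y(tmin) = 0} and \code{y(tmax) = xmax - xmin}. \code{time_step} is
#' the y spacing between two sampled snapshots \code{file_step} apart.
#'
#' @param config a \code{\link{tree_config}}.
#' @return A list with \code{time_step} and \code{y_max} (the y of tmax).
#' @export
time_scale <- function(config) {
  span <- config$xmax - config$xmin
  list(time_step = config$file_step * span / (config$tmax - config$tmin),
       y_max = span)
}

#' Map a saved iteration to its scaled time-axis coordinate
#'
#' Linear in the file index: \code{(file_index - tmin) * (xmax - xmin) /
#' (tmax - tmin)}, i.e. \code{(file_index - tmin)/file_step * time_step}.
#'
#' @param file_index saved iteration(s), in \code{[tmin, tmax]}.
#' @param config a \code{\link{tree_config}}.
#' @return Numeric y coordinate(s).
#' @export
time_to_y <- function(file_index, config) {
  (file_index - config$tmin) * (config$xmax - config$xmin) /
    (config$tmax - config$tmin)
}

#' Root cell of a clone
#'
#' The clone root is the clone's first cell: its founding mutated daughter
#' (whose mother belongs to a different clone) or, for the initial clone,
#' the founder cell itself. Ties on birth iteration are broken by the
#' smallest cell id.
#'
#' @param history a \code{\link{cell_history}}.
#' @param clone_id the clone to look up.
#' @return The root's cell id.
#' @export
clone_root <- function(history, clone_id) {
  members <- history[history$clone_id == clone_id, , drop = FALSE]
  if (!nrow(members)) stop("no cells of clone ", clone_id, " in history")
  mrow <- match(members$mother_id, history$cell_id)
  entry <- members$mother_id == 0 | history$clone_id[mrow] != clone_id
  entry[is.na(entry)] <- TRUE
  cand <- members[entry, , drop = FALSE]
  if (!nrow(cand)) stop("clone ", clone_id, " has no entry cell (cyclic history?)")
  cand <- cand[order(cand$birth_iter, cand$cell_id), , drop = FALSE]
  cand$cell_id[1]
}

#' Position of a cell (or its nearest recorded ancestor) at a snapshot
#'
#' Looks a cell up in the snapshot at \code{file_index}. If the cell is not
#' listed and was not yet born there (\code{birth_iter >= file_index}), the
#' lookup falls back to its nearest ancestor present at that snapshot --
#' this is how a daughter born between two sampled snapshots gets its branch
#' anchored at its mother's position. A cell that was born before the
#' snapshot but is not listed is dead or has left the domain: no position.
#'
#' @param series a \code{\link{snapshot_series}}.
#' @param history a \code{\link{cell_history}}.
#' @param cell_id the cell to locate.
#' @param file_index a saved iteration.
#' @return Numeric \code{c(x, y)}, or NULL if neither the cell nor any
#'   ancestor is present.
#' @export
position_of <- function(series, history, cell_id, file_index) {
  snap <- get_snapshot(series, file_index)
  id <- cell_id
  repeat {
    i <- match(id, snap$ids)
    if (!is.na(i)) return(snap$xy[i, ])
    row <- match(id, history$cell_id)
    if (is.na(row)) stop("unknown cell id ", id)
    if (history$birth_iter[row] < file_index) return(NULL)
    id <- history$mother_id[row]
    if (id == 0) return(NULL)
  }
}

new_branch_set <- function(df, mode, scope, clone = NA_integer_) {
  if (is.null(df) || !nrow(df)) {
    df <- data.frame(clone_id = integer(0), x1 = numeric(0), y1 = numeric(0),
                     z1 = numeric(0), x2 = numeric(0), y2 = numeric(0),
                     z2 = numeric(0))
  }
  rownames(df) <- NULL
  attr(df, "mode") <- mode
  attr(df, "scope") <- scope
  attr(df, "clone") <- clone
  attr(df, "clones_present") <- sort(unique(df$clone_id))
  class(df) <- c("branch_set", "data.frame")
  df
}

#' @export
print.branch_set <- function(x, ...) {
  cat(sprintf("<branch_set> %d branches, mode=%s, scope=%s, clones: %s\n",
              nrow(x), attr(x, "mode"), attr(x, "scope"),
              paste(attr(x, "clones_present"), collapse = ", ")))
  invisible(x)
}

# Shared branch construction: walk consecutive sampled snapshot pairs and,
# for every member cell present at the later snapshot, draw a 3D segment
# from the cell's (or its nearest ancestor's) position at the earlier
# snapshot. `members` is the set of cell ids whose traces are drawn; the
# ancestor fallback may anchor a clone's first segment at a mother from the
# parent clone -- that entry segment belongs to the daughter clone.
build_branches <- function(history, series, members, clone_label, config) {
  s <- sampled_indices(config$tmin, config$tmax, config$file_step,
                       attr(series, "stride"))
  missing <- setdiff(s, series_indices(series))
  if (length(missing))
    stop("sampled file indices not saved in dataset: ",
         paste(utils::head(missing, 5), collapse = ", "))
  out <- vector("list", length(s) - 1)
  for (j in seq_len(length(s) - 1)) {
    k1 <- s[j]; k2 <- s[j + 1]
    snap2 <- get_snapshot(series, k2)
    present <- snap2$ids[snap2$ids %in% members]
    if (!length(present)) next
    i2 <- match(present, snap2$ids)
    p2 <- snap2$xy[i2, , drop = FALSE]
    snap1 <- get_snapshot(series, k1)
    i1 <- match(present, snap1$ids)
    p1 <- matrix(NA_real_, length(present), 2)
    hit <- !is.na(i1)
    p1[hit, ] <- snap1$xy[i1[hit], , drop = FALSE]
    # ancestor fallback for cells absent from the earlier snapshot
    for (w in which(is.na(i1))) {
      pos <- position_of(series, history, present[w], k1)
      p1[w, ] <- if (is.null(pos)) c(NA_real_, NA_real_) else pos
    }
    keep <- !is.na(p1[, 1])
    if (!any(keep)) next
    cl <- if (length(clone_label) == 1) rep(clone_label, sum(keep))
          else clone_label[match(present[keep], members)]
    out[[j]] <- data.frame(clone_id = cl,
                           x1 = p1[keep, 1], y1 = time_to_y(k1, config),
                           z1 = p1[keep, 2],
                           x2 = p2[keep, 1], y2 = time_to_y(k2, config),
                           z2 = p2[keep, 2])
  }
  do.call(rbind, out)
}

#' Build the full 3D lineage tree of one clone
#'
#' Draws every mother-daughter trace of the clone, including cells that
#' later died or left the domain: for each pair of consecutive sampled
#' snapshots and each clone member present at the later one, a straight 3D
#' segment connects the member's (or its nearest ancestor's) position at the
#' earlier snapshot to its position at the later one, with time mapped to
#' the y axis by \code{\link{time_to_y}}. For a mutated clone the first
#' segment starts at the mother's position in the parent clone; that entry
#' segment is owned by the daughter clone.
#'
#' @param history a \code{\link{cell_history}}.
#' @param series a \code{\link{snapshot_series}}.
#' @param clone_id the clone to draw.
#' @param config a \code{\link{tree_config}}.
#' @param .members internal: restrict traces to this cell-id set.
#' @return A \code{branch_set} data frame with columns \code{clone_id, x1,
#'   y1, z1, x2, y2, z2} (y is scaled time).
#' @export
build_full_tree <- function(history, series, clone_id, config, .members = NULL) {
  clone_root(history, clone_id)  # errors if the clone is absent
  members <- history$cell_id[history$clone_id == clone_id]
  if (!is.null(.members)) members <- intersect(members, .members)
  df <- build_branches(history, series, members, clone_id, config)
  new_branch_set(df, mode = if (is.null(.members)) "full" else "alive",
                 scope = "single", clone = clone_id)
}

#' Cells with a descendant alive at the final snapshot
#'
#' Walks mother links upward from every cell alive in the final snapshot,
#' collecting each cell on the way: exactly the cells that are themselves
#' alive at \code{tmax} or have at least one surviving descendant. With a
#' \code{clone_id}, the walk starts from the clone's own surviving leaves
#' and the result is restricted to members of that clone, so a clone whose
#' cells all died prunes to the empty set even if descendants that mutated
#' into other clones survive -- the single-clone alive tree traces back only
#' from that clone's leaves.
#'
#' @param history a \code{\link{cell_history}}.
#' @param final_snapshot the \code{\link{snapshot}} at \code{tmax}.
#' @param clone_id optional clone restriction.
#' @return Sorted integer vector of surviving cell ids.
#' @export
surviving_set <- function(history, final_snapshot, clone_id = NULL) {
  alive <- unique(final_snapshot$ids)
  if (!is.null(clone_id)) {
    rows <- match(alive, history$cell_id)
    alive <- alive[history$clone_id[rows] == clone_id]
  }
  surv <- integer(0)
  frontier <- alive
  while (length(frontier)) {
    surv <- c(surv, frontier)
    rows <- match(frontier, history$cell_id)
    mothers <- unique(history$mother_id[rows])
    mothers <- mothers[mothers != 0]
    frontier <- setdiff(mothers, surv)
  }
  if (!is.null(clone_id)) {
    rows <- match(surv, history$cell_id)
    surv <- surv[history$clone_id[rows] == clone_id]
  }
  sort(unique(surv))
}

#' Build the survivor-pruned 3D lineage tree of one clone
#'
#' The full tree restricted to cells with at least one descendant alive at
#' the final sampled snapshot: branches of cells that died or left the
#' domain (and whose whole progeny did) are omitted. A clone with no
#' survivors yields an empty branch set.
#'
#' @inheritParams build_full_tree
#' @return A \code{branch_set} (always a subset of the full tree's).
#' @export
build_alive_tree <- function(history, series, clone_id, config) {
  final <- get_snapshot(series, config$tmax)
  surv <- surviving_set(history, final, clone_id)
  bs <- build_full_tree(history, series, clone_id, config, .members = surv)
  attr(bs, "mode") <- "alive"
  bs
}

#' Build the 3D lineage forest over clones 0..num_clones
#'
#' The union of per-clone trees: each clone id from 0 to \code{num_clones}
#' contributes its single-clone tree (full or survivor-pruned); ids with no
#' cells in the history are skipped. The branch multiset equals the
#' concatenation of the single-clone results.
#'
#' @param history a \code{\link{cell_history}}.
#' @param series a \code{\link{snapshot_series}}.
#' @param num_clones highest clone id to include.
#' @param mode \code{"full"} or \code{"alive"}.
#' @param config a \code{\link{tree_config}}.
#' @return A \code{branch_set} with scope \code{"all"}.
#' @export
build_forest <- function(history, series, num_clones, mode = c("full", "alive"),
                         config) {
  mode <- match.arg(mode)
  present <- unique(history$clone_id)
  trees <- lapply(0:num_clones, function(cl) {
    if (!(cl %in% present)) return(NULL)
    if (mode == "full") build_full_tree(history, series, cl, config)
    else build_alive_tree(history, series, cl, config)
  })
  df <- do.call(rbind, lapply(trees, function(t) {
    if (is.null(t)) NULL else as.data.frame(t)
  }))
  new_branch_set(df, mode = mode, scope = "all")
}

#' Serialize a branch set to a plain-text segment list
#'
#' One segment per line: \code{x1 y1 z1 x2 y2 z2 clone}.
#'
#' @param branches a \code{branch_set}.
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
write_branches <- function(branches, path) {
  writeLines(paste(signif(branches$x1, 6), signif(branches$y1, 6),
                   signif(branches$z1, 6), signif(branches$x2, 6),
                   signif(branches$y2, 6), signif(branches$z2, 6),
                   branches$clone_id), path)
  invisible(path)
}
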