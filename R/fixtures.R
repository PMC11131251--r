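#' Tiny hand-constructed datasets with exactly known trees
#'
#' Each fixture is a miniature dataset (at most a few cells and snapshots,
#' save stride 1) whose full and survivor-pruned trees can be enumerated by
#' hand, for use as exact oracles in tests and examples:
#' \describe{
#'   \item{one_cell}{a single immortal motionless founder over 3 snapshots;
#'     its full tree is 2 collinear segments at a fixed (x, y).}
#'   \item{one_division}{the founder divides at the middle snapshot; both
#'     daughters survive. Full tree: 1 root segment + 2 daughter segments.}
#'   \item{dying_branch}{one daughter survives, the other dies; the full
#'     tree is the surviving path plus a dead stub, the pruned tree is the
#'     path alone.}
#'   \item{two_clones}{one daughter mutates into clone 1; its clone root is
#'     the mutated daughter and its first segment starts at the mother's
#'     position.}
#'   \item{drug_extinction}{the sensitive clone 0 dies out after a division
#'     while a mutated clone 1 survives; clone 0's pruned tree is empty. The
#'     fixture carries a small drug field whose quantization uses all four
#'     bands.}
#' }
#'
#' @param kind fixture name.
#' @return A \code{sim_output}-shaped list: \code{history}, \code{series},
#'   \code{drug} (NULL unless stated), \code{clone_count}, and \code{config},
#'   a ready \code{\link{tree_config}} spanning the fixture (rectangle
#'   [-10, 10]^2).
#' @export
make_fixture <- function(kind = c("one_cell", "one_division", "dying_branch",
                                  "two_clones", "drug_extinction")) {
  kind <- match.arg(kind)
  snap <- function(k, ids, x, y) snapshot(k, ids, cbind(x, y))
  cfg <- function(tmax) tree_config(".", xmin = -10, xmax = 10, ymin = -10,
                                    ymax = 10, tmin = 0, tmax = tmax,
                                    file_step = 1)
  out <- switch(kind,
    one_cell = list(
      history = cell_history(1, 0, 0, 0, 0),
      series = snapshot_series(list(snap(0, 1, 2, 3), snap(1, 1, 2, 3),
                                    snap(2, 1, 2, 3)), stride = 1),
      drug = NULL, clone_count = 1L, config = cfg(2)),
    one_division = list(
      # founder (cell 1) divides at iteration 1; the snapshot at the
      # division iteration still lists the mother, the daughters appear
      # from the next snapshot on
      history = cell_history(1:3, c(0, 0, 0), c(0, 1, 1),
                             c(0, 1, 1), c(1, 0, 0)),
      series = snapshot_series(list(snap(0, 1, 0, 0), snap(1, 1, 0, 1),
                                    snap(2, 2:3, c(-2, 2), c(2, 2))),
                               stride = 1),
      drug = NULL, clone_count = 1L, config = cfg(2)),
    dying_branch = list(
      history = cell_history(1:3, c(0, 0, 0), c(0, 1, 1),
                             c(0, 1, 1), c(1, 0, 2)),
      series = snapshot_series(list(snap(0, 1, 0, 0), snap(1, 1, 0, 1),
                                    snap(2, 2:3, c(-2, 2), c(2, 2)),
                                    snap(3, 2, -3, 3)),
                               stride = 1),
      drug = NULL, clone_count = 1L, config = cfg(3)),
    two_clones = list(
      history = cell_history(1:3, c(0, 0, 1), c(0, 1, 1),
                             c(0, 1, 1), c(1, 0, 0)),
      series = snapshot_series(list(snap(0, 1, 0, 0), snap(1, 1, 0, 1),
                                    snap(2, 2:3, c(-2, 2), c(2, 2)),
                                    snap(3, 2:3, c(-3, 4), c(3, 3))),
                               stride = 1),
      drug = NULL, clone_count = 2L, config = cfg(3)),
    drug_extinction = list(
      # cell 2 (sensitive, clone 0) dies of drug at iteration 2; cell 3
      # founded resistant clone 1 and survives
      history = cell_history(1:3, c(0, 0, 1), c(0, 1, 1),
                             c(0, 1, 1), c(1, 2, 0)),
      series = snapshot_series(list(snap(0, 1, 0, 0), snap(1, 1, 0, 1),
                                    snap(2, 2:3, c(-2, 2), c(2, 2)),
                                    snap(3, 3, 4, 3)),
                               stride = 1),
      drug = drug_field(matrix(c(0, 0.3, 0.6, 1.0), 2, 2),
                        c(-10, 10, -10, 10)),
      clone_count = 2L, config = cfg(3)))
  class(out) <- "sim_output"
  out
}
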