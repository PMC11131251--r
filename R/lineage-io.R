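#' Cell history table
#'
#' A cell history records the genealogy of every cell that ever existed in a
#' simulation or tracked experiment: one row per cell with its unique id, the
#' clone it belongs to, its mother's id, and the iterations at which it was
#' born and at which it divided or died.
#'
#' @param cell_id integer vector of unique positive cell ids.
#' @param clone_id integer vector of non-negative clone labels (clones are
#'   numbered starting at 0).
#' @param mother_id integer vector; 0 is the founder sentinel ("no mother").
#' @param birth_iter integer vector of non-negative birth iterations.
#' @param end_iter integer vector; the iteration at which the cell divided
#'   into two daughters or died/left the domain, or 0 if the cell is still
#'   alive and undivided.
#'
#' @return A data frame of class \code{cell_history} with the five columns
#'   above and a \code{children} attribute: a list mapping each mother's
#'   \code{cell_id} (as character) to the integer vector of its daughters.
#' @export
cell_history <- function(cell_id, clone_id, mother_id, birth_iter, end_iter) {
  h <- data.frame(
    cell_id = as.integer(cell_id),
    clone_id = as.integer(clone_id),
    mother_id = as.integer(mother_id),
    birth_iter = as.integer(birth_iter),
    end_iter = as.integer(end_iter)
  )
  validate_cell_history(h)
  kids <- split(h$cell_id, factor(h$mother_id))
  kids[["0"]] <- NULL
  attr(h, "children") <- kids
  class(h) <- c("cell_history", "data.frame")
  h
}

validate_cell_history <- function(h) {
  if (anyDuplicated(h$cell_id))
    stop("duplicate cell_id in history: ",
         paste(unique(h$cell_id[duplicated(h$cell_id)]), collapse = ", "))
  if (any(h$cell_id < 1))
    stop("cell_id must be a positive integer (0 is reserved for the founder sentinel)")
  if (any(h$clone_id < 0)) stop("clone_id must be >= 0")
  if (any(h$birth_iter < 0)) stop("birth_iter must be >= 0")
  bad <- h$end_iter != 0 & h$end_iter < h$birth_iter
  if (any(bad))
    stop("end_iter before birth_iter for cell(s): ",
         paste(h$cell_id[bad], collapse = ", "))
  nonfounder <- h$mother_id != 0
  dangling <- nonfounder & !(h$mother_id %in% h$cell_id)
  if (any(dangling))
    stop("mother_id refers to unknown cell(s): ",
         paste(unique(h$mother_id[dangling]), collapse = ", "))
  mrow <- match(h$mother_id, h$cell_id)
  early <- nonfounder & h$birth_iter < h$birth_iter[mrow]
  if (any(early, na.rm = TRUE))
    stop("cell born before its mother: ",
         paste(h$cell_id[which(early)], collapse = ", "))
  ndaughters <- table(factor(h$mother_id[nonfounder], levels = h$cell_id))
  if (any(ndaughters > 2))
    stop("cell with more than two daughters: ",
         paste(names(ndaughters)[ndaughters > 2], collapse = ", "))
  invisible(h)
}

#' @export
print.cell_history <- function(x, ...) {
  cat(sprintf("<cell_history> %d cells, %d clones (ids %d..%d)\n",
              nrow(x), length(unique(x$clone_id)),
              min(x$clone_id), max(x$clone_id)))
  NextMethod()
}

#' Daughters of a cell
#'
#' @param history a \code{cell_history}.
#' @param cell_id a single cell id.
#' @return Integer vector of daughter cell ids (length 0 or 2 in a
#'   division-complete history).
#' @export
children_of <- function(history, cell_id) {
  kids <- attr(history, "children")[[as.character(cell_id)]]
  if (is.null(kids)) integer(0) else kids
}

#' Classify the fate of every cell in a history
#'
#' The history format conflates division and death in its final column: a
#' non-zero \code{end_iter} marks either event. A cell is classified as
#' divided if it has daughters, as dead (or having left the domain, which the
#' format cannot distinguish) if it ended without daughters, and as alive if
#' \code{end_iter == 0}.
#'
#' @param history a \code{cell_history}.
#' @return Character vector (per row): "alive", "divided" or "died".
#' @export
cell_fate <- function(history) {
  ndaughters <- vapply(history$cell_id,
                       function(i) length(children_of(history, i)), 0L)
  ifelse(history$end_iter == 0, "alive",
         ifelse(ndaughters > 0, "divided", "died"))
}

#' Read a cell history file
#'
#' Parses the plain-text genealogy table: one cell per row, five
#' whitespace-separated integer fields
#' \code{cell_id clone_id mother_id birth_iter end_iter}.
#' Blank lines are ignored.
#'
#' @param path path to a \code{cell_history.txt} file.
#' @return A validated \code{\link{cell_history}}.
#' @export
read_cell_history <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  fields <- strsplit(trimws(lines[nonblank]), "[[:space:]]+")
  n <- lengths(fields)
  if (any(n != 5L)) {
    bad <- nonblank[which(n != 5L)[1]]
    stop(sprintf("malformed cell history row at line %d of %s: expected 5 fields, found %d",
                 bad, path, n[which(n != 5L)[1]]))
  }
  vals <- suppressWarnings(as.numeric(unlist(fields)))
  if (anyNA(vals)) {
    bad <- nonblank[ceiling(which(is.na(vals))[1] / 5)]
    stop(sprintf("non-numeric field in cell history at line %d of %s", bad, path))
  }
  m <- matrix(vals, ncol = 5, byrow = TRUE)
  cell_history(m[, 1], m[, 2], m[, 3], m[, 4], m[, 5])
}

#' Snapshot of cells present at one saved iteration
#'
#' @param file_index the saved iteration number (the \code{_#} file suffix).
#' @param ids integer vector of cell ids present.
#' @param xy numeric matrix (length(ids) x 2) of coordinates, row-aligned
#'   with \code{ids}.
#' @return An object of class \code{snapshot}.
#' @export
snapshot <- function(file_index, ids, xy) {
  ids <- as.integer(ids)
  xy <- matrix(as.numeric(xy), ncol = 2)
  if (length(ids) != nrow(xy))
    stop(sprintf("snapshot %d: %d ids but %d coordinate rows (the two files must list the same cells in the same order)",
                 file_index, length(ids), nrow(xy)))
  if (anyDuplicated(ids))
    stop(sprintf("snapshot %d: duplicate cell ids", file_index))
  structure(list(file_index = as.integer(file_index), ids = ids, xy = xy),
            class = "snapshot")
}

#' @export
print.snapshot <- function(x, ...) {
  cat(sprintf("<snapshot> index %d, %d cells\n", x$file_index, length(x$ids)))
  invisible(x)
}

#' Read one snapshot from its paired id / coordinate files
#'
#' Every saved iteration is stored as two row-aligned files: a one-column
#' file of cell ids and a two-column file of x y coordinates. A mismatch in
#' row count between the two files is a hard error, since row order is the
#' only link between a cell id and its position.
#'
#' @param id_path path to the \code{cellID_<index>.txt} file.
#' @param xy_path path to the \code{cellXY_<index>.txt} file.
#' @param file_index the saved iteration the pair belongs to.
#' @return A \code{\link{snapshot}}. Empty files yield an empty snapshot
#'   (legal: all cells may have died).
#' @export
read_snapshot <- function(id_path, xy_path, file_index) {
  read_cols <- function(path, ncol_expect) {
    if (!file.exists(path)) stop("no such file: ", path)
    lines <- readLines(path, warn = FALSE)
    keep <- which(nzchar(trimws(lines)))
    if (!length(keep)) return(matrix(numeric(0), 0, ncol_expect))
    fields <- strsplit(trimws(lines[keep]), "[[:space:]]+")
    n <- lengths(fields)
    if (any(n != ncol_expect)) {
      bad <- which(n != ncol_expect)[1]
      stop(sprintf("malformed row at line %d of %s: expected %d fields, found %d",
                   keep[bad], path, ncol_expect, n[bad]))
    }
    vals <- suppressWarnings(as.numeric(unlist(fields)))
    if (anyNA(vals))
      stop(sprintf("non-numeric field in %s", path))
    matrix(vals, ncol = ncol_expect, byrow = TRUE)
  }
  ids <- read_cols(id_path, 1L)
  xy <- read_cols(xy_path, 2L)
  if (nrow(ids) != nrow(xy))
    stop(sprintf("snapshot %d: %s lists %d cells but %s lists %d (the order and number of cells in the two files must be identical)",
                 file_index, basename(id_path), nrow(ids),
                 basename(xy_path), nrow(xy)))
  snapshot(file_index, drop(ids[, 1]), xy)
}

#' Series of snapshots covering a time range
#'
#' @param snapshots list of \code{\link{snapshot}} objects.
#' @param stride the save stride: the spacing (in iterations) between
#'   consecutive saved file indices. Inferred from the indices if missing.
#' @return An object of class \code{snapshot_series}: a list keyed by file
#'   index (as character), with a \code{stride} attribute.
#' @export
snapshot_series <- function(snapshots, stride = NULL) {
  idx <- vapply(snapshots, function(s) s$file_index, 0L)
  o <- order(idx)
  snapshots <- snapshots[o]
  idx <- idx[o]
  if (anyDuplicated(idx)) stop("duplicate snapshot file indices")
  if (is.null(stride)) {
    stride <- if (length(idx) > 1) min(diff(idx)) else 1L
  }
  names(snapshots) <- as.character(idx)
  structure(snapshots, stride = as.integer(stride), class = "snapshot_series")
}

#' @export
print.snapshot_series <- function(x, ...) {
  idx <- series_indices(x)
  cat(sprintf("<snapshot_series> %d snapshots, indices %d..%d (stride %d)\n",
              length(x), min(idx), max(idx), attr(x, "stride")))
  invisible(x)
}

#' Saved file indices of a snapshot series
#' @param series a \code{snapshot_series}.
#' @return Sorted integer vector of saved file indices.
#' @export
series_indices <- function(series) sort(as.integer(names(series)))

get_snapshot <- function(series, file_index) {
  s <- series[[as.character(file_index)]]
  if (is.null(s))
    stop("no snapshot saved at file index ", file_index)
  s
}

#' Read all snapshots of a dataset directory
#'
#' Scans \code{dir} for \code{cellID_<index>.txt} files and reads each with
#' its paired \code{cellXY_<index>.txt}.
#'
#' @param dir the \code{data/} directory holding the snapshot files.
#' @return A \code{\link{snapshot_series}}.
#' @export
read_snapshot_series <- function(dir) {
  idf <- list.files(dir, pattern = "^cellID_\\d+\\.txt$")
  if (!length(idf)) stop("no cellID_<index>.txt files found in ", dir)
  idx <- as.integer(sub("^cellID_(\\d+)\\.txt$", "\\1", idf))
  snaps <- lapply(idx, function(k) {
    read_snapshot(file.path(dir, sprintf("cellID_%d.txt", k)),
                  file.path(dir, sprintf("cellXY_%d.txt", k)), k)
  })
  snapshot_series(snaps)
}

#' Microenvironmental factor field
#'
#' A 2D concentration matrix (e.g. a drug or oxygen distribution) over the
#' rectangular tissue patch. Rows run along the x axis and columns along the
#' y axis of the tissue.
#'
#' @param values numeric matrix of non-negative finite concentrations.
#' @param extent numeric length-4 vector \code{c(xmin, xmax, ymin, ymax)}.
#' @return An object of class \code{drug_field}.
#' @export
drug_field <- function(values, extent) {
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop("drug field contains non-finite values")
  if (any(values < 0)) stop("drug field contains negative concentrations")
  extent <- as.numeric(extent)
  if (length(extent) != 4 || extent[2] <= extent[1] || extent[4] <= extent[3])
    stop("extent must be c(xmin, xmax, ymin, ymax) with xmax > xmin, ymax > ymin")
  structure(list(values = values, extent = extent), class = "drug_field")
}

#' Read a 2D concentration matrix
#'
#' @param path path to a whitespace-separated rectangular numeric matrix
#'   (\code{drug.txt}).
#' @param extent tissue rectangle \code{c(xmin, xmax, ymin, ymax)} the
#'   matrix spans.
#' @return A \code{\link{drug_field}}.
#' @export
read_drug_map <- function(path, extent) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (!length(keep)) stop("empty drug map file: ", path)
  fields <- strsplit(trimws(lines[keep]), "[[:space:]]+")
  n <- lengths(fields)
  if (length(unique(n)) != 1)
    stop(sprintf("ragged drug map in %s: row lengths %s",
                 path, paste(unique(n), collapse = ", ")))
  vals <- suppressWarnings(as.numeric(unlist(fields)))
  if (anyNA(vals)) stop("non-numeric field in drug map ", path)
  drug_field(matrix(vals, nrow = length(keep), byrow = TRUE), extent)
}

#' Write a dataset in the plain-text exchange format
#'
#' Emits \code{cell_history.txt}, one \code{cellID_<index>.txt} /
#' \code{cellXY_<index>.txt} pair per snapshot, and optionally
#' \code{drug.txt}, under \code{<dir>/data/}. Integer fields round-trip
#' exactly through \code{\link{read_cell_history}} and
#' \code{\link{read_snapshot}}; coordinates are written with 6 significant
#' digits.
#'
#' @param history a \code{\link{cell_history}}.
#' @param series a \code{\link{snapshot_series}}.
#' @param drug optional \code{\link{drug_field}}.
#' @param dir dataset root directory (created if needed).
#' @return Invisibly, the character vector of files written.
#' @export
write_dataset <- function(history, series, drug = NULL, dir) {
  data_dir <- file.path(dir, "data")
  ok <- dir.create(data_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(data_dir)) stop("cannot create ", data_dir)
  written <- character(0)
  hist_path <- file.path(data_dir, "cell_history.txt")
  writeLines(sprintf("%d %d %d %d %d", history$cell_id, history$clone_id,
                     history$mother_id, history$birth_iter, history$end_iter),
             hist_path)
  written <- c(written, hist_path)
  for (key in names(series)) {
    s <- series[[key]]
    idp <- file.path(data_dir, sprintf("cellID_%d.txt", s$file_index))
    xyp <- file.path(data_dir, sprintf("cellXY_%d.txt", s$file_index))
    writeLines(sprintf("%d", s$ids), idp)
    writeLines(paste(signif(s$xy[, 1], 6), signif(s$xy[, 2], 6)), xyp)
    written <- c(written, idp, xyp)
  }
  if (!is.null(drug)) {
    dp <- file.path(data_dir, "drug.txt")
    writeLines(apply(drug$values, 1, function(r) paste(signif(r, 6), collapse = " ")),
               dp)
    written <- c(written, dp)
  }
  invisible(written)
}

#' Read a whole dataset directory
#'
#' @param path_data dataset root; files are read from
#'   \code{<path_data>/data/}.
#' @param extent tissue rectangle for the drug map (required if
#'   \code{drug.txt} is present and \code{read_drug} is TRUE).
#' @param read_drug whether to read \code{drug.txt} when present.
#' @return A list with elements \code{history}, \code{series} and
#'   \code{drug} (NULL when absent).
#' @export
read_dataset <- function(path_data, extent = NULL, read_drug = TRUE) {
  data_dir <- file.path(path_data, "data")
  if (!dir.exists(data_dir)) stop("no data/ subdirectory under ", path_data)
  history <- read_cell_history(file.path(data_dir, "cell_history.txt"))
  series <- read_snapshot_series(data_dir)
  drug <- NULL
  drug_path <- file.path(data_dir, "drug.txt")
  if (read_drug && file.exists(drug_path)) {
    if (is.null(extent)) stop("extent required to read drug.txt")
    drug <- read_drug_map(drug_path, extent)
  }
  list(history = history, series = series, drug = drug)
}

#' Configuration of a tree-drawing run
#'
#' Bundles the user arguments shared by the four tree routines: the dataset
#' directory, the tissue rectangle, the time window and sampling stride, and
#' the gradient / figure-saving switches.
#'
#' @param path_data dataset root directory (its \code{data/} subdirectory
#'   holds the input files).
#' @param num_clones total number of clones to draw (all-clones routines).
#' @param clone_num single clone id to draw (single-clone routines).
#' @param is_gradient draw the quantized microenvironment backdrop (TRUE/1)
#'   or not (FALSE/0).
#' @param xmin,xmax,ymin,ymax tissue rectangle.
#' @param tmin,tmax first and last saved iteration to draw.
#' @param file_step sampling stride over saved iterations; larger values
#'   skip intermediate positions and straighten branches.
#' @param to_print save the figure as a JPEG (TRUE/1) or not (FALSE/0).
#' @return A validated list of class \code{tree_config}.
#' @export
tree_config <- function(path_data = ".", num_clones = NULL, clone_num = NULL,
                        is_gradient = FALSE, xmin, xmax, ymin, ymax,
                        tmin, tmax, file_step, to_print = FALSE) {
  cfg <- list(path_data = path_data,
              num_clones = if (is.null(num_clones)) NULL else as.integer(num_clones),
              clone_num = if (is.null(clone_num)) NULL else as.integer(clone_num),
              is_gradient = as.logical(is_gradient),
              xmin = as.numeric(xmin), xmax = as.numeric(xmax),
              ymin = as.numeric(ymin), ymax = as.numeric(ymax),
              tmin = as.integer(tmin), tmax = as.integer(tmax),
              file_step = as.integer(file_step),
              to_print = as.logical(to_print))
  if (cfg$xmax <= cfg$xmin) stop("xmax must be > xmin")
  if (cfg$ymax <= cfg$ymin) stop("ymax must be > ymin")
  if (cfg$tmax <= cfg$tmin) stop("tmax must be > tmin")
  if (cfg$file_step < 1) stop("file_step must be >= 1")
  if (!is.null(cfg$num_clones) && cfg$num_clones < 0)
    stop("num_clones must be >= 0")
  if (!is.null(cfg$clone_num) && cfg$clone_num < 0)
    stop("clone_num must be >= 0")
  class(cfg) <- "tree_config"
  cfg
}

#' Validate a dataset directory against the exchange-format contract
#'
#' Runs the structural checks a tree-drawing run relies on and reports each:
#' presence of the required snapshot files over \code{tmin..tmax}, row
#' alignment of every id/coordinate file pair, parseability and referential
#' integrity of the history, membership of every snapshot id in the history,
#' consistency of snapshot membership with each cell's lifespan, and
#' coordinates within the configured tissue rectangle (a warning-level
#' check: cells that left the domain are legitimately absent, but a present
#' cell outside the rectangle is suspicious).
#'
#' @param dir dataset root directory.
#' @param config a \code{\link{tree_config}} giving the rectangle and time
#'   window to check against.
#' @return A data frame of class \code{validation_report} with columns
#'   \code{check}, \code{status} ("ok", "warn" or "fail") and \code{detail}.
#' @export
validate_dataset <- function(dir, config) {
  checks <- list()
  add <- function(check, status, detail = "") {
    checks[[length(checks) + 1]] <<- data.frame(check = check, status = status,
                                                detail = detail)
  }
  data_dir <- file.path(dir, "data")
  if (!dir.exists(data_dir)) {
    add("data_dir", "fail", paste("missing", data_dir))
    return(finish_report(checks))
  }

  history <- tryCatch(read_cell_history(file.path(data_dir, "cell_history.txt")),
                      error = function(e) e)
  if (inherits(history, "error")) {
    add("history_integrity", "fail", conditionMessage(history))
    history <- NULL
  } else add("history_integrity", "ok",
             sprintf("%d cells, %d clones", nrow(history),
                     length(unique(history$clone_id))))

  idf <- list.files(data_dir, pattern = "^cellID_\\d+\\.txt$")
  idx <- sort(as.integer(sub("^cellID_(\\d+)\\.txt$", "\\1", idf)))
  if (length(idx) < 2) {
    add("snapshot_files", if (length(idx)) "warn" else "fail",
        sprintf("found %d snapshot(s)", length(idx)))
    stride <- 1L
  } else {
    stride <- min(diff(idx))
    wanted <- seq(config$tmin, config$tmax, by = stride)
    missing <- setdiff(wanted, idx)
    if (length(missing))
      add("snapshot_files", "fail",
          sprintf("missing indices (stride %d): %s", stride,
                  paste(utils::head(missing, 5), collapse = ", ")))
    else
      add("snapshot_files", "ok",
          sprintf("indices %d..%d at stride %d", config$tmin, config$tmax, stride))
  }

  aligned <- TRUE
  snaps <- list()
  for (k in idx) {
    s <- tryCatch(read_snapshot(file.path(data_dir, sprintf("cellID_%d.txt", k)),
                                file.path(data_dir, sprintf("cellXY_%d.txt", k)), k),
                  error = function(e) e)
    if (inherits(s, "error")) {
      add("snapshot_alignment", "fail", conditionMessage(s))
      aligned <- FALSE
    } else snaps[[as.character(k)]] <- s
  }
  if (aligned) add("snapshot_alignment", "ok",
                   sprintf("%d snapshot pairs row-aligned", length(snaps)))

  if (!is.null(history) && length(snaps)) {
    unknown <- unlist(lapply(snaps, function(s) setdiff(s$ids, history$cell_id)))
    if (length(unknown))
      add("snapshot_ids_in_history", "fail",
          paste("unknown ids:", paste(utils::head(unique(unknown), 5), collapse = ", ")))
    else add("snapshot_ids_in_history", "ok", "")

    bad_span <- character(0)
    for (s in snaps) {
      i <- match(s$ids, history$cell_id)
      viol <- history$birth_iter[i] > s$file_index |
        (history$end_iter[i] != 0 & history$end_iter[i] < s$file_index)
      if (any(viol))
        bad_span <- c(bad_span, sprintf("index %d: cell(s) %s", s$file_index,
                                        paste(utils::head(s$ids[viol], 3), collapse = ", ")))
    }
    if (length(bad_span))
      add("lifespan_consistency", "fail", paste(utils::head(bad_span, 3), collapse = "; "))
    else add("lifespan_consistency", "ok", "")

    oob <- character(0)
    for (s in snaps) {
      out <- s$xy[, 1] < config$xmin | s$xy[, 1] > config$xmax |
        s$xy[, 2] < config$ymin | s$xy[, 2] > config$ymax
      if (any(out)) oob <- c(oob, sprintf("index %d: %d cell(s)", s$file_index, sum(out)))
    }
    if (length(oob))
      add("coordinate_bounds", "warn",
          paste("outside rectangle:", paste(utils::head(oob, 3), collapse = "; ")))
    else add("coordinate_bounds", "ok", "")
  }

  finish_report(checks)
}

finish_report <- function(checks) {
  rep <- do.call(rbind, checks)
  class(rep) <- c("validation_report", "data.frame")
  rep
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  for (i in seq_len(nrow(x))) {
    mark <- switch(x$status[i], ok = "OK  ", warn = "WARN", fail = "FAIL")
    cat(sprintf("  [%s] %-25s %s\n", mark, x$check[i], x$detail[i]))
  }
  invisible(x)
}

#' Did a validation report pass all hard checks?
#' @param report a \code{validation_report}.
#' @return TRUE if no check has status "fail" (warnings allowed).
#' @export
report_passed <- function(report) !any(report$status == "fail")
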