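#' Deterministic clone colors
#'
#' Every clone gets a fixed color from its id alone, stable across runs and
#' figures: clone 0 is pink; other clones take golden-angle-spaced hues in
#' HSV, which keeps colors well separated for many tens of clones (hues
#' eventually pack closely but never repeat exactly for distinct ids in one
#' figure).
#'
#' @param clone_id integer vector of clone ids.
#' @return Character vector of colors.
#' @export
clone_color <- function(clone_id) {
  gold <- 0.61803398875
  ifelse(clone_id == 0, "#FFC0CB",
         grDevices::hsv((clone_id * gold) %% 1, 0.8, 0.85))
}

#' Assemble a 3D lineage-tree scene
#'
#' Packs a branch set, the axis box implied by the configuration, the clone
#' palette and an optional quantized backdrop into a plottable scene object.
#' The scene is introspectable: \code{nrow(scene$segments)} is exactly the
#' number of branches drawn.
#'
#' @param branches a \code{branch_set}.
#' @param config a \code{\link{tree_config}}.
#' @param background optional \code{band_map}; drawn only when
#'   \code{config$is_gradient} is TRUE.
#' @param theta,phi viewing angles (degrees) of the projection; re-render
#'   with different angles to rotate the figure.
#' @return An object of class \code{tree_scene}.
#' @export
tree_scene <- function(branches, config, background = NULL,
                       theta = 40, phi = 20) {
  plane <- NULL
  if (isTRUE(config$is_gradient) && !is.null(background))
    plane <- background_plane(background, config)
  segs <- as.data.frame(branches)
  segs$col <- clone_color(segs$clone_id)
  structure(list(segments = segs, plane = plane, config = config,
                 theta = theta, phi = phi,
                 title = sprintf("%s lineage tree (%s)",
                                 attr(branches, "mode"),
                                 if (identical(attr(branches, "scope"), "all"))
                                   "all clones"
                                 else paste("clone", attr(branches, "clone")))),
            class = "tree_scene")
}

#' @export
print.tree_scene <- function(x, ...) {
  cat(sprintf("<tree_scene> %d segments%s, theta=%g phi=%g\n",
              nrow(x$segments),
              if (is.null(x$plane)) "" else " + background plane",
              x$theta, x$phi))
  invisible(x)
}

#' Draw a lineage-tree scene on the current graphics device
#'
#' Projects the scene with \code{\link[graphics]{persp}}: tissue x on the
#' plot x axis, scaled time on the y (depth) axis, tissue y on the vertical
#' z axis. The backdrop plane (if any) is drawn first so branches overlay
#' it. An empty branch set draws valid empty axes -- the correct picture for
#' a clone with no surviving cells.
#'
#' @param x a \code{tree_scene}.
#' @param theta,phi optional viewing-angle overrides.
#' @param ... further arguments passed to \code{persp} (e.g. \code{cex.axis}).
#' @return Invisibly, the scene.
#' @export
plot.tree_scene <- function(x, theta = x$theta, phi = x$phi, ...) {
  cfg <- x$config
  ylim <- c(0, cfg$xmax - cfg$xmin)
  pmat <- graphics::persp(x = c(cfg$xmin, cfg$xmax), y = ylim,
                          z = matrix(cfg$ymin, 2, 2),
                          zlim = c(cfg$ymin, cfg$ymax),
                          xlab = "x (tissue)", ylab = "time (scaled)",
                          zlab = "y (tissue)", theta = theta, phi = phi,
                          col = NA, border = NA, ticktype = "detailed",
                          expand = 0.8, main = x$title, ...)
  if (!is.null(x$plane)) {
    for (k in seq_along(x$plane$xs)) {
      p <- grDevices::trans3d(x$plane$xs[[k]], x$plane$y_time,
                              x$plane$zs[[k]], pmat)
      graphics::polygon(p$x, p$y, col = x$plane$col[k], border = NA)
    }
  }
  s <- x$segments
  if (nrow(s)) {
    a <- grDevices::trans3d(s$x1, s$y1, s$z1, pmat)
    b <- grDevices::trans3d(s$x2, s$y2, s$z2, pmat)
    graphics::segments(a$x, a$y, b$x, b$y, col = s$col, lwd = 1.2)
  }
  invisible(x)
}

#' Render a branch set (assemble the scene and draw it)
#'
#' @inheritParams tree_scene
#' @param draw draw on the current device (default) or only build the scene.
#' @return The \code{tree_scene}, invisibly when drawn.
#' @export
render_tree <- function(branches, config, background = NULL,
                        theta = 40, phi = 20, draw = TRUE) {
  scene <- tree_scene(branches, config, background, theta, phi)
  if (draw) {
    plot(scene)
    invisible(scene)
  } else scene
}

#' Export a scene as a JPEG file
#'
#' Renders the scene on an off-screen JPEG device, so export works headless.
#'
#' @param scene a \code{tree_scene}.
#' @param path output file path.
#' @param width,height image size in pixels.
#' @param quality JPEG quality (0-100).
#' @return Invisibly, \code{path}.
#' @export
export_jpeg <- function(scene, path, width = 1000, height = 800, quality = 92) {
  grDevices::jpeg(path, width = width, height = height, quality = quality)
  on.exit(grDevices::dev.off(), add = TRUE)
  plot(scene)
  invisible(path)
}

# Shared driver of the four user-facing routines: read the dataset, build
# the requested tree, render and optionally export.
run_tree_routine <- function(config, scope, mode, theta, phi, draw, out_file) {
  ds <- read_dataset(config$path_data,
                     extent = c(config$xmin, config$xmax,
                                config$ymin, config$ymax),
                     read_drug = isTRUE(config$is_gradient))
  branches <- if (scope == "all") {
    build_forest(ds$history, ds$series, config$num_clones, mode, config)
  } else if (mode == "full") {
    build_full_tree(ds$history, ds$series, config$clone_num, config)
  } else {
    build_alive_tree(ds$history, ds$series, config$clone_num, config)
  }
  background <- NULL
  if (isTRUE(config$is_gradient)) {
    if (is.null(ds$drug))
      stop("is_gradient = 1 but no drug.txt in ", file.path(config$path_data, "data"))
    background <- quantize_field(ds$drug)
  }
  scene <- tree_scene(branches, config, background, theta, phi)
  file <- NULL
  if (isTRUE(config$to_print)) {
    file <- out_file %||% file.path(config$path_data, default_fig_name(scope, mode, config))
    export_jpeg(scene, file)
  }
  if (draw) plot(scene)
  invisible(list(branches = branches, scene = scene, file = file))
}

default_fig_name <- function(scope, mode, config) {
  stem <- if (scope == "all") {
    if (mode == "full") "tree_all" else "tree_alive_all"
  } else {
    sprintf("tree_%sclone_%d", if (mode == "full") "" else "alive_",
            config$clone_num)
  }
  paste0(stem, ".jpg")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Draw the full 3D lineage tree of all clones
#'
#' Reads the dataset under \code{path_data/data/}, builds the full (all
#' cells, including those that died or left the domain) lineage forest for
#' clones \code{0..num_clones}, and renders it; with \code{to_print = 1} the
#' figure is also saved as a JPEG in \code{path_data}.
#'
#' @param path_data dataset root directory.
#' @param num_clones total number of clones to draw (ids 0..num_clones).
#' @param is_gradient draw the four-band microenvironment backdrop (needs
#'   \code{drug.txt}).
#' @param xmin,xmax,ymin,ymax tissue rectangle.
#' @param tmin,tmax time window (saved iteration numbers).
#' @param file_step sampling stride over saved iterations.
#' @param to_print save the figure as a JPEG.
#' @param theta,phi viewing angles; re-run with different values to rotate.
#' @param draw draw on the current device.
#' @param out_file override the default JPEG path.
#' @return Invisibly, a list with the \code{branches}, the \code{scene} and
#'   the JPEG \code{file} (NULL if not saved).
#' @export
tree3d_all <- function(path_data, num_clones, is_gradient = FALSE,
                       xmin, xmax, ymin, ymax, tmin, tmax, file_step,
                       to_print = FALSE, theta = 40, phi = 20,
                       draw = interactive(), out_file = NULL) {
  cfg <- tree_config(path_data, num_clones = num_clones,
                     is_gradient = is_gradient, xmin = xmin, xmax = xmax,
                     ymin = ymin, ymax = ymax, tmin = tmin, tmax = tmax,
                     file_step = file_step, to_print = to_print)
  run_tree_routine(cfg, "all", "full", theta, phi, draw, out_file)
}

#' Draw the survivor-pruned 3D lineage tree of all clones
#'
#' Like \code{\link{tree3d_all}}, but keeps only branches of cells with at
#' least one descendant alive at \code{tmax}.
#'
#' @inheritParams tree3d_all
#' @return See \code{\link{tree3d_all}}.
#' @export
tree3d_alive_all <- function(path_data, num_clones, is_gradient = FALSE,
                             xmin, xmax, ymin, ymax, tmin, tmax, file_step,
                             to_print = FALSE, theta = 40, phi = 20,
                             draw = interactive(), out_file = NULL) {
  cfg <- tree_config(path_data, num_clones = num_clones,
                     is_gradient = is_gradient, xmin = xmin, xmax = xmax,
                     ymin = ymin, ymax = ymax, tmin = tmin, tmax = tmax,
                     file_step = file_step, to_print = to_print)
  run_tree_routine(cfg, "all", "alive", theta, phi, draw, out_file)
}

#' Draw the full 3D lineage tree of one clone
#'
#' @inheritParams tree3d_all
#' @param clone_num the clone id to draw (clones are numbered from 0).
#' @return See \code{\link{tree3d_all}}.
#' @export
tree3d_clone <- function(path_data, clone_num, is_gradient = FALSE,
                         xmin, xmax, ymin, ymax, tmin, tmax, file_step,
                         to_print = FALSE, theta = 40, phi = 20,
                         draw = interactive(), out_file = NULL) {
  cfg <- tree_config(path_data, clone_num = clone_num,
                     is_gradient = is_gradient, xmin = xmin, xmax = xmax,
                     ymin = ymin, ymax = ymax, tmin = tmin, tmax = tmax,
                     file_step = file_step, to_print = to_print)
  run_tree_routine(cfg, "single", "full", theta, phi, draw, out_file)
}

#' Draw the survivor-pruned 3D lineage tree of one clone
#'
#' A clone whose cells all died (e.g. a drug-sensitive clone after
#' treatment) yields an empty tree: valid axes with no branches.
#'
#' @inheritParams tree3d_clone
#' @return See \code{\link{tree3d_all}}.
#' @export
tree3d_alive_clone <- function(path_data, clone_num, is_gradient = FALSE,
                               xmin, xmax, ymin, ymax, tmin, tmax, file_step,
                               to_print = FALSE, theta = 40, phi = 20,
                               draw = interactive(), out_file = NULL) {
  cfg <- tree_config(path_data, clone_num = clone_num,
                     is_gradient = is_gradient, xmin = xmin, xmax = xmax,
                     ymin = ymin, ymax = ymax, tmin = tmin, tmax = tmax,
                     file_step = file_step, to_print = to_print)
  run_tree_routine(cfg, "single", "alive", theta, phi, draw, out_file)
}
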