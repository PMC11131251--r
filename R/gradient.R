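#' Four-band palette for the microenvironment backdrop
#'
#' Fixed colors from the lowest to the highest concentration band:
#' blue, cyan, yellow, red.
#' @return Character vector of 4 colors (band 0 first).
#' @export
band_palette <- function() c("blue", "cyan", "yellow", "red")

#' Quantize a concentration field into four ordered bands
#'
#' Splits the field's value range \code{[min, max]} into four equal-width
#' bins. Value \code{v} maps to band \code{floor(4 (v - min)/(max - min))},
#' clipped to 3 so that \code{v == max} lands in the top band; band 0 is the
#' lowest. A constant field (min == max) maps entirely to band 0.
#'
#' @param field a \code{\link{drug_field}}.
#' @return An object of class \code{band_map}: list with \code{band} (an
#'   integer matrix over \{0,1,2,3\} shaped like the field), \code{thresholds}
#'   (the 3 interior bin edges), \code{colors} (band 0..3) and the field's
#'   \code{extent}.
#' @export
quantize_field <- function(field) {
  v <- field$values
  lo <- min(v); hi <- max(v)
  if (hi > lo) {
    band <- floor(4 * (v - lo) / (hi - lo))
    band[band > 3] <- 3L
    thresholds <- lo + (1:3) * (hi - lo) / 4
  } else {
    band <- array(0L, dim = dim(v))
    thresholds <- rep(lo, 3)
  }
  structure(list(band = matrix(as.integer(band), nrow(v), ncol(v)),
                 thresholds = thresholds, colors = band_palette(),
                 extent = field$extent),
            class = "band_map")
}

#' @export
print.band_map <- function(x, ...) {
  cat(sprintf("<band_map> %d x %d, bands used: %s\n",
              nrow(x$band), ncol(x$band),
              paste(sort(unique(as.vector(x$band))), collapse = ", ")))
  invisible(x)
}

#' Lay a quantized field out as a colored plane in the 3D scene
#'
#' The backdrop is drawn in the tissue (x, y) plane -- the plot's x-z plane
#' -- at scaled time 0 (the tmin face), so the tree grows away from its
#' environment map. Each matrix cell becomes one colored rectangle; rows of
#' the matrix run along tissue x, columns along tissue y.
#'
#' @param bands a \code{band_map}.
#' @param config a \code{\link{tree_config}} (used for the rectangle).
#' @return A list of class \code{background_plane} with parallel lists
#'   \code{xs}, \code{zs} (corner coordinates per rectangle), vector
#'   \code{col}, and \code{y_time} (the time-axis placement, 0).
#' @export
background_plane <- function(bands, config) {
  nx <- nrow(bands$band); ny <- ncol(bands$band)
  ex <- c(config$xmin, config$xmax, config$ymin, config$ymax)
  xedges <- seq(ex[1], ex[2], length.out = nx + 1)
  zedges <- seq(ex[3], ex[4], length.out = ny + 1)
  xs <- vector("list", nx * ny)
  zs <- vector("list", nx * ny)
  col <- character(nx * ny)
  k <- 0
  for (i in seq_len(nx)) {
    for (j in seq_len(ny)) {
      k <- k + 1
      xs[[k]] <- c(xedges[i], xedges[i + 1], xedges[i + 1], xedges[i])
      zs[[k]] <- c(zedges[j], zedges[j], zedges[j + 1], zedges[j + 1])
      col[k] <- bands$colors[bands$band[i, j] + 1L]
    }
  }
  structure(list(xs = xs, zs = zs, col = col, y_time = 0),
            class = "background_plane")
}
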