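#' Medial axis of a dendritic shaft
#'
#' A `medial_axis` is an ordered 3D polyline traced through the middle of a
#' dendritic shaft, stored together with the cumulative arc length at each
#' vertex. All coordinates are in micrometres.
#'
#' @param points Numeric matrix with one row per vertex and columns x, y, z
#'   (micrometres), in root-to-tip order.
#' @return An object of class `medial_axis`: a list with `points` (n x 3
#'   matrix) and `cum_s` (cumulative arc length per vertex, `cum_s[1] == 0`).
#' @examples
#' ax <- medial_axis(cbind(x = c(0, 0), y = c(0, 0), z = c(0, 10)))
#' axis_length(ax)
#' @export
medial_axis <- function(points) {
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 3L) {
    stop("axis points must be a numeric matrix with columns x, y, z")
  }
  if (nrow(points) < 2L) stop("degenerate axis: need at least 2 vertices")
  if (anyNA(points)) stop("axis points contain missing values")
  seg <- sqrt(rowSums((points[-1L, , drop = FALSE] -
                         points[-nrow(points), , drop = FALSE])^2))
  if (any(seg == 0)) {
    stop("duplicate consecutive vertices at row ",
         which(seg == 0)[1L] + 1L)
  }
  dimnames(points) <- list(NULL, c("x", "y", "z"))
  structure(list(points = points, cum_s = c(0, cumsum(seg))),
            class = "medial_axis")
}

#' @export
print.medial_axis <- function(x, ...) {
  cat(sprintf("<medial_axis: %d vertices, %.3f um>\n",
              nrow(x$points), axis_length(x)))
  invisible(x)
}

#' Total arc length of a medial axis
#'
#' @param axis A [medial_axis()].
#' @return Total arc length in micrometres.
#' @export
axis_length <- function(axis) {
  stopifnot(inherits(axis, "medial_axis"))
  axis$cum_s[length(axis$cum_s)]
}

#' Point on the axis at a given arc length
#'
#' Linear interpolation along the polyline.
#'
#' @param axis A [medial_axis()].
#' @param s Arc length in micrometres, in `[0, axis_length(axis)]`.
#' @return Numeric length-3 coordinate.
#' @export
axis_point_at <- function(axis, s) {
  stopifnot(inherits(axis, "medial_axis"))
  L <- axis_length(axis)
  if (s < -1e-9 || s > L + 1e-9) stop("arc length out of range")
  s <- min(max(s, 0), L)
  i <- findInterval(s, axis$cum_s, rightmost.closed = TRUE)
  i <- min(i, nrow(axis$points) - 1L)
  u <- (s - axis$cum_s[i]) / (axis$cum_s[i + 1L] - axis$cum_s[i])
  (1 - u) * axis$points[i, ] + u * axis$points[i + 1L, ]
}
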