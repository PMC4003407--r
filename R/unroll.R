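#' Project a 3D point onto the medial axis
#'
#' Finds the closest point on the polyline (interpolated within segments)
#' and returns its arc-length coordinate together with the radial offset
#' vector. Ties between equally close segments are broken toward the
#' smaller arc length, so the result is deterministic.
#'
#' @param point Numeric length-3 coordinate (micrometres).
#' @param axis A [medial_axis()].
#' @return A list with `s` (arc length, micrometres) and `radial`
#'   (length-3 vector `point - foot`).
#' @export
project_to_axis <- function(point, axis) {
  stopifnot(inherits(axis, "medial_axis"), length(point) == 3L)
  p <- axis$points
  n <- nrow(p)
  a <- p[-n, , drop = FALSE]
  d <- p[-1L, , drop = FALSE] - a
  len2 <- rowSums(d * d)
  w <- matrix(rep(as.numeric(point), each = n - 1L), ncol = 3L) - a
  u <- pmin(pmax(rowSums(w * d) / len2, 0), 1)
  foot <- a + d * u
  dist2 <- rowSums((foot - matrix(rep(as.numeric(point), each = n - 1L),
                                  ncol = 3L))^2)
  s_cand <- axis$cum_s[-length(axis$cum_s)] + u * sqrt(len2)
  # ties toward smaller s: order candidates by (dist2, s)
  best <- order(dist2, s_cand)[1L]
  list(s = s_cand[best], radial = unname(as.numeric(point) - foot[best, ]))
}

#' Rotation-minimizing frames along a medial axis
#'
#' Builds an orthonormal frame (tangent, normal, binormal) at every vertex.
#' The tangent is the local polyline direction (segment directions averaged
#' at interior vertices); the first normal is `reference_dir`
#' orthogonalized against the first tangent; subsequent normals are
#' propagated with the double-reflection rotation-minimizing construction,
#' which introduces no spurious twist and never flips, unlike Frenet frames
#' (undefined on straight segments). The binormal is `t x n`, so the frame
#' is right-handed.
#'
#' @param axis A [medial_axis()].
#' @param reference_dir Length-3 direction fixing the angular origin
#'   (theta = 0); must not be parallel to the first tangent. Default
#'   `c(1, 0, 0)`.
#' @return An object of class `axis_frames`: list of n x 3 matrices
#'   `tangent`, `normal`, `binormal`.
#' @export
compute_frames <- function(axis, reference_dir = c(1, 0, 0)) {
  stopifnot(inherits(axis, "medial_axis"), length(reference_dir) == 3L)
  p <- axis$points
  n <- nrow(p)
  seg <- p[-1L, , drop = FALSE] - p[-n, , drop = FALSE]
  seg <- seg / sqrt(rowSums(seg * seg))
  tg <- matrix(0, n, 3L)
  tg[1L, ] <- seg[1L, ]
  tg[n, ] <- seg[n - 1L, ]
  if (n > 2L) {
    mid <- seg[-(n - 1L), , drop = FALSE] + seg[-1L, , drop = FALSE]
    tg[2:(n - 1L), ] <- mid / sqrt(rowSums(mid * mid))
  }
  r <- as.numeric(reference_dir)
  r0 <- r - sum(r * tg[1L, ]) * tg[1L, ]
  if (sqrt(sum(r0 * r0)) < 1e-9 * sqrt(sum(r * r))) {
    stop("reference_dir is parallel to the first tangent; choose another")
  }
  nor <- matrix(0, n, 3L)
  nor[1L, ] <- r0 / sqrt(sum(r0 * r0))
  # double-reflection propagation (Wang et al. 2008)
  for (i in seq_len(n - 1L)) {
    v1 <- p[i + 1L, ] - p[i, ]
    c1 <- sum(v1 * v1)
    rL <- nor[i, ] - (2 / c1) * sum(v1 * nor[i, ]) * v1
    tL <- tg[i, ] - (2 / c1) * sum(v1 * tg[i, ]) * v1
    v2 <- tg[i + 1L, ] - tL
    c2 <- sum(v2 * v2)
    ni <- if (c2 < 1e-300) rL else rL - (2 / c2) * sum(v2 * rL) * v2
    ni <- ni - sum(ni * tg[i + 1L, ]) * tg[i + 1L, ]
    nor[i + 1L, ] <- ni / sqrt(sum(ni * ni))
  }
  bin <- cbind(tg[, 2L] * nor[, 3L] - tg[, 3L] * nor[, 2L],
               tg[, 3L] * nor[, 1L] - tg[, 1L] * nor[, 3L],
               tg[, 1L] * nor[, 2L] - tg[, 2L] * nor[, 1L])
  structure(list(tangent = tg, normal = nor, binormal = bin),
            class = "axis_frames")
}

# Orthonormal frame at an arbitrary arc length, by linear interpolation of
# the vertex frames followed by re-orthogonalization. Exact at vertices and
# on straight axes.
frame_at <- function(axis, frames, s) {
  cs <- axis$cum_s
  i <- findInterval(s, cs, rightmost.closed = TRUE)
  i <- min(max(i, 1L), length(cs) - 1L)
  u <- (s - cs[i]) / (cs[i + 1L] - cs[i])
  u <- min(max(u, 0), 1)
  tg <- (1 - u) * frames$tangent[i, ] + u * frames$tangent[i + 1L, ]
  tg <- tg / sqrt(sum(tg * tg))
  nor <- (1 - u) * frames$normal[i, ] + u * frames$normal[i + 1L, ]
  nor <- nor - sum(nor * tg) * tg
  nor <- nor / sqrt(sum(nor * nor))
  bin <- c(tg[2L] * nor[3L] - tg[3L] * nor[2L],
           tg[3L] * nor[1L] - tg[1L] * nor[3L],
           tg[1L] * nor[2L] - tg[2L] * nor[1L])
  list(tangent = tg, normal = nor, binormal = bin)
}

#' Unroll spines into (arc length, angle) coordinates
#'
#' The straightening/unrolling transform: each spine's insertion point is
#' projected onto the medial axis to obtain its arc-length position `s_um`,
#' and its angular position `theta_deg` around the axis is measured in the
#' rotation-minimizing frame at that point, counter-clockwise about the
#' tangent (`theta = atan2(r . binormal, r . normal)`, mapped to
#' `[0, 360)`).
#'
#' @param spines A `spine_table` (see [read_spine_table()]).
#' @param axis A [medial_axis()].
#' @param frames An `axis_frames` from [compute_frames()]; computed with
#'   defaults when omitted.
#' @return A `data.frame` of class `unrolled_spines` with columns
#'   `spine_id, s_um, theta_deg, radial_dist_um, length_um, volume_um3`,
#'   input order preserved, with attribute `axis_length` (micrometres).
#' @export
unroll_spines <- function(spines, axis, frames = compute_frames(axis)) {
  stopifnot(inherits(axis, "medial_axis"), inherits(frames, "axis_frames"))
  n <- nrow(spines)
  s <- numeric(n); theta <- numeric(n); rd <- numeric(n)
  for (k in seq_len(n)) {
    pr <- project_to_axis(as.numeric(spines[k, c("x", "y", "z")]), axis)
    fr <- frame_at(axis, frames, pr$s)
    rd[k] <- sqrt(sum(pr$radial^2))
    if (rd[k] == 0) {
      warning("spine ", spines$spine_id[k],
              " lies exactly on the axis; theta set to 0")
      theta[k] <- 0
    } else {
      th <- atan2(sum(pr$radial * fr$binormal),
                  sum(pr$radial * fr$normal)) * 180 / pi
      theta[k] <- th %% 360
    }
    s[k] <- pr$s
  }
  out <- data.frame(spine_id = spines$spine_id, s_um = s, theta_deg = theta,
                    radial_dist_um = rd, length_um = spines$length_um,
                    volume_um3 = spines$volume_um3,
                    stringsAsFactors = FALSE)
  attr(out, "axis_length") <- axis_length(axis)
  class(out) <- c("unrolled_spines", "data.frame")
  out
}

#' Write unrolled coordinates to CSV
#'
#' @param unrolled An `unrolled_spines` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_unrolled_csv <- function(unrolled, path) {
  df <- as.data.frame(unrolled)
  num <- c("s_um", "theta_deg", "radial_dist_um", "length_um", "volume_um3")
  df[num] <- lapply(df[num], function(v) formatC(v, digits = 6, format = "g"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
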