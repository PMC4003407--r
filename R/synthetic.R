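#' Parameters for the synthetic spine generator
#'
#' Defaults emulate the spine statistics of an adult human layer III
#' pyramidal dendrite segment: density 1.41 spines/um, lognormal marks
#' calibrated so mean spine length is about 1.4 um and mean spine volume
#' about 0.35 um^3, insertion points at 0.4 um from the shaft axis.
#' The angular structure is either uniform-random around the axis or
#' helical with a given pitch (period) and Gaussian angular jitter.
#'
#' @param dendrite_length Axis length to populate, micrometres.
#' @param density Spines per micrometre of dendrite.
#' @param radial_dist Distance of insertion points from the axis
#'   (shaft-radius proxy), micrometres.
#' @param angle_model `"uniform"` or `"helical"`.
#' @param helix_period Arc length of one full angular turn (helical model
#'   only), micrometres.
#' @param angle_jitter_sd Gaussian jitter of helical angles, degrees.
#' @param length_meanlog,length_sdlog Lognormal parameters of spine length
#'   (um).
#' @param volume_meanlog,volume_sdlog Lognormal parameters of spine volume
#'   (um^3).
#' @param poisson_n If `TRUE` draw the spine count from a Poisson law with
#'   mean `density * length`; by default the count is the deterministic
#'   `round(density * length)` so simulations are exactly reproducible.
#' @param seed Integer seed; every draw comes from one seeded stream in a
#'   fixed order, so equal seeds give byte-identical tables.
#' @return A list of class `generator_params`.
#' @export
generator_params <- function(dendrite_length = 100,
                             density = 1.41,
                             radial_dist = 0.4,
                             angle_model = c("uniform", "helical"),
                             helix_period = 10,
                             angle_jitter_sd = 0,
                             length_meanlog = log(1.4) - 0.6^2 / 2,
                             length_sdlog = 0.6,
                             volume_meanlog = log(0.35) - 0.8^2 / 2,
                             volume_sdlog = 0.8,
                             poisson_n = FALSE,
                             seed = 1L) {
  angle_model <- match.arg(angle_model)
  if (dendrite_length <= 0) stop("dendrite_length must be positive")
  if (density <= 0) stop("density must be positive")
  if (radial_dist <= 0) stop("radial_dist must be positive")
  if (angle_model == "helical" &&
      (is.null(helix_period) || !is.finite(helix_period) || helix_period <= 0))
    stop("helical angle model needs a positive helix_period")
  if (angle_jitter_sd < 0) stop("angle_jitter_sd must be non-negative")
  structure(list(dendrite_length = dendrite_length, density = density,
                 radial_dist = radial_dist, angle_model = angle_model,
                 helix_period = helix_period,
                 angle_jitter_sd = angle_jitter_sd,
                 length_meanlog = length_meanlog, length_sdlog = length_sdlog,
                 volume_meanlog = volume_meanlog, volume_sdlog = volume_sdlog,
                 poisson_n = isTRUE(poisson_n), seed = as.integer(seed)),
            class = "generator_params")
}

#' Generate a test medial axis
#'
#' Produces a straight line, a gentle helix, or a smooth random spline
#' curve, sampled densely enough that the polyline arc length matches the
#' requested length to well within 0.1% (the sampled polyline is rescaled
#' so the total is exact).
#'
#' @param kind `"straight"`, `"helix"` or `"spline"`.
#' @param length Requested total arc length, micrometres, positive.
#' @param seed Integer seed (used by the spline kind).
#' @param n_vertices Number of polyline vertices (>= 100).
#' @return A [medial_axis()] whose total arc length equals `length`.
#' @export
generate_axis <- function(kind = c("straight", "helix", "spline"),
                          length = 100, seed = 1L, n_vertices = 400L) {
  kind <- match.arg(kind)
  if (length <= 0) stop("length must be positive")
  n_vertices <- max(as.integer(n_vertices), 100L)
  pts <- switch(kind,
    straight = cbind(0, 0, seq(0, length, length.out = n_vertices)),
    helix = {
      # radius 3 um, one turn per ~30 um of arc
      radius <- 3
      turns <- length / 30
      tt <- seq(0, 2 * pi * turns, length.out = n_vertices)
      climb <- sqrt((length / (2 * pi * turns))^2 - radius^2)
      cbind(radius * cos(tt), radius * sin(tt), climb * tt)
    },
    spline = {
      old <- get0(".Random.seed", envir = globalenv())
      on.exit(restore_seed(old), add = TRUE)
      set.seed(seed)
      ncp <- 8L
      zc <- seq(0, length, length.out = ncp)
      xc <- cumsum(stats::rnorm(ncp, 0, length / 40)); xc <- xc - xc[1L]
      yc <- cumsum(stats::rnorm(ncp, 0, length / 40)); yc <- yc - yc[1L]
      tt <- seq(0, 1, length.out = n_vertices)
      cbind(stats::spline(seq(0, 1, length.out = ncp), xc, xout = tt)$y,
            stats::spline(seq(0, 1, length.out = ncp), yc, xout = tt)$y,
            stats::spline(seq(0, 1, length.out = ncp), zc, xout = tt)$y)
    })
  ax <- medial_axis(pts)
  medial_axis(pts * (length / axis_length(ax)))
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Generate a synthetic spine table along an axis
#'
#' Draws spine positions uniformly along the axis, angular positions from
#' the chosen model (uniform around the axis, or helical:
#' `theta = (360 s / period + jitter) mod 360`), and lognormal length and
#' volume marks, then reconstructs 3D insertion points at `radial_dist`
#' from the axis in the rotation-minimizing frame at each position. All
#' draws come from one seeded stream in a fixed order (s, theta/jitter,
#' lengths, volumes), so the output is fully reproducible from
#' `params$seed`.
#'
#' @param axis A [medial_axis()] (its total length is used; pair it with
#'   `params$dendrite_length`).
#' @param params A [generator_params()].
#' @param frames Optional precomputed [compute_frames()] result.
#' @return A `spine_table` with ids `s0001`, `s0002`, ... in order of
#'   generation.
#' @export
generate_spines <- function(axis, params, frames = compute_frames(axis)) {
  stopifnot(inherits(axis, "medial_axis"),
            inherits(params, "generator_params"))
  L <- axis_length(axis)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old), add = TRUE)
  set.seed(params$seed)
  n <- if (params$poisson_n) stats::rpois(1L, params$density * L)
       else as.integer(round(params$density * L))
  s <- stats::runif(n, 0, L)
  theta <- if (params$angle_model == "uniform") {
    stats::runif(n, 0, 360)
  } else {
    jit <- if (params$angle_jitter_sd > 0)
      stats::rnorm(n, 0, params$angle_jitter_sd) else numeric(n)
    (360 * s / params$helix_period + jit) %% 360
  }
  len <- stats::rlnorm(n, params$length_meanlog, params$length_sdlog)
  vol <- stats::rlnorm(n, params$volume_meanlog, params$volume_sdlog)
  pts <- matrix(0, n, 3L)
  for (k in seq_len(n)) {
    fr <- frame_at(axis, frames, s[k])
    base <- axis_point_at(axis, s[k])
    th <- theta[k] * pi / 180
    pts[k, ] <- base + params$radial_dist *
      (cos(th) * fr$normal + sin(th) * fr$binormal)
  }
  spine_table(data.frame(
    spine_id = sprintf("s%04d", seq_len(n)),
    x = pts[, 1L], y = pts[, 2L], z = pts[, 3L],
    length_um = len, volume_um3 = vol,
    stringsAsFactors = FALSE))
}
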