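#' Summary statistics of a spine table
#'
#' @param spines A `spine_table`.
#' @param axis_length Axis length in micrometres, positive.
#' @return A list of class `summary_stats` with `n_spines`, `density`
#'   (spines/um), `mean_length` (um) and `mean_volume` (um^3). On an
#'   empty table density is 0 and the means are `NaN`, with a warning.
#' @export
summary_stats <- function(spines, axis_length) {
  if (axis_length <= 0) stop("axis_length must be positive")
  n <- nrow(spines)
  if (n == 0L) {
    warning("empty spine table: means are undefined")
    return(structure(list(n_spines = 0L, density = 0,
                          mean_length = NaN, mean_volume = NaN),
                     class = "summary_stats"))
  }
  structure(list(n_spines = n, density = n / axis_length,
                 mean_length = mean(spines$length_um),
                 mean_volume = mean(spines$volume_um3)),
            class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf(
    "%d spines; density %.2f spines/um; mean length %.2f um; mean volume %.2f um^3\n",
    x$n_spines, x$density, x$mean_length, x$mean_volume))
  invisible(x)
}

new_pattern_test <- function(statistic, p_value, n_permutations, seed,
                             method, ...) {
  structure(list(statistic = statistic, p_value = p_value,
                 n_permutations = n_permutations, seed = seed,
                 method = method, ...),
            class = "pattern_test")
}

#' @export
print.pattern_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, p = %.4g (%d permutations, seed %d)\n",
              x$method, x$statistic, x$p_value, x$n_permutations, x$seed))
  invisible(x)
}

# log-spaced candidate periods between twice the mean inter-spine spacing
# and the axis length
default_period_grid <- function(s, axis_length, n_candidates = 20L) {
  lo <- 2 * axis_length / length(s)
  exp(seq(log(lo), log(axis_length), length.out = n_candidates))
}

#' Permutation test for angular (helical) periodicity
#'
#' Tests whether spine angles wind regularly around the dendrite as a
#' function of arc length — the helical arrangement proposed for Purkinje
#' cell spines — against the random arrangement typical of pyramidal
#' cells. For each candidate period P the phases
#' `(theta - 360 s / P) mod 360` are reduced to their mean resultant
#' length (circular concentration, 1 when all phases coincide); the test
#' statistic is the maximum over the period grid. The null distribution
#' permutes theta against s and applies the same maximization, so the
#' selection over periods does not inflate the test. One-sided: large
#' statistics indicate periodicity. The Monte-Carlo p-value uses the
#' add-one formula `(1 + #{perm >= obs}) / (1 + B)`.
#'
#' @param unrolled An `unrolled_spines` data frame (>= 10 spines).
#' @param n_permutations Number B of permutations. Default 999.
#' @param seed Integer seed for the permutation stream.
#' @param periods Candidate periods (um); default a 20-point log-spaced
#'   grid between twice the mean inter-spine spacing and the axis length.
#' @param axis_length Axis length; defaults to the attribute carried by
#'   `unrolled`, else `max(s)`.
#' @return A `pattern_test` with `statistic`, `p_value`,
#'   `n_permutations`, `seed` and `best_period` (um).
#' @export
angular_periodicity_test <- function(unrolled, n_permutations = 999L,
                                     seed = 1L, periods = NULL,
                                     axis_length = NULL) {
  n <- nrow(unrolled)
  if (n < 10L) stop("insufficient markers: need at least 10 spines")
  if (is.null(axis_length)) {
    axis_length <- attr(unrolled, "axis_length")
    if (is.null(axis_length)) axis_length <- max(unrolled$s_um)
  }
  if (is.null(periods)) {
    periods <- default_period_grid(unrolled$s_um, axis_length)
  }
  deg2rad <- pi / 180
  u <- exp(1i * unrolled$theta_deg * deg2rad)              # n
  W <- exp(-1i * outer(unrolled$s_um, 360 / periods) * deg2rad)  # n x P
  obs <- max(Mod(crossprod(W, u))) / n
  best <- periods[which.max(Mod(crossprod(W, u)))]
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  B <- as.integer(n_permutations)
  U <- vapply(seq_len(B), function(b) u[sample.int(n)],
              complex(n))                                   # n x B
  perm_stats <- apply(Mod(crossprod(W, U)), 2L, max) / n
  p <- (1 + sum(perm_stats >= obs)) / (1 + B)
  new_pattern_test(obs, p, B, as.integer(seed),
                   "angular periodicity (max mean resultant length)",
                   best_period = best, periods = periods)
}

#' Permutation test for clustering of a spine category along the dendrite
#'
#' Formalizes the listening observation that one timbre "often sounds
#' together": among spines of the target category the statistic is the
#' mean distance (in arc length s) to the nearest same-category neighbour.
#' The null redistributes the category labels uniformly over all spines.
#' One-sided: small statistics indicate clustering, so the add-one
#' Monte-Carlo p-value counts permutations at least as extreme in that
#' direction, `(1 + #{perm <= obs}) / (1 + B)`.
#'
#' @param unrolled An `unrolled_spines` data frame.
#' @param category Character vector of category labels, one per spine
#'   (e.g. `length_to_timbre(unrolled$length_um)`).
#' @param target The category tested for clustering (>= 2 spines in it).
#' @param n_permutations Number B of permutations. Default 999.
#' @param seed Integer seed.
#' @return A `pattern_test`.
#' @export
category_clustering_test <- function(unrolled, category, target,
                                     n_permutations = 999L, seed = 1L) {
  stopifnot(length(category) == nrow(unrolled))
  s <- unrolled$s_um
  m <- sum(category == target)
  if (m < 2L) stop("need at least 2 spines in the target category")
  obs <- mean_nn_dist(s[category == target])
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  B <- as.integer(n_permutations)
  perm_stats <- vapply(seq_len(B), function(b) {
    mean_nn_dist(s[sample.int(length(s), m)])
  }, numeric(1))
  p <- (1 + sum(perm_stats <= obs)) / (1 + B)
  new_pattern_test(obs, p, B, as.integer(seed),
                   sprintf("clustering of '%s' (mean nearest-neighbour s-distance)",
                           target))
}

mean_nn_dist <- function(s) {
  s <- sort(s)
  gaps <- diff(s)
  nn <- c(gaps[1L], pmin(gaps[-length(gaps)], gaps[-1L]), gaps[length(gaps)])
  if (length(s) == 2L) nn <- c(gaps, gaps)
  mean(nn)
}
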