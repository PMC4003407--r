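# Independent oracles for the geometry and mapping operations. Each is a
# deliberately naive implementation (dense sampling, brute-force loops,
# small-step transport) kept separate from the package's code paths.

# brute-force cumulative arc length by a plain pairwise-distance loop
oracle_cum_arclength <- function(points) {
  cs <- numeric(nrow(points))
  for (i in 2:nrow(points)) {
    cs[i] <- cs[i - 1] + sqrt(sum((points[i, ] - points[i - 1, ])^2))
  }
  cs
}

# projection oracle: sample the whole polyline at `step` um resolution and
# take the nearest sample
oracle_project <- function(point, axis, step = 1e-4) {
  L <- axis_length(axis)
  sgrid <- seq(0, L, by = step)
  # sample polyline positions at sgrid by vectorized interpolation
  cs <- axis$cum_s
  seg <- findInterval(sgrid, cs, rightmost.closed = TRUE)
  seg <- pmin(seg, nrow(axis$points) - 1L)
  u <- (sgrid - cs[seg]) / (cs[seg + 1L] - cs[seg])
  P <- axis$points[seg, , drop = FALSE] * (1 - u) +
    axis$points[seg + 1L, , drop = FALSE] * u
  d2 <- (P[, 1] - point[1])^2 + (P[, 2] - point[2])^2 + (P[, 3] - point[3])^2
  sgrid[which.min(d2)]
}

# small-step parallel transport of a normal along a refined polyline:
# rotate by the rotation carrying tangent i to tangent i+1
oracle_parallel_transport <- function(points, reference_dir) {
  n <- nrow(points)
  tg <- matrix(0, n, 3)
  seg <- points[-1, , drop = FALSE] - points[-n, , drop = FALSE]
  seg <- seg / sqrt(rowSums(seg^2))
  tg[1, ] <- seg[1, ]; tg[n, ] <- seg[n - 1, ]
  if (n > 2) {
    mid <- seg[-(n - 1), , drop = FALSE] + seg[-1, , drop = FALSE]
    tg[2:(n - 1), ] <- mid / sqrt(rowSums(mid^2))
  }
  cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                             a[3] * b[1] - a[1] * b[3],
                             a[1] * b[2] - a[2] * b[1])
  nor <- matrix(0, n, 3)
  v <- reference_dir - sum(reference_dir * tg[1, ]) * tg[1, ]
  nor[1, ] <- v / sqrt(sum(v^2))
  for (i in 1:(n - 1)) {
    ax <- cross3(tg[i, ], tg[i + 1, ])
    sa <- sqrt(sum(ax^2)); ca <- sum(tg[i, ] * tg[i + 1, ])
    if (sa < 1e-14) {
      nor[i + 1, ] <- nor[i, ]
    } else {
      k <- ax / sa
      ang <- atan2(sa, ca)
      vv <- nor[i, ]
      nor[i + 1, ] <- vv * cos(ang) + cross3(k, vv) * sin(ang) +
        k * sum(k * vv) * (1 - cos(ang))
    }
    # keep exactly orthogonal to the tangent
    nn <- nor[i + 1, ] - sum(nor[i + 1, ] * tg[i + 1, ]) * tg[i + 1, ]
    nor[i + 1, ] <- nn / sqrt(sum(nn^2))
  }
  list(tangent = tg, normal = nor)
}

# linear scan over wedge boundaries (no arithmetic shortcut)
oracle_wedge <- function(theta, n_wedges) {
  bounds <- seq(0, 360, length.out = n_wedges + 1)
  for (w in seq_len(n_wedges)) {
    if (theta >= bounds[w] && theta < bounds[w + 1]) return(w - 1L)
  }
  n_wedges - 1L
}

# random rigid motion (proper rotation + translation)
random_rigid_motion <- function(seed) {
  set.seed(seed)
  A <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(A)
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, tvec = rnorm(3, 0, 10))
}

apply_rigid <- function(pts, motion) {
  sweep(pts %*% t(motion$R), 2, motion$tvec, "+")
}
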