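# Small programmatic fixtures shared across test files.

straight_axis <- function(length = 10, n = 11) {
  medial_axis(cbind(0, 0, seq(0, length, length.out = n)))
}

# spine table on a straight z-axis at given (s, theta, r) cylindrical coords
cylinder_spines <- function(s, theta_deg, r = 1, length_um = 1,
                            volume_um3 = 0.3) {
  th <- theta_deg * pi / 180
  spine_table(data.frame(
    spine_id = sprintf("s%03d", seq_along(s)),
    x = r * cos(th), y = r * sin(th), z = s,
    length_um = rep_len(length_um, length(s)),
    volume_um3 = rep_len(volume_um3, length(s)),
    stringsAsFactors = FALSE))
}

write_swc <- function(points, path, parent_shuffle = FALSE) {
  n <- nrow(points)
  rows <- data.frame(id = seq_len(n), type = 3L,
                     x = points[, 1], y = points[, 2], z = points[, 3],
                     radius = 0.2, parent = c(-1L, seq_len(n - 1L)))
  if (parent_shuffle) rows <- rows[sample.int(n), ]
  writeLines(c("# synthetic unbranched dendrite trace",
               apply(rows, 1, function(r) paste(trimws(format(r, scientific = FALSE)), collapse = " "))),
             path)
  invisible(path)
}
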