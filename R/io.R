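#' Read a dendrite medial axis from an SWC file
#'
#' SWC is the community standard for traced neurite morphologies: seven
#' whitespace-separated columns `id type x y z radius parent`, one node per
#' line, `#` comments. Only a single unbranched path is accepted here; the
#' path is reconstructed by following parent pointers from the root, so the
#' row order of the file is not trusted. Coordinates are taken as
#' micrometres and the radius column is ignored.
#'
#' @param path Path to an SWC file.
#' @return A [medial_axis()] with vertices in root-to-tip order.
#' @export
read_axis_swc <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) < 2L) stop("degenerate axis: fewer than 2 SWC nodes")
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  if (any(nf != 7L)) {
    stop("malformed SWC line ", lineno[which(nf != 7L)[1L]],
         ": expected 7 columns")
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))),
              ncol = 7L, byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(apply(m, 1L, anyNA))[1L]
    stop("malformed SWC line ", lineno[bad], ": non-numeric field")
  }
  id <- as.integer(m[, 1L]); parent <- as.integer(m[, 7L])
  if (anyDuplicated(id)) stop("duplicate SWC node id")
  root <- which(parent == -1L)
  if (length(root) != 1L) stop("axis must have exactly one root node")
  nchildren <- table(factor(parent, levels = id))
  if (any(nchildren > 1L)) stop("axis must be unbranched")
  # walk root -> tip via the child map
  child_of <- match(id, parent)  # row index of the child of each node
  ord <- integer(nrow(m)); ord[1L] <- root
  for (k in seq_len(nrow(m) - 1L)) {
    nxt <- child_of[ord[k]]
    if (is.na(nxt)) stop("SWC parent pointers do not form a single path")
    ord[k + 1L] <- nxt
  }
  medial_axis(m[ord, 3:5, drop = FALSE])
}

#' Read a medial axis from a CSV polyline
#'
#' Expects a header with columns `x,y,z` (micrometres), one vertex per row
#' in root-to-tip order.
#'
#' @param path Path to a CSV file.
#' @return A [medial_axis()].
#' @export
read_axis_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("axis CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(df) < 2L) stop("degenerate axis: fewer than 2 vertices")
  m <- sapply(need, function(cn) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    if (anyNA(v)) stop("non-numeric value in column '", cn, "' at row ",
                       which(is.na(v))[1L])
    v
  })
  medial_axis(m)
}

#' Write a medial axis to CSV
#'
#' Floats are written with 6 significant digits so that write/read
#' round-trips are bit-reproducible at that precision.
#'
#' @param axis A [medial_axis()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_axis_csv <- function(axis, path) {
  stopifnot(inherits(axis, "medial_axis"))
  df <- as.data.frame(axis$points)
  df[] <- lapply(df, function(v) formatC(v, digits = 6, format = "g"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a spine marker table
#'
#' One row per spine: the 3D insertion point where the spine joins the
#' dendritic shaft, plus its morphometric marks. Header
#' `spine_id,x,y,z,length_um,volume_um3` is required; units are micrometres
#' and cubic micrometres.
#'
#' @param path Path to a CSV file.
#' @return A `data.frame` of class `spine_table` with those columns, row
#'   order preserved.
#' @export
read_spine_table <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("spine_id", "x", "y", "z", "length_um", "volume_um3")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("spine CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  for (cn in setdiff(need, "spine_id")) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    if (anyNA(v) && nrow(df) > 0L)
      stop("non-numeric value in column '", cn, "' at row ",
           which(is.na(v))[1L])
    df[[cn]] <- v
  }
  spine_table(df)
}

#' Validate a spine table
#'
#' @param df A data.frame with columns
#'   `spine_id,x,y,z,length_um,volume_um3`.
#' @return The validated table, classed `spine_table`.
#' @export
spine_table <- function(df) {
  need <- c("spine_id", "x", "y", "z", "length_um", "volume_um3")
  stopifnot(all(need %in% names(df)))
  df <- as.data.frame(df)[need]
  df$spine_id <- as.character(df$spine_id)
  if (anyDuplicated(df$spine_id)) {
    stop("duplicate spine_id: ",
         df$spine_id[anyDuplicated(df$spine_id)])
  }
  bad <- df$length_um < 0
  if (any(bad)) stop("negative length_um for spine ",
                     df$spine_id[which(bad)[1L]])
  bad <- df$volume_um3 < 0
  if (any(bad)) stop("negative volume_um3 for spine ",
                     df$spine_id[which(bad)[1L]])
  class(df) <- c("spine_table", "data.frame")
  df
}

#' Write a spine table to CSV
#'
#' @param spines A `spine_table` (see [read_spine_table()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spine_table <- function(spines, path) {
  df <- as.data.frame(spines)
  num <- c("x", "y", "z", "length_um", "volume_um3")
  df[num] <- lapply(df[num], function(v) formatC(v, digits = 6, format = "g"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
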