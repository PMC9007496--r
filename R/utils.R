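# Internal helpers: argument checking and polyline geometry.

stop_config <- function(...) {
  stop(structure(class = c("kymoflux_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_range <- function(...) {
  stop(structure(class = c("kymoflux_range_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_scalar <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_config(name, " must be a finite numeric scalar")
  if (positive && x <= 0)
    stop_config(name, " must be > 0")
  invisible(x)
}

# Vertices are an n x 2 matrix of (row, col) pixel coordinates, 1-based.
as_vertices <- function(path) {
  v <- as.matrix(path)
  if (!is.numeric(v) || ncol(v) != 2L || nrow(v) < 2L)
    stop_config("path must be a numeric matrix of >= 2 (row, col) vertices")
  storage.mode(v) <- "double"
  v
}

# Cumulative arc length (in pixels) at each vertex, starting at 0.
path_cumlen <- function(vertices) {
  d <- sqrt(rowSums(diff(vertices)^2))
  c(0, cumsum(d))
}

# Points on the polyline at arc-length positions s_px (vectorised).
# Returns a length(s) x 2 matrix of (row, col).  s is clamped to the path.
path_point <- function(vertices, s_px) {
  cl <- path_cumlen(vertices)
  total <- cl[length(cl)]
  if (total <= 0) stop_config("path has zero arc length")
  s <- pmin(pmax(s_px, 0), total)
  seg <- findInterval(s, cl, rightmost.closed = TRUE)
  seg <- pmin(pmax(seg, 1L), nrow(vertices) - 1L)
  len <- cl[seg + 1L] - cl[seg]
  frac <- ifelse(len > 0, (s - cl[seg]) / len, 0)
  vertices[seg, , drop = FALSE] +
    (vertices[seg + 1L, , drop = FALSE] - vertices[seg, , drop = FALSE]) * frac
}

# Unit tangents at arc-length positions s_px (taken from the containing
# segment; constant within a segment).
path_tangent <- function(vertices, s_px) {
  cl <- path_cumlen(vertices)
  seg <- findInterval(pmin(pmax(s_px, 0), cl[length(cl)]), cl,
                      rightmost.closed = TRUE)
  seg <- pmin(pmax(seg, 1L), nrow(vertices) - 1L)
  d <- vertices[seg + 1L, , drop = FALSE] - vertices[seg, , drop = FALSE]
  d / sqrt(rowSums(d^2))
}

# For every pixel of a (rows x cols) field, the arc-length (px) of its
# projection onto the polyline and the perpendicular distance (px) to it.
# Used to decide which pixels fall inside the photobleach corridor.
path_pixel_projection <- function(vertices, shape) {
  rows <- shape[1]; cols <- shape[2]
  pr <- rep(seq_len(rows), times = cols)
  pc <- rep(seq_len(cols), each = rows)
  cl <- path_cumlen(vertices)
  best_d2 <- rep(Inf, rows * cols)
  best_s <- rep(0, rows * cols)
  for (k in seq_len(nrow(vertices) - 1L)) {
    a <- vertices[k, ]; b <- vertices[k + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) next
    t <- ((pr - a[1]) * ab[1] + (pc - a[2]) * ab[2]) / len2
    t <- pmin(pmax(t, 0), 1)
    dr <- pr - (a[1] + t * ab[1])
    dc <- pc - (a[2] + t * ab[2])
    d2 <- dr * dr + dc * dc
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_s[upd] <- cl[k] + t[upd] * sqrt(len2)
  }
  list(arc_px = matrix(best_s, rows, cols),
       dist_px = matrix(sqrt(best_d2), rows, cols))
}
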