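# Internal geometry helpers. Physical coordinates are voxel-center positions in
# micrometres: voxel index i (1-based, R convention) maps to (i - 1) * pitch.

#' @importFrom rlang .data abort warn
#' @importFrom stats median quantile rnorm rpois runif sd setNames splinefun fft
#' @importFrom utils head tail
NULL

vox_to_um <- function(idx, pitch) {
  sweep(idx - 1, 2, pitch, `*`)
}

um_to_vox <- function(um, pitch) {
  round(sweep(um, 2, pitch, `/`)) + 1L
}

as_point_matrix <- function(p) {
  if (is.null(dim(p))) matrix(p, ncol = 3) else as.matrix(p)
}

#' Distance from points to a 3-D segment
#'
#' Returns, for each point, the distance to the segment `a`--`b` and the
#' parameter t in [0, 1] of the perpendicular foot (clamped to the segment).
#' @noRd
point_segment_distance <- function(pts, a, b) {
  pts <- as_point_matrix(pts)
  ab <- b - a
  len2 <- sum(ab^2)
  d <- sweep(pts, 2, a, `-`)
  t <- if (len2 <= 0) rep(0, nrow(pts)) else pmin(1, pmax(0, drop(d %*% ab) / len2))
  foot <- outer(t, ab) + rep(a, each = nrow(pts))
  dist <- sqrt(rowSums((pts - foot)^2))
  list(dist = dist, t = t)
}

polyline_lengths <- function(points) {
  if (nrow(points) < 2) return(numeric(0))
  sqrt(rowSums((points[-1, , drop = FALSE] - points[-nrow(points), , drop = FALSE])^2))
}

cumulative_arclength <- function(points) {
  c(0, cumsum(polyline_lengths(points)))
}

#' Sample a smooth interpolating curve through 3-D control points
#'
#' Natural cubic splines in each coordinate against cumulative chord length,
#' resampled at approximately `step_um` spacing.
#' @noRd
sample_spline_curve <- function(control_points, step_um = 0.1) {
  cp <- as_point_matrix(control_points)
  if (nrow(cp) < 2) abort("need at least 2 control points")
  s <- cumulative_arclength(cp)
  if (nrow(cp) == 2) {
    n <- max(2L, ceiling(s[2] / step_um) + 1L)
    t <- seq(0, s[2], length.out = n)
    return(cbind(
      approx_coord(s, cp[, 1], t), approx_coord(s, cp[, 2], t),
      approx_coord(s, cp[, 3], t)
    ))
  }
  fx <- splinefun(s, cp[, 1], method = "natural")
  fy <- splinefun(s, cp[, 2], method = "natural")
  fz <- splinefun(s, cp[, 3], method = "natural")
  t <- seq(0, s[length(s)], by = step_um)
  if (t[length(t)] < s[length(s)]) t <- c(t, s[length(s)])
  cbind(fx(t), fy(t), fz(t))
}

approx_coord <- function(x, y, xout) {
  stats::approx(x, y, xout = xout, rule = 2)$y
}

#' Restore-on-exit seeded RNG scope
#' @noRd
with_seed_restore <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed %% .Machine$integer.max)
  force(code)
}

# Deterministic sub-seed derivation, kept within 32-bit integer range.
derive_seed <- function(seed, offset) {
  (as.numeric(seed) * 1009 + offset) %% 2147483647
}

# 26-connectivity offsets (excluding the zero offset), lexicographic order.
neighbor_offsets_26 <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}
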