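#' Construct a dendritic backbone
#'
#' Ordered centerline polyline with per-point radius and cumulative arc length
#' (starting at 0). The backbone parameterizes the dendrite so that spines can
#' be located by their arc-length position across sessions.
#'
#' @param points_um n x 3 matrix of centerline points (um).
#' @param radius_um Per-point positive radius (um); recycled if scalar.
#' @return A `backbone` object.
#' @export
backbone <- function(points_um, radius_um) {
  points_um <- as_point_matrix(points_um)
  if (nrow(points_um) < 2) abort("backbone needs at least 2 points")
  radius_um <- rep_len(radius_um, nrow(points_um))
  if (any(radius_um <= 0)) abort("radius must be positive")
  cum <- cumulative_arclength(points_um)
  if (any(diff(cum) <= 0)) abort("consecutive backbone points must be distinct")
  structure(
    list(points_um = points_um, radius_um = radius_um, cum_arclength_um = cum),
    class = "backbone"
  )
}

#' @export
print.backbone <- function(x, ...) {
  cat(sprintf(
    "<backbone> %d points, length %.2f um, mean radius %.2f um\n",
    nrow(x$points_um), backbone_length(x), mean(x$radius_um)
  ))
  invisible(x)
}

#' Total arc length of a backbone
#' @param bb A `backbone`.
#' @return Length in um.
#' @export
backbone_length <- function(bb) {
  bb$cum_arclength_um[length(bb$cum_arclength_um)]
}

#' Project points onto a backbone: arc position and lateral offset
#'
#' For each query point, finds the nearest backbone segment (perpendicular
#' foot, clamped to segment ends) and returns the cumulative arc length of
#' the foot point plus the perpendicular (lateral) distance. Ties between
#' segments resolve to the earlier segment.
#'
#' @param bb A `backbone`.
#' @param points One 3-D point or an n x 3 matrix (um).
#' @return Tibble with columns `arc_um` and `lateral_um`, one row per point.
#' @export
arc_position <- function(bb, points) {
  pts <- as_point_matrix(points)
  P <- bb$points_um
  nseg <- nrow(P) - 1L
  best_d <- rep(Inf, nrow(pts))
  best_arc <- rep(0, nrow(pts))
  for (i in seq_len(nseg)) {
    ps <- point_segment_distance(pts, P[i, ], P[i + 1, ])
    seglen <- bb$cum_arclength_um[i + 1] - bb$cum_arclength_um[i]
    better <- ps$dist < best_d - 1e-12
    best_arc[better] <- bb$cum_arclength_um[i] + ps$t[better] * seglen
    best_d[better] <- ps$dist[better]
  }
  tibble::tibble(arc_um = best_arc, lateral_um = best_d)
}

#' Local backbone radius at given arc positions
#' @param bb A `backbone`.
#' @param arc_um Arc positions (um).
#' @return Interpolated radii (um).
#' @export
radius_at_arc <- function(bb, arc_um) {
  stats::approx(bb$cum_arclength_um, bb$radius_um, xout = arc_um, rule = 2)$y
}

#' Point on the backbone centerline at given arc positions
#' @param bb A `backbone`.
#' @param arc_um Arc positions (um).
#' @return n x 3 matrix of centerline points.
#' @export
backbone_point_at_arc <- function(bb, arc_um) {
  centerline_at_arc(bb$points_um, arc_um)$point
}

#' Trace the dendritic backbone between seed points
#'
#' Extracts the centerline of a single unbranched dendritic segment from a
#' stack: a minimum-cost bright path between the seeds on the 26-connected
#' voxel graph (cost = physical step length divided by mean voxel intensity,
#' restricted to voxels above an automatic background threshold), followed by
#' recentering of each path point to the local intensity centroid in its
#' normal plane, smoothing, even resampling, and per-point radius estimation
#' from the half-width at half-maximum of the perpendicular intensity profile.
#'
#' @param stack An `image_stack`.
#' @param seeds 2 (or more, ordered) 3-D points on the dendrite, in um.
#' @param threshold Mask threshold on the smoothed stack; `NULL` estimates
#'   `median + 2.2 * mad` from it.
#' @param resample_um Spacing of the returned centerline points.
#' @param smooth_sigma_vox Gaussian smoothing (voxels) applied before masking
#'   and path search; radius estimation always uses the raw stack.
#' @param min_component_vox Suprathreshold components smaller than this are
#'   treated as noise and removed from the mask.
#' @return A `backbone`.
#' @export
trace_backbone <- function(stack, seeds, threshold = NULL, resample_um = 0.2,
                           smooth_sigma_vox = c(1, 1, 0.6),
                           min_component_vox = 50L) {
  seeds <- as_point_matrix(seeds)
  if (nrow(seeds) < 2) abort("need at least two seed points")
  v <- stack$intensities
  pitch <- stack$voxel_pitch_um
  shape <- dim(v)
  # mask and path costs use a lightly smoothed copy: shot noise cannot then
  # fragment dim (z-straddling) tube sections, and isolated noise voxels
  # rarely exceed the threshold at all
  vs <- if (any(smooth_sigma_vox > 0)) gaussian_blur_3d(v, smooth_sigma_vox) else v
  bg_level <- median(vs)
  if (is.null(threshold)) {
    threshold <- bg_level + 2.2 * max(stats::mad(vs), 1e-6) + 1e-9
  }

  mask <- vs > threshold
  if (!any(mask)) abort("tracing failure: no voxels above the background threshold")
  g <- voxel_graph(vs, mask, pitch)
  # keep only substantial connected structures; residual noise clusters are small
  comp <- igraph::components(g$graph)
  big <- comp$csize[comp$membership] >= min_component_vox
  mask[g$vox_lin[!big]] <- FALSE
  if (!any(mask)) abort("tracing failure: no structure above the background threshold")

  path_vox <- NULL
  for (i in seq_len(nrow(seeds) - 1L)) {
    a <- snap_to_mask(seeds[i, ], mask, pitch, max_um = 1.5)
    b <- snap_to_mask(seeds[i + 1, ], mask, pitch, max_um = 1.5)
    if (is.null(a) || is.null(b)) {
      abort("tracing failure: seed not on a suprathreshold structure")
    }
    va <- match(a, g$vox_lin)
    vb <- match(b, g$vox_lin)
    sp <- suppressWarnings(
      igraph::shortest_paths(g$graph, from = va, to = vb, weights = igraph::E(g$graph)$weight)
    )
    vp <- sp$vpath[[1]]
    if (length(vp) == 0) {
      abort("tracing failure: no bright path connects the seeds above threshold")
    }
    seg <- lin_to_vox(g$vox_lin[as.integer(vp)], shape)
    path_vox <- if (is.null(path_vox)) seg else rbind(path_vox, seg[-1, , drop = FALSE])
  }

  pts <- vox_to_um(path_vox, pitch)
  pts <- recenter_path(pts, vs, pitch, threshold, window_um = 1.2)
  pts <- smooth_polyline(pts, span = 5)
  pts <- resample_polyline(pts, resample_um)
  rad <- estimate_radius_profile(pts, v, pitch, median(v))
  backbone(pts, rad)
}

running_median <- function(x, k) {
  n <- length(x)
  h <- k %/% 2L
  vapply(seq_len(n), function(i) {
    median(x[max(1, i - h):min(n, i + h)])
  }, numeric(1))
}

estimate_background <- function(v) {
  m <- median(v)
  s <- stats::mad(v)
  list(level = m, threshold = m + 3 * max(s, 1e-6) + 1e-9)
}

# Bright-voxel graph: vertices = masked voxels, 26-connectivity, edge weight
# = physical step length / mean endpoint intensity.
voxel_graph <- function(v, mask, pitch) {
  shape <- dim(v)
  lin <- which(mask)
  id_of <- integer(length(v))
  id_of[lin] <- seq_along(lin)
  coords <- lin_to_vox(lin, shape)
  offs <- neighbor_offsets_26()
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (k in seq_len(nrow(offs))) {
    o <- offs[k, ]
    if (o[3] < 0 || (o[3] == 0 && (o[2] < 0 || (o[2] == 0 && o[1] < 0)))) next # each pair once
    nb <- sweep(coords, 2, o, `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= shape[1] & nb[, 2] >= 1 & nb[, 2] <= shape[2] &
      nb[, 3] >= 1 & nb[, 3] <= shape[3]
    nb_lin <- nb[ok, 1] + (nb[ok, 2] - 1) * shape[1] + (nb[ok, 3] - 1) * shape[1] * shape[2]
    tgt <- id_of[nb_lin]
    keep <- tgt > 0
    f <- which(ok)[keep]
    t2 <- tgt[keep]
    step <- sqrt(sum((o * pitch)^2))
    ww <- step / pmax((v[lin[f]] + v[lin[t2]]) / 2, 1e-6)
    from <- c(from, f); to <- c(to, t2); w <- c(w, ww)
  }
  gr <- igraph::make_empty_graph(n = length(lin), directed = FALSE)
  gr <- igraph::add_edges(gr, rbind(from, to))
  igraph::E(gr)$weight <- w
  list(graph = gr, vox_lin = lin)
}

lin_to_vox <- function(lin, shape) {
  lin0 <- lin - 1L
  x <- lin0 %% shape[1]
  y <- (lin0 %/% shape[1]) %% shape[2]
  z <- lin0 %/% (shape[1] * shape[2])
  cbind(x + 1L, y + 1L, z + 1L)
}

# Nearest masked voxel (linear index) within max_um of a physical point.
snap_to_mask <- function(point_um, mask, pitch, max_um = 1.5) {
  shape <- dim(mask)
  ctr <- round(point_um / pitch) + 1
  if (any(ctr < 1) || any(ctr > shape)) return(NULL)
  r_vox <- ceiling(max_um / pitch)
  lo <- pmax(ctr - r_vox, 1); hi <- pmin(ctr + r_vox, shape)
  g <- expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2], z = lo[3]:hi[3])
  lin <- g$x + (g$y - 1) * shape[1] + (g$z - 1) * shape[1] * shape[2]
  cand <- lin[mask[lin]]
  if (length(cand) == 0) return(NULL)
  pc <- vox_to_um(lin_to_vox(cand, shape), pitch)
  d2 <- rowSums(sweep(pc, 2, point_um, `-`)^2)
  if (min(d2) > max_um^2) return(NULL)
  cand[which.min(d2)]
}

# Move each path point to the intensity centroid of its neighborhood,
# projected onto the plane normal to the local tangent.
recenter_path <- function(pts, v, pitch, threshold, window_um = 1.2) {
  n <- nrow(pts)
  if (n < 3) return(pts)
  shape <- dim(v)
  out <- pts
  for (i in seq_len(n)) {
    i0 <- max(1, i - 1); i1 <- min(n, i + 1)
    tg <- pts[i1, ] - pts[i0, ]
    tg <- tg / max(sqrt(sum(tg^2)), 1e-9)
    ctr <- pts[i, ]
    lo <- pmax(floor((ctr - window_um) / pitch) + 1, 1)
    hi <- pmin(ceiling((ctr + window_um) / pitch) + 1, shape)
    g <- expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2], z = lo[3]:hi[3])
    pc <- cbind((g$x - 1) * pitch[1], (g$y - 1) * pitch[2], (g$z - 1) * pitch[3])
    d2 <- rowSums(sweep(pc, 2, ctr, `-`)^2)
    sel <- d2 <= window_um^2
    if (!any(sel)) next
    wt <- v[cbind(g$x[sel], g$y[sel], g$z[sel])] - threshold
    wt <- pmax(wt, 0)
    if (sum(wt) <= 0) next
    cen <- colSums(pc[sel, , drop = FALSE] * wt) / sum(wt)
    disp <- cen - ctr
    disp <- disp - sum(disp * tg) * tg # keep only the normal-plane component
    out[i, ] <- ctr + disp
  }
  out
}

smooth_polyline <- function(pts, span = 5) {
  n <- nrow(pts)
  if (n <= span) return(pts)
  h <- span %/% 2
  out <- pts
  for (i in seq_len(n)) {
    i0 <- max(1, i - h); i1 <- min(n, i + h)
    out[i, ] <- colMeans(pts[i0:i1, , drop = FALSE])
  }
  out
}

resample_polyline <- function(pts, step_um) {
  cum <- cumulative_arclength(pts)
  L <- cum[length(cum)]
  if (L <= step_um) return(pts[c(1, nrow(pts)), , drop = FALSE])
  s <- seq(0, L, by = step_um)
  if (s[length(s)] < L) s <- c(s, L)
  centerline_at_arc(pts, s)$point
}

# Per-point radius: HWHM of the background-subtracted perpendicular intensity
# profile, averaged over two orthogonal normal directions (trilinear sampling).
estimate_radius_profile <- function(pts, v, pitch, background, max_r_um = 2.5) {
  n <- nrow(pts)
  rad <- numeric(n)
  for (i in seq_len(n)) {
    i0 <- max(1, i - 1); i1 <- min(n, i + 1)
    tg <- pts[i1, ] - pts[i0, ]
    tg <- tg / max(sqrt(sum(tg^2)), 1e-9)
    # profile along the two in-plane perpendiculars only: the coarse z pitch
    # and the elongated axial PSF make out-of-plane profiles unusable
    n1 <- c(-tg[2], tg[1], 0)
    if (sqrt(sum(n1^2)) < 1e-6) n1 <- c(1, 0, 0)
    n1 <- n1 / sqrt(sum(n1^2))
    hw <- c(
      hwhm_along(v, pitch, pts[i, ], n1, max_r_um, background),
      hwhm_along(v, pitch, pts[i, ], -n1, max_r_um, background)
    )
    hw <- hw[is.finite(hw)]
    rad[i] <- if (length(hw)) mean(hw) else NA_real_
  }
  med <- median(rad, na.rm = TRUE)
  rad[!is.finite(rad)] <- if (is.finite(med)) med else 0.5
  pmax(rad, 0.05)
}

hwhm_along <- function(v, pitch, origin, dir, max_r_um, background = 0,
                       step_um = 0.05) {
  r <- seq(0, max_r_um, by = step_um)
  pts <- outer(r, dir) + rep(origin, each = length(r))
  prof <- trilinear_sample(v, pts, pitch) - background
  peak <- prof[1]
  if (!is.finite(peak) || peak <= 0) return(NA_real_)
  half <- peak / 2
  below <- which(prof < half)
  if (length(below) == 0) return(NA_real_)
  j <- below[1]
  if (j == 1) return(0)
  # linear interpolation between samples j-1 and j
  f <- (prof[j - 1] - half) / max(prof[j - 1] - prof[j], 1e-12)
  r[j - 1] + f * step_um
}

trilinear_sample <- function(v, pts_um, pitch) {
  shape <- dim(v)
  g <- sweep(pts_um, 2, pitch, `/`) # 0-based continuous voxel coords
  g[, 1] <- pmin(pmax(g[, 1], 0), shape[1] - 1)
  g[, 2] <- pmin(pmax(g[, 2], 0), shape[2] - 1)
  g[, 3] <- pmin(pmax(g[, 3], 0), shape[3] - 1)
  f0 <- floor(g)
  fr <- g - f0
  f0 <- f0 + 1 # to 1-based corner index
  f1 <- pmin(f0 + 1, matrix(shape, nrow(g), 3, byrow = TRUE))
  val <- numeric(nrow(g))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ix <- if (dx == 0) f0[, 1] else f1[, 1]
    iy <- if (dy == 0) f0[, 2] else f1[, 2]
    iz <- if (dz == 0) f0[, 3] else f1[, 3]
    wx <- if (dx == 0) 1 - fr[, 1] else fr[, 1]
    wy <- if (dy == 0) 1 - fr[, 2] else fr[, 2]
    wz <- if (dz == 0) 1 - fr[, 3] else fr[, 3]
    val <- val + wx * wy * wz * v[cbind(ix, iy, iz)]
  }
  val
}

#' Write a backbone (or morphology tree) as SWC text
#'
#' Plain SWC: `index type x y z radius parent`, coordinates in um.
#' @param x A `backbone` or `morph_tree`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(x, path) {
  if (inherits(x, "backbone")) {
    n <- nrow(x$points_um)
    df <- data.frame(
      index = seq_len(n), type = 3L,
      x = x$points_um[, 1], y = x$points_um[, 2], z = x$points_um[, 3],
      radius = x$radius_um, parent = c(-1L, seq_len(n - 1L))
    )
  } else if (inherits(x, "morph_tree")) {
    df <- data.frame(
      index = x$nodes$id, type = x$nodes$type,
      x = x$nodes$x_um, y = x$nodes$y_um, z = x$nodes$z_um,
      radius = x$nodes$radius_um, parent = x$nodes$parent
    )
  } else {
    abort("write_swc expects a backbone or morph_tree")
  }
  lines <- sprintf(
    "%d %d %.6g %.6g %.6g %.6g %d",
    df$index, df$type, df$x, df$y, df$z, df$radius, df$parent
  )
  writeLines(c("# SWC: index type x y z radius parent (um)", lines), path)
  invisible(path)
}

#' Read SWC text into a backbone
#'
#' Assumes an unbranched chain (each node's parent is the previous node).
#' @param path SWC path.
#' @return A `backbone`.
#' @export
read_swc_backbone <- function(path) {
  df <- read_swc_table(path)
  backbone(cbind(df$x, df$y, df$z), df$radius)
}

read_swc_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0) abort(sprintf("empty SWC file: %s", path))
  m <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
  data.frame(
    index = as.integer(m[, 1]), type = as.integer(m[, 2]),
    x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6],
    parent = as.integer(m[, 7])
  )
}
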