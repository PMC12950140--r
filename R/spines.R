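#' Spine detection parameters
#'
#' @param min_protrusion_um Inclusion cutoff on protrusion length; spines must
#'   protrude strictly more than this from the backbone tube surface. The
#'   default 0.72 um corresponds to 4 lateral pixels at 0.18 um pitch.
#' @param max_elevation_deg Inclusion cutoff on the spine-axis elevation above
#'   the xy imaging plane ("primarily parallel to the imaging plane").
#' @param search_radius_um Maximum endpoint-to-backbone distance considered.
#' @param endpoint_prominence Relative prominence threshold: candidates must
#'   exceed background + prominence * (robust max - background).
#' @param background_level Background estimate; `NULL` = from the stack.
#' @param smooth_sigma_vox Gaussian pre-smoothing (voxels) for maxima
#'   detection; stabilizes detection against shot noise.
#' @param tube_margin_um Lateral clearance beyond the local tube radius below
#'   which maxima are treated as shaft, not spine.
#' @param dedupe_arc_um If positive, marks whose endpoint-foot arc falls
#'   within this distance of a brighter mark are dropped as duplicate
#'   detections of one spine. Off (0) by default: on curved dendrites the
#'   perpendicular projection compresses arc spacing and can push two real
#'   neighbors inside any useful threshold.
#' @return A `detection_params` list.
#' @export
detection_params <- function(min_protrusion_um = 0.72,
                             max_elevation_deg = 45,
                             search_radius_um = 3.0,
                             endpoint_prominence = 0.25,
                             background_level = NULL,
                             smooth_sigma_vox = c(1, 1, 1),
                             tube_margin_um = 0.15,
                             dedupe_arc_um = 0) {
  stopifnot(min_protrusion_um > 0, search_radius_um > min_protrusion_um)
  structure(
    list(
      min_protrusion_um = min_protrusion_um,
      max_elevation_deg = max_elevation_deg,
      search_radius_um = search_radius_um,
      endpoint_prominence = endpoint_prominence,
      background_level = background_level,
      smooth_sigma_vox = smooth_sigma_vox,
      tube_margin_um = tube_margin_um,
      dedupe_arc_um = dedupe_arc_um
    ),
    class = "detection_params"
  )
}

#' Detect candidate spine endpoints
#'
#' Automated surrogate for manual endpoint marking: local intensity maxima of
#' the (lightly smoothed) stack that lie outside the backbone tube, within
#' `search_radius_um` of the backbone, and above the prominence threshold.
#' Duplicate maxima within one voxel are merged (brightest kept). Manually
#' annotated endpoints, when supplied, are passed through verbatim with
#' `source = "manual"`.
#'
#' @param stack An `image_stack`.
#' @param bb The `backbone` traced on this stack.
#' @param params A [detection_params()].
#' @param manual Optional tibble/data.frame of manual annotations with columns
#'   `x_um`, `y_um`, `z_um` (and optionally `spine_id`).
#' @return Tibble of candidates: x/y/z_um, intensity, arc_um, lateral_um,
#'   source.
#' @export
detect_endpoints <- function(stack, bb, params = detection_params(),
                             manual = NULL) {
  v <- stack$intensities
  pitch <- stack$voxel_pitch_um
  shape <- dim(v)
  bg <- params$background_level %||% estimate_background(v)$level
  vs <- if (any(params$smooth_sigma_vox > 0)) {
    gaussian_blur_3d(v, params$smooth_sigma_vox)
  } else v
  robust_max <- quantile(vs, 0.999)
  thr <- bg + params$endpoint_prominence * max(robust_max - bg, 1e-9)

  cand_lin <- which(vs > thr)
  out <- tibble::tibble(
    x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
    intensity = numeric(0), arc_um = numeric(0), lateral_um = numeric(0),
    source = character(0)
  )
  if (length(cand_lin) > 0) {
    coords <- lin_to_vox(cand_lin, shape)
    pts <- vox_to_um(coords, pitch)
    pos <- arc_position(bb, pts)
    r_loc <- radius_at_arc(bb, pos$arc_um)
    keep <- pos$lateral_um > r_loc + params$tube_margin_um &
      pos$lateral_um <= params$search_radius_um + r_loc
    cand_lin <- cand_lin[keep]
    if (length(cand_lin) > 0) {
      is_max <- local_maxima(vs, cand_lin)
      cand_lin <- cand_lin[is_max]
    }
    if (length(cand_lin) > 0) {
      coords <- lin_to_vox(cand_lin, shape)
      pts <- vox_to_um(coords, pitch)
      inten <- v[cand_lin]
      merged <- merge_close_points(pts, inten, radius_um = max(pitch))
      pts <- merged$points; inten <- merged$intensity
      # sub-voxel refinement: intensity centroid of the head neighborhood
      # (z especially, where the 1-um pitch otherwise dominates the error);
      # the weight floor sits above the noise so that background voxels in the
      # window cannot drag the centroid toward the window centre
      floor_level <- bg + 1.5 * stats::mad(vs)
      pts <- t(apply(pts, 1, function(p) {
        p <- refine_centroid(vs, pitch, p, floor_level, radius_um = c(0.45, 0.45, 1.3))
        refine_centroid(vs, pitch, p, floor_level, radius_um = c(0.45, 0.45, 1.3))
      }))
      pos <- arc_position(bb, pts)
      out <- tibble::tibble(
        x_um = pts[, 1], y_um = pts[, 2], z_um = pts[, 3],
        intensity = inten, arc_um = pos$arc_um, lateral_um = pos$lateral_um,
        source = "automatic"
      )
    }
  }
  if (!is.null(manual) && nrow(manual) > 0) {
    mpts <- cbind(manual$x_um, manual$y_um, manual$z_um)
    mpos <- arc_position(bb, mpts)
    man <- tibble::tibble(
      x_um = manual$x_um, y_um = manual$y_um, z_um = manual$z_um,
      intensity = trilinear_sample(v, mpts, pitch),
      arc_um = mpos$arc_um, lateral_um = mpos$lateral_um,
      source = "manual"
    )
    out <- dplyr::bind_rows(man, out)
  }
  out
}

# Background-subtracted intensity centroid within an axis-aligned ellipsoid.
refine_centroid <- function(v, pitch, center_um, background, radius_um) {
  shape <- dim(v)
  lo <- pmax(floor((center_um - radius_um) / pitch) + 1, 1)
  hi <- pmin(ceiling((center_um + radius_um) / pitch) + 1, shape)
  if (any(lo > hi)) return(center_um)
  g <- expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2], z = lo[3]:hi[3])
  pc <- cbind((g$x - 1) * pitch[1], (g$y - 1) * pitch[2], (g$z - 1) * pitch[3])
  e <- sweep(sweep(pc, 2, center_um, `-`), 2, radius_um, `/`)
  sel <- rowSums(e^2) <= 1
  if (!any(sel)) return(center_um)
  wt <- pmax(v[cbind(g$x[sel], g$y[sel], g$z[sel])] - background, 0)
  if (sum(wt) <= 0) return(center_um)
  colSums(pc[sel, , drop = FALSE] * wt) / sum(wt)
}

# TRUE where the voxel is >= all of its 26 neighbors (out-of-bounds ignored).
local_maxima <- function(v, lin) {
  shape <- dim(v)
  coords <- lin_to_vox(lin, shape)
  ok <- rep(TRUE, length(lin))
  offs <- neighbor_offsets_26()
  val <- v[lin]
  for (k in seq_len(nrow(offs))) {
    nb <- sweep(coords, 2, offs[k, ], `+`)
    inb <- nb[, 1] >= 1 & nb[, 1] <= shape[1] & nb[, 2] >= 1 & nb[, 2] <= shape[2] &
      nb[, 3] >= 1 & nb[, 3] <= shape[3]
    nb_lin <- nb[inb, 1] + (nb[inb, 2] - 1) * shape[1] + (nb[inb, 3] - 1) * shape[1] * shape[2]
    ok[inb] <- ok[inb] & val[inb] >= v[nb_lin]
  }
  ok
}

merge_close_points <- function(pts, intensity, radius_um) {
  ord <- order(-intensity)
  keep <- logical(nrow(pts))
  for (i in ord) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    d2 <- rowSums(sweep(pts[keep, , drop = FALSE], 2, pts[i, ], `-`)^2)
    if (min(d2) > radius_um^2) keep[i] <- TRUE
  }
  list(points = pts[keep, , drop = FALSE], intensity = intensity[keep])
}

#' Brightest linear path from a spine endpoint to the backbone
#'
#' Among 26-connected voxel paths from the endpoint to any backbone-tube
#' voxel within the search radius, returns one maximizing the minimum
#' intensity along the path (bottleneck criterion); ties are broken by
#' shorter path length (voxel steps), then by lexicographic voxel order
#' during breadth-first expansion.
#'
#' @param stack An `image_stack`.
#' @param endpoint_um 3-D endpoint (um).
#' @param bb A `backbone`.
#' @param search_radius_um Search radius around the endpoint.
#' @return List: `path_vox` (n x 3 voxel indices, endpoint first),
#'   `path_um`, `bottleneck` (minimum intensity on the path), `n_steps`;
#'   or `NULL` if no admissible path exists (a message is logged).
#' @export
brightest_path <- function(stack, endpoint_um, bb, search_radius_um = 3.0) {
  v <- stack$intensities
  pitch <- stack$voxel_pitch_um
  shape <- dim(v)
  ep_vox <- pmin(pmax(round(endpoint_um / pitch) + 1, 1), shape)

  lo <- pmax(floor((endpoint_um - search_radius_um) / pitch) + 1, 1)
  hi <- pmin(ceiling((endpoint_um + search_radius_um) / pitch) + 1, shape)
  g <- expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2], z = lo[3]:hi[3])
  pts <- cbind((g$x - 1) * pitch[1], (g$y - 1) * pitch[2], (g$z - 1) * pitch[3])
  d2 <- rowSums(sweep(pts, 2, endpoint_um, `-`)^2)
  sel <- d2 <= search_radius_um^2
  g <- g[sel, , drop = FALSE]
  pts <- pts[sel, , drop = FALSE]

  pos <- arc_position(bb, pts)
  r_loc <- radius_at_arc(bb, pos$arc_um)
  target <- pos$lateral_um <= r_loc

  lin <- g$x + (g$y - 1) * shape[1] + (g$z - 1) * shape[1] * shape[2]
  start_lin <- ep_vox[1] + (ep_vox[2] - 1) * shape[1] + (ep_vox[3] - 1) * shape[1] * shape[2]
  start <- match(start_lin, lin)
  if (is.na(start)) return(path_failure("endpoint outside search region"))
  if (!any(target)) return(path_failure("no backbone voxel within search radius"))
  if (target[start]) {
    return(list(
      path_vox = matrix(as.integer(ep_vox), 1), path_um = matrix(endpoint_um, 1),
      bottleneck = v[start_lin], n_steps = 0L
    ))
  }

  region <- bfs_region(g, lin, shape)
  inten <- v[lin]

  # binary search on the bottleneck threshold over the region's intensities
  levels <- sort(unique(inten))
  reach <- function(t) {
    adm <- inten >= t
    if (!adm[start]) return(FALSE)
    comp <- flood_from(start, region$nbr, adm)
    any(comp & target)
  }
  lo_i <- 1L; hi_i <- length(levels)
  if (!reach(levels[lo_i])) return(path_failure("endpoint disconnected from backbone"))
  while (lo_i < hi_i) {
    mid <- (lo_i + hi_i + 1L) %/% 2L
    if (reach(levels[mid])) lo_i <- mid else hi_i <- mid - 1L
  }
  tstar <- levels[lo_i]

  # among admissible voxels, the physically shortest path (um, not steps):
  # z steps cost their full 1-um pitch, so in-plane corridors win ties
  adm <- inten >= tstar
  path_idx <- dijkstra_shortest(start, which(target), region$nbr, adm,
                                cbind(g$x, g$y, g$z), pitch, lin)
  if (is.null(path_idx)) return(path_failure("no admissible path"))
  coords <- cbind(g$x[path_idx], g$y[path_idx], g$z[path_idx])
  list(
    path_vox = coords,
    path_um = vox_to_um(coords, pitch),
    bottleneck = tstar,
    n_steps = length(path_idx) - 1L
  )
}

path_failure <- function(reason) {
  message("brightest_path: ", reason, "; endpoint discarded")
  NULL
}

# Precompute neighbor lists (indices into the region) for a voxel subset.
bfs_region <- function(g, lin, shape) {
  n <- nrow(g)
  # map linear voxel index -> region index via binary search on sorted lin
  ord <- order(lin)
  sorted_lin <- lin[ord]
  offs <- neighbor_offsets_26()
  nbr <- vector("list", n)
  for (k in seq_len(nrow(offs))) {
    o <- offs[k, ]
    nb_lin <- (g$x + o[1]) + (g$y + o[2] - 1) * shape[1] + (g$z + o[3] - 1) * shape[1] * shape[2]
    inb <- g$x + o[1] >= 1 & g$x + o[1] <= shape[1] &
      g$y + o[2] >= 1 & g$y + o[2] <= shape[2] &
      g$z + o[3] >= 1 & g$z + o[3] <= shape[3]
    idx <- findInterval(nb_lin, sorted_lin)
    hit <- inb & idx > 0 & sorted_lin[pmax(idx, 1)] == nb_lin
    tgt <- ord[idx[hit]]
    src <- which(hit)
    for (j in seq_along(src)) nbr[[src[j]]] <- c(nbr[[src[j]]], tgt[j])
  }
  # sort each neighbor list by linear voxel index for lexicographic expansion
  for (i in seq_len(n)) if (length(nbr[[i]])) nbr[[i]] <- nbr[[i]][order(lin[nbr[[i]]])]
  list(nbr = nbr)
}

flood_from <- function(start, nbr, adm) {
  n <- length(adm)
  visited <- logical(n)
  visited[start] <- TRUE
  frontier <- start
  while (length(frontier) > 0) {
    nxt <- unique(unlist(nbr[frontier], use.names = FALSE))
    nxt <- nxt[adm[nxt] & !visited[nxt]]
    visited[nxt] <- TRUE
    frontier <- nxt
  }
  visited
}

# Dijkstra over the admissible region voxels with physical step lengths;
# deterministic tie-breaking by linear voxel index.
dijkstra_shortest <- function(start, targets, nbr, adm, coords, pitch, lin) {
  n <- length(adm)
  dist <- rep(Inf, n)
  parent <- integer(n)
  done <- logical(n)
  dist[start] <- 0
  target_set <- logical(n); target_set[targets] <- TRUE
  repeat {
    open <- which(!done & is.finite(dist))
    if (length(open) == 0) return(NULL)
    u <- open[order(dist[open], lin[open])][1]
    if (target_set[u]) break
    done[u] <- TRUE
    for (w in nbr[[u]]) {
      if (!adm[w] || done[w]) next
      step <- sqrt(sum(((coords[w, ] - coords[u, ]) * pitch)^2))
      nd <- dist[u] + step
      if (nd < dist[w] - 1e-12 ||
          (abs(nd - dist[w]) <= 1e-12 && parent[w] > 0 && lin[u] < lin[parent[w]])) {
        dist[w] <- nd
        parent[w] <- u
      }
    }
  }
  path <- u
  while (path[1] != start) path <- c(parent[path[1]], path)
  path
}

#' Build spine marks from endpoints via brightest-path attachment
#'
#' For each candidate endpoint: finds the brightest linear path to the
#' backbone, computes the attachment arc position, the protrusion length
#' (geodesic path length from the endpoint to the backbone tube surface) and
#' the spine-axis elevation above the xy plane.
#'
#' @param stack An `image_stack`.
#' @param bb A `backbone`.
#' @param endpoints Tibble from [detect_endpoints()] (or manual annotations
#'   with x/y/z_um columns).
#' @param params A [detection_params()].
#' @return A `spine_marks` tibble: endpoint coordinates, attachment_arc_um,
#'   protrusion_um, elevation_deg, bottleneck, n_steps, source, included (NA
#'   until [apply_inclusion_filters()]), path (list-column of voxel paths).
#' @export
spine_marks <- function(stack, bb, endpoints, params = detection_params()) {
  # attachment paths are computed on the noise-suppressed image: shot noise
  # otherwise opens sparse bright corridors that inflate the geodesic length
  search_stack <- stack
  if (any(params$smooth_sigma_vox > 0)) {
    search_stack$intensities <- gaussian_blur_3d(stack$intensities,
                                                 params$smooth_sigma_vox)
  }
  rows <- purrr::pmap(
    list(endpoints$x_um, endpoints$y_um, endpoints$z_um,
         endpoints$source %||% rep("automatic", nrow(endpoints))),
    function(x, y, z, src) {
      ep <- c(x, y, z)
      bp <- brightest_path(search_stack, ep, bb, params$search_radius_um)
      if (is.null(bp)) return(NULL)
      geom <- attachment_geometry(bb, ep, bp)
      tibble::tibble(
        x_um = x, y_um = y, z_um = z,
        attachment_arc_um = geom$arc_um,
        protrusion_um = geom$protrusion_um,
        elevation_deg = geom$elevation_deg,
        bottleneck = bp$bottleneck,
        n_steps = bp$n_steps,
        source = src,
        included = NA,
        path = list(bp$path_vox)
      )
    }
  )
  rows <- purrr::compact(rows)
  if (length(rows) > 0 && params$dedupe_arc_um > 0) {
    out <- dplyr::bind_rows(rows)
    # dedupe on the endpoint perpendicular-foot arc (stable even when the
    # attachment path wanders), keeping the brighter of two close marks
    foot <- arc_position(bb, cbind(out$x_um, out$y_um, out$z_um))$arc_um
    keep <- dedupe_marks_by_arc(foot, out$bottleneck, params$dedupe_arc_um)
    rows <- list(out[keep, , drop = FALSE])
  }
  if (length(rows) == 0) {
    return(structure(tibble::tibble(
      x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
      attachment_arc_um = numeric(0), protrusion_um = numeric(0),
      elevation_deg = numeric(0), bottleneck = numeric(0),
      n_steps = integer(0), source = character(0), included = logical(0),
      path = list()
    ), class = c("spine_marks", "tbl_df", "tbl", "data.frame")))
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("spine_marks", class(out))
  out
}

# Greedy arc-proximity deduplication: marks are visited in decreasing
# brightest-path bottleneck order; a mark within `arc_tol` of an already
# kept mark is a duplicate detection of the same spine.
dedupe_marks_by_arc <- function(arcs, bottleneck, arc_tol) {
  keep <- logical(length(arcs))
  for (i in order(-bottleneck)) {
    if (!any(keep) || min(abs(arcs[keep] - arcs[i])) > arc_tol) keep[i] <- TRUE
  }
  keep
}

# Arc position of the tube-surface crossing, protrusion length along the
# path, and spine-axis elevation.
attachment_geometry <- function(bb, endpoint_um, bp) {
  pum <- bp$path_um
  n <- nrow(pum)
  pos <- arc_position(bb, pum)
  r_loc <- radius_at_arc(bb, pos$arc_um)
  off <- pos$lateral_um
  inside <- off <= r_loc
  first_in <- which(inside)[1]
  steps <- if (n > 1) polyline_lengths(pum) else numeric(0)
  cum <- c(0, cumsum(steps))
  if (is.na(first_in)) {
    protrusion <- cum[n]
    arc <- pos$arc_um[n]
    attach_pt <- backbone_point_at_arc(bb, arc)[1, ]
  } else if (first_in == 1) {
    protrusion <- 0
    arc <- pos$arc_um[1]
    attach_pt <- backbone_point_at_arc(bb, arc)[1, ]
  } else {
    o_prev <- off[first_in - 1] - r_loc[first_in - 1]
    o_in <- off[first_in] - r_loc[first_in]
    f <- o_prev / max(o_prev - o_in, 1e-12)
    protrusion <- cum[first_in - 1] + f * steps[first_in - 1]
    arc <- pos$arc_um[first_in - 1] +
      f * (pos$arc_um[first_in] - pos$arc_um[first_in - 1])
    attach_pt <- backbone_point_at_arc(bb, arc)[1, ]
  }
  # the geodesic cannot be shorter than the straight-line distance from the
  # endpoint to the tube surface; enforce this lower bound so a noisy path
  # that clips the tube early cannot underestimate the protrusion
  ep_pos <- arc_position(bb, matrix(endpoint_um, 1))
  lower <- ep_pos$lateral_um - radius_at_arc(bb, ep_pos$arc_um)
  protrusion <- max(protrusion, lower, 0)
  axis <- endpoint_um - attach_pt
  nrm <- sqrt(sum(axis^2))
  elev <- if (nrm < 1e-9) 0 else asin(min(abs(axis[3]) / nrm, 1)) * 180 / pi
  list(arc_um = arc, protrusion_um = protrusion, elevation_deg = elev)
}

#' Apply the inclusion filters to spine marks
#'
#' A spine is included when its protrusion length is strictly greater than
#' `min_protrusion_um` (default 0.72 um = 4 lateral pixels) and its axis is
#' primarily parallel to the imaging plane (elevation at most
#' `max_elevation_deg`). Excluded marks are retained with `included = FALSE`.
#' Idempotent.
#'
#' @param marks A `spine_marks` tibble.
#' @param params A [detection_params()].
#' @return The marks with the `included` flag set.
#' @export
apply_inclusion_filters <- function(marks, params = detection_params()) {
  marks$included <- marks$protrusion_um > params$min_protrusion_um &
    marks$elevation_deg <= params$max_elevation_deg
  marks
}

#' Read manual spine-endpoint annotations
#'
#' CSV with columns session, x_um, y_um, z_um and optionally spine_id.
#' @param path CSV path.
#' @return Tibble of annotations.
#' @export
read_annotations <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    session = readr::col_character(),
    x_um = readr::col_double(),
    y_um = readr::col_double(),
    z_um = readr::col_double(),
    .default = readr::col_guess()
  ))
}
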