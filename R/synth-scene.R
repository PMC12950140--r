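#' Generate a ground-truthed longitudinal dendrite/spine scene
#'
#' Builds the complete description of a simulated multi-session two-photon
#' experiment: a smooth dendritic backbone (single unbranched apical segment,
#' mostly in-plane), a population of spines placed along the backbone with
#' programmed per-session presence (gains and losses between consecutive
#' sessions) and per-session brightness multipliers. The scene is the single
#' source of truth for the simulator ([render_session()]) and for recovery
#' tests: every downstream estimate can be compared against it.
#'
#' Spines are placed on a jittered arc-length grid so that any two spines that
#' ever exist are separated by more than `min_separation_um`; keeping this
#' above the cross-session match tolerance makes the programmed schedule
#' unambiguously recoverable on clean renders.
#'
#' @param n_spines Number of spines present at baseline.
#' @param sessions Ordered unique session labels; first is the baseline.
#' @param losses,gains Integer vectors, one entry per inter-session interval
#'   (`length(sessions) - 1`): spines eliminated / added at each follow-up.
#' @param seed Integer seed; `(params, seed)` fully determine the scene.
#' @param stack_shape_vox Rendered stack dimensions (x, y, z) in voxels.
#' @param voxel_pitch_um Voxel pitch (x, y, z) in micrometres; the default
#'   matches 0.18 um lateral sampling with a 1 um z-step.
#' @param backbone_radius_um Dendritic shaft radius.
#' @param protrusion_range_um Range of programmed protrusion lengths, measured
#'   from the backbone tube surface to the spine endpoint.
#' @param elevation_range_deg Range of spine-axis elevations above the xy
#'   imaging plane (0 = in-plane).
#' @param head_radius_range_um Range of spine head radii.
#' @param brightness Per-session brightness multipliers: `NULL` (all 1),
#'   a vector of length `length(sessions)` applied to every spine, or a
#'   matrix with one row per ever-existing spine. Baseline must be 1.
#' @param min_separation_um Minimum arc-length separation between any two
#'   spines that ever exist.
#' @param amplitude Fluorescence amplitude of the dendritic shaft (arbitrary
#'   units; spine heads render at `amplitude * multiplier`).
#' @param allow_recurrence If `TRUE`, schedules may re-gain a previously lost
#'   spine; off by default.
#'
#' @return A `spine_scene` object: backbone control points, spine table
#'   (a tibble), presence and brightness matrices, rendering geometry, seed.
#' @seealso [render_session()], [export_ground_truth()], [scene_centerline()]
#' @export
#' @examples
#' sc <- make_scene(n_spines = 6, losses = c(1, 0, 1), gains = c(1, 1, 0), seed = 7)
#' colSums(sc$presence)
make_scene <- function(n_spines = 10,
                       sessions = c("BL", "d3", "d7", "d14"),
                       losses = c(1, 1, 1),
                       gains = c(1, 1, 1),
                       seed = 1,
                       stack_shape_vox = c(192, 192, 21),
                       voxel_pitch_um = c(0.18, 0.18, 1.0),
                       backbone_radius_um = 0.5,
                       protrusion_range_um = c(1.0, 2.0),
                       elevation_range_deg = c(0, 30),
                       head_radius_range_um = c(0.4, 0.6),
                       brightness = NULL,
                       min_separation_um = 2.2,
                       amplitude = 100,
                       allow_recurrence = FALSE) {
  stopifnot(n_spines >= 0, length(sessions) >= 2)
  if (anyDuplicated(sessions)) abort("session labels must be unique")
  n_int <- length(sessions) - 1L
  if (length(losses) != n_int || length(gains) != n_int) {
    abort("losses and gains must have one entry per inter-session interval")
  }
  if (any(losses < 0) || any(gains < 0)) abort("losses and gains must be nonnegative")
  if (any(voxel_pitch_um <= 0)) abort("voxel pitch must be strictly positive")

  # Feasibility: losses at each interval cannot exceed spines then present.
  present_now <- n_spines
  for (j in seq_len(n_int)) {
    if (losses[j] > present_now) {
      abort(sprintf(
        "infeasible schedule: interval %d removes %d spines but only %d are present",
        j, losses[j], present_now
      ))
    }
    present_now <- present_now - losses[j] + gains[j]
  }

  with_seed_restore(seed, {
    extent_um <- (stack_shape_vox - 1) * voxel_pitch_um
    margin <- 4.0
    z_mid <- extent_um[3] / 2
    # Gentle in-plane S-curve across the field with a small z excursion,
    # mimicking an apical dendrite segment imaged near-parallel to the plane.
    cp <- rbind(
      c(margin, margin, z_mid - 1),
      c(0.45 * extent_um[1], 0.30 * extent_um[2], z_mid),
      c(0.60 * extent_um[1], 0.70 * extent_um[2], z_mid + 1),
      c(extent_um[1] - margin, extent_um[2] - margin, z_mid)
    )
    centerline <- sample_spline_curve(cp, step_um = 0.1)
    total_len <- cumulative_arclength(centerline)
    total_len <- total_len[length(total_len)]

    n_ever <- n_spines + sum(gains)
    arc_lo <- 2.0
    arc_hi <- total_len - 2.0
    usable <- arc_hi - arc_lo
    if (n_ever > 0 && usable < n_ever * min_separation_um) {
      abort(sprintf(
        "backbone too short: %d spines need %.1f um at %.1f um separation, have %.1f um",
        n_ever, n_ever * min_separation_um, min_separation_um, usable
      ))
    }
    arcs <- numeric(0)
    if (n_ever > 0) {
      arcs <- jittered_grid(n_ever, arc_lo, arc_hi, min_separation_um)
      arcs <- arcs[sample.int(n_ever)] # random id <-> position association
    }

    presence <- matrix(FALSE, nrow = n_ever, ncol = length(sessions),
                       dimnames = list(NULL, sessions))
    if (n_ever > 0) presence[seq_len(n_spines), 1] <- TRUE
    next_new <- n_spines + 1L
    for (j in seq_len(n_int)) {
      presence[, j + 1] <- presence[, j]
      alive <- which(presence[, j])
      if (losses[j] > 0) {
        dead <- alive[sample.int(length(alive), losses[j])]
        presence[dead, j + 1] <- FALSE
      }
      if (gains[j] > 0) {
        pool <- next_new:(next_new + gains[j] - 1L)
        presence[pool, j + 1] <- TRUE
        next_new <- next_new + gains[j]
      }
      if (!allow_recurrence) {
        # spines lost earlier never return: enforced by construction above
      }
    }

    bright <- expand_brightness(brightness, n_ever, sessions)
    bright[!presence] <- NA_real_

    spines <- tibble::tibble(
      spine_id = if (n_ever > 0) sprintf("s%02d", seq_len(n_ever)) else character(0),
      arc_um = arcs,
      protrusion_um = runif(n_ever, protrusion_range_um[1], protrusion_range_um[2]),
      azimuth_deg = runif(n_ever, 0, 360),
      elevation_deg = runif(n_ever, elevation_range_deg[1], elevation_range_deg[2]),
      head_radius_um = runif(n_ever, head_radius_range_um[1], head_radius_range_um[2]),
      side = sample(c(-1, 1), max(n_ever, 1), replace = TRUE)[seq_len(n_ever)]
    )

    structure(
      list(
        backbone_control_points = cp,
        backbone_radius_um = backbone_radius_um,
        sessions = sessions,
        spines = spines,
        presence = presence,
        brightness = bright,
        voxel_pitch_um = voxel_pitch_um,
        stack_shape_vox = as.integer(stack_shape_vox),
        amplitude = amplitude,
        neck_radius_um = 0.16,
        neck_amplitude_frac = 0.8,
        seed = seed,
        schedule = list(losses = losses, gains = gains)
      ),
      class = "spine_scene"
    )
  })
}

# n points in [lo, hi], consecutive gaps > sep, jittered around an even grid.
jittered_grid <- function(n, lo, hi, sep) {
  slot <- (hi - lo) / n
  centers <- lo + (seq_len(n) - 0.5) * slot
  jit <- (slot - sep) / 2
  centers + runif(n, -jit, jit)
}

expand_brightness <- function(brightness, n_ever, sessions) {
  ns <- length(sessions)
  if (is.null(brightness)) {
    m <- matrix(1, nrow = n_ever, ncol = ns)
  } else if (is.matrix(brightness)) {
    if (!all(dim(brightness) == c(n_ever, ns))) {
      abort("brightness matrix must be n_ever_spines x n_sessions")
    }
    m <- brightness
  } else {
    if (length(brightness) != ns) abort("brightness vector must match sessions")
    m <- matrix(rep(brightness, each = max(n_ever, 1)), nrow = max(n_ever, 1))[seq_len(n_ever), , drop = FALSE]
  }
  if (n_ever > 0 && any(!is.na(m[, 1]) & m[, 1] != 1)) {
    abort("baseline brightness multiplier must be 1.0")
  }
  if (any(m[!is.na(m)] <= 0)) abort("brightness multipliers must be positive")
  dimnames(m) <- list(NULL, sessions)
  m
}

#' Densely sampled ground-truth centerline of a scene
#'
#' @param scene A `spine_scene`.
#' @param step_um Sampling step along the curve.
#' @return Matrix of 3-D points (um) tracing the programmed backbone.
#' @export
scene_centerline <- function(scene, step_um = 0.1) {
  sample_spline_curve(scene$backbone_control_points, step_um = step_um)
}

# Point on the centerline at arc position s, with unit tangent.
centerline_at_arc <- function(centerline, s) {
  cum <- cumulative_arclength(centerline)
  s <- pmin(pmax(s, 0), cum[length(cum)])
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i <- pmin(i, nrow(centerline) - 1L)
  seg <- centerline[i + 1, , drop = FALSE] - centerline[i, , drop = FALSE]
  seglen <- sqrt(rowSums(seg^2))
  f <- (s - cum[i]) / pmax(seglen, 1e-12)
  point <- centerline[i, , drop = FALSE] + seg * f
  tangent <- seg / pmax(seglen, 1e-12)
  list(point = point, tangent = tangent)
}

#' Ground-truth spine endpoints of a scene at one session
#'
#' Endpoint = head centre, placed `protrusion_um` beyond the backbone tube
#' surface along the spine axis.
#' @param scene A `spine_scene`.
#' @param session Session label; `NULL` returns all ever-existing spines.
#' @return Tibble: spine_id, endpoint coordinates (um), attachment arc,
#'   protrusion, elevation.
#' @export
scene_spine_endpoints <- function(scene, session = NULL) {
  sp <- scene$spines
  if (nrow(sp) == 0) {
    return(tibble::tibble(
      spine_id = character(0), x_um = numeric(0), y_um = numeric(0),
      z_um = numeric(0), arc_um = numeric(0), protrusion_um = numeric(0),
      elevation_deg = numeric(0)
    ))
  }
  keep <- if (is.null(session)) rep(TRUE, nrow(sp)) else {
    if (!session %in% scene$sessions) abort(sprintf("unknown session label '%s'", session))
    scene$presence[, session]
  }
  cl <- scene_centerline(scene)
  at <- centerline_at_arc(cl, sp$arc_um)
  dirs <- spine_directions(at$tangent, sp$azimuth_deg, sp$elevation_deg, sp$side)
  dist <- scene$backbone_radius_um + sp$protrusion_um
  ep <- at$point + dirs * dist
  tibble::tibble(
    spine_id = sp$spine_id,
    x_um = ep[, 1], y_um = ep[, 2], z_um = ep[, 3],
    arc_um = sp$arc_um, protrusion_um = sp$protrusion_um,
    elevation_deg = sp$elevation_deg
  )[keep, ]
}

# Unit spine-axis directions: perpendicular-ish to the local tangent, rotated
# about it by azimuth, then tilted out of the xy plane by elevation.
spine_directions <- function(tangent, azimuth_deg, elevation_deg, side) {
  n <- nrow(tangent)
  # in-plane normal to the tangent (rotate xy-projection by 90 degrees)
  nx <- -tangent[, 2]
  ny <- tangent[, 1]
  nrm <- sqrt(nx^2 + ny^2)
  nx <- nx / pmax(nrm, 1e-12)
  ny <- ny / pmax(nrm, 1e-12)
  el <- elevation_deg * pi / 180
  dir <- cbind(
    side * nx * cos(el),
    side * ny * cos(el),
    sin(el)
  )
  dir / sqrt(rowSums(dir^2))
}

#' @export
print.spine_scene <- function(x, ...) {
  cat(sprintf(
    "<spine_scene> %d sessions (%s), %d spines ever, backbone r=%.2f um, stack %s vox, seed %s\n",
    length(x$sessions), paste(x$sessions, collapse = ", "), nrow(x$spines),
    x$backbone_radius_um, paste(x$stack_shape_vox, collapse = "x"), format(x$seed)
  ))
  invisible(x)
}

#' Per-spine per-session ground-truth table
#'
#' One row per spine per session in which it is present.
#' @param scene A `spine_scene`.
#' @return Tibble: spine_id, session, arc_um, present, brightness_multiplier.
#' @export
export_ground_truth <- function(scene) {
  sp <- scene$spines
  rows <- tidyr::expand_grid(
    spine_id = sp$spine_id,
    session = scene$sessions
  )
  if (nrow(rows) == 0) {
    return(tibble::tibble(
      spine_id = character(0), session = character(0), arc_um = numeric(0),
      present = logical(0), brightness_multiplier = numeric(0)
    ))
  }
  idx <- cbind(
    match(rows$spine_id, sp$spine_id),
    match(rows$session, scene$sessions)
  )
  rows$arc_um <- sp$arc_um[idx[, 1]]
  rows$present <- scene$presence[idx]
  rows$brightness_multiplier <- scene$brightness[idx]
  dplyr::filter(rows, .data$present)
}

#' Recompute the gain/loss schedule realized by a scene's presence matrix
#'
#' @param scene A `spine_scene`.
#' @return Tibble with one row per inter-session interval: session, n_prev,
#'   gained, lost.
#' @export
scene_schedule <- function(scene) {
  p <- scene$presence
  ns <- length(scene$sessions)
  purrr::map_dfr(seq_len(ns - 1L), function(j) {
    tibble::tibble(
      session = scene$sessions[j + 1],
      n_prev = sum(p[, j]),
      gained = sum(p[, j + 1] & !p[, j]),
      lost = sum(p[, j] & !p[, j + 1])
    )
  })
}
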