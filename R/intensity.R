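#' ROI parameters for spine intensity measurement
#'
#' @param r_spine_um Lateral radius of the spine ROI around the endpoint.
#' @param shaft_halflen_um Arc half-length of the shaft ROI around the
#'   attachment point.
#' @param bg_offset_um Distance from the endpoint, directed away from the
#'   backbone, at which the background ROI is centred.
#' @param z_halfwidth_planes ROIs extend this many z-planes above and below
#'   the optimal (brightest) imaging plane.
#' @return An `roi_params` list.
#' @export
roi_params <- function(r_spine_um = 0.45, shaft_halflen_um = 1.0,
                       bg_offset_um = 3.0, z_halfwidth_planes = 1L) {
  structure(
    list(
      r_spine_um = r_spine_um, shaft_halflen_um = shaft_halflen_um,
      bg_offset_um = bg_offset_um, z_halfwidth_planes = as.integer(z_halfwidth_planes)
    ),
    class = "roi_params"
  )
}

#' Spine, shaft and background ROI intensity for one spine mark
#'
#' Three disjoint 3-D ROIs: the spine ROI is a cylinder (lateral radius
#' `r_spine_um`) around the endpoint spanning the brightest z-plane +/- 1;
#' the shaft ROI is the backbone tube within `shaft_halflen_um` of the
#' attachment arc; the background ROI mirrors the spine ROI displaced away
#' from the backbone into structure-free space. The normalized intensity is
#' `(spine - background) / (shaft - background)`, cancelling session-wise
#' illumination and expression drift.
#'
#' @param stack An `image_stack`.
#' @param mark One row of a `spine_marks` tibble (or a list with `x_um`,
#'   `y_um`, `z_um`, `attachment_arc_um`).
#' @param bb A `backbone`.
#' @param roi An [roi_params()].
#' @param smooth_sigma_vox Gaussian smoothing (voxels) applied before ROI
#'   averaging; suppresses shot noise so that per-spine baseline ratios are
#'   not noise-inflated. Zero disables. The same setting must be used for all
#'   sessions being compared.
#' @return Tibble: spine_mean, shaft_mean, background_mean,
#'   normalized_intensity, session, valid (FALSE if ROIs overlapped or the
#'   shaft did not exceed background).
#' @export
spine_intensity <- function(stack, mark, bb, roi = roi_params(),
                            smooth_sigma_vox = c(0, 0, 0)) {
  if (any(smooth_sigma_vox > 0)) {
    stack$intensities <- gaussian_blur_3d(stack$intensities, smooth_sigma_vox)
  }
  v <- stack$intensities
  pitch <- stack$voxel_pitch_um
  shape <- dim(v)
  ep <- c(mark$x_um, mark$y_um, mark$z_um)

  # optimal imaging plane: the plane of the (sub-voxel) endpoint. Using the
  # endpoint position rather than a per-session brightest-plane argmax keeps
  # the ROI content identical across sessions when two planes are near-equal.
  zc <- min(max(round(ep[3] / pitch[3]) + 1, 1), shape[3])
  zr <- (zc - roi$z_halfwidth_planes):(zc + roi$z_halfwidth_planes)
  zr <- zr[zr >= 1 & zr <= shape[3]]

  spine_idx <- cylinder_voxels(shape, pitch, ep[1:2], roi$r_spine_um, zr)

  arc <- mark$attachment_arc_um
  shaft_idx <- shaft_voxels(shape, pitch, bb, arc, roi$shaft_halflen_um, zr)

  # background: displace the spine ROI radially away from the backbone;
  # fall back to the opposite side if the first candidate touches structure
  attach_pt <- backbone_point_at_arc(bb, arc)[1, ]
  dir2 <- ep[1:2] - attach_pt[1:2]
  nd <- sqrt(sum(dir2^2))
  dir2 <- if (nd < 1e-9) c(1, 0) else dir2 / nd
  bg_idx <- NULL
  for (cand in list(ep[1:2] + dir2 * roi$bg_offset_um,
                    ep[1:2] - dir2 * (roi$bg_offset_um + 2 * nd),
                    ep[1:2] + c(-dir2[2], dir2[1]) * roi$bg_offset_um)) {
    idx <- cylinder_voxels(shape, pitch, cand, roi$r_spine_um, zr)
    if (length(idx) == 0) next
    ctrs <- vox_to_um(lin_to_vox(idx, shape), pitch)
    pos <- arc_position(bb, ctrs)
    clearance <- pos$lateral_um > radius_at_arc(bb, pos$arc_um) + 1.0
    if (all(clearance)) { bg_idx <- idx; break }
  }

  valid <- length(spine_idx) > 0 && length(shaft_idx) > 0 && !is.null(bg_idx)
  if (valid) {
    overlap <- length(intersect(spine_idx, shaft_idx)) > 0 ||
      length(intersect(spine_idx, bg_idx)) > 0 ||
      length(intersect(shaft_idx, bg_idx)) > 0
    if (overlap) valid <- FALSE
  }
  if (!valid) {
    return(tibble::tibble(
      spine_mean = NA_real_, shaft_mean = NA_real_, background_mean = NA_real_,
      normalized_intensity = NA_real_, session = stack$session, valid = FALSE
    ))
  }
  sm <- mean(v[spine_idx]); hm <- mean(v[shaft_idx]); bm <- mean(v[bg_idx])
  norm <- if (hm > bm) (sm - bm) / (hm - bm) else NA_real_
  tibble::tibble(
    spine_mean = sm, shaft_mean = hm, background_mean = bm,
    normalized_intensity = norm, session = stack$session,
    valid = is.finite(norm)
  )
}

best_plane <- function(v, ep, pitch, r_um) {
  shape <- dim(v)
  idx_by_z <- vapply(seq_len(shape[3]), function(z) {
    idx <- cylinder_voxels(shape, pitch, ep[1:2], r_um, z)
    if (length(idx) == 0) return(-Inf)
    mean(v[idx])
  }, numeric(1))
  zc0 <- min(max(round(ep[3] / pitch[3]) + 1, 1), shape[3])
  # restrict to planes near the endpoint so a bright shaft elsewhere cannot win
  near <- max(1, zc0 - 2):min(shape[3], zc0 + 2)
  near[which.max(idx_by_z[near])]
}

cylinder_voxels <- function(shape, pitch, center_xy, r_um, z_planes) {
  lo <- pmax(floor((center_xy - r_um) / pitch[1:2]) + 1, 1)
  hi <- pmin(ceiling((center_xy + r_um) / pitch[1:2]) + 1, shape[1:2])
  if (any(lo > hi) || length(z_planes) == 0) return(integer(0))
  g <- expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2], z = z_planes)
  dx <- (g$x - 1) * pitch[1] - center_xy[1]
  dy <- (g$y - 1) * pitch[2] - center_xy[2]
  sel <- dx^2 + dy^2 <= r_um^2
  (g$x + (g$y - 1) * shape[1] + (g$z - 1) * shape[1] * shape[2])[sel]
}

shaft_voxels <- function(shape, pitch, bb, arc, halflen_um, z_planes) {
  s <- seq(max(0, arc - halflen_um), min(backbone_length(bb), arc + halflen_um),
           by = min(pitch) / 2)
  ctr <- backbone_point_at_arc(bb, s)
  r <- radius_at_arc(bb, s)
  idx <- integer(0)
  for (i in seq_len(nrow(ctr))) {
    idx <- c(idx, cylinder_voxels(shape, pitch, ctr[i, 1:2], r[i], z_planes))
  }
  unique(idx)
}

#' Normalized spine-intensity series across sessions
#'
#' For each track, measures the normalized intensity in every session where
#' the spine is present and expresses it relative to baseline. Following the
#' convention that intensity analysis is restricted to spines identifiable at
#' all time points, tracks missing from any session are dropped by default.
#'
#' @param tracks A `spine_tracks` object.
#' @param marks_by_session Named list of `spine_marks` per session (rows
#'   indexed by `mark_row` of the tracks).
#' @param stacks_by_session Named list of `image_stack`s.
#' @param bb A single `backbone` (applied to every session) or a named list
#'   of per-session backbones in each session's own frame.
#' @param baseline_session Baseline label; default the first session.
#' @param roi An [roi_params()].
#' @param require_all_sessions Drop tracks absent in any session (default);
#'   otherwise only tracks absent at baseline are dropped.
#' @param smooth_sigma_vox Noise-suppression smoothing (voxels) applied once
#'   per session stack before ROI measurement; zero disables.
#' @param shifts_by_session Optional named list of `rigid_shift`s (session ->
#'   reference). When given, every session's ROI is anchored at the track's
#'   baseline endpoint mapped into that session's frame, so ROI content stays
#'   identical across sessions instead of following per-session localization
#'   jitter.
#' @return An `intensity_series` list: `per_track` tibble (track_id, session,
#'   normalized_intensity, value = normalized / baseline), `summary` tibble
#'   (session, mean, sem, n), and `matrix` (tracks x sessions of `value`).
#' @export
intensity_series <- function(tracks, marks_by_session, stacks_by_session, bb,
                             baseline_session = NULL, roi = roi_params(),
                             require_all_sessions = TRUE,
                             smooth_sigma_vox = c(1, 1, 0.5),
                             shifts_by_session = NULL) {
  sessions <- attr(tracks, "sessions")
  bbs <- if (inherits(bb, "backbone")) {
    setNames(rep(list(bb), length(sessions)), sessions)
  } else bb
  if (any(smooth_sigma_vox > 0)) {
    stacks_by_session <- lapply(stacks_by_session, function(st) {
      st$intensities <- gaussian_blur_3d(st$intensities, smooth_sigma_vox)
      st
    })
  }
  baseline_session <- baseline_session %||% sessions[1]
  p <- track_presence(tracks)
  ids <- rownames(p)
  keep <- if (require_all_sessions) rowSums(p) == ncol(p) else p[, baseline_session]
  ids <- ids[keep]

  rows <- purrr::map_dfr(ids, function(id) {
    tr <- tracks[tracks$track_id == as.integer(id), ]
    base_row <- which(tr$session == baseline_session)
    base_mk <- if (length(base_row)) {
      marks_by_session[[baseline_session]][tr$mark_row[base_row], ]
    } else NULL
    purrr::map_dfr(seq_len(nrow(tr)), function(r) {
      s <- tr$session[r]
      mk <- marks_by_session[[s]][tr$mark_row[r], ]
      if (!is.null(shifts_by_session) && !is.null(base_mk)) {
        # anchor the ROI at the baseline endpoint, mapped into this session
        ep <- c(base_mk$x_um, base_mk$y_um, base_mk$z_um) +
          shifts_by_session[[baseline_session]]$translation_um -
          shifts_by_session[[s]]$translation_um
        mk <- list(x_um = ep[1], y_um = ep[2], z_um = ep[3],
                   attachment_arc_um = arc_position(bbs[[s]], ep)$arc_um)
      }
      im <- spine_intensity(stacks_by_session[[s]], mk, bbs[[s]], roi)
      tibble::tibble(
        track_id = as.integer(id), session = s,
        normalized_intensity = im$normalized_intensity, valid = im$valid
      )
    })
  })
  if (nrow(rows) == 0) {
    return(structure(
      list(
        per_track = tibble::tibble(
          track_id = integer(0), session = character(0),
          normalized_intensity = numeric(0), value = numeric(0)
        ),
        summary = tibble::tibble(
          session = character(0), mean = numeric(0), sem = numeric(0),
          n = integer(0)
        ),
        matrix = matrix(numeric(0), 0, length(sessions),
                        dimnames = list(NULL, sessions)),
        baseline_session = baseline_session
      ),
      class = "intensity_series"
    ))
  }
  base <- rows[rows$session == baseline_session,
               c("track_id", "normalized_intensity")]
  names(base)[2] <- "baseline_value"
  rows <- dplyr::left_join(rows, base, by = "track_id")
  rows$value <- rows$normalized_intensity / rows$baseline_value
  rows <- rows[is.finite(rows$value), ]

  summary <- rows |>
    dplyr::group_by(.data$session) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sem = stats::sd(.data$value) / sqrt(dplyr::n()),
      n = dplyr::n(),
      .groups = "drop"
    )
  summary <- summary[order(match(summary$session, sessions)), ]

  uid <- sort(unique(rows$track_id))
  m <- matrix(NA_real_, length(uid), length(sessions),
              dimnames = list(uid, sessions))
  m[cbind(match(rows$track_id, uid), match(rows$session, sessions))] <- rows$value

  structure(
    list(
      per_track = rows[, c("track_id", "session", "normalized_intensity", "value")],
      summary = summary,
      matrix = m,
      baseline_session = baseline_session
    ),
    class = "intensity_series"
  )
}

#' Cumulative distribution of relative intensity values at one session
#'
#' @param series An `intensity_series`.
#' @param session Session label.
#' @return Tibble: value, cumulative_probability (empirical CDF support).
#' @export
intensity_cdf <- function(series, session) {
  x <- sort(series$per_track$value[series$per_track$session == session])
  tibble::tibble(
    value = x,
    cumulative_probability = seq_along(x) / length(x)
  )
}

#' @export
print.intensity_series <- function(x, ...) {
  cat(sprintf("<intensity_series> baseline %s, %d tracks\n",
              x$baseline_session, nrow(x$matrix)))
  print(x$summary)
  invisible(x)
}
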