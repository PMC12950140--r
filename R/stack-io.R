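#' Construct a 3-D image stack
#'
#' Container for one imaging session: a 3-D nonnegative intensity array in
#' `[x, y, z]` order with voxel pitch in micrometres and a session label.
#' Voxel index `i` (1-based) corresponds to physical coordinate
#' `(i - 1) * pitch` um (voxel centres).
#'
#' @param intensities 3-D numeric array, `[x, y, z]`.
#' @param voxel_pitch_um Pitch (x, y, z) in um, strictly positive.
#' @param session Session label.
#' @return An `image_stack` object.
#' @export
image_stack <- function(intensities, voxel_pitch_um = c(0.18, 0.18, 1.0),
                        session = "BL") {
  if (length(dim(intensities)) != 3) abort("intensities must be a 3-D array")
  if (any(dim(intensities) < 1)) abort("each axis needs at least one voxel")
  if (any(voxel_pitch_um <= 0)) abort("voxel pitch must be strictly positive")
  if (any(intensities < 0)) abort("intensities must be nonnegative")
  structure(
    list(
      intensities = intensities,
      voxel_pitch_um = as.numeric(voxel_pitch_um),
      session = as.character(session)
    ),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf(
    "<image_stack> session %s, %dx%dx%d vox @ (%.3g, %.3g, %.3g) um, range [%g, %g]\n",
    x$session, d[1], d[2], d[3], x$voxel_pitch_um[1], x$voxel_pitch_um[2],
    x$voxel_pitch_um[3], min(x$intensities), max(x$intensities)
  ))
  invisible(x)
}

#' Write an image stack as multi-page 16-bit TIFF with a JSON sidecar
#'
#' One TIFF page per z-plane; voxel pitch and session label go to
#' `<path>.meta.json`. Intensities must fit in 16-bit unsigned range.
#'
#' @param stack An `image_stack`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
save_stack <- function(stack, path) {
  v <- stack$intensities
  if (max(v) > 65535) abort("intensities exceed 16-bit range")
  pages <- lapply(seq_len(dim(v)[3]), function(z) {
    # TIFF pages are row-major images: rows = y, cols = x
    t(v[, , z]) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none",
                  reduce = FALSE)
  meta <- list(
    voxel_pitch_um = stack$voxel_pitch_um,
    session = stack$session,
    shape_vox = dim(v),
    axes = "xyz"
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".meta.json")

#' Load an image stack written by [save_stack()]
#'
#' @param path TIFF path; `<path>.meta.json` must exist alongside.
#' @return An `image_stack` with intensities bitwise equal to those saved.
#' @export
load_stack <- function(path) {
  if (!file.exists(path)) abort(sprintf("stack file not found: %s", path))
  sc <- sidecar_path(path)
  if (!file.exists(sc)) {
    abort(sprintf("missing metadata sidecar '%s' (voxel pitch unknown)", sc))
  }
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (is.null(meta$voxel_pitch_um)) {
    abort(sprintf("sidecar '%s' lacks voxel_pitch_um", sc))
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  vol <- array(0, dim = c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages)))
  for (z in seq_along(pages)) vol[, , z] <- t(pages[[z]])
  vol <- round(vol * 65535)
  image_stack(vol, voxel_pitch_um = as.numeric(meta$voxel_pitch_um),
              session = meta$session %||% "unknown")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write ground truth to CSV
#' @param scene A `spine_scene`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(scene, path) {
  readr::write_csv(export_ground_truth(scene), path)
  invisible(path)
}

#' Read a ground-truth CSV written by [write_ground_truth()]
#' @param path CSV path.
#' @return Tibble with the per-spine per-session truth rows.
#' @export
read_ground_truth <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    spine_id = readr::col_character(),
    session = readr::col_character(),
    arc_um = readr::col_double(),
    present = readr::col_logical(),
    brightness_multiplier = readr::col_double()
  ))
}
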