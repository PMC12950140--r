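#' Rigid translation registration between two sessions
#'
#' Finds the integer-voxel translation by regularized phase correlation of
#' the mean-subtracted, noise-suppressed stacks (computed via FFT), then
#' refines each axis to sub-voxel precision by parabolic interpolation of the
#' correlation peak. Rotation is assumed negligible (head-plate-fixed
#' imaging); the recovered translation maps `moving` into the frame of
#' `reference`: a structure at position p um in `moving` sits at
#' `p + translation_um` in `reference`.
#'
#' @param reference,moving `image_stack`s with identical shapes and pitch.
#' @param max_shift_frac Search range per axis as a fraction of the field.
#' @param score_floor Pearson-correlation floor below which the result is
#'   flagged low-confidence (a warning is emitted; the pipeline continues).
#' @param smooth_sigma_vox Gaussian smoothing (voxels) applied to both stacks
#'   before correlation; zero disables.
#' @return A `rigid_shift`: `translation_um`, `translation_vox`, `score` in
#'   [-1, 1], `low_confidence` flag.
#' @export
register_sessions <- function(reference, moving, max_shift_frac = 0.25,
                              score_floor = 0.2,
                              smooth_sigma_vox = c(1, 1, 0.6)) {
  a <- reference$intensities
  b <- moving$intensities
  if (!all(dim(a) == dim(b))) abort("stacks must have identical shapes")
  pitch <- reference$voxel_pitch_um
  d <- dim(a)
  # correlate noise-suppressed copies: independent per-voxel noise otherwise
  # dilutes the Pearson score of a sparse structure toward zero
  if (any(smooth_sigma_vox > 0)) {
    a <- gaussian_blur_3d(a, smooth_sigma_vox)
    b <- gaussian_blur_3d(b, smooth_sigma_vox)
  }

  fa <- fft(a - mean(a))
  fb <- fft(b - mean(b))
  # regularized phase correlation: whitening the cross-spectrum turns the
  # broad autocorrelation ridge of line-like structures (a dendrite slides
  # along itself almost freely) into a sharp localized peak
  x <- fa * Conj(fb)
  cc <- Re(fft(x / (Mod(x) + 1e-3 * max(Mod(x))), inverse = TRUE)) / length(a)

  # circular lag k along an axis corresponds to signed shift of moving by
  # +s voxels where s in (-d/2, d/2]
  max_shift <- pmax(1, floor(d * max_shift_frac))
  lags <- lapply(1:3, function(ax) signed_lags(d[ax]))
  allowed <- array(TRUE, dim = d)
  for (ax in 1:3) {
    ok <- abs(lags[[ax]]) <= max_shift[ax]
    idx <- rep(FALSE, d[ax]); idx[ok] <- TRUE
    allowed <- sweep_keep(allowed, idx, ax)
  }
  cc_masked <- cc
  cc_masked[!allowed] <- -Inf
  peak <- arrayInd(which.max(cc_masked), d)[1, ]
  shift_vox <- c(lags[[1]][peak[1]], lags[[2]][peak[2]], lags[[3]][peak[3]])
  # peak prominence over the lag field: genuine structure produces a peak far
  # above the other lags, while a pure-noise pair peaks only through the
  # maximum over thousands of lags
  ccv <- cc[allowed]
  peak_z <- (max(ccv) - median(ccv)) / max(stats::mad(ccv), 1e-12)

  # sub-voxel parabola per axis around the peak
  sub <- numeric(3)
  for (ax in 1:3) {
    im <- peak; ip <- peak
    im[ax] <- wrap_index(peak[ax] - 1L, d[ax])
    ip[ax] <- wrap_index(peak[ax] + 1L, d[ax])
    ym <- cc[matrix(im, 1)]; y0 <- cc[matrix(peak, 1)]; yp <- cc[matrix(ip, 1)]
    den <- ym - 2 * y0 + yp
    sub[ax] <- if (is.finite(den) && abs(den) > 1e-12) {
      max(min(0.5 * (ym - yp) / den, 0.5), -0.5)
    } else 0
  }

  score <- overlap_correlation(a, b, shift_vox)
  low <- !is.finite(score) || score < score_floor || peak_z < 8
  if (low) {
    warn(sprintf(
      "registration low-confidence: score %.3f (floor %.3f), peak z %.1f",
      ifelse(is.finite(score), score, NA), score_floor, peak_z
    ))
  }
  structure(
    list(
      translation_vox = shift_vox + sub,
      translation_um = (shift_vox + sub) * pitch,
      score = if (is.finite(score)) score else 0,
      peak_z = peak_z,
      low_confidence = low
    ),
    class = "rigid_shift"
  )
}

signed_lags <- function(n) {
  k <- 0:(n - 1)
  ifelse(k <= n / 2, k, k - n)
}

wrap_index <- function(i, n) ((i - 1) %% n) + 1L

sweep_keep <- function(arr, keep, axis) {
  d <- dim(arr)
  idx <- lapply(d, seq_len)
  idx[[axis]] <- which(!keep)
  if (length(idx[[axis]]) > 0) {
    arr[idx[[1]], idx[[2]], idx[[3]]] <- FALSE
  }
  arr
}

# Pearson correlation on the overlap after shifting `b` by integer voxels.
overlap_correlation <- function(a, b, shift_vox) {
  d <- dim(a)
  s <- round(shift_vox)
  # voxel (i) of b maps to (i + s) of a
  a_lo <- pmax(1, 1 + s); a_hi <- pmin(d, d + s)
  if (any(a_lo > a_hi)) return(NA_real_)
  b_lo <- a_lo - s; b_hi <- a_hi - s
  av <- a[a_lo[1]:a_hi[1], a_lo[2]:a_hi[2], a_lo[3]:a_hi[3]]
  bv <- b[b_lo[1]:b_hi[1], b_lo[2]:b_hi[2], b_lo[3]:b_hi[3]]
  if (sd(av) == 0 || sd(bv) == 0) return(NA_real_)
  stats::cor(as.vector(av), as.vector(bv))
}

#' Apply a rigid shift to points
#'
#' Maps points from the moving frame into the reference frame.
#' @param shift A `rigid_shift`.
#' @param points_um One 3-D point or an n x 3 matrix (um).
#' @return Shifted points, same shape.
#' @export
apply_shift <- function(shift, points_um) {
  pts <- as_point_matrix(points_um)
  sweep(pts, 2, shift$translation_um, `+`)
}

#' @export
print.rigid_shift <- function(x, ...) {
  cat(sprintf(
    "<rigid_shift> (%.2f, %.2f, %.2f) um, score %.3f%s\n",
    x$translation_um[1], x$translation_um[2], x$translation_um[3], x$score,
    if (x$low_confidence) " [LOW CONFIDENCE]" else ""
  ))
  invisible(x)
}
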