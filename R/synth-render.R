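#' Acquisition noise model for rendered stacks
#'
#' A simple, standard forward model for two-photon acquisition: the clean
#' structure render is blurred with an anisotropic Gaussian PSF, offset by a
#' constant background, corrupted by photon-counting (Poisson) shot noise and
#' additive Gaussian read noise, then quantized to 16-bit counts.
#'
#' @param background_offset Constant background level (counts).
#' @param psf_sigma_um Gaussian PSF sigma per axis (x, y, z) in um; zeros
#'   disable blurring.
#' @param shot_noise If `TRUE`, each voxel is Poisson-resampled.
#' @param gaussian_read_sigma Additive Gaussian read-noise sigma (counts).
#' @return A `noise_model` list.
#' @export
noise_model <- function(background_offset = 10,
                        psf_sigma_um = c(0.25, 0.25, 0.9),
                        shot_noise = TRUE,
                        gaussian_read_sigma = 5) {
  stopifnot(background_offset >= 0, all(psf_sigma_um >= 0), gaussian_read_sigma >= 0)
  structure(
    list(
      background_offset = background_offset,
      psf_sigma_um = psf_sigma_um,
      shot_noise = isTRUE(shot_noise),
      gaussian_read_sigma = gaussian_read_sigma
    ),
    class = "noise_model"
  )
}

#' Noise-free, blur-free render settings
#' @param background_offset Constant background level (counts), default 0.
#' @return A `noise_model` with PSF, shot and read noise disabled.
#' @export
clean_noise_model <- function(background_offset = 0) {
  noise_model(
    background_offset = background_offset, psf_sigma_um = c(0, 0, 0),
    shot_noise = FALSE, gaussian_read_sigma = 0
  )
}

#' Approximate structure signal-to-noise ratio of a render configuration
#'
#' SNR = structure amplitude / noise standard deviation at structure level
#' (shot variance amplitude + background, plus read variance).
#' @param scene A `spine_scene`.
#' @param noise A `noise_model`.
#' @return Scalar SNR (Inf for clean renders).
#' @export
render_snr <- function(scene, noise) {
  v <- 0
  if (noise$shot_noise) v <- v + scene$amplitude + noise$background_offset
  v <- v + noise$gaussian_read_sigma^2
  if (v == 0) return(Inf)
  scene$amplitude / sqrt(v)
}

#' Render one session of a scene into a 3-D image stack
#'
#' The dendrite is rasterized as a tube of the programmed radius along the
#' backbone; each spine present in the session is rendered as a thin neck from
#' the tube surface to the head centre plus a spherical head, with intensities
#' scaled by the session's brightness multiplier. Noise is then applied per
#' the noise model. Rendering is deterministic given the scene seed and
#' session.
#'
#' @param scene A `spine_scene`.
#' @param session Session label present in `scene$sessions`.
#' @param noise A `noise_model`; default is the standard noisy model.
#' @return An [image_stack()].
#' @export
render_session <- function(scene, session, noise = noise_model()) {
  if (!session %in% scene$sessions) {
    abort(sprintf("unknown session label '%s'", session))
  }
  si <- match(session, scene$sessions)
  shape <- scene$stack_shape_vox
  pitch <- scene$voxel_pitch_um
  vol <- array(0, dim = shape)

  cl <- scene_centerline(scene, step_um = 0.25)
  vol <- rasterize_polyline_tube(vol, cl, scene$backbone_radius_um,
                                 scene$amplitude, pitch)

  sp <- scene$spines
  present <- if (nrow(sp) > 0) scene$presence[, si] else logical(0)
  if (any(present)) {
    cl_fine <- scene_centerline(scene, step_um = 0.1)
    at <- centerline_at_arc(cl_fine, sp$arc_um)
    dirs <- spine_directions(at$tangent, sp$azimuth_deg, sp$elevation_deg, sp$side)
    for (k in which(present)) {
      mult <- scene$brightness[k, si]
      base <- at$point[k, ]
      surface <- base + dirs[k, ] * scene$backbone_radius_um
      headc <- base + dirs[k, ] * (scene$backbone_radius_um + sp$protrusion_um[k])
      amp <- scene$amplitude * mult
      vol <- rasterize_polyline_tube(
        vol, rbind(base, headc), scene$neck_radius_um,
        amp * scene$neck_amplitude_frac, pitch
      )
      vol <- rasterize_ball(vol, headc, sp$head_radius_um[k], amp, pitch)
    }
  }

  if (any(noise$psf_sigma_um > 0)) {
    vol <- gaussian_blur_3d(vol, noise$psf_sigma_um / pitch)
  }
  vol <- vol + noise$background_offset
  if (noise$shot_noise || noise$gaussian_read_sigma > 0) {
    with_seed_restore(derive_seed(scene$seed, 131 * si), {
      if (noise$shot_noise) {
        vol[] <- rpois(length(vol), lambda = pmax(vol, 0))
      }
      if (noise$gaussian_read_sigma > 0) {
        vol <- vol + rnorm(length(vol), 0, noise$gaussian_read_sigma)
      }
    })
  }
  vol <- round(pmin(pmax(vol, 0), 65535))
  image_stack(vol, voxel_pitch_um = pitch, session = session)
}

# Sub-voxel sample offsets (um) for partial-volume rasterization: a 3 x 3 x 5
# grid inside one voxel; z gets the most samples because the 1-um z pitch is
# far coarser than the rendered structures.
subvoxel_offsets <- function(pitch) {
  as.matrix(expand.grid(
    dx = c(-1, 0, 1) / 3 * pitch[1],
    dy = c(-1, 0, 1) / 3 * pitch[2],
    dz = c(-2, -1, 0, 1, 2) / 5 * pitch[3]
  ))
}

# Add a capsule (segment with radius; a == b gives a ball) of constant
# amplitude. Each voxel receives amplitude * (occupied volume fraction),
# estimated by sub-voxel supersampling; overlapping structures combine by max.
# Partial-volume weighting matters: at a 1-um z step structures routinely
# straddle planes, and a voxel-centre-inside test would mis-render them.
rasterize_capsule <- function(vol, a, b, radius_um, amplitude, pitch,
                              offsets = subvoxel_offsets(pitch)) {
  shape <- dim(vol)
  lo <- pmin(a, b) - radius_um - pitch / 2
  hi <- pmax(a, b) + radius_um + pitch / 2
  ilo <- pmax(floor(lo / pitch) + 1, 1)
  ihi <- pmin(ceiling(hi / pitch) + 1, shape)
  if (any(ilo > ihi)) return(vol)
  g <- expand.grid(x = ilo[1]:ihi[1], y = ilo[2]:ihi[2], z = ilo[3]:ihi[3])
  ctr <- cbind((g$x - 1) * pitch[1], (g$y - 1) * pitch[2], (g$z - 1) * pitch[3])
  nvox <- nrow(ctr)
  nsub <- nrow(offsets)
  pts <- ctr[rep(seq_len(nvox), times = nsub), , drop = FALSE] +
    offsets[rep(seq_len(nsub), each = nvox), , drop = FALSE]
  inside <- point_segment_distance(pts, a, b)$dist <= radius_um
  frac <- rowMeans(matrix(inside, nrow = nvox))
  hit <- frac > 0
  if (!any(hit)) return(vol)
  idx_lin <- (g$x + (g$y - 1) * shape[1] + (g$z - 1) * shape[1] * shape[2])[hit]
  vol[idx_lin] <- pmax(vol[idx_lin], amplitude * frac[hit])
  vol
}

rasterize_polyline_tube <- function(vol, polyline, radius_um, amplitude, pitch) {
  n <- nrow(polyline)
  if (n < 2) return(vol)
  offsets <- subvoxel_offsets(pitch)
  for (i in seq_len(n - 1L)) {
    vol <- rasterize_capsule(vol, polyline[i, ], polyline[i + 1, ], radius_um,
                             amplitude, pitch, offsets)
  }
  vol
}

rasterize_ball <- function(vol, center, radius_um, amplitude, pitch) {
  rasterize_capsule(vol, center, center, radius_um, amplitude, pitch)
}

# Separable Gaussian blur with edge renormalization (the kernel mass falling
# outside the volume is compensated, so flat fields stay flat at the borders);
# sigma given in voxels per axis.
gaussian_blur_3d <- function(vol, sigma_vox) {
  norm <- array(1, dim = dim(vol))
  blurred <- vol
  any_blur <- FALSE
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    any_blur <- TRUE
    r <- max(1L, ceiling(3 * s))
    k <- exp(-(-r:r)^2 / (2 * s^2))
    k <- k / sum(k)
    blurred <- convolve_axis(blurred, k, ax)
    norm <- convolve_axis(norm, k, ax)
  }
  if (!any_blur) return(vol)
  blurred / norm
}

convolve_axis <- function(vol, kernel, axis) {
  d <- dim(vol)
  r <- (length(kernel) - 1L) / 2L
  out <- array(0, dim = d)
  for (j in seq_along(kernel)) {
    off <- j - r - 1L
    src <- shift_array(vol, off, axis)
    out <- out + kernel[j] * src
  }
  out
}

# Shift along one axis with zero padding (off > 0 moves content toward higher
# indices by -off... defined so that out[i] uses vol[i + off]).
shift_array <- function(vol, off, axis) {
  if (off == 0) return(vol)
  d <- dim(vol)
  idx <- lapply(d, seq_len)
  src <- idx
  n <- d[axis]
  take <- seq_len(n) + off
  valid <- take >= 1 & take <= n
  out <- array(0, dim = d)
  dst <- idx; dst[[axis]] <- which(valid)
  src[[axis]] <- take[valid]
  out[dst[[1]], dst[[2]], dst[[3]]] <- vol[src[[1]], src[[2]], src[[3]]]
  out
}
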