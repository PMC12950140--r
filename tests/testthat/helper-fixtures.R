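# Shared fixtures. Heavy objects are built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Clean straight tube along x, axis on voxel centres, for tracing geometry.
straight_tube_stack <- function(radius_um = 0.5, amplitude = 100,
                                shape = c(96, 41, 11),
                                pitch = c(0.18, 0.18, 1.0)) {
  vol <- array(0, dim = shape)
  axis_y <- (21 - 1) * pitch[2]
  axis_z <- (6 - 1) * pitch[3]
  a <- c(1 * pitch[1], axis_y, axis_z)
  b <- c((shape[1] - 2) * pitch[1], axis_y, axis_z)
  vol <- spinedyn:::rasterize_capsule(vol, a, b, radius_um, amplitude, pitch)
  image_stack(vol, voxel_pitch_um = pitch, session = "BL")
}

# A small toy stack + backbone for brightest-path semantics: 5 x 5 x 3 grid,
# unit pitch, backbone along x at y = 0 in the middle z plane.
toy_path_setup <- function(vol) {
  stopifnot(all(dim(vol) == c(5, 5, 3)))
  st <- image_stack(vol, voxel_pitch_um = c(1, 1, 1), session = "toy")
  bb <- backbone(rbind(c(0, 0, 1), c(4, 0, 1)), radius_um = 0.45)
  list(stack = st, backbone = bb)
}

toy_tube_lin <- function() {
  # linear indices of the toy backbone tube voxels: y = 1 (0 um), z plane 2
  x <- 1:5
  x + (1 - 1) * 5 + (2 - 1) * 25
}

# Default noisy study-condition scene + BL render + traced backbone (cached).
noisy_scene_fixture <- function(seed = 3) {
  fixture(paste0("noisy_", seed), function() {
    sc <- make_scene(seed = seed)
    st <- render_session(sc, "BL", noise_model())
    cl <- scene_centerline(sc)
    bb <- trace_backbone(st, rbind(cl[1, ], cl[nrow(cl), ]))
    list(scene = sc, stack = st, backbone = bb, centerline = cl)
  })
}

clean_scene_fixture <- function(seed = 3) {
  fixture(paste0("clean_", seed), function() {
    sc <- make_scene(seed = seed)
    st <- render_session(sc, "BL", clean_noise_model())
    cl <- scene_centerline(sc)
    bb <- trace_backbone(st, rbind(cl[1, ], cl[nrow(cl), ]))
    list(scene = sc, stack = st, backbone = bb, centerline = cl)
  })
}

# Match detections to ground truth within tol; returns precision/recall.
detection_pr <- function(detected, truth, tol_um = 0.5) {
  if (nrow(detected) == 0) {
    return(c(precision = NA_real_, recall = 0, tp = 0,
             fp = 0, fn = nrow(truth)))
  }
  d <- outer(seq_len(nrow(detected)), seq_len(nrow(truth)),
             Vectorize(function(i, j) {
               sqrt((detected$x_um[i] - truth$x_um[j])^2 +
                      (detected$y_um[i] - truth$y_um[j])^2 +
                      (detected$z_um[i] - truth$z_um[j])^2)
             }))
  tp <- sum(apply(d, 2, min) < tol_um)
  fp <- sum(apply(d, 1, min) >= tol_um)
  c(precision = (nrow(detected) - fp) / nrow(detected),
    recall = tp / nrow(truth), tp = tp, fp = fp, fn = nrow(truth) - tp)
}
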