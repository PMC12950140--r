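test_that("two corridors of unequal brightness: the brighter one is chosen", {
  vol <- array(1, dim = c(5, 5, 3))
  vol[1:5, 1, 2] <- 90 # backbone tube at y = 1, middle z plane
  # corridor A (bright, 80): straight down column x = 3
  vol[3, 2:4, 2] <- 80
  # corridor B (dim, 40): via column x = 5
  vol[5, 2:4, 2] <- 40
  vol[4, 4, 2] <- 40
  vol[3, 5, 2] <- 100 # endpoint
  tp <- toy_path_setup(vol)
  res <- brightest_path(tp$stack, c(2, 4, 1), tp$backbone, search_radius_um = 6)
  expect_equal(res$bottleneck, 80)
  # path stays in the bright corridor (x = 3 column)
  expect_true(all(res$path_vox[, 1] == 3))
})

test_that("bottleneck value matches exhaustive simple-path enumeration (5x5x1)", {
  tube <- toy_tube_lin()
  for (seed in 1:12) {
    set.seed(seed)
    vol <- array(0, dim = c(5, 5, 3))
    vol[, , 2] <- matrix(sample(1:99, 25, replace = TRUE), 5, 5)
    tp <- toy_path_setup(vol)
    start_um <- c(2, 4, 1) # voxel (3, 5, 2)
    res <- brightest_path(tp$stack, start_um, tp$backbone, search_radius_um = 8)
    start_lin <- 3 + (5 - 1) * 5 + (2 - 1) * 25
    want <- oracle_bottleneck_dfs(vol, start_lin, tube)
    expect_equal(res$bottleneck, want, info = paste("seed", seed))
  }
})

test_that("bottleneck matches threshold-scan oracle on random 5x5x3 grids", {
  tube <- toy_tube_lin()
  for (seed in 1:50) {
    set.seed(100 + seed)
    vol <- array(sample(1:200, 75, replace = TRUE), dim = c(5, 5, 3))
    tp <- toy_path_setup(vol)
    start_um <- c(sample(0:4, 1), 4, sample(0:2, 1))
    res <- brightest_path(tp$stack, start_um, tp$backbone, search_radius_um = 9)
    start_lin <- (start_um[1] + 1) + (5 - 1) * 5 + start_um[3] * 25
    want <- oracle_bottleneck_scan(vol, start_lin, tube)
    expect_equal(res$bottleneck, want, info = paste("seed", seed))
    # returned path is admissible: its minimum equals the bottleneck
    path_lin <- res$path_vox[, 1] + (res$path_vox[, 2] - 1) * 5 +
      (res$path_vox[, 3] - 1) * 25
    expect_equal(min(vol[path_lin]), res$bottleneck)
    # consecutive path voxels are 26-connected
    if (nrow(res$path_vox) > 1) {
      steps <- abs(diff(res$path_vox))
      expect_true(all(steps <= 1))
    }
  }
})

test_that("an endpoint adjacent to the tube yields a degenerate path", {
  vol <- array(10, dim = c(5, 5, 3))
  tp <- toy_path_setup(vol)
  res <- brightest_path(tp$stack, c(2, 1, 1), tp$backbone, search_radius_um = 4)
  expect_lte(res$n_steps, 1)
  # endpoint on the tube itself: zero-step path
  res0 <- brightest_path(tp$stack, c(2, 0, 1), tp$backbone, search_radius_um = 4)
  expect_equal(res0$n_steps, 0L)
})

test_that("no admissible path is reported as a discarded detection", {
  vol <- array(10, dim = c(5, 5, 3))
  tp <- toy_path_setup(vol)
  expect_message(
    res <- brightest_path(tp$stack, c(4, 4, 2), tp$backbone,
                          search_radius_um = 1.0),
    "discarded"
  )
  expect_null(res)
})

test_that("inclusion filters follow the strict protrusion and elevation rules", {
  mk <- tibble::tibble(
    x_um = 1:5, y_um = 1, z_um = 1,
    attachment_arc_um = 1:5,
    protrusion_um = c(0.5, 0.72, 0.7201, 1.0, 1.0),
    elevation_deg = c(10, 10, 10, 30, 80),
    source = "automatic", included = NA
  )
  out <- apply_inclusion_filters(mk, detection_params())
  # 0.5 and exactly 0.72 excluded (strictly-greater rule); 80 deg excluded
  expect_equal(out$included, c(FALSE, FALSE, TRUE, TRUE, FALSE))
  # idempotence
  out2 <- apply_inclusion_filters(out, detection_params())
  expect_identical(out, out2)
  # excluded marks are retained
  expect_equal(nrow(out), 5)
})

test_that("raising the protrusion threshold never increases inclusions", {
  set.seed(7)
  mk <- tibble::tibble(
    x_um = runif(40), y_um = runif(40), z_um = runif(40),
    attachment_arc_um = runif(40, 0, 30),
    protrusion_um = runif(40, 0.1, 3),
    elevation_deg = runif(40, 0, 90),
    source = "automatic", included = NA
  )
  counts <- vapply(seq(0.2, 2.5, by = 0.1), function(th) {
    sum(apply_inclusion_filters(
      mk, detection_params(min_protrusion_um = th, search_radius_um = 5)
    )$included)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("a scene with zero spines yields no detections", {
  sc <- make_scene(n_spines = 0, losses = c(0, 0, 0), gains = c(0, 0, 0),
                   seed = 3, stack_shape_vox = c(96, 96, 15))
  st <- render_session(sc, "BL", noise_model())
  cl <- scene_centerline(sc)
  bb <- trace_backbone(st, rbind(cl[1, ], cl[nrow(cl), ]))
  eps <- detect_endpoints(st, bb)
  expect_equal(nrow(eps), 0)
})

test_that("manual annotations pass through verbatim as candidates", {
  fx <- clean_scene_fixture()
  manual <- tibble::tibble(
    session = "BL", x_um = c(10.1, 20.2), y_um = c(9.9, 15.5),
    z_um = c(10, 11), spine_id = c("m1", "m2")
  )
  eps <- detect_endpoints(fx$stack, fx$backbone, manual = manual)
  man <- eps[eps$source == "manual", ]
  expect_equal(man$x_um, manual$x_um)
  expect_equal(man$y_um, manual$y_um)
  expect_equal(man$z_um, manual$z_um)
})

test_that("endpoints of a clean scene are recovered within half a micron", {
  fx <- clean_scene_fixture()
  eps <- detect_endpoints(fx$stack, fx$backbone)
  truth <- scene_spine_endpoints(fx$scene, "BL")
  pr <- detection_pr(eps, truth, tol_um = 0.5)
  expect_gte(pr["recall"], 0.9)
  expect_gte(pr["precision"], 0.9)
})

test_that("clean-scene marks recover programmed arcs and protrusions", {
  fx <- clean_scene_fixture()
  eps <- detect_endpoints(fx$stack, fx$backbone)
  mk <- apply_inclusion_filters(spine_marks(fx$stack, fx$backbone, eps))
  truth <- scene_spine_endpoints(fx$scene, "BL")
  expect_equal(nrow(mk), nrow(truth))
  est <- sort(mk$attachment_arc_um)
  tru <- sort(truth$arc_um)
  expect_lt(max(abs(est - tru)), 1.0)
  # programmed protrusions are >= 1 um, so every spine passes the filter
  expect_true(all(mk$included))
})
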