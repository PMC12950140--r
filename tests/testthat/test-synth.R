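test_that("scene schedules are realized exactly and deterministically", {
  sc <- make_scene(n_spines = 10, losses = c(2, 0, 1), gains = c(1, 1, 0),
                   seed = 7)
  sums <- colSums(sc$presence)
  expect_equal(unname(sums), c(10, 9, 10, 9))
  # 8 spines survive the first interval
  expect_equal(sum(sc$presence[, 1] & sc$presence[, 2]), 8)
  sched <- scene_schedule(sc)
  expect_equal(sched$lost, c(2, 0, 1))
  expect_equal(sched$gained, c(1, 1, 0))

  sc2 <- make_scene(n_spines = 10, losses = c(2, 0, 1), gains = c(1, 1, 0),
                    seed = 7)
  expect_identical(sc, sc2)
})

test_that("infeasible schedules are rejected with a message", {
  expect_error(make_scene(n_spines = 10, losses = c(12, 0, 0),
                          gains = c(0, 0, 0)), "infeasible")
  expect_error(make_scene(n_spines = 3, losses = c(2, 2, 0),
                          gains = c(0, 0, 0)), "infeasible")
})

test_that("presence matrices realize random feasible schedules (property)", {
  for (seed in 1:100) {
    set.seed(seed)
    n0 <- sample(4:9, 1)
    losses <- integer(3); gains <- integer(3)
    alive <- n0
    for (j in 1:3) {
      losses[j] <- sample(0:min(2, alive), 1)
      gains[j] <- sample(0:2, 1)
      alive <- alive - losses[j] + gains[j]
    }
    sc <- make_scene(n_spines = n0, losses = losses, gains = gains,
                     seed = seed)
    sched <- scene_schedule(sc)
    expect_equal(sched$lost, losses, info = paste("seed", seed))
    expect_equal(sched$gained, gains, info = paste("seed", seed))
    # conservation along the presence matrix
    expect_equal(diff(colSums(sc$presence)), gains - losses,
                 ignore_attr = TRUE)
    # arc invariants
    expect_true(all(sc$spines$arc_um >= 0))
    expect_true(all(diff(sort(sc$spines$arc_um)) > 2.0))
  }
})

test_that("clean renders satisfy the background and brightness contracts", {
  sc <- make_scene(n_spines = 4, losses = c(0, 0, 0), gains = c(0, 0, 0),
                   seed = 5, stack_shape_vox = c(96, 96, 15),
                   brightness = c(1, 2, 1, 1))
  st_bl <- render_session(sc, "BL", clean_noise_model(background_offset = 7))
  expect_equal(st_bl$intensities[1, 1, 1], 7)
  expect_equal(st_bl$intensities[96, 96, 15], 7)

  # head-voxel ratio between sessions with multiplier 2 vs 1
  st_d3 <- render_session(sc, "d3", clean_noise_model(background_offset = 7))
  truth <- scene_spine_endpoints(sc, "BL")
  pitch <- sc$voxel_pitch_um
  for (j in seq_len(nrow(truth))) {
    iv <- round(c(truth$x_um[j], truth$y_um[j], truth$z_um[j]) / pitch) + 1
    v_bl <- st_bl$intensities[iv[1], iv[2], iv[3]] - 7
    v_d3 <- st_d3$intensities[iv[1], iv[2], iv[3]] - 7
    expect_gt(v_bl, 0)
    expect_equal(v_d3 / v_bl, 2.0, tolerance = 0.05)
  }
})

test_that("doubling amplitude doubles every structure voxel (linearity)", {
  sc1 <- make_scene(n_spines = 3, losses = c(0, 0, 0), gains = c(0, 0, 0),
                    seed = 9, stack_shape_vox = c(96, 96, 15), amplitude = 100)
  sc2 <- make_scene(n_spines = 3, losses = c(0, 0, 0), gains = c(0, 0, 0),
                    seed = 9, stack_shape_vox = c(96, 96, 15), amplitude = 200)
  v1 <- render_session(sc1, "BL", clean_noise_model())$intensities
  v2 <- render_session(sc2, "BL", clean_noise_model())$intensities
  expect_equal(v2, 2 * v1, tolerance = 0.02)
})

test_that("shot noise is unbiased around the clean value (Monte-Carlo)", {
  lambda <- 50
  n <- 100
  vals <- numeric(n)
  sc <- make_scene(n_spines = 0, losses = c(0, 0, 0), gains = c(0, 0, 0),
                   seed = 1, stack_shape_vox = c(8, 8, 3))
  nm <- noise_model(background_offset = lambda, psf_sigma_um = c(0, 0, 0),
                    shot_noise = TRUE, gaussian_read_sigma = 0)
  # pick a voxel whose clean value is exactly the background lambda
  clean <- render_session(sc, "BL", noise_model(
    background_offset = lambda, psf_sigma_um = c(0, 0, 0),
    shot_noise = FALSE, gaussian_read_sigma = 0))$intensities
  vox <- arrayInd(which(clean == lambda)[1], dim(clean))
  for (i in seq_len(n)) {
    sc$seed <- i
    vals[i] <- render_session(sc, "BL", nm)$intensities[vox[1], vox[2], vox[3]]
  }
  se <- sqrt(lambda / n)
  expect_lt(abs(mean(vals) - lambda), 3 * se)
})

test_that("renders are deterministic given scene seed and session", {
  sc <- make_scene(n_spines = 3, losses = c(0, 0, 0), gains = c(0, 0, 0),
                   seed = 13, stack_shape_vox = c(96, 96, 15))
  a <- render_session(sc, "d7", noise_model())
  b <- render_session(sc, "d7", noise_model())
  expect_identical(a$intensities, b$intensities)
})

test_that("ground-truth export has one row per present spine-session", {
  sc <- make_scene(n_spines = 1, losses = c(0, 0, 0), gains = c(0, 0, 0),
                   seed = 2, stack_shape_vox = c(96, 96, 15))
  gt <- export_ground_truth(sc)
  expect_equal(nrow(gt), 4)

  sc0 <- make_scene(n_spines = 0, losses = c(0, 0, 0), gains = c(0, 0, 0),
                    seed = 2, stack_shape_vox = c(96, 96, 15))
  gt0 <- export_ground_truth(sc0)
  expect_equal(nrow(gt0), 0)
  expect_named(gt0, c("spine_id", "session", "arc_um", "present",
                      "brightness_multiplier"))
})

test_that("ground truth round-trips byte-identically through CSV", {
  sc <- make_scene(n_spines = 4, losses = c(1, 0, 0), gains = c(0, 0, 0),
                   seed = 4, stack_shape_vox = c(96, 96, 15))
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_ground_truth(sc, p1)
  gt <- read_ground_truth(p1)
  readr::write_csv(gt, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_equal(nrow(gt), sum(sc$presence))
})

test_that("brightness multipliers are validated", {
  expect_error(
    make_scene(n_spines = 2, losses = c(0, 0, 0), gains = c(0, 0, 0),
               seed = 1, stack_shape_vox = c(96, 96, 15),
               brightness = c(1.5, 1, 1, 1)),
    "baseline"
  )
  expect_error(
    make_scene(n_spines = 2, losses = c(0, 0, 0), gains = c(0, 0, 0),
               seed = 1, stack_shape_vox = c(96, 96, 15),
               brightness = c(1, -2, 1, 1)),
    "positive"
  )
  expect_error(render_session(make_scene(seed = 1), "d99"), "unknown session")
})
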