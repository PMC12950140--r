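test_that("a clean straight tube traces onto its axis with accurate radius", {
  st <- straight_tube_stack(radius_um = 0.5)
  pitch <- st$voxel_pitch_um
  axis_y <- 20 * pitch[2]
  axis_z <- 5 * pitch[3]
  seeds <- rbind(c(2 * pitch[1], axis_y, axis_z),
                 c(93 * pitch[1], axis_y, axis_z))
  bb <- trace_backbone(st, seeds)
  interior <- bb$points_um[, 1] > 2 & bb$points_um[, 1] < 14.5
  dev <- sqrt((bb$points_um[interior, 2] - axis_y)^2 +
                (bb$points_um[interior, 3] - axis_z)^2)
  expect_lt(sqrt(mean(dev^2)), 0.5 * min(pitch))
  expect_lt(abs(mean(bb$radius_um[interior]) - 0.5), 0.25 * 0.5)
})

test_that("seeds in empty background raise a tracing failure", {
  st <- straight_tube_stack()
  expect_error(
    trace_backbone(st, rbind(c(1, 0.5, 0.5), c(16, 0.5, 0.5))),
    "tracing failure"
  )
})

test_that("arc projection matches identity, geometry and the brute oracle", {
  # identity at nodes
  pts <- cbind(seq(0, 10, by = 0.5), 0, 0)
  bb <- backbone(pts, 0.4)
  res <- arc_position(bb, pts)
  expect_equal(res$arc_um, seq(0, 10, by = 0.5))
  expect_equal(res$lateral_um, rep(0, nrow(pts)))

  # point 1 um perpendicular off the midpoint of a straight 10 um backbone
  one <- arc_position(backbone(rbind(c(0, 0, 0), c(10, 0, 0)), 0.4),
                      c(5, 1, 0))
  expect_equal(one$arc_um, 5.0)
  expect_equal(one$lateral_um, 1.0)

  # random points against the exhaustive nearest-segment oracle
  set.seed(42)
  t <- seq(0, 1, length.out = 200)
  wig <- cbind(20 * t, 3 * sin(4 * pi * t), cos(2 * pi * t))
  bbw <- backbone(wig, 0.4)
  for (i in 1:50) {
    q <- c(runif(1, -2, 22), runif(1, -5, 5), runif(1, -2, 2))
    got <- arc_position(bbw, q)
    want <- oracle_arc_position(wig, 0.4, q)
    expect_equal(got$arc_um, unname(want["arc"]), tolerance = 1e-10)
    expect_equal(got$lateral_um, unname(want["lat"]), tolerance = 1e-10)
  }
})

test_that("reversed seeds give the same polyline with mirrored arcs", {
  fx <- clean_scene_fixture()
  st <- fx$stack
  cl <- fx$centerline
  seeds_f <- rbind(cl[1, ], cl[nrow(cl), ])
  seeds_r <- seeds_f[2:1, ]
  bb_f <- trace_backbone(st, seeds_f)
  bb_r <- trace_backbone(st, seeds_r)
  L_f <- backbone_length(bb_f)
  expect_equal(L_f, backbone_length(bb_r), tolerance = 0.02 * L_f)
  # sample matched arc positions: s on forward ~ L - s on reverse
  probe <- cl[seq(10, nrow(cl) - 10, length.out = 20), ]
  arc_f <- arc_position(bb_f, probe)$arc_um
  arc_r <- arc_position(bb_r, probe)$arc_um
  expect_equal(arc_f, backbone_length(bb_r) - arc_r, tolerance = 0.15)
})

test_that("arc length is invariant under a rigid shift of stack and seeds", {
  st <- straight_tube_stack()
  pitch <- st$voxel_pitch_um
  axis_y <- 20 * pitch[2]; axis_z <- 5 * pitch[3]
  seeds <- rbind(c(5 * pitch[1], axis_y, axis_z),
                 c(90 * pitch[1], axis_y, axis_z))
  bb0 <- trace_backbone(st, seeds)
  # shift the volume by whole voxels and the seeds by the same displacement
  sh <- c(3L, -2L, 1L)
  v <- st$intensities
  d <- dim(v)
  v2 <- array(0, dim = d)
  xs <- max(1, 1 + sh[1]):min(d[1], d[1] + sh[1])
  ys <- max(1, 1 + sh[2]):min(d[2], d[2] + sh[2])
  zs <- max(1, 1 + sh[3]):min(d[3], d[3] + sh[3])
  v2[xs, ys, zs] <- v[xs - sh[1], ys - sh[2], zs - sh[3]]
  st2 <- image_stack(v2, pitch, "shifted")
  bb1 <- trace_backbone(st2, sweep(seeds, 2, sh * pitch, `+`))
  expect_equal(backbone_length(bb1), backbone_length(bb0),
               tolerance = 0.02 * backbone_length(bb0))
})

test_that("SWC round-trips a backbone", {
  bb <- backbone(cbind(seq(0, 5, by = 0.5), sin(seq(0, 5, by = 0.5)), 1),
                 seq(0.3, 0.8, length.out = 11))
  p <- withr::local_tempfile(fileext = ".swc")
  write_swc(bb, p)
  bb2 <- read_swc_backbone(p)
  expect_equal(bb2$points_um, bb$points_um, tolerance = 1e-5,
               ignore_attr = TRUE)
  expect_equal(bb2$radius_um, bb$radius_um, tolerance = 1e-5)
  expect_equal(bb2$cum_arclength_um, bb$cum_arclength_um, tolerance = 1e-5)
})
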