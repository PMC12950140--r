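straight_process_tree <- function(len_um, n_nodes = 6) {
  x <- seq(0, len_um, length.out = n_nodes)
  morph_tree(tibble::tibble(
    id = seq_len(n_nodes), x_um = x, y_um = 0, z_um = 0,
    radius_um = 1, parent = c(-1L, seq_len(n_nodes - 1L))
  ))
}

random_tree <- function(seed, n = 25) {
  set.seed(seed)
  nodes <- tibble::tibble(
    id = 1L, x_um = 0, y_um = 0, z_um = 0, radius_um = 2, parent = -1L
  )
  for (i in 2:n) {
    parent <- sample(nodes$id, 1)
    p <- nodes[nodes$id == parent, ]
    step <- rnorm(3, 0, 4)
    nodes <- dplyr::bind_rows(nodes, tibble::tibble(
      id = as.integer(i), x_um = p$x_um + step[1], y_um = p$y_um + step[2],
      z_um = p$z_um + step[3],
      radius_um = runif(1, 0.2, 1.5), parent = as.integer(parent)
    ))
  }
  morph_tree(nodes)
}

test_that("Sholl counts match the worked single-process examples", {
  tr <- straight_process_tree(50)
  expect_equal(sholl_profile(tr, seq(10, 50, 10))$intersections,
               rep(1L, 5))
  short <- straight_process_tree(5, n_nodes = 3)
  expect_equal(sholl_profile(short, 10)$intersections, 0L)
  expect_error(sholl_profile(tr, c(10, 10)), "increasing")
})

test_that("Sholl counts match dense-sampling crossings on random trees", {
  for (seed in 1:8) {
    tr <- random_tree(seed)
    radii <- c(2.5, 5.1, 7.7, 10.3, 15.9, 21.4)
    got <- sholl_profile(tr, radii)$intersections
    want <- oracle_sholl(tr$nodes, radii)
    expect_equal(got, want, info = paste("seed", seed))
  }
})

test_that("Sholl profiles are invariant under rotation about the root", {
  tr <- random_tree(99)
  radii <- c(3.3, 6.6, 9.9, 14.2)
  base <- sholl_profile(tr, radii)$intersections
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  xyz <- as.matrix(tr$nodes[, c("x_um", "y_um", "z_um")]) %*% t(R)
  tr2 <- tr
  tr2$nodes$x_um <- xyz[, 1]; tr2$nodes$y_um <- xyz[, 2]
  tr2$nodes$z_um <- xyz[, 3]
  expect_equal(sholl_profile(tr2, radii)$intersections, base)
})

test_that("morphology summary matches closed forms", {
  # root with 3 straight 10 um children
  tr <- morph_tree(tibble::tibble(
    id = 1:4, x_um = c(0, 10, 0, 0), y_um = c(0, 0, 10, 0),
    z_um = c(0, 0, 0, 10), radius_um = 1, parent = c(-1L, 1L, 1L, 1L)
  ))
  s <- morphology_summary(tr)
  expect_equal(s$total_length_um, 30)
  expect_equal(s$n_primary_processes, 3)
  expect_equal(s$volume_um3, 3 * pi * 10 / 3 * 3) # three frusta r1 = r2 = 1

  # single 2 um cylinder of radius 1 -> 2 pi
  cyl <- morph_tree(tibble::tibble(
    id = 1:2, x_um = c(0, 2), y_um = 0, z_um = 0, radius_um = 1,
    parent = c(-1L, 1L)
  ))
  expect_equal(morphology_summary(cyl)$volume_um3, 2 * pi)
})

test_that("frustum volumes agree with fine numerical integration", {
  for (seed in 1:5) {
    tr <- random_tree(400 + seed, n = 12)
    got <- morphology_summary(tr)$volume_um3
    # numerical: slice each segment into thin discs
    seg <- spinedyn:::tree_segments(tr)
    num <- 0
    for (i in seq_len(nrow(seg$a))) {
      h <- sqrt(sum((seg$b[i, ] - seg$a[i, ])^2))
      t <- seq(0, 1, length.out = 20001)
      r <- seg$ra[i] + t * (seg$rb[i] - seg$ra[i])
      num <- num + sum(pi * r^2) * h / length(t)
    }
    expect_equal(got, num, tolerance = 1e-3)
  }
})

test_that("SWC round-trips a morphology tree", {
  tr <- random_tree(7, n = 15)
  p <- withr::local_tempfile(fileext = ".swc")
  write_swc(tr, p)
  tr2 <- read_swc_tree(p)
  expect_equal(tr2$nodes$x_um, tr$nodes$x_um, tolerance = 1e-4)
  expect_equal(tr2$nodes$parent, tr$nodes$parent)
  expect_equal(morphology_summary(tr2)$total_length_um,
               morphology_summary(tr)$total_length_um, tolerance = 1e-3)
})

test_that("malformed trees are rejected", {
  expect_error(morph_tree(tibble::tibble(
    id = 1:2, x_um = 0, y_um = 0, z_um = 0, radius_um = 1,
    parent = c(-1L, -1L)
  )), "one root")
  expect_error(morph_tree(tibble::tibble(
    id = 1:2, x_um = 0, y_um = 0, z_um = 0, radius_um = 1,
    parent = c(2L, -1L)
  )), "precede")
})
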