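marks_from_arcs <- function(arcs) {
  tibble::tibble(attachment_arc_um = arcs, included = TRUE)
}

test_that("the worked matching example resolves as specified", {
  tracks <- match_spines(
    list(s1 = marks_from_arcs(c(5.0, 12.0, 20.0)),
         s2 = marks_from_arcs(c(5.2, 19.8, 30.0))),
    tolerance_um = 2
  )
  d <- dynamics_ratios(tracks, c("s1", "s2"))
  expect_equal(d$n_prev, 3)
  expect_equal(d$gained, 1) # the 30.0 spine
  expect_equal(d$lost, 1)   # the 12.0 spine
  p <- track_presence(tracks)
  # 5.0<->5.2 and 20.0<->19.8 matched
  expect_equal(sum(rowSums(p) == 2), 2)
})

test_that("identical mark sets match fully with zero events", {
  arcs <- c(3.1, 8.4, 15.9, 22.2)
  tracks <- match_spines(
    list(a = marks_from_arcs(arcs), b = marks_from_arcs(arcs)),
    tolerance_um = 2
  )
  d <- dynamics_ratios(tracks, c("a", "b"))
  expect_equal(d$gained, 0)
  expect_equal(d$lost, 0)
  expect_equal(d$addition_ratio, 0)
  expect_equal(d$elimination_ratio, 0)
  expect_equal(d$turnover_ratio, 0)
})

test_that("assignment cost equals the brute-force minimum (50 instances)", {
  for (seed in 1:50) {
    set.seed(seed)
    na <- sample(0:8, 1); nb <- sample(0:8, 1)
    a <- sort(runif(na, 0, 30))
    b <- sort(runif(nb, 0, 30))
    tol <- runif(1, 0.5, 4)
    got <- assign_arcs(a, b, tol)
    want <- oracle_assignment(a, b, tol)
    expect_equal(nrow(got), want$count, info = paste("seed", seed))
    expect_equal(sum(got$cost), want$cost, tolerance = 1e-9,
                 info = paste("seed", seed))
    if (nrow(got) > 0) expect_true(all(got$cost <= tol + 1e-12))
  }
})

test_that("matching is symmetric: swapping sessions swaps gains and losses", {
  for (seed in 1:20) {
    set.seed(200 + seed)
    a <- sort(runif(sample(2:7, 1), 0, 30))
    b <- sort(runif(sample(2:7, 1), 0, 30))
    t_ab <- match_spines(list(x = marks_from_arcs(a), y = marks_from_arcs(b)),
                         tolerance_um = 2)
    t_ba <- match_spines(list(y = marks_from_arcs(b), x = marks_from_arcs(a)),
                         tolerance_um = 2)
    d_ab <- dynamics_ratios(t_ab, c("x", "y"))
    d_ba <- dynamics_ratios(t_ba, c("y", "x"))
    expect_equal(d_ab$gained, d_ba$lost)
    expect_equal(d_ab$lost, d_ba$gained)
  }
})

test_that("manual correspondence overrides links and rejects duplicates", {
  a <- c(5, 10)
  b <- c(6.5, 10.1)
  # automatic matching would pair 5<->6.5 and 10<->10.1; the forced link
  # pairs mark 1 of session a with mark 2 of session b instead
  links <- tibble::tibble(session_a = "a", id_a = 1L,
                          session_b = "b", id_b = 2L)
  tracks <- match_spines(list(a = marks_from_arcs(a), b = marks_from_arcs(b)),
                         tolerance_um = 2, manual_links = links)
  df <- tidy(tracks)
  t1 <- df$track_id[df$session == "a" & df$mark_row == 1]
  expect_equal(df$track_id[df$session == "b" & df$mark_row == 2], t1)

  dup <- tibble::tibble(session_a = c("a", "a"), id_a = c(1L, 2L),
                        session_b = c("b", "b"), id_b = c(2L, 2L))
  expect_error(
    match_spines(list(a = marks_from_arcs(a), b = marks_from_arcs(b)),
                 tolerance_um = 2, manual_links = dup),
    "duplicate"
  )
})

test_that("dynamics ratios follow the stated formulas", {
  # N_prev = 10, G = 1, L = 2 -> (0.10, 0.20, 0.15)
  pres <- matrix(FALSE, 11, 2, dimnames = list(NULL, c("t0", "t1")))
  pres[1:10, 1] <- TRUE
  pres[c(1:8, 11), 2] <- TRUE # lose 9 and 10, gain 11
  rows <- purrr::map_dfr(seq_len(11), function(i) {
    s <- c("t0", "t1")[pres[i, ]]
    if (length(s) == 0) return(NULL)
    tibble::tibble(track_id = i, session = s, present = TRUE,
                   mark_row = NA_integer_, arc_um = i)
  })
  tracks <- structure(rows, sessions = c("t0", "t1"), tolerance_um = 2,
                      class = c("spine_tracks", class(rows)))
  d <- dynamics_ratios(tracks, c("t0", "t1"))
  expect_equal(d$addition_ratio, 0.10)
  expect_equal(d$elimination_ratio, 0.20)
  expect_equal(d$turnover_ratio, 0.15)

  # N_prev = 0 -> ratios undefined
  empty_prev <- tibble::tibble(track_id = 1L, session = "t1", present = TRUE,
                               mark_row = NA_integer_, arc_um = 1)
  tr0 <- structure(empty_prev, sessions = c("t0", "t1"), tolerance_um = 2,
                   class = c("spine_tracks", class(empty_prev)))
  d0 <- dynamics_ratios(tr0, c("t0", "t1"))
  expect_true(is.na(d0$addition_ratio))
})

test_that("spine density counts included marks over the segment length", {
  bb <- backbone(rbind(c(0, 0, 0), c(50, 0, 0)), 0.4)
  mk <- tibble::tibble(attachment_arc_um = seq(2, 47, length.out = 10),
                       included = TRUE)
  expect_equal(spine_density(mk, bb), 10 / 50)
  expect_equal(spine_density(mk[0, ], bb), 0)
  expect_equal(spine_density(mk, bb, c(0, 25)), sum(mk$attachment_arc_um <= 25) / 25)
  expect_error(spine_density(mk, bb, c(5, 5)), "zero-length")
  mk2 <- mk; mk2$included[1:5] <- FALSE
  expect_equal(spine_density(mk2, bb), 5 / 50)
})

test_that("conservation N_t = N_prev - L + G holds on random schedules", {
  for (seed in 1:25) {
    set.seed(300 + seed)
    sessions <- c("BL", "d3", "d7", "d14")
    marks <- setNames(lapply(sessions, function(s) {
      marks_from_arcs(sort(runif(sample(3:9, 1), 0, 40)))
    }), sessions)
    tracks <- match_spines(marks, tolerance_um = 2)
    p <- track_presence(tracks)
    for (j in 1:3) {
      d <- dynamics_ratios(tracks, sessions[c(j, j + 1)])
      expect_equal(sum(p[, j + 1]), d$n_prev - d$lost + d$gained)
    }
    # stable + eliminated fractions of baseline spines sum to 1
    for (j in 2:4) {
      stable <- sum(p[, 1] & p[, j])
      elim <- sum(p[, 1] & !p[, j])
      expect_equal((stable + elim) / sum(p[, 1]), 1)
    }
  }
})

test_that("dynamics_summary supports consecutive and baseline reference modes", {
  sessions <- c("BL", "d3", "d7")
  marks <- list(
    BL = marks_from_arcs(c(5, 10, 15)),
    d3 = marks_from_arcs(c(5, 10)),
    d7 = marks_from_arcs(c(5, 10, 20, 25))
  )
  tracks <- match_spines(marks, tolerance_um = 2)
  cons <- dynamics_summary(tracks, backbone_length_um = 30)
  expect_equal(cons$ratios$session_prev, c("BL", "d3"))
  base <- dynamics_summary(tracks, backbone_length_um = 30, mode = "baseline")
  expect_equal(base$ratios$session_prev, c("BL", "BL"))
  expect_equal(base$ratios$lost[2], 1)   # spine at 15 gone vs baseline
  expect_equal(base$ratios$gained[2], 2) # 20 and 25 new vs baseline
  expect_equal(cons$density$n_spines, c(3, 2, 4))
})

test_that("tidiers summarize tracks", {
  tracks <- match_spines(
    list(a = marks_from_arcs(c(1, 5)), b = marks_from_arcs(c(1, 5, 9))),
    tolerance_um = 2
  )
  g <- glance(tracks)
  expect_equal(g$n_tracks, 3)
  expect_equal(g$n_sessions, 2)
  expect_equal(g$n_always_present, 2)
  td <- tidy(tracks)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 5)
})
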