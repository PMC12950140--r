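#' Match spines across consecutive sessions by arc-length position
#'
#' Corresponding spines in different sessions are identified by their
#' arc-length position along the (reference) dendritic backbone. For each
#' consecutive session pair, the matching is the maximum-cardinality,
#' minimum-total-arc-distance assignment among pairs with
#' `|arc_a - arc_b| <= tolerance_um`. Because arc positions are scalar, the
#' optimal assignment is non-crossing and is computed exactly by dynamic
#' programming on the sorted positions. Unmatched earlier spines end their
#' track (elimination); unmatched later spines start new tracks (addition).
#'
#' @param marks_by_session Named list (session label -> tibble) of included
#'   spine marks with an `attachment_arc_um` (or `arc_um`) column, arcs
#'   already expressed in the reference frame.
#' @param tolerance_um Hard cap on the arc distance of a matched pair.
#' @param manual_links Optional tibble (session_a, id_a, session_b, id_b) of
#'   manual correspondences that override the automatic assignment; row ids
#'   index into each session's mark tibble. Duplicate links to one spine are
#'   rejected.
#' @return A `spine_tracks` object: tibble with track_id, session, present,
#'   mark_row, arc_um; attributes `sessions`, `tolerance_um`.
#' @export
match_spines <- function(marks_by_session, tolerance_um = 2.0,
                         manual_links = NULL) {
  sessions <- names(marks_by_session)
  if (is.null(sessions) || any(sessions == "")) {
    abort("marks_by_session must be a named list (session labels)")
  }
  arcs <- lapply(marks_by_session, mark_arcs)

  forced <- validate_manual_links(manual_links, sessions, arcs)

  ns <- length(sessions)
  # track bookkeeping: for each session, map mark row -> track id
  track_of <- lapply(arcs, function(a) rep(NA_integer_, length(a)))
  next_track <- 1L
  for (j in seq_along(arcs[[1]])) {
    track_of[[1]][j] <- next_track
    next_track <- next_track + 1L
  }
  pairs_by_interval <- vector("list", ns - 1L)
  for (si in seq_len(ns - 1L)) {
    a <- arcs[[si]]
    b <- arcs[[si + 1]]
    f <- forced[[si]]
    m <- assign_arcs(a, b, tolerance_um, forced = f)
    pairs_by_interval[[si]] <- m
    if (nrow(m) > 0) {
      for (r in seq_len(nrow(m))) {
        track_of[[si + 1]][m$j[r]] <- track_of[[si]][m$i[r]]
      }
    }
    unmatched_b <- setdiff(seq_along(b), m$j)
    for (j in unmatched_b) {
      track_of[[si + 1]][j] <- next_track
      next_track <- next_track + 1L
    }
  }

  rows <- purrr::map_dfr(seq_len(ns), function(si) {
    n <- length(arcs[[si]])
    if (n == 0) return(NULL)
    tibble::tibble(
      track_id = track_of[[si]],
      session = sessions[si],
      mark_row = seq_len(n),
      arc_um = arcs[[si]]
    )
  })
  if (nrow(rows) == 0) {
    rows <- tibble::tibble(
      track_id = integer(0), session = character(0),
      mark_row = integer(0), arc_um = numeric(0)
    )
  }
  rows$present <- TRUE
  structure(
    rows[, c("track_id", "session", "present", "mark_row", "arc_um")],
    sessions = sessions,
    tolerance_um = tolerance_um,
    class = c("spine_tracks", class(rows))
  )
}

# Arc coordinate used for matching and densities: an explicit match_arc_um
# (endpoint perpendicular-foot arc, robust to noisy attachment paths) wins
# over the attachment arc, which wins over a plain arc_um column.
mark_arcs <- function(marks) {
  if (is.null(marks) || nrow(marks) == 0) return(numeric(0))
  if ("match_arc_um" %in% names(marks)) return(marks$match_arc_um)
  if ("attachment_arc_um" %in% names(marks)) return(marks$attachment_arc_um)
  marks$arc_um
}

validate_manual_links <- function(manual_links, sessions, arcs) {
  forced <- rep(list(NULL), length(sessions) - 1L)
  if (is.null(manual_links) || nrow(manual_links) == 0) return(forced)
  for (r in seq_len(nrow(manual_links))) {
    sa <- match(manual_links$session_a[r], sessions)
    sb <- match(manual_links$session_b[r], sessions)
    if (is.na(sa) || is.na(sb) || sb != sa + 1L) {
      abort("manual links must connect consecutive known sessions")
    }
    forced[[sa]] <- rbind(forced[[sa]],
                          c(manual_links$id_a[r], manual_links$id_b[r]))
  }
  for (si in seq_along(forced)) {
    f <- forced[[si]]
    if (!is.null(f) && (anyDuplicated(f[, 1]) || anyDuplicated(f[, 2]))) {
      abort("duplicate manual links to one spine are not allowed")
    }
  }
  forced
}

#' Maximum-cardinality minimum-cost assignment of scalar positions
#'
#' Pairs may only form when `|a_i - b_j| <= tolerance`. Among all
#' maximum-cardinality matchings, returns one of minimum total absolute arc
#' distance (non-crossing DP on sorted positions; optimal for scalar costs).
#'
#' @param a,b Numeric vectors of arc positions.
#' @param tolerance Hard pairing cap.
#' @param forced Optional 2-column matrix of forced (i, j) links.
#' @return Tibble with columns `i`, `j`, `cost` (one row per matched pair).
#' @export
assign_arcs <- function(a, b, tolerance, forced = NULL) {
  empty <- tibble::tibble(i = integer(0), j = integer(0), cost = numeric(0))
  keep_a <- seq_along(a)
  keep_b <- seq_along(b)
  forced_rows <- empty
  if (!is.null(forced) && nrow(forced) > 0) {
    forced_rows <- tibble::tibble(
      i = as.integer(forced[, 1]), j = as.integer(forced[, 2]),
      cost = abs(a[forced[, 1]] - b[forced[, 2]])
    )
    keep_a <- setdiff(keep_a, forced_rows$i)
    keep_b <- setdiff(keep_b, forced_rows$j)
  }
  if (length(keep_a) == 0 || length(keep_b) == 0) return(forced_rows)

  oa <- keep_a[order(a[keep_a])]
  ob <- keep_b[order(b[keep_b])]
  sa <- a[oa]
  sb <- b[ob]
  n <- length(sa); m <- length(sb)
  # dp over prefixes: value = (matched count, -total cost), maximized lexicographically
  NEG <- -1e18
  cnt <- matrix(0L, n + 1, m + 1)
  cost <- matrix(0, n + 1, m + 1)
  choice <- matrix(0L, n + 1, m + 1) # 1 = skip i, 2 = skip j, 3 = match
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      # skip i
      bc <- cnt[i, j + 1]; bco <- cost[i, j + 1]; ch <- 1L
      # skip j
      if (cnt[i + 1, j] > bc || (cnt[i + 1, j] == bc && cost[i + 1, j] < bco)) {
        bc <- cnt[i + 1, j]; bco <- cost[i + 1, j]; ch <- 2L
      }
      # match i, j
      d <- abs(sa[i] - sb[j])
      if (d <= tolerance) {
        mc <- cnt[i, j] + 1L; mco <- cost[i, j] + d
        if (mc > bc || (mc == bc && mco < bco)) {
          bc <- mc; bco <- mco; ch <- 3L
        }
      }
      cnt[i + 1, j + 1] <- bc
      cost[i + 1, j + 1] <- bco
      choice[i + 1, j + 1] <- ch
    }
  }
  i <- n; j <- m
  pi <- integer(0); pj <- integer(0)
  while (i > 0 && j > 0) {
    ch <- choice[i + 1, j + 1]
    if (ch == 3L) {
      pi <- c(oa[i], pi); pj <- c(ob[j], pj)
      i <- i - 1; j <- j - 1
    } else if (ch == 1L) {
      i <- i - 1
    } else {
      j <- j - 1
    }
  }
  out <- tibble::tibble(i = pi, j = pj, cost = abs(a[pi] - b[pj]))
  dplyr::arrange(dplyr::bind_rows(forced_rows, out), .data$i)
}

#' Presence matrix of spine tracks
#'
#' @param tracks A `spine_tracks` object.
#' @return Logical matrix, tracks x sessions.
#' @export
track_presence <- function(tracks) {
  sessions <- attr(tracks, "sessions")
  ids <- sort(unique(tracks$track_id))
  m <- matrix(FALSE, length(ids), length(sessions),
              dimnames = list(ids, sessions))
  if (nrow(tracks) > 0) {
    m[cbind(match(tracks$track_id, ids), match(tracks$session, sessions))] <- TRUE
  }
  m
}

#' Spine density over an arc-length segment
#'
#' Count of included spine marks whose attachment arc lies in the segment,
#' divided by the segment length.
#'
#' @param marks Spine marks (only rows with `included = TRUE` count; a tibble
#'   without an `included` column counts all rows).
#' @param bb A `backbone` (used to validate the segment).
#' @param segment Arc interval `c(from, to)` in um; default the full backbone.
#' @return Spines per um.
#' @export
spine_density <- function(marks, bb, segment = NULL) {
  if (is.null(segment)) segment <- c(0, backbone_length(bb))
  if (diff(segment) <= 0) abort("zero-length segment")
  if (segment[1] < 0 || segment[2] > backbone_length(bb) + 1e-9) {
    abort("segment outside backbone extent")
  }
  arcs <- mark_arcs(marks)
  if ("included" %in% names(marks)) arcs <- arcs[which(marks$included)]
  sum(arcs >= segment[1] & arcs <= segment[2]) / diff(segment)
}

#' Addition, elimination and turnover ratios for one session pair
#'
#' With `N_prev` spines present at the earlier session, `G` gained (present
#' later, absent earlier) and `L` lost: addition = G / N_prev, elimination =
#' L / N_prev, turnover = (G + L) / (2 N_prev).
#'
#' @param tracks A `spine_tracks` object.
#' @param session_pair Two session labels `c(t_prev, t)`.
#' @return Tibble: session_prev, session, n_prev, gained, lost,
#'   addition_ratio, elimination_ratio, turnover_ratio (NA when N_prev = 0).
#' @export
dynamics_ratios <- function(tracks, session_pair) {
  p <- track_presence(tracks)
  sessions <- attr(tracks, "sessions")
  idx <- match(session_pair, sessions)
  if (anyNA(idx)) abort("unknown session label in session_pair")
  prev <- p[, idx[1]]
  cur <- p[, idx[2]]
  n_prev <- sum(prev)
  g <- sum(cur & !prev)
  l <- sum(prev & !cur)
  tibble::tibble(
    session_prev = session_pair[1],
    session = session_pair[2],
    n_prev = n_prev, gained = g, lost = l,
    addition_ratio = if (n_prev > 0) g / n_prev else NA_real_,
    elimination_ratio = if (n_prev > 0) l / n_prev else NA_real_,
    turnover_ratio = if (n_prev > 0) (g + l) / (2 * n_prev) else NA_real_
  )
}

#' Per-session densities and per-interval dynamics ratios
#'
#' @param tracks A `spine_tracks` object.
#' @param backbone_length_um Analyzed backbone length (um) for densities.
#' @param mode `"consecutive"` compares each session with the previous one;
#'   `"baseline"` compares every follow-up with the first session.
#' @return A `spine_dynamics` list: `density` tibble (session, n_spines,
#'   density_per_um) and `ratios` tibble (one row per interval).
#' @export
dynamics_summary <- function(tracks, backbone_length_um,
                             mode = c("consecutive", "baseline")) {
  mode <- match.arg(mode)
  sessions <- attr(tracks, "sessions")
  p <- track_presence(tracks)
  density <- tibble::tibble(
    session = sessions,
    n_spines = unname(colSums(p)),
    density_per_um = unname(colSums(p)) / backbone_length_um
  )
  ref <- if (mode == "consecutive") head(sessions, -1) else {
    rep(sessions[1], length(sessions) - 1)
  }
  ratios <- purrr::map2_dfr(ref, sessions[-1], function(s0, s1) {
    dynamics_ratios(tracks, c(s0, s1))
  })
  structure(
    list(density = density, ratios = ratios,
         backbone_length_um = backbone_length_um, mode = mode),
    class = "spine_dynamics"
  )
}

#' @export
print.spine_dynamics <- function(x, ...) {
  cat(sprintf("<spine_dynamics> %s mode, backbone %.1f um\n",
              x$mode, x$backbone_length_um))
  print(x$density)
  print(x$ratios)
  invisible(x)
}
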