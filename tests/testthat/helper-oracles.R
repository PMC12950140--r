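# Independent brute-force oracles used to pin algorithm semantics.
# These deliberately re-derive results from first principles and share no code
# with the package implementation.

# --- bottleneck path oracles -------------------------------------------------

oracle_neighbors <- function(idx, dims) {
  co <- arrayInd(idx, dims)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  nb <- sweep(offs, 2, as.numeric(co), `+`)
  ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] & nb[, 2] >= 1 & nb[, 2] <= dims[2] &
    nb[, 3] >= 1 & nb[, 3] <= dims[3]
  nb <- nb[ok, , drop = FALSE]
  nb[, 1] + (nb[, 2] - 1) * dims[1] + (nb[, 3] - 1) * dims[1] * dims[2]
}

# Linear scan over decreasing thresholds: the optimum bottleneck is the
# largest t at which start reaches any target through voxels with I >= t.
oracle_bottleneck_scan <- function(vol, start_lin, target_lin) {
  dims <- dim(vol)
  for (t in sort(unique(as.vector(vol)), decreasing = TRUE)) {
    keep <- vol >= t
    if (!keep[start_lin]) next
    seen <- logical(length(vol))
    seen[start_lin] <- TRUE
    queue <- start_lin
    while (length(queue) > 0) {
      cur <- queue[1]; queue <- queue[-1]
      for (nb in oracle_neighbors(cur, dims)) {
        if (keep[nb] && !seen[nb]) {
          seen[nb] <- TRUE
          queue <- c(queue, nb)
        }
      }
    }
    if (any(seen[target_lin])) return(t)
  }
  NA_real_
}

# Exhaustive depth-first enumeration of simple paths with branch-and-bound on
# the running minimum; exact because pruning only removes paths that cannot
# beat the incumbent bottleneck.
oracle_bottleneck_dfs <- function(vol, start_lin, target_lin) {
  dims <- dim(vol)
  target <- logical(length(vol)); target[target_lin] <- TRUE
  best <- -Inf
  visit <- function(node, visited, curmin) {
    curmin <- min(curmin, vol[node])
    if (curmin <= best) return()
    if (target[node]) { best <<- max(best, curmin); return() }
    visited[node] <- TRUE
    for (nb in oracle_neighbors(node, dims)) {
      if (!visited[nb]) visit(nb, visited, curmin)
    }
  }
  visit(start_lin, logical(length(vol)), Inf)
  best
}

# --- assignment oracle -------------------------------------------------------

# All matchings between positions a and b with |a_i - b_j| <= tol, maximizing
# cardinality then minimizing total distance, by exhaustive recursion.
oracle_assignment <- function(a, b, tol) {
  best <- list(count = -1L, cost = Inf)
  recurse <- function(i, used_b, count, cost) {
    if (i > length(a)) {
      if (count > best$count || (count == best$count && cost < best$cost)) {
        best <<- list(count = count, cost = cost)
      }
      return()
    }
    recurse(i + 1L, used_b, count, cost) # leave a_i unmatched
    for (j in seq_along(b)) {
      if (!used_b[j] && abs(a[i] - b[j]) <= tol) {
        used_b[j] <- TRUE
        recurse(i + 1L, used_b, count + 1L, cost + abs(a[i] - b[j]))
        used_b[j] <- FALSE
      }
    }
  }
  recurse(1L, logical(length(b)), 0L, 0)
  best
}

# --- Sholl oracle ------------------------------------------------------------

# Dense sampling of every segment at fine steps; crossings = sign changes of
# (distance to root) - r along the sample sequence.
oracle_sholl <- function(nodes, radii, step = 0.01) {
  root <- nodes[nodes$parent == -1, ]
  counts <- integer(length(radii))
  child <- nodes[nodes$parent != -1, ]
  for (k in seq_len(nrow(child))) {
    p <- nodes[match(child$parent[k], nodes$id), ]
    a <- c(p$x_um, p$y_um, p$z_um)
    b <- c(child$x_um[k], child$y_um[k], child$z_um[k])
    len <- sqrt(sum((b - a)^2))
    ts <- seq(0, 1, length.out = max(2, ceiling(len / step)))
    pts <- outer(ts, b - a) + rep(a, each = length(ts))
    d <- sqrt(rowSums(sweep(pts, 2, c(root$x_um, root$y_um, root$z_um), `-`)^2))
    for (ri in seq_along(radii)) {
      s <- sign(d - radii[ri])
      counts[ri] <- counts[ri] + sum(s[-1] * s[-length(s)] < 0)
    }
  }
  counts
}

# --- alternation oracle ------------------------------------------------------

oracle_alternation <- function(entries) {
  n <- length(entries)
  if (n < 3) return(NA_real_)
  ok <- 0L
  for (i in 1:(n - 2)) {
    w <- entries[i:(i + 2)]
    if (w[1] != w[2] && w[1] != w[3] && w[2] != w[3]) ok <- ok + 1L
  }
  100 * ok / (n - 2)
}

# --- nearest-segment projection oracle ---------------------------------------

oracle_arc_position <- function(points_mat, radius, query) {
  cum <- c(0, cumsum(sqrt(rowSums(diff(points_mat)^2))))
  best <- c(arc = NA_real_, lat = Inf)
  for (i in seq_len(nrow(points_mat) - 1)) {
    a <- points_mat[i, ]; b <- points_mat[i + 1, ]
    ab <- b - a
    t <- sum((query - a) * ab) / sum(ab^2)
    t <- min(max(t, 0), 1)
    ft <- a + t * ab
    d <- sqrt(sum((query - ft)^2))
    if (d < best["lat"] - 1e-12) {
      best <- c(arc = cum[i] + t * (cum[i + 1] - cum[i]), lat = d)
    }
  }
  best
}
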