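#' Construct a reconstructed morphology tree
#'
#' SWC-style rooted tree: one soma/root node, every other node linked to a
#' parent that appears earlier in the table. Used for Sholl profiles and
#' reconstruction summaries (astrocyte volume, primary processes).
#'
#' @param nodes Data frame / tibble with columns `id`, `x_um`, `y_um`,
#'   `z_um`, `radius_um`, `parent` (`-1` for the root) and optionally `type`.
#' @return A `morph_tree` object.
#' @export
morph_tree <- function(nodes) {
  nodes <- tibble::as_tibble(nodes)
  if (!"type" %in% names(nodes)) nodes$type <- 3L
  req <- c("id", "x_um", "y_um", "z_um", "radius_um", "parent")
  if (!all(req %in% names(nodes))) {
    abort(paste("morph_tree nodes need columns:", paste(req, collapse = ", ")))
  }
  if (nrow(nodes) == 0) abort("empty tree")
  roots <- which(nodes$parent == -1L)
  if (length(roots) != 1) abort("tree must have exactly one root")
  pos <- match(nodes$parent, nodes$id)
  child <- seq_len(nrow(nodes))[-roots]
  if (anyNA(pos[child]) || any(pos[child] >= child)) {
    abort("each parent must precede its child")
  }
  structure(list(nodes = nodes), class = "morph_tree")
}

#' Read an SWC file into a morphology tree
#' @param path SWC path.
#' @return A `morph_tree`.
#' @export
read_swc_tree <- function(path) {
  df <- read_swc_table(path)
  morph_tree(tibble::tibble(
    id = df$index, type = df$type, x_um = df$x, y_um = df$y, z_um = df$z,
    radius_um = df$radius, parent = df$parent
  ))
}

tree_segments <- function(tree) {
  n <- tree$nodes
  child <- n[n$parent != -1L, ]
  pidx <- match(child$parent, n$id)
  list(
    a = cbind(n$x_um[pidx], n$y_um[pidx], n$z_um[pidx]),
    b = cbind(child$x_um, child$y_um, child$z_um),
    ra = n$radius_um[pidx],
    rb = child$radius_um
  )
}

tree_root <- function(tree) {
  r <- tree$nodes[tree$nodes$parent == -1L, ]
  c(r$x_um, r$y_um, r$z_um)
}

#' Sholl profile: process intersections with concentric spheres
#'
#' Counts, for each radius, the crossings of tree segments with the sphere of
#' that radius centred on the root (soma). Straight segments may cross a
#' sphere once (endpoints straddling) or twice (chord); crossings are counted
#' from the exact segment-sphere intersection (quadratic roots in the open
#' segment interior). Tangency counts as no crossing.
#'
#' @param tree A `morph_tree`.
#' @param radii_um Strictly increasing positive radii.
#' @return Tibble: radius_um, intersections.
#' @export
sholl_profile <- function(tree, radii_um) {
  if (any(radii_um <= 0) || any(diff(radii_um) <= 0)) {
    abort("radii must be positive and strictly increasing")
  }
  seg <- tree_segments(tree)
  root <- tree_root(tree)
  counts <- vapply(radii_um, function(r) {
    if (nrow(seg$a) == 0) return(0L)
    sum(vapply(seq_len(nrow(seg$a)), function(i) {
      segment_sphere_crossings(seg$a[i, ] - root, seg$b[i, ] - root, r)
    }, integer(1)))
  }, integer(1))
  tibble::tibble(radius_um = radii_um, intersections = counts)
}

# Number of parameters t in (0, 1] with |a + t (b - a)| = r, counting sign
# changes only (tangency -> 0). The half-open interval assigns a crossing at
# a shared node to the earlier segment exactly once.
segment_sphere_crossings <- function(a, b, r) {
  d <- b - a
  A <- sum(d^2)
  if (A == 0) return(0L)
  B <- 2 * sum(a * d)
  C <- sum(a^2) - r^2
  disc <- B^2 - 4 * A * C
  if (disc <= 0) return(0L) # miss or tangency
  sq <- sqrt(disc)
  t1 <- (-B - sq) / (2 * A)
  t2 <- (-B + sq) / (2 * A)
  sum(c(t1, t2) > 0 & c(t1, t2) <= 1)
}

#' Morphology summary: total length, primary processes, volume
#'
#' Primary processes are the direct children of the root; total length is the
#' sum of segment lengths; volume is the sum of conical-frustum volumes over
#' segments, `pi h / 3 (r1^2 + r1 r2 + r2^2)`.
#'
#' @param tree A `morph_tree`.
#' @return Tibble: total_length_um, n_primary_processes, volume_um3.
#' @export
morphology_summary <- function(tree) {
  seg <- tree_segments(tree)
  root_id <- tree$nodes$id[tree$nodes$parent == -1L]
  lens <- if (nrow(seg$a) == 0) numeric(0) else {
    sqrt(rowSums((seg$b - seg$a)^2))
  }
  vol <- sum(pi * lens / 3 * (seg$ra^2 + seg$ra * seg$rb + seg$rb^2))
  tibble::tibble(
    total_length_um = sum(lens),
    n_primary_processes = sum(tree$nodes$parent == root_id),
    volume_um3 = vol
  )
}
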