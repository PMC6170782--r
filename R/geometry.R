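#' Closest points between two capsule axis segments
#'
#' Finds the pair of points, one on each axis segment, minimizing the
#' Euclidean distance between two cells' axes.  Segment `i` spans
#' `p_i - (L_i/2) d_i` to `p_i + (L_i/2) d_i`.  Zero-length segments are
#' treated as points.
#'
#' @param p1,p2 numeric 2-vectors, segment centres.
#' @param d1,d2 unit 2-vectors, segment directions.
#' @param L1,L2 segment lengths (>= 0).
#' @return A list with `point_a`, `point_b` (2-vectors) and `distance`.
#' @examples
#' segment_closest_points(c(0, 0), c(1, 0), 4, c(0, 1), c(0, 1), 1)
#' @export
segment_closest_points <- function(p1, d1, L1, p2, d2, L2) {
  stopifnot(L1 >= 0, L2 >= 0)
  stopifnot(abs(sum(d1^2) - 1) < 1e-6, abs(sum(d2^2) - 1) < 1e-6)
  res <- closest_points_cpp(as.numeric(p1), as.numeric(d1), L1,
                            as.numeric(p2), as.numeric(d2), L2)
  list(point_a = res$point_a, point_b = res$point_b, distance = res$distance)
}

#' Pairwise adhesion strength from two cells' adhesin levels
#'
#' The adhesin considered here is self-recognizing: a bond requires both
#' partners to express it, so the effective pair strength is the minimum of
#' the two per-cell levels.  A non-expressing partner disables the bond,
#' matching the observation that adhesion between lineage domains has no
#' effect when only one domain is adhesive.
#'
#' @param adhesin_a,adhesin_b non-negative per-cell adhesion levels
#'   (vectorized).
#' @return `pmin(adhesin_a, adhesin_b)`.
#' @export
pair_adhesion <- function(adhesin_a, adhesin_b) {
  stopifnot(all(adhesin_a >= 0), all(adhesin_b >= 0))
  pmin(adhesin_a, adhesin_b)
}

#' Detect cell-cell contacts in a colony
#'
#' A contact is declared between an unordered pair of cells when the
#' distance between their axis segments is below `r_a + r_b + margin`.
#' A uniform spatial grid keeps the cost near-linear in cell count.  Each
#' contact carries the closest points on both axes, the unit normal from
#' cell a to cell b, the perpendicular tangent, the overlap
#' (`r_a + r_b - distance`, positive when interpenetrating) and the
#' pairwise adhesion strength [pair_adhesion()].  Coincident closest points
#' get the deterministic normal (1, 0).
#'
#' @param colony a [colony] object.
#' @param margin non-negative contact margin in micrometres; defaults to the
#'   colony's physics parameter.
#' @return A data frame with one row per contact: `cell_a`, `cell_b` (ids,
#'   `cell_a < cell_b`), `ax, ay, bx, by` (closest points), `nx, ny`
#'   (normal), `tx, ty` (tangent), `overlap`, `distance`, `k_pair`.
#' @export
detect_contacts <- function(colony, margin = colony$params$contact_margin) {
  stopifnot(inherits(colony, "colony"), margin >= 0)
  cl <- colony$cells
  m <- contacts_grid_cpp(cl$x, cl$y, cl$dx, cl$dy, cl$length, cl$radius,
                         cl$adhesin, margin)
  data.frame(
    cell_a = cl$id[m[, "i"]],
    cell_b = cl$id[m[, "j"]],
    ax = m[, "ax"], ay = m[, "ay"], bx = m[, "bx"], by = m[, "by"],
    nx = m[, "nx"], ny = m[, "ny"],
    tx = -m[, "ny"], ty = m[, "nx"],
    overlap = m[, "overlap"], distance = m[, "dist"],
    k_pair = m[, "k_pair"]
  )
}
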