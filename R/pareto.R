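#' Pareto front of the intrinsic/extrinsic fitness trade-off
#'
#' Finds the non-dominated set of points when both coordinates are
#' maximised (intrinsic fitness on x, extrinsic immune fitness on y; the
#' extrinsic component is non-positive, so maximising it means least
#' immunogenic). A point is dominated if another point is at least as good
#' on both axes and strictly better on one. Coincident points are kept as a
#' single front vertex listing all member indices.
#'
#' @param x,y Coordinates (equal length), or `x` a `freefit_landscape`
#'   (then `intrinsic`/`extrinsic` columns are used).
#' @return A `pareto_front` list: `vertices` (data.frame `x`, `y`, `index`
#'   of the representative point, sorted by increasing x), `members`
#'   (list of all point indices at each vertex) and `on_front` (logical per
#'   input point).
#' @export
#' @examples
#' pf <- pareto_front(c(0, 1, 2, 0.5), c(0, -1, -3, -2))
#' pf$vertices
pareto_front <- function(x, y = NULL) {
  if (inherits(x, "freefit_landscape")) {
    y <- x$extrinsic
    x <- x$intrinsic
  }
  stopifnot(length(x) == length(y), length(x) >= 1L)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop_input("coordinates must be finite")
  }
  n <- length(x)
  on_front <- vapply(seq_len(n), function(i) {
    !any((x >= x[i] & y >= y[i]) & (x > x[i] | y > y[i]))
  }, TRUE)
  idx <- which(on_front)
  key <- paste(x[idx], y[idx], sep = "|")
  reps <- idx[!duplicated(key)]
  members <- split(idx, factor(key, levels = unique(key)))
  ord <- order(x[reps], y[reps])
  vertices <- data.frame(x = x[reps], y = y[reps], index = reps)[ord, ]
  rownames(vertices) <- NULL
  structure(list(vertices = vertices, members = unname(members[ord]),
                 on_front = on_front),
            class = "pareto_front")
}

# Euclidean distance from points to one segment (vectorised over points).
dist_to_segment <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  len2 <- dx * dx + dy * dy
  t <- if (len2 == 0) rep(0, length(px)) else {
    pmin(pmax(((px - ax) * dx + (py - ay) * dy) / len2, 0), 1)
  }
  sqrt((px - (ax + t * dx))^2 + (py - (ay + t * dy))^2)
}

#' Distance of each point to the Pareto front
#'
#' Euclidean distance to the piecewise-linear polyline through the front
#' vertices (distance to the single vertex when the front has one point);
#' front members are at distance zero.
#'
#' @param x,y Point coordinates (or `x` a `freefit_landscape`).
#' @param front A [pareto_front()].
#' @return Non-negative distances, one per point.
#' @export
distance_to_front <- function(x, y = NULL, front) {
  if (inherits(x, "freefit_landscape")) {
    y <- x$extrinsic
    x <- x$intrinsic
  }
  v <- front$vertices
  if (!nrow(v)) stop_input("empty front")
  d <- dist_to_segment(x, y, v$x[1], v$y[1], v$x[1], v$y[1])
  if (nrow(v) > 1L) {
    for (s in seq_len(nrow(v) - 1L)) {
      d <- pmin(d, dist_to_segment(x, y, v$x[s], v$y[s],
                                   v$x[s + 1L], v$y[s + 1L]))
    }
  }
  d
}

#' Optimal free-fitness coordinate constrained to the Pareto front
#'
#' Maximises intrinsic + extrinsic fitness (i.e. free fitness) along the
#' front polyline. The objective is linear, so the maximum is attained at a
#' vertex; on ties (a segment of slope -1) the vertex with the larger
#' intrinsic coordinate is returned.
#'
#' @param front A [pareto_front()].
#' @return List `x`, `y`, `objective` (= x + y), `vertex_index` (row of
#'   `front$vertices`).
#' @export
optimal_front_point <- function(front) {
  v <- front$vertices
  if (!nrow(v)) stop_input("empty front")
  obj <- v$x + v$y
  best <- which(obj >= max(obj) - 1e-12)
  i <- best[which.max(v$x[best])]
  list(x = v$x[i], y = v$y[i], objective = obj[i], vertex_index = i)
}
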