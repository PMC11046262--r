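# Planar geometry for marker pose and region tests.
#
# Image coordinate convention throughout the package: origin at the top-left
# of the frame, x increases rightward, y increases downward (raster
# convention). All coordinates are in pixels of a single camera's frame.

#' Marker observation
#'
#' One detected square fiducial marker in one video frame: which camera saw
#' it, when, which dictionary pattern it carries, and the four corner points
#' in the detector's canonical order (top-left of the upright pattern first,
#' then clockwise as seen on screen).
#'
#' @param camera_id Camera identifier (character scalar).
#' @param frame_index Non-negative integer frame index within the stream.
#' @param timestamp Time of the frame in seconds from session start.
#' @param marker_id Integer dictionary index of the decoded pattern.
#' @param corners Numeric 4x2 matrix of corner coordinates (x, y) in pixels,
#'   canonical order.
#' @return An object of class `marker_observation`.
#' @examples
#' obs <- marker_observation("cam1", 0, 0,
#'   marker_id = 0,
#'   corners = rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)))
#' pose_from_corners(obs)
#' @export
marker_observation <- function(camera_id, frame_index, timestamp, marker_id,
                               corners) {
  corners <- as.matrix(corners)
  if (!is.numeric(corners) || !identical(dim(corners), c(4L, 2L))) {
    stop("'corners' must be a numeric 4x2 matrix", call. = FALSE)
  }
  if (any(!is.finite(corners))) {
    stop("corner coordinates must be finite", call. = FALSE)
  }
  if (!is_simple_quad(corners)) {
    stop("marker corners must form a simple quadrilateral", call. = FALSE)
  }
  if (abs(polygon_area(corners)) < sqrt(.Machine$double.eps)) {
    stop("degenerate marker: corners enclose zero area", call. = FALSE)
  }
  if (frame_index < 0) stop("'frame_index' must be non-negative", call. = FALSE)
  structure(
    list(camera_id = as.character(camera_id),
         frame_index = as.integer(frame_index),
         timestamp = as.numeric(timestamp),
         marker_id = as.integer(marker_id),
         corners = unname(corners)),
    class = "marker_observation")
}

#' Wall specification
#'
#' Directed segment along the chamber's module wall in one camera's image,
#' plus a point known to lie inside the chamber. The interior hint orients
#' the wall normal so that yaw angles are signed toward-the-wall positive.
#'
#' @param p0,p1 Numeric length-2 endpoints (x, y) of the wall segment, pixels.
#' @param interior_hint Numeric length-2 point inside the chamber, away from
#'   the wall line.
#' @return An object of class `wall_spec`.
#' @export
wall_spec <- function(p0, p1, interior_hint) {
  p0 <- as.numeric(p0); p1 <- as.numeric(p1)
  interior_hint <- as.numeric(interior_hint)
  stopifnot(length(p0) == 2, length(p1) == 2, length(interior_hint) == 2)
  if (all(p0 == p1)) stop("wall endpoints must differ", call. = FALSE)
  w <- p1 - p0
  # perpendicular distance of the hint from the wall line
  d <- abs(w[1] * (interior_hint[2] - p0[2]) - w[2] * (interior_hint[1] - p0[1])) /
    sqrt(sum(w^2))
  if (d < sqrt(.Machine$double.eps)) {
    stop("'interior_hint' must not lie on the wall line", call. = FALSE)
  }
  structure(list(p0 = p0, p1 = p1, interior_hint = interior_hint),
            class = "wall_spec")
}

#' Region of interest
#'
#' A simple polygon in one camera's pixel frame within which the marker
#' center must lie for the animal to count as engaged. A camera may have
#' several regions; membership in any one suffices.
#'
#' @param camera_id Camera identifier.
#' @param vertices Numeric n x 2 matrix (n >= 3) of polygon vertices in order.
#' @return An object of class `region_of_interest`.
#' @export
region_of_interest <- function(camera_id, vertices) {
  vertices <- as.matrix(vertices)
  if (!is.numeric(vertices) || ncol(vertices) != 2 || nrow(vertices) < 3) {
    stop("'vertices' must be a numeric matrix with >= 3 rows and 2 columns",
         call. = FALSE)
  }
  if (any(!is.finite(vertices))) stop("vertices must be finite", call. = FALSE)
  structure(list(camera_id = as.character(camera_id),
                 vertices = unname(vertices)),
            class = "region_of_interest")
}

# Signed shoelace area of a closed polygon given as an n x 2 matrix.
polygon_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}

# Proper intersection test for two segments, used to reject self-intersecting
# ("bowtie") corner orderings.
segments_cross <- function(a0, a1, b0, b1) {
  d <- function(p, q, r) (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
  d1 <- d(b0, b1, a0); d2 <- d(b0, b1, a1)
  d3 <- d(a0, a1, b0); d4 <- d(a0, a1, b1)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

is_simple_quad <- function(corners) {
  # only the two pairs of opposite edges can cross
  !segments_cross(corners[1, ], corners[2, ], corners[3, ], corners[4, ]) &&
    !segments_cross(corners[2, ], corners[3, ], corners[4, ], corners[1, ])
}

#' Marker pose from corner points
#'
#' Reduces a four-corner marker detection to a planar pose: the marker center
#' (mean of the corners) and a unit heading vector pointing from the center
#' toward the midpoint of the nose-side ("front") edge. Which physical edge
#' faces the animal's nose depends on how the marker mount is glued, so the
#' front edge is a configuration knob.
#'
#' @param obs A `marker_observation`, or a bare 4x2 corner matrix in
#'   canonical order.
#' @param front_edge Integer 0..3 selecting the nose-side edge: edge k joins
#'   corner k and corner (k + 1) mod 4 (0-based, canonical order).
#' @return List with `center` (length-2 numeric) and `heading` (length-2
#'   unit vector).
#' @examples
#' sq <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10))
#' pose_from_corners(sq, front_edge = 0)  # heading (0, -1): "up" in the image
#' @export
pose_from_corners <- function(obs, front_edge = 0) {
  corners <- if (inherits(obs, "marker_observation")) obs$corners else as.matrix(obs)
  if (!identical(dim(corners), c(4L, 2L))) {
    stop("need exactly 4 corners", call. = FALSE)
  }
  if (!(front_edge %in% 0:3)) stop("'front_edge' must be in 0..3", call. = FALSE)
  center <- colMeans(corners)
  i <- front_edge + 1L
  j <- front_edge %% 4L + 2L; if (j == 5L) j <- 1L
  mid <- (corners[i, ] + corners[j, ]) / 2
  v <- mid - center
  n <- sqrt(sum(v^2))
  if (n < sqrt(.Machine$double.eps)) {
    stop("degenerate pose: front-edge midpoint coincides with marker center",
         call. = FALSE)
  }
  list(center = center, heading = v / n)
}

#' Yaw of a heading relative to the module wall
#'
#' Signed in-plane angle of the nose-ward heading vector measured against the
#' wall's direction, in degrees in (-180, 180]. The wall normal is oriented
#' from the chamber interior toward the wall, so 90 degrees means the animal
#' faces the wall squarely, 0/180 degrees means it is parallel to the wall,
#' and negative values mean it faces away from the wall.
#'
#' @param heading Numeric length-2 non-zero vector, or an n x 2 matrix of
#'   headings for vectorized evaluation.
#' @param wall A [wall_spec()].
#' @return Yaw in degrees in (-180, 180] (numeric vector).
#' @examples
#' w <- wall_spec(c(100, 0), c(100, 100), interior_hint = c(50, 50))
#' yaw_angle(c(1, 0), w)   # 90: facing the wall head-on
#' yaw_angle(c(0, 1), w)   # 0: parallel to the wall
#' yaw_angle(c(-1, 0), w)  # -90: facing away
#' @export
yaw_angle <- function(heading, wall) {
  stopifnot(inherits(wall, "wall_spec"))
  h <- if (is.matrix(heading)) heading else matrix(as.numeric(heading), ncol = 2)
  if (ncol(h) != 2) stop("'heading' must have two components", call. = FALSE)
  nrm <- sqrt(rowSums(h^2))
  if (any(nrm < sqrt(.Machine$double.eps))) {
    stop("zero-length heading", call. = FALSE)
  }
  w <- wall$p1 - wall$p0
  w <- w / sqrt(sum(w^2))
  n <- c(w[2], -w[1])                      # one of the two unit normals
  to_wall <- wall$p0 - wall$interior_hint  # points from interior toward wall
  if (sum(to_wall * n) < 0) n <- -n
  ang <- atan2(h %*% n, h %*% w) * 180 / pi
  ang <- as.numeric(ang)
  # atan2 returns (-180, 180]; keep that convention exactly
  ang[ang <= -180] <- ang[ang <= -180] + 360
  ang
}

#' Point-in-polygon test (even-odd rule, boundary inclusive)
#'
#' Tests whether a point lies inside or on the boundary of a region of
#' interest. Non-convex polygons are handled by the even-odd rule; points on
#' an edge or vertex count as inside.
#'
#' @param p Numeric length-2 point, or an n x 2 matrix of points.
#' @param roi A [region_of_interest()] or a bare n x 2 vertex matrix.
#' @param tol Distance tolerance for the boundary test, pixels.
#' @return Logical vector, one element per point.
#' @examples
#' sq <- region_of_interest("cam1", rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)))
#' point_in_roi(c(5, 5), sq)   # TRUE
#' point_in_roi(c(10, 5), sq)  # TRUE: boundary counts as inside
#' point_in_roi(c(15, 5), sq)  # FALSE
#' @export
point_in_roi <- function(p, roi, tol = 1e-9) {
  v <- if (inherits(roi, "region_of_interest")) roi$vertices else as.matrix(roi)
  if (nrow(v) < 3) stop("polygon needs at least 3 vertices", call. = FALSE)
  pts <- if (is.matrix(p)) p else matrix(as.numeric(p), ncol = 2)
  px <- pts[, 1]; py <- pts[, 2]
  nv <- nrow(v)
  inside <- logical(length(px))
  on_edge <- logical(length(px))
  for (k in seq_len(nv)) {
    a <- v[k, ]; b <- v[k %% nv + 1, ]
    # boundary: perpendicular distance to segment within tol
    ab <- b - a
    len2 <- sum(ab^2)
    t <- if (len2 > 0) pmin(1, pmax(0, ((px - a[1]) * ab[1] + (py - a[2]) * ab[2]) / len2)) else 0
    dx <- px - (a[1] + t * ab[1]); dy <- py - (a[2] + t * ab[2])
    on_edge <- on_edge | (dx * dx + dy * dy <= tol * tol)
    # even-odd ray cast: horizontal ray toward +x
    crosses <- ((a[2] > py) != (b[2] > py)) &
      (px < a[1] + (py - a[2]) / (b[2] - a[2]) * (b[1] - a[1]))
    crosses[is.na(crosses)] <- FALSE
    inside <- xor(inside, crosses)
  }
  inside | on_edge
}

# Uniform sample of n points inside a polygon by rejection from the bounding
# box. Used by the session simulator.
sample_in_polygon <- function(n, vertices, margin = 0) {
  v <- if (inherits(vertices, "region_of_interest")) vertices$vertices else vertices
  lo <- apply(v, 2, min) + margin
  hi <- apply(v, 2, max) - margin
  if (any(hi <= lo)) stop("polygon too small for requested margin", call. = FALSE)
  out <- matrix(NA_real_, n, 2)
  need <- seq_len(n)
  guard <- 0
  while (length(need) > 0 && guard < 1000) {
    m <- length(need)
    cand <- cbind(stats::runif(m, lo[1], hi[1]), stats::runif(m, lo[2], hi[2]))
    ok <- point_in_roi(cand, v)
    out[need[ok], ] <- cand[ok, , drop = FALSE]
    need <- need[!ok]
    guard <- guard + 1
  }
  if (length(need) > 0) stop("rejection sampling failed; degenerate polygon?", call. = FALSE)
  out
}
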