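test_that("pose from corners recovers center and nose-ward heading", {
  sq <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10))
  p <- pose_from_corners(sq, front_edge = 0)
  expect_equal(p$center, c(5, 5))
  expect_equal(p$heading, c(0, -1))
  expect_equal(pose_from_corners(sq, front_edge = 2)$heading, c(0, 1))

  # unit square rotated 30 degrees about its center: heading rotates with it
  th <- 30 * pi / 180
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  ctr <- c(0.5, 0.5)
  sq1 <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  rotated <- t(rot %*% (t(sq1) - ctr)) + matrix(ctr, 4, 2, byrow = TRUE)
  expect_equal(pose_from_corners(rotated, 0)$heading,
               as.numeric(rot %*% c(0, -1)))
})

test_that("pose errors on degenerate input", {
  # front-edge midpoint coincides with the corner centroid
  dart <- rbind(c(0, 0), c(10, 0), c(10, -5), c(0, 5))
  expect_error(pose_from_corners(dart, 0), "degenerate pose")
  expect_error(pose_from_corners(rbind(c(0, 0), c(1, 0), c(2, 0)), 0),
               "4 corners")
  expect_error(pose_from_corners(rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)),
                                 front_edge = 4), "front_edge")
})

test_that("marker observations are validated", {
  good <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10))
  obs <- marker_observation("cam1", 3, 0.05, 0, good)
  expect_s3_class(obs, "marker_observation")
  expect_error(marker_observation("cam1", 0, 0, 0, good * 0), "zero area")
  bowtie <- rbind(c(0, 0), c(10, 10), c(10, 0), c(0, 10))
  expect_error(marker_observation("cam1", 0, 0, 0, bowtie), "simple")
})

test_that("yaw against the wall follows the signed toward-wall convention", {
  w <- wall_spec(c(100, 0), c(100, 100), interior_hint = c(50, 50))
  expect_equal(yaw_angle(c(1, 0), w), 90)    # facing the wall head-on
  expect_equal(yaw_angle(c(0, 1), w), 0)     # parallel to the wall
  expect_equal(yaw_angle(c(-1, 0), w), -90)  # facing away
  expect_error(yaw_angle(c(0, 0), w), "zero-length")
  expect_error(wall_spec(c(1, 1), c(1, 1), c(0, 0)), "differ")
  expect_error(wall_spec(c(0, 0), c(10, 0), c(5, 0)), "interior_hint")
})

test_that("yaw is invariant under translation and uniform scaling", {
  set.seed(11)
  for (i in 1:20) {
    p0 <- runif(2, 0, 200); p1 <- runif(2, 0, 200)
    hint <- runif(2, 0, 200)
    h <- runif(2, -1, 1)
    w <- try(wall_spec(p0, p1, hint), silent = TRUE)
    if (inherits(w, "try-error") || sqrt(sum(h^2)) < 1e-3) next
    base <- yaw_angle(h, w)
    shift <- runif(2, -50, 50); s <- runif(1, 0.1, 10)
    w2 <- wall_spec(s * (p0 + shift), s * (p1 + shift), s * (hint + shift))
    expect_equal(yaw_angle(h, w2), base, tolerance = 1e-10)
  }
})

test_that("rotating the heading shifts yaw by the same angle", {
  w <- chamber_wall()
  set.seed(12)
  for (i in 1:20) {
    yaw0 <- runif(1, -179, 179)
    delta <- runif(1, -179, 179)
    h0 <- heading_for_yaw(yaw0)
    h1 <- heading_for_yaw(yaw0 + delta)
    got <- yaw_angle(h1, w) - yaw_angle(h0, w)
    expect_equal(((got - delta + 180) %% 360) - 180, 0, tolerance = 1e-8)
  }
})

test_that("cyclic corner re-ordering with matching front edge keeps heading", {
  set.seed(13)
  for (i in 1:10) {
    corners <- corners_from_pose(runif(2, 50, 200), heading_for_yaw(runif(1, -180, 180)), 30)
    base <- pose_from_corners(corners, 0)
    for (k in 1:3) {
      perm <- corners[((0:3 + k) %% 4) + 1, ]
      shifted <- pose_from_corners(perm, (0 - k) %% 4)
      expect_equal(shifted$heading, base$heading, tolerance = 1e-12)
      expect_equal(shifted$center, base$center, tolerance = 1e-12)
    }
  }
})

test_that("point-in-ROI handles interior, exterior, and boundary", {
  sq <- region_of_interest("cam1", rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)))
  expect_true(point_in_roi(c(5, 5), sq))
  expect_false(point_in_roi(c(15, 5), sq))
  expect_true(point_in_roi(c(10, 5), sq))   # edge counts as inside
  expect_true(point_in_roi(c(0, 0), sq))    # vertex counts as inside
  expect_error(point_in_roi(c(0, 0), rbind(c(0, 0), c(1, 1))), "3 vertices")
  expect_error(region_of_interest("cam1", rbind(c(0, 0), c(1, 1))), "3 rows")
  # non-convex: even-odd rule
  lshape <- rbind(c(0, 0), c(10, 0), c(10, 4), c(4, 4), c(4, 10), c(0, 10))
  expect_true(point_in_roi(c(2, 8), lshape))
  expect_false(point_in_roi(c(8, 8), lshape))
})

test_that("point-in-ROI agrees with an independent even-odd oracle", {
  # scalar crossing-number oracle, written separately from the implementation
  oracle <- function(px, py, v) {
    n <- nrow(v); inside <- FALSE
    j <- n
    for (i in seq_len(n)) {
      if ((v[i, 2] > py) != (v[j, 2] > py)) {
        xint <- v[j, 1] + (py - v[j, 2]) / (v[i, 2] - v[j, 2]) * (v[i, 1] - v[j, 1])
        if (px < xint) inside <- !inside
      }
      j <- i
    }
    inside
  }
  set.seed(14)
  for (rep in 1:8) {
    nv <- sample(3:8, 1)
    v <- cbind(runif(nv, 0, 10), runif(nv, 0, 10))
    if (abs(arutrack:::polygon_area(v)) < 1) next
    # grid points offset to avoid boundary coincidences
    g <- as.matrix(expand.grid(x = seq(0.137, 9.9, by = 0.61),
                               y = seq(0.211, 9.9, by = 0.61)))
    got <- point_in_roi(g, v)
    want <- mapply(oracle, g[, 1], g[, 2], MoreArgs = list(v = v))
    # ignore points essentially on the boundary, where conventions differ
    near <- abs(got - want) & sapply(seq_len(nrow(g)), function(i) {
      min(sapply(seq_len(nv), function(k) {
        a <- v[k, ]; b <- v[k %% nv + 1, ]
        ab <- b - a; t <- max(0, min(1, sum((g[i, ] - a) * ab) / sum(ab^2)))
        sqrt(sum((g[i, ] - a - t * ab)^2))
      }))
    }) < 1e-6
    expect_equal(got[!near], want[!near])
  }
})
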