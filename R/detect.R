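# Marker detection in raster frames.
#
# The detector binarizes the frame, extracts dark connected components
# (EBImage::bwlabel / ocontour), fits a quadrilateral to each component
# boundary, refines the four edges to sub-pixel precision from intensity
# crossings, then perspective-samples the 6x6 cell grid and matches the
# decoded 4x4 code against the dictionary over all four corner rotations.
# Deterministic for a fixed frame.

# Bilinear interpolation at continuous image coordinates (x right, y down,
# pixel centers at (j - 0.5, i - 0.5)). Coordinates are clamped to the frame.
bilinear_sample <- function(img, x, y) {
  h <- nrow(img); w <- ncol(img)
  gx <- pmin(pmax(x - 0.5, 0), w - 1)
  gy <- pmin(pmax(y - 0.5, 0), h - 1)
  c0 <- pmin(floor(gx), w - 2); r0 <- pmin(floor(gy), h - 2)
  fx <- gx - c0; fy <- gy - r0
  i0 <- r0 + 1; j0 <- c0 + 1
  v00 <- img[cbind(i0, j0)]; v01 <- img[cbind(i0, j0 + 1)]
  v10 <- img[cbind(i0 + 1, j0)]; v11 <- img[cbind(i0 + 1, j0 + 1)]
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}

# Homography mapping source points (x, y) to destination points by the
# direct linear transform; src/dst are 4x2. Returns a 3x3 matrix.
homography_from_points <- function(src, dst) {
  a <- matrix(0, 8, 8); b <- numeric(8)
  for (i in 1:4) {
    x <- src[i, 1]; y <- src[i, 2]; u <- dst[i, 1]; v <- dst[i, 2]
    a[2 * i - 1, ] <- c(x, y, 1, 0, 0, 0, -u * x, -u * y)
    a[2 * i, ]     <- c(0, 0, 0, x, y, 1, -v * x, -v * y)
    b[2 * i - 1] <- u; b[2 * i] <- v
  }
  hv <- solve(a, b)
  matrix(c(hv, 1), 3, 3, byrow = TRUE)
}

apply_homography <- function(h, pts) {
  p <- cbind(pts, 1) %*% t(h)
  cbind(p[, 1] / p[, 3], p[, 2] / p[, 3])
}

# Initial quadrilateral from a boundary point cloud: pick 4 convex-hull
# vertices spanning maximal area, then order them clockwise on screen.
initial_quad <- function(pts) {
  hull <- pts[grDevices::chull(pts), , drop = FALSE]
  nh <- nrow(hull)
  if (nh < 4) return(NULL)
  d2 <- as.matrix(stats::dist(hull))
  ij <- which(d2 == max(d2), arr.ind = TRUE)[1, ]
  i <- ij[1]; j <- ij[2]
  pi_ <- hull[i, ]; pj <- hull[j, ]
  cross_d <- (pj[1] - pi_[1]) * (hull[, 2] - pi_[2]) -
    (pj[2] - pi_[2]) * (hull[, 1] - pi_[1])
  k <- which.max(cross_d); l <- which.min(cross_d)
  if (abs(cross_d[k]) < 1e-9 || abs(cross_d[l]) < 1e-9) return(NULL)
  q <- hull[c(i, k, j, l), , drop = FALSE]
  order_quad(q)
}

# Order 4 corners by angle about their centroid; with y down this yields the
# canonical on-screen clockwise winding (top-left, top-right, bottom-right,
# bottom-left for an upright square, up to cyclic start).
order_quad <- function(q) {
  cm <- colMeans(q)
  q[order(atan2(q[, 2] - cm[2], q[, 1] - cm[1])), , drop = FALSE]
}

# Sub-pixel refinement: for each edge, locate the dark->light intensity
# crossing along outward normals at several stations, fit a line through the
# crossing points, and intersect adjacent lines.
refine_quad_edges <- function(img, quad, search = 2.5) {
  cm <- colMeans(quad)
  lines <- vector("list", 4)
  for (e in 1:4) {
    a <- quad[e, ]; b <- quad[e %% 4 + 1, ]
    ev <- b - a; elen <- sqrt(sum(ev^2))
    if (elen < 4) return(NULL)
    ev <- ev / elen
    nv <- c(ev[2], -ev[1])
    mid <- (a + b) / 2
    if (sum((mid - cm) * nv) < 0) nv <- -nv   # outward
    ts <- seq(0.18, 0.82, length.out = 9)
    offs <- seq(-search, search, by = 0.25)
    pts <- matrix(NA_real_, length(ts), 2)
    for (s in seq_along(ts)) {
      base <- a + ts[s] * elen * ev
      prof <- bilinear_sample(img, base[1] + offs * nv[1], base[2] + offs * nv[2])
      thr <- (min(prof) + max(prof)) / 2
      if (max(prof) - min(prof) < 0.1) next
      above <- prof >= thr
      idx <- which(!above[-length(above)] & above[-1])  # dark -> light outward
      if (length(idx) == 0) next
      i0 <- idx[length(idx)]
      frac <- (thr - prof[i0]) / (prof[i0 + 1] - prof[i0])
      off <- offs[i0] + frac * (offs[i0 + 1] - offs[i0])
      pts[s, ] <- base + off * nv
    }
    pts <- pts[stats::complete.cases(pts), , drop = FALSE]
    if (nrow(pts) < 4) return(NULL)
    ctr <- colMeans(pts)
    sv <- svd(sweep(pts, 2, ctr))
    lines[[e]] <- list(p = ctr, d = sv$v[, 1])
  }
  out <- matrix(NA_real_, 4, 2)
  for (e in 1:4) {
    l1 <- lines[[(e - 2) %% 4 + 1]]   # edge ending at corner e
    l2 <- lines[[e]]                  # edge starting at corner e
    m <- cbind(l1$d, -l2$d)
    if (abs(det(m)) < 1e-9) return(NULL)
    t12 <- solve(m, l2$p - l1$p)
    out[e, ] <- l1$p + t12[1] * l1$d
  }
  out
}

# Sample the 6x6 cell means through a homography from the upright cell grid
# to the quad (corner 1 = grid top-left).
sample_cells <- function(img, quad) {
  src <- rbind(c(0, 0), c(6, 0), c(6, 6), c(0, 6))
  h <- homography_from_points(src, quad)
  sub <- c(0.3, 0.5, 0.7)
  cells <- matrix(NA_real_, 6, 6)
  for (i in 1:6) for (j in 1:6) {
    g <- as.matrix(expand.grid(x = j - 1 + sub, y = i - 1 + sub))
    p <- apply_homography(h, g)
    cells[i, j] <- mean(bilinear_sample(img, p[, 1], p[, 2]))
  }
  cells
}

decode_cells <- function(cells, dict, max_error_bits = 1) {
  thr <- (min(cells) + max(cells)) / 2
  if (max(cells) - min(cells) < 0.2) return(NULL)
  bits <- (cells > thr) * 1L
  border <- c(bits[1, ], bits[6, ], bits[2:5, 1], bits[2:5, 6])
  if (sum(border) > 0) return(NULL)       # border ring must be all black
  code <- bits[2:5, 2:5]
  errs <- vapply(dict, function(m) sum(m != code), numeric(1))
  best <- which.min(errs)
  if (errs[best] > max_error_bits) return(NULL)
  list(marker_id = best - 1L, error_bits = errs[best])
}

#' Detect square fiducial markers in a frame
#'
#' Finds dictionary markers in a grayscale frame and returns their ids and
#' sub-pixel corner coordinates in canonical order (pattern top-left first,
#' then clockwise on screen). Detection is deterministic for a fixed frame.
#'
#' @param image Numeric height x width matrix in [0, 1], or a file path to a
#'   PNG frame (read via [read_frame()]).
#' @param dict Dictionary from [marker_dictionary()], or the string
#'   `"4x4_16"` / `"4x4_32"`; an unrecognized string is a configuration
#'   error.
#' @param target_marker_id Keep only this id (`NULL` keeps all).
#' @param min_side Minimum marker side length in pixels to accept.
#' @param max_error_bits Bit errors tolerated when matching the code.
#' @return List of detections, each a list with `marker_id`, `corners`
#'   (4x2), and `error_bits`. Empty list when nothing is found.
#' @export
detect_markers <- function(image, dict = marker_dictionary(),
                           target_marker_id = NULL, min_side = 8,
                           max_error_bits = 1) {
  if (is.character(dict)) {
    dict <- switch(dict,
      "4x4_16" = marker_dictionary(16),
      "4x4_32" = marker_dictionary(32),
      stop("unknown dictionary identifier: ", dict, call. = FALSE))
  }
  if (is.character(image)) image <- read_frame(image)
  stopifnot(is.matrix(image), is.numeric(image))
  h <- nrow(image); w <- ncol(image)
  rng <- range(image)
  if (diff(rng) < 0.1) return(list())
  thr <- mean(rng)
  dark <- (t(image) < thr) * 1            # EBImage convention: first dim = x
  lab <- EBImage::bwlabel(dark)
  nlab <- max(lab)
  if (nlab == 0) return(list())
  areas <- tabulate(lab[lab > 0], nbins = nlab)
  contours <- EBImage::ocontour(lab)
  out <- list()
  for (k in seq_len(nlab)) {
    if (areas[k] < max(25, min_side^2 / 2) || areas[k] > 0.4 * w * h) next
    oc <- contours[[k]]
    if (is.null(oc) || nrow(oc) < 12) next
    pts <- cbind(oc[, 1] + 0.5, oc[, 2] + 0.5)  # 0-based indices -> pixel centers
    quad <- initial_quad(pts)
    if (is.null(quad)) next
    sides <- sqrt(rowSums((quad[c(2, 3, 4, 1), ] - quad)^2))
    if (min(sides) < min_side || max(sides) / min(sides) > 4) next
    refined <- refine_quad_edges(image, quad)
    if (!is.null(refined) && is_simple_quad(refined) &&
        abs(polygon_area(refined)) > 1) {
      quad <- order_quad(refined)
    }
    hit <- NULL
    for (r in 0:3) {
      qr <- quad[((0:3 + r) %% 4) + 1, , drop = FALSE]
      dec <- decode_cells(sample_cells(image, qr), dict, max_error_bits)
      if (!is.null(dec)) {
        hit <- c(dec, list(corners = qr))
        break
      }
    }
    if (is.null(hit)) next
    if (!is.null(target_marker_id) && hit$marker_id != target_marker_id) next
    out[[length(out) + 1]] <- hit
  }
  out
}

#' Read a PNG frame as a grayscale matrix
#'
#' @param path Path to a PNG file.
#' @return Height x width numeric matrix in [0, 1] (multi-channel images are
#'   averaged to luminance).
#' @export
read_frame <- function(path) {
  if (!file.exists(path)) stop("cannot read frame: ", path, call. = FALSE)
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- apply(img[, , 1:min(3, dim(img)[3]), drop = FALSE], c(1, 2), mean)
  img
}

#' Write a grayscale frame to PNG
#'
#' @param image Height x width matrix in [0, 1].
#' @param path Output path.
#' @export
write_frame <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' Detect markers across a directory of PNG frames
#'
#' Frames are named `<camera>_<frameindex>.png`. Each frame contributes one
#' detection-log row per marker found, or a single `detected = 0` row.
#'
#' @param dir Directory of PNG frames.
#' @param camera_id Camera whose frames to process.
#' @param fps Frame rate used to derive timestamps from frame indices.
#' @param dict,target_marker_id Passed to [detect_markers()].
#' @param session_id Session identifier recorded in the log.
#' @return Detection-log data frame (see [empty_detection_log()]).
#' @export
detect_frames_dir <- function(dir, camera_id, fps = 60,
                              dict = marker_dictionary(),
                              target_marker_id = NULL, session_id = "session") {
  pat <- paste0("^", camera_id, "_([0-9]+)\\.png$")
  files <- list.files(dir, pattern = pat)
  if (length(files) == 0) stop("no frames for camera ", camera_id, " in ", dir,
                               call. = FALSE)
  idx <- as.integer(sub(pat, "\\1", files))
  ord <- order(idx)
  files <- files[ord]; idx <- idx[ord]
  rows <- vector("list", length(files))
  for (i in seq_along(files)) {
    dets <- detect_markers(file.path(dir, files[i]), dict = dict,
                           target_marker_id = target_marker_id)
    ts <- idx[i] / fps
    if (length(dets) == 0) {
      rows[[i]] <- detection_log_row(session_id, camera_id, idx[i], ts)
    } else {
      rows[[i]] <- do.call(rbind, lapply(dets, function(d) {
        detection_log_row(session_id, camera_id, idx[i], ts,
                          marker_id = d$marker_id, corners = d$corners)
      }))
    }
  }
  do.call(rbind, rows)
}
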