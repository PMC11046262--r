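# Synthetic marker-frame renderer.
#
# Rasterizes a marker bitmap into a grayscale frame under rotation and
# translation, with a white quiet-zone border (one cell wide) around the
# black marker ring so the marker separates from any background, and
# optional linear motion blur along the heading direction. Pixel (row i,
# col j) of the image matrix covers [j-1, j] x [i-1, i] in continuous image
# coordinates; its center is (j - 0.5, i - 0.5).

#' Render a marker into a synthetic frame
#'
#' Draws the full marker bitmap (black ring plus code cells) of side
#' `size_px` pixels, centered at `center`, rotated by `angle_deg`, onto a
#' uniform background, with a one-cell white quiet zone. At angle 0 the
#' marker is upright (canonical top-left corner at the image top-left of the
#' marker) and the nose-ward heading is (0, -1); positive angles rotate the
#' heading clockwise on screen. Optional linear motion blur averages
#' `blur_kernel` unit-spaced copies displaced along the heading, emulating
#' marker motion at `blur_kernel * fps * fov_width / resolution_width` cm/s
#' (see [blur_velocity()]).
#'
#' @param bitmap 6x6 binary bitmap from [marker_bitmap()] (0 = black).
#' @param center Length-2 marker center in pixels.
#' @param angle_deg Rotation of the marker, degrees.
#' @param size_px Side length of the black marker square, pixels.
#' @param frame_size Length-2 `c(width, height)` of the frame, pixels.
#' @param blur_kernel Integer blur length in pixels; 0 or 1 disables blur.
#' @param background Background intensity in [0, 1].
#' @param supersample Sub-pixel sampling factor per axis for anti-aliasing.
#' @return List: `image` (height x width matrix in [0, 1]), `corners`
#'   (4x2 planted corner ground truth, canonical order), `center`,
#'   `heading` (unit vector), `marker_id` attribute left to the caller.
#' @export
render_marker_frame <- function(bitmap, center, angle_deg, size_px,
                                frame_size = c(320, 240), blur_kernel = 0,
                                background = 0.7, supersample = 3) {
  stopifnot(identical(dim(bitmap), c(6L, 6L)), size_px > 0)
  width <- frame_size[1]; height <- frame_size[2]
  th <- angle_deg * pi / 180
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)  # columns: image of (1,0),(0,1)
  heading <- as.numeric(rot %*% c(0, -1))
  s <- size_px
  cs <- s / 6                      # cell size
  half_ext <- s / 2 + cs           # marker + quiet zone half-extent
  k <- max(0L, as.integer(blur_kernel))
  offsets <- if (k > 1) (seq_len(k) - (k + 1) / 2) else 0
  # bounding check incl. blur displacement: rotated square reach is half_ext*sqrt(2)
  reach <- half_ext * sqrt(2) + max(abs(offsets))
  if (center[1] - reach < 0 || center[1] + reach > width ||
      center[2] - reach < 0 || center[2] + reach > height) {
    stop("marker (with quiet zone/blur) extends past the frame", call. = FALSE)
  }

  xs <- seq_len(width) - 0.5
  ys <- seq_len(height) - 0.5
  X <- matrix(xs, height, width, byrow = TRUE)
  Y <- matrix(ys, height, width)
  ss <- max(1L, as.integer(supersample))
  sub <- (seq_len(ss) - (ss + 1) / 2) / ss

  acc <- matrix(0, height, width)
  nsmp <- 0
  for (off in offsets) {
    cx <- center[1] + off * heading[1]
    cy <- center[2] + off * heading[2]
    for (dx in sub) for (dy in sub) {
      # inverse rotation (rot is orthonormal)
      px <- X + dx - cx; py <- Y + dy - cy
      lx <- rot[1, 1] * px + rot[2, 1] * py
      ly <- rot[1, 2] * px + rot[2, 2] * py
      val <- matrix(background, height, width)
      inq <- pmax(abs(lx), abs(ly)) <= half_ext
      val[inq] <- 1  # quiet zone white
      inm <- pmax(abs(lx), abs(ly)) < s / 2
      if (any(inm)) {
        col <- pmin(6L, pmax(1L, floor((lx[inm] + s / 2) / cs) + 1L))
        row <- pmin(6L, pmax(1L, floor((ly[inm] + s / 2) / cs) + 1L))
        val[inm] <- bitmap[cbind(row, col)]
      }
      acc <- acc + val
      nsmp <- nsmp + 1
    }
  }
  img <- acc / nsmp
  corners <- rbind(c(-s / 2, -s / 2), c(s / 2, -s / 2),
                   c(s / 2, s / 2), c(-s / 2, s / 2))
  corners <- t(rot %*% t(corners)) + matrix(center, 4, 2, byrow = TRUE)
  list(image = img, corners = corners, center = as.numeric(center),
       heading = heading)
}
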