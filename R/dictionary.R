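# Deterministic 4x4 marker dictionary.
#
# Square fiducial markers are a black border ring around an n x n binary
# pattern; the pattern's dictionary index is its identity. The dictionary
# here is generated once, deterministically, under a fixed internal seed:
# candidate patterns are accepted greedily subject to (i) a minimum Hamming
# distance of 4 to every accepted pattern under all four rotations, (ii)
# distance >= 4 to their own non-trivial rotations (so orientation is
# unambiguous), (iii) distance >= 3 between every accepted pattern and every
# rotation of every accepted pattern's mirror image (so a mirrored frame
# never decodes), and (iv) 4..12 white bits (both classes present, which the
# cell-threshold decoder needs).

.dict_cache <- new.env(parent = emptyenv())

rotate_bits <- function(m) {
  # 90 degrees clockwise
  t(m[nrow(m):1, , drop = FALSE])
}

mirror_bits <- function(m) m[, ncol(m):1, drop = FALSE]

all_rotations <- function(m) {
  out <- vector("list", 4)
  out[[1]] <- m
  for (k in 2:4) out[[k]] <- rotate_bits(out[[k - 1]])
  out
}

min_rot_distance <- function(a, b) {
  min(vapply(all_rotations(b), function(r) sum(a != r), numeric(1)))
}

#' Marker dictionary
#'
#' Returns the package's deterministic dictionary of 4x4 marker patterns as a
#' list of 0/1 matrices (1 = white cell). Patterns are rotation-unambiguous
#' and mutually separated by a rotational Hamming distance of at least 4, so
#' the detector can correct one misread bit; mirrored patterns never match.
#' The same dictionary backs both the renderer and the detector.
#'
#' @param n Number of markers (up to 32).
#' @return List of `n` binary 4x4 matrices; marker id `i` is element `i + 1`
#'   (ids are 0-based, as is conventional for fiducial dictionaries).
#' @export
marker_dictionary <- function(n = 16) {
  stopifnot(n >= 1, n <= 32)
  key <- "dict32"
  if (is.null(.dict_cache[[key]])) {
    .dict_cache[[key]] <- generate_dictionary(32)
  }
  .dict_cache[[key]][seq_len(n)]
}

generate_dictionary <- function(n) {
  # fixed internal stream; leave the caller's RNG state untouched
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(406010, kind = "Mersenne-Twister")
  accepted <- list()
  tries <- 0
  while (length(accepted) < n && tries < 1e5) {
    tries <- tries + 1
    cand <- matrix(sample(0:1, 16, replace = TRUE), 4, 4)
    nw <- sum(cand)
    if (nw < 4 || nw > 12) next
    rots <- all_rotations(cand)
    if (min(vapply(rots[2:4], function(r) sum(cand != r), numeric(1))) < 4) next
    mir_rots <- all_rotations(mirror_bits(cand))
    if (min(vapply(mir_rots, function(r) sum(cand != r), numeric(1))) < 3) next
    ok <- TRUE
    for (m in accepted) {
      if (min_rot_distance(m, cand) < 4) { ok <- FALSE; break }
      if (min(vapply(mir_rots, function(r) sum(m != r), numeric(1))) < 3) { ok <- FALSE; break }
      if (min(vapply(all_rotations(mirror_bits(m)), function(r) sum(cand != r),
                     numeric(1))) < 3) { ok <- FALSE; break }
    }
    if (ok) accepted[[length(accepted) + 1]] <- cand
  }
  if (length(accepted) < n) stop("dictionary generation failed", call. = FALSE)
  accepted
}

#' Full marker bitmap including the border ring
#'
#' Expands a dictionary pattern to the complete printable bitmap: a one-cell
#' black border surrounding the 4x4 code, i.e. a 6x6 grid of 0/1 cells
#' (0 = black, 1 = white). Row 1 is the top of the upright marker; the
#' canonical top-left corner is the outer corner of cell (1, 1).
#'
#' @param marker_id 0-based dictionary index.
#' @param dict Dictionary from [marker_dictionary()].
#' @return 6x6 binary matrix.
#' @export
marker_bitmap <- function(marker_id, dict = marker_dictionary()) {
  if (marker_id < 0 || marker_id >= length(dict)) {
    stop("unknown marker id ", marker_id, call. = FALSE)
  }
  full <- matrix(0L, 6, 6)
  full[2:5, 2:5] <- dict[[marker_id + 1]]
  full
}
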