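#' Block-matching configuration
#'
#' Parameters of the similarity search that stacks 2D patches into 3D
#' groups. Defaults are the standard settings for MVCT slices on the
#' windowed `[0, 255]` processing scale: 8x8 patches, groups of 5, a
#' 39x39 search window, sliding interval 3 and match threshold 400.
#'
#' @param n_block patch side in pixels.
#' @param n_number maximum group depth (number of stacked blocks).
#' @param window search window side `L` in pixels (odd).
#' @param step sliding interval between reference anchors, pixels.
#' @param tau_match maximum admissible block distance (squared l2 per
#'   pixel on the processing scale).
#' @param lambda_2d prefilter shrinkage coefficient; with the default 0
#'   the distance is computed on raw blocks (the usual convention at
#'   moderate noise), otherwise blocks are 2D-transformed and
#'   hard-thresholded at `lambda_2d * sigma` before the distance.
#' @param sigma assumed noise standard deviation on the processing scale
#'   (only used by the prefilter when `lambda_2d > 0`).
#' @param depth one of `"at_most"` (members are candidates within
#'   `tau_match`, so groups can be shallower than `n_number`) or
#'   `"exact"` (always the `n_number` nearest blocks, ignoring
#'   `tau_match`).
#' @return An object of class `match_config`.
#' @export
match_config <- function(n_block = 8L, n_number = 5L, window = 39L,
                         step = 3L, tau_match = 400, lambda_2d = 0,
                         sigma = 0, depth = c("at_most", "exact")) {
  depth <- match.arg(depth)
  n_block <- as.integer(n_block); n_number <- as.integer(n_number)
  window <- as.integer(window); step <- as.integer(step)
  if (n_block < 2L) stop("n_block must be >= 2", call. = FALSE)
  if (n_number < 1L) stop("n_number must be >= 1", call. = FALSE)
  if (window < n_block) stop("window must be >= n_block", call. = FALSE)
  if (step < 1L) stop("step must be >= 1", call. = FALSE)
  if (tau_match < 0) stop("tau_match must be >= 0", call. = FALSE)
  if (lambda_2d < 0 || sigma < 0)
    stop("lambda_2d and sigma must be >= 0", call. = FALSE)
  structure(list(n_block = n_block, n_number = n_number, window = window,
                 step = step, tau_match = tau_match, lambda_2d = lambda_2d,
                 sigma = sigma, depth = depth), class = "match_config")
}

#' Prefiltered block distance
#'
#' Distance between two equally sized blocks:
#' `|| g(T(ref)) - g(T(cand)) ||_2^2 / n_block^2`, where `T` is the 2D
#' block transform and `g` hard thresholding at `lambda_2d * sigma`.
#' With `lambda_2d = 0` (the default) no shrinkage is applied and the
#' distance reduces to the plain per-pixel squared l2 difference, which
#' is what `tau_match = 400` on the `[0, 255]` scale refers to. The
#' distance is symmetric and zero iff the blocks are identical.
#'
#' @param ref,cand numeric `n_block x n_block` matrices on the
#'   processing scale.
#' @param cfg a [match_config()].
#' @return a single distance, >= 0.
#' @export
prefilter_distance <- function(ref, cand, cfg = match_config()) {
  ref <- as.matrix(ref); cand <- as.matrix(cand)
  if (!all(dim(ref) == cfg$n_block) || !all(dim(cand) == cfg$n_block))
    stop("blocks must be n_block x n_block", call. = FALSE)
  if (cfg$lambda_2d > 0) {
    lam <- cfg$lambda_2d * cfg$sigma
    ref <- hard_threshold(forward_2d(ref), lam)$values
    cand <- hard_threshold(forward_2d(cand), lam)$values
  }
  sum((ref - cand)^2) / cfg$n_block^2
}

#' Reference anchor positions along one axis
#'
#' Anchors at `0, step, 2 step, ...` (0-based, patch anchored at its
#' top-left pixel) with a final anchor clamped to `side - n_block` so the
#' last patch touches the border and every pixel is covered.
#'
#' @param side image extent along the axis, pixels.
#' @param n_block patch side.
#' @param step sliding interval.
#' @return integer vector of 0-based anchor positions.
#' @export
reference_anchors <- function(side, n_block, step) {
  last <- side - n_block
  if (last < 0L) stop("image smaller than the block size", call. = FALSE)
  unique(as.integer(c(seq(0L, last, by = step), last)))
}

.match_w2d <- function(cfg) {
  if (cfg$lambda_2d > 0) .wavelet_matrix(cfg$n_block)$analysis
  else diag(cfg$n_block)
}

.make_group <- function(img, ref, members, distances, n_block) {
  m <- nrow(members)
  stack <- array(0, c(n_block, n_block, m))
  for (k in seq_len(m)) {
    r <- members[k, 1]; c <- members[k, 2]
    stack[, , k] <- img[(r + 1):(r + n_block), (c + 1):(c + n_block)]
  }
  structure(list(ref_coord = ref, members = members, distances = distances,
                 stack = stack), class = "block_group")
}

#' Find the blocks most similar to a reference block
#'
#' Scans every integer anchor inside the `window x window` box centred on
#' `ref_coord` (clipped at the image borders), computes the prefiltered
#' distance to the reference block and keeps, after the `tau_match`
#' filter, the `n_number` closest. The reference itself is always the
#' first member; remaining members are ordered by distance, ties broken
#' by ascending row-major scan order, so the result is deterministic.
#'
#' @param img numeric matrix on the processing scale.
#' @param ref_coord 0-based `(row, col)` anchor of the reference block.
#' @param cfg a [match_config()].
#' @return A `block_group`: `ref_coord`, `members` (0-based anchor
#'   matrix, reference first), `distances`, and `stack`
#'   (`n_block x n_block x depth` array whose first slab is the
#'   reference block).
#' @export
find_similar <- function(img, ref_coord, cfg = match_config()) {
  img <- as.matrix(img)
  res <- .cpp_block_match(img, as.integer(ref_coord[1]),
                          as.integer(ref_coord[2]),
                          cfg$n_block, cfg$n_number, cfg$window,
                          cfg$tau_match, cfg$lambda_2d * cfg$sigma,
                          .match_w2d(cfg), cfg$depth == "exact")
  .make_group(img, res$ref[1, ], res$members[[1]], res$distances[[1]],
              cfg$n_block)
}

#' Match every reference block of an image
#'
#' Runs [find_similar()] at every reference anchor given by
#' [reference_anchors()] on both axes (row-major order), so that every
#' pixel of the image is covered by at least one reference patch.
#'
#' @inheritParams find_similar
#' @return list of `block_group` objects, one per reference anchor.
#' @export
iterate_references <- function(img, cfg = match_config()) {
  img <- as.matrix(img)
  ar <- reference_anchors(nrow(img), cfg$n_block, cfg$step)
  ac <- reference_anchors(ncol(img), cfg$n_block, cfg$step)
  res <- .cpp_block_match(img, ar, ac, cfg$n_block, cfg$n_number,
                          cfg$window, cfg$tau_match,
                          cfg$lambda_2d * cfg$sigma, .match_w2d(cfg),
                          cfg$depth == "exact")
  lapply(seq_len(nrow(res$ref)), function(g)
    .make_group(img, res$ref[g, ], res$members[[g]], res$distances[[g]],
                cfg$n_block))
}
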