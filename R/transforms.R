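## Linear transforms used by block matching and collaborative filtering:
## a separable biorthogonal-1.5 wavelet on square blocks, an orthonormal
## transform (Hadamard or DCT-II) along the group stack, and the hard
## thresholding operator.

# bior1.5 analysis filter bank (10-tap lowpass, 2-tap highpass)
.bior15_dec_lo <- c(
   0.016572815184059706, -0.016572815184059706,
  -0.121533978016437850,  0.121533978016437850,
   0.707106781186547600,  0.707106781186547600,
   0.121533978016437850, -0.121533978016437850,
  -0.016572815184059706,  0.016572815184059706)
.bior15_dec_hi <- c(-0.7071067811865476, 0.7071067811865476)

.transform_cache <- new.env(parent = emptyenv())

# single analysis step on even length n: returns n x n matrix whose first
# n/2 rows are the lowpass (approximation) outputs and last n/2 the
# highpass, under half-sample symmetric extension
.dwt_step_matrix <- function(n) {
  step_one <- function(f) {
    p <- length(f)
    m <- matrix(0, n / 2, n)
    for (k in seq_len(n / 2)) {
      for (i in seq_along(f)) {
        # tap i of filter f hits extended index 2k - 1 + (i - p/2)
        j <- 2 * k - 1 + i - length(f) / 2
        # half-sample symmetric reflection into 1..n
        while (j < 1 || j > n) {
          if (j < 1) j <- 1 - j
          if (j > n) j <- 2 * n + 1 - j
        }
        m[k, j] <- m[k, j] + f[i]
      }
    }
    m
  }
  rbind(step_one(.bior15_dec_lo), step_one(.bior15_dec_hi))
}

# full multilevel bior1.5 analysis matrix for a power-of-2 side
.wavelet_matrix <- function(n) {
  key <- paste0("bior2d_", n)
  if (!is.null(.transform_cache[[key]])) return(.transform_cache[[key]])
  if (n < 2 || bitwAnd(n, n - 1L) != 0)
    stop("block side must be a power of 2 (>= 2), got ", n, call. = FALSE)
  w <- diag(n)
  size <- n
  while (size >= 2) {
    step <- diag(n)
    step[1:size, 1:size] <- .dwt_step_matrix(size)
    w <- step %*% w
    size <- size / 2
  }
  inv <- solve(w)
  .transform_cache[[key]] <- list(analysis = w, synthesis = inv)
  .transform_cache[[key]]
}

.hadamard_matrix <- function(m) {
  h <- matrix(1, 1, 1)
  while (nrow(h) < m) h <- rbind(cbind(h, h), cbind(h, -h))
  h / sqrt(m)
}

.dct2_matrix <- function(m) {
  k <- 0:(m - 1)
  mat <- sqrt(2 / m) * cos(pi * (2 * matrix(k, m, m, byrow = TRUE) + 1) *
                             matrix(k, m, m) / (2 * m))
  mat[1, ] <- 1 / sqrt(m)
  mat
}

# orthonormal stack transform: Hadamard when m is a power of 2, DCT-II
# otherwise (group depths pruned by the match threshold need not be 2^k)
stack_transform_matrix <- function(m) {
  key <- paste0("stack_", m)
  if (!is.null(.transform_cache[[key]])) return(.transform_cache[[key]])
  stopifnot(m >= 1)
  mat <- if (m == 1) matrix(1, 1, 1)
    else if (bitwAnd(m, m - 1L) == 0) .hadamard_matrix(m)
    else .dct2_matrix(m)
  .transform_cache[[key]] <- mat
  mat
}

#' Hard thresholding
#'
#' Zeroes every coefficient whose magnitude does not exceed `lam`
#' (boundary hits `|c| == lam` are zeroed) and reports how many
#' coefficients survive. The retained count feeds the aggregation
#' weights of the collaborative filter.
#'
#' @param coeffs numeric vector/matrix/array of transform coefficients.
#' @param lam threshold, >= 0.
#' @return list with `values` (same shape as `coeffs`) and
#'   `retained_count`.
#' @export
hard_threshold <- function(coeffs, lam) {
  if (!is.numeric(lam) || length(lam) != 1L || is.na(lam) || lam < 0)
    stop("threshold lam must be a single value >= 0", call. = FALSE)
  out <- coeffs
  out[abs(out) <= lam] <- 0
  list(values = out, retained_count = sum(out != 0))
}

#' 2D block transform (biorthogonal 1.5 wavelet)
#'
#' Full separable multilevel bior1.5 decomposition of a square block with
#' half-sample symmetric boundary extension. `inverse_2d` is the exact
#' inverse (synthesis bank); round trips are identity to machine
#' precision.
#'
#' @param block square numeric matrix with power-of-2 side (default use
#'   is 8x8).
#' @return coefficient matrix of the same shape.
#' @export
forward_2d <- function(block) {
  block <- as.matrix(block)
  if (nrow(block) != ncol(block))
    stop("block must be square", call. = FALSE)
  w <- .wavelet_matrix(nrow(block))$analysis
  w %*% block %*% t(w)
}

#' @param coeffs coefficient matrix from [forward_2d()].
#' @rdname forward_2d
#' @export
inverse_2d <- function(coeffs) {
  coeffs <- as.matrix(coeffs)
  s <- .wavelet_matrix(nrow(coeffs))$synthesis
  s %*% coeffs %*% t(s)
}

#' 1D stack transform (orthonormal)
#'
#' Transform applied along the third (stack) dimension of a matched
#' group: an orthonormal Hadamard transform when the length is a power
#' of 2, an orthonormal DCT-II otherwise, identity for length 1. Being
#' orthonormal it preserves the l2 norm (Parseval).
#'
#' @param v numeric vector (one stack fibre).
#' @return coefficient vector of the same length.
#' @export
forward_1d <- function(v) {
  drop(stack_transform_matrix(length(v)) %*% v)
}

#' @rdname forward_1d
#' @export
inverse_1d <- function(v) {
  drop(crossprod(stack_transform_matrix(length(v)), v))
}

#' 3D group transform
#'
#' The separable 3D transform of a matched group: the 2D bior1.5
#' transform on each block followed by the orthonormal 1D transform
#' along the stack axis. `inverse_3d` inverts both steps.
#'
#' @param group numeric array `n x n x m` (a stack of `m` blocks).
#' @return coefficient array of the same shape.
#' @export
forward_3d <- function(group) {
  group <- .as_group_array(group)
  d <- dim(group)
  w <- .wavelet_matrix(d[1])$analysis
  out <- apply_2d_batch(group, w)
  apply_stack_transform(out, stack_transform_matrix(d[3]))
}

#' @param coeffs coefficient array from [forward_3d()].
#' @rdname forward_3d
#' @export
inverse_3d <- function(coeffs) {
  coeffs <- .as_group_array(coeffs)
  d <- dim(coeffs)
  out <- apply_stack_transform(coeffs, t(stack_transform_matrix(d[3])))
  apply_2d_batch(out, .wavelet_matrix(d[1])$synthesis)
}

.as_group_array <- function(group) {
  if (is.matrix(group)) dim(group) <- c(dim(group), 1L)
  if (!is.array(group) || length(dim(group)) != 3L)
    stop("group must be an n x n x m array", call. = FALSE)
  group
}

# W %*% X %*% t(W) for every n x n slab of a (n, n, k) array, vectorized
apply_2d_batch <- function(arr, w) {
  d <- dim(arr)
  x <- w %*% matrix(arr, d[1])                    # rows of every slab
  x <- array(x, d)
  x <- aperm(x, c(2, 1, 3))
  x <- w %*% matrix(x, d[2])                      # columns of every slab
  aperm(array(x, d[c(2, 1, 3)]), c(2, 1, 3))
}

# M applied along the 3rd dimension of a (n, n, m) array
apply_stack_transform <- function(arr, m) {
  d <- dim(arr)
  x <- matrix(arr, d[1] * d[2], d[3])
  array(x %*% t(m), d)
}
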