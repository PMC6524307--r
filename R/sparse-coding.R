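#' Per-block DC removal
#'
#' Subtracts the mean of every 2D block in a group stack (one DC value
#' per block). Adding the DC values back reproduces the input exactly;
#' the centered stack is what gets sparse-coded, and the DC values are
#' restored at reconstruction.
#'
#' @param stack numeric `n x n x m` array (a matched group).
#' @return list with `centered` (same shape) and `dc` (length `m`).
#' @export
remove_dc <- function(stack) {
  stack <- .as_group_array(stack)
  m <- dim(stack)[3]
  dc <- numeric(m)
  for (k in seq_len(m)) {
    dc[k] <- mean(stack[, , k])
    stack[, , k] <- stack[, , k] - dc[k]
  }
  list(centered = stack, dc = dc)
}

#' @param centered centered stack from `remove_dc`.
#' @param dc per-block DC values.
#' @rdname remove_dc
#' @export
add_dc <- function(centered, dc) {
  centered <- .as_group_array(centered)
  for (k in seq_len(dim(centered)[3]))
    centered[, , k] <- centered[, , k] + dc[k]
  centered
}

#' Orthogonal matching pursuit over the discriminative dictionary
#'
#' Greedy sparse approximation: at each iteration the atom with the
#' largest absolute correlation with the current residual is added (ties
#' resolved to the lowest atom index), the coefficients are refit by
#' least squares on the selected set, and the residual updated. Stops
#' when `c_dfr` atoms are selected or the residual l2 norm falls to
#' `tol_rel * ||signal||`. The result is split into the high-quality and
#' noise-model parts by atom label.
#'
#' @param signal numeric vector, the vectorized (DC-removed) group; its
#'   length must equal the atom length.
#' @param dict a [feature_dictionary()].
#' @param c_dfr sparsity cap (joint, over both sub-dictionaries).
#' @param tol_rel relative residual tolerance.
#' @param dc optional per-block DC values to carry along.
#' @return An object of class `sparse_code`: `indices`, `coeffs`,
#'   `hq_part`, `na_part`, `residual_norm`, `dc`.
#' @export
omp <- function(signal, dict, c_dfr = 10L, tol_rel = 1e-6, dc = NULL) {
  stopifnot(inherits(dict, "feature_dictionary"))
  if (length(signal) != nrow(dict$atoms))
    stop("signal length does not match atom length", call. = FALSE)
  res <- .cpp_omp_batch(dict$atoms, matrix(signal, ncol = 1),
                        as.integer(c_dfr), tol_rel)
  .sparse_code(res$indices[[1]], res$coeffs[[1]], res$residual_norm[1],
               dict, dc)
}

# batch variant used by the pipeline: one column of `signals` per group
omp_batch <- function(signals, dict, c_dfr = 10L, tol_rel = 1e-6) {
  .cpp_omp_batch(dict$atoms, signals, as.integer(c_dfr), tol_rel)
}

.sparse_code <- function(indices, coeffs, residual_norm, dict, dc = NULL) {
  hq <- dict$labels[indices] == "HQ"
  structure(list(
    indices = indices, coeffs = coeffs,
    hq_part = list(indices = indices[hq], coeffs = coeffs[hq]),
    na_part = list(indices = indices[!hq], coeffs = coeffs[!hq]),
    residual_norm = residual_norm, dc = dc),
    class = "sparse_code")
}

#' Reconstructions from a sparse code
#'
#' `reconstruct_hq` rebuilds the group from the high-quality atoms only,
#' adding the per-block DC values back — the noise-model coefficients are
#' discarded, which is the enhancement step. `reconstruct_na` returns the
#' discarded noise-model content (no DC), useful for diagnostics.
#'
#' @param code a `sparse_code` (with `dc` set for `reconstruct_hq`).
#' @param dict the [feature_dictionary()] the code was computed against.
#' @return `n x n x m` array on the processing scale.
#' @export
reconstruct_hq <- function(code, dict) {
  d <- dict$atom_dims
  v <- .reconstruct_part(code$hq_part, dict)
  stack <- array(v, d)
  if (!is.null(code$dc)) stack <- add_dc(stack, code$dc)
  stack
}

#' @rdname reconstruct_hq
#' @export
reconstruct_na <- function(code, dict) {
  array(.reconstruct_part(code$na_part, dict), dict$atom_dims)
}

.reconstruct_part <- function(part, dict) {
  if (!length(part$indices)) return(numeric(nrow(dict$atoms)))
  drop(dict$atoms[, part$indices, drop = FALSE] %*% part$coeffs)
}
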