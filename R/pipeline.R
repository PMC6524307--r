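#' Enhancement pipeline configuration
#'
#' Bundles the block-matching parameters with the filtering method and
#' its thresholds. `method = "BM3D"` runs grouping plus collaborative 3D
#' hard-threshold filtering only; `method = "BM3D_DFR"` first replaces
#' every matched group by its discriminative sparse reconstruction (high
#' quality atoms only) and then applies the same collaborative filter.
#'
#' @param match a [match_config()].
#' @param method `"BM3D"` or `"BM3D_DFR"`.
#' @param dict a [feature_dictionary()] (required for `"BM3D_DFR"`).
#' @param lambda_3d 3D hard-threshold coefficient; the threshold applied
#'   to the 3D transform coefficients is `lambda_3d * sigma`.
#' @param sigma noise standard deviation on the `[0, 255]` processing
#'   scale; `NULL` (default) estimates it from the slice via the median
#'   absolute deviation of the finest diagonal wavelet subband.
#' @param c_dfr sparsity cap of the sparse-coding step.
#' @param tol_rel relative residual tolerance of the sparse-coding step.
#' @param w display [windowing()] mapping HU to the processing scale.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(match = match_config(),
                            method = c("BM3D", "BM3D_DFR"),
                            dict = NULL, lambda_3d = 2.7, sigma = NULL,
                            c_dfr = 10L, tol_rel = 1e-6,
                            w = windowing()) {
  method <- match.arg(method)
  stopifnot(inherits(match, "match_config"), inherits(w, "windowing"))
  if (lambda_3d < 0) stop("lambda_3d must be >= 0", call. = FALSE)
  if (method == "BM3D_DFR" && !inherits(dict, "feature_dictionary"))
    stop("BM3D_DFR requires a feature_dictionary", call. = FALSE)
  structure(list(match = match, method = method, dict = dict,
                 lambda_3d = lambda_3d, sigma = sigma,
                 c_dfr = as.integer(c_dfr), tol_rel = tol_rel, w = w),
            class = "pipeline_config")
}

#' Estimate the noise standard deviation of a slice
#'
#' Robust estimate from the finest diagonal (Haar) wavelet subband:
#' `median(|HH|) / 0.6745`. Computed on the processing scale. Cells whose
#' pixels sit at the clipped ends of the display window (exactly 0 or
#' 255, where windowing has flattened the noise) are excluded so that
#' large air or bone regions do not bias the estimate toward zero.
#'
#' @param img numeric matrix on the processing scale.
#' @return estimated sigma, >= 0.
#' @export
estimate_sigma <- function(img) {
  img <- as.matrix(img)
  nr <- 2L * (nrow(img) %/% 2L); nc <- 2L * (ncol(img) %/% 2L)
  x <- img[seq_len(nr), seq_len(nc)]
  a <- x[seq(1, nr, 2), seq(1, nc, 2)]; b <- x[seq(2, nr, 2), seq(1, nc, 2)]
  d <- x[seq(1, nr, 2), seq(2, nc, 2)]; e <- x[seq(2, nr, 2), seq(2, nc, 2)]
  hh <- (a - b - d + e) / 2
  inside <- function(v) v > 0 & v < 255
  ok <- inside(a) & inside(b) & inside(d) & inside(e)
  if (!any(ok)) ok <- rep(TRUE, length(hh))
  stats::median(abs(hh[ok])) / 0.6745
}

#' Discriminative sparse reconstruction of one group
#'
#' The DFR step for a single matched group: per-block DC removal, sparse
#' coding over the discriminative dictionary, and reconstruction from the
#' high-quality atoms with the DC added back. Groups shallower than the
#' atom depth are coded against the dictionary truncated (and
#' renormalized) to the group depth.
#'
#' @param group a `block_group` from [find_similar()], or a bare
#'   `n x n x m` stack.
#' @param dict a [feature_dictionary()].
#' @param cfg a [pipeline_config()] (for `c_dfr` and `tol_rel`).
#' @return the reconstructed stack, same shape as the input.
#' @export
dfr_filter_group <- function(group, dict, cfg = pipeline_config()) {
  if (is.null(dict)) stop("no dictionary configured", call. = FALSE)
  stack <- if (inherits(group, "block_group")) group$stack else
    .as_group_array(group)
  m <- dim(stack)[3]
  dict_m <- truncate_dictionary(dict, m)
  cd <- remove_dc(stack)
  code <- omp(as.vector(cd$centered), dict_m, c_dfr = cfg$c_dfr,
              tol_rel = cfg$tol_rel, dc = cd$dc)
  reconstruct_hq(code, dict_m)
}

#' Collaborative 3D hard-threshold filtering
#'
#' Forward 3D transform of the group (2D bior1.5 per block, orthonormal
#' transform along the stack), hard thresholding at
#' `lambda_3d * sigma`, inverse transform. The number of retained
#' coefficients drives the aggregation weight.
#'
#' @param stack `n x n x m` numeric array on the processing scale.
#' @param lambda_3d threshold coefficient.
#' @param sigma noise standard deviation on the processing scale.
#' @return list with `stack` (filtered) and `retained_count`.
#' @export
collaborative_filter <- function(stack, lambda_3d = 2.7, sigma = 0) {
  co <- forward_3d(stack)
  ht <- hard_threshold(co, lambda_3d * sigma)
  list(stack = inverse_3d(ht$values), retained_count = ht$retained_count)
}

#' Aggregation weight of one group
#'
#' The classic inverse-variance weight `1 / (sigma^2 * N_retained)`,
#' where `N_retained` is the number of 3D coefficients surviving the hard
#' threshold (floored at 1). Sparser groups — better explained by few
#' coefficients — get larger weight.
#'
#' @param retained_count coefficients retained by the hard threshold.
#' @param sigma noise standard deviation on the processing scale.
#' @return a single weight, > 0 and finite.
#' @export
compute_weight <- function(retained_count, sigma) {
  stopifnot(retained_count >= 0)
  1 / (max(sigma, 1e-8)^2 * max(retained_count, 1))
}

#' Weighted aggregation of block estimates
#'
#' Every filtered group contributes its member blocks back at their
#' original positions; each output pixel is the weight-normalized average
#' of all block estimates covering it.
#'
#' @param estimates list of estimates, each a list with `stack`
#'   (`n x n x m`), `members` (0-based anchor matrix `m x 2`) and
#'   `weight` (scalar > 0).
#' @param shape output `(rows, cols)`.
#' @return numeric matrix of the aggregated image.
#' @export
aggregate_estimates <- function(estimates, shape) {
  num <- matrix(0, shape[1], shape[2])
  den <- matrix(0, shape[1], shape[2])
  for (e in estimates) {
    st <- .as_group_array(e$stack)
    n1 <- dim(st)[1]; n2 <- dim(st)[2]
    for (k in seq_len(dim(st)[3])) {
      r <- e$members[k, 1]; c <- e$members[k, 2]
      if (r < 0 || c < 0 || r + n1 > shape[1] || c + n2 > shape[2])
        stop("block estimate outside the image", call. = FALSE)
      ri <- (r + 1):(r + n1); ci <- (c + 1):(c + n2)
      num[ri, ci] <- num[ri, ci] + e$weight * st[, , k]
      den[ri, ci] <- den[ri, ci] + e$weight
    }
  }
  if (any(den == 0))
    stop("internal error: uncovered pixel during aggregation",
         call. = FALSE)
  num / den
}

#' Enhance one CT slice
#'
#' The full method: the slice is mapped onto the `[0, 255]` processing
#' scale with the configured display window; overlapping 8x8 reference
#' patches are matched into 3D groups; with `method = "BM3D_DFR"` each
#' group is first replaced by its discriminative sparse reconstruction;
#' every group is collaboratively filtered by 3D transform hard
#' thresholding; all filtered blocks are aggregated by weighted
#' averaging; and the result is mapped back to HU. Pixels whose original
#' HU lies outside the display window are passed through unchanged, which
#' preserves the density (HU) information outside the soft-tissue range.
#'
#' @param img a [ct_image()].
#' @param cfg a [pipeline_config()].
#' @return the enhanced [ct_image()]; attributes `method`, `sigma`,
#'   `n_groups` and `config_hash` record the run.
#' @export
enhance_slice <- function(img, cfg = pipeline_config()) {
  stopifnot(inherits(img, "ct_image"), inherits(cfg, "pipeline_config"))
  mc <- cfg$match
  if (any(dim(img$pixels) < mc$n_block))
    stop("image smaller than the block size", call. = FALSE)
  win <- apply_window(img$pixels, cfg$w)
  sigma <- if (is.null(cfg$sigma)) estimate_sigma(win) else cfg$sigma
  groups <- iterate_references(win, mc)
  estimates <- .filter_groups(groups, cfg, sigma)
  agg <- aggregate_estimates(estimates, dim(win))
  hu <- unwindow(agg, cfg$w)
  lo <- cfg$w$level - cfg$w$width / 2
  hi <- cfg$w$level + cfg$w$width / 2
  outside <- img$pixels <= lo | img$pixels >= hi
  hu[outside] <- img$pixels[outside]
  out <- ct_image(hu, spacing = img$spacing, modality = img$modality,
                  slice_index = img$slice_index)
  attr(out, "method") <- cfg$method
  attr(out, "sigma") <- sigma
  attr(out, "n_groups") <- length(groups)
  attr(out, "config_hash") <- config_hash(cfg)
  out
}

#' @param series a [ct_series()]; every slice is enhanced independently.
#' @rdname enhance_slice
#' @export
enhance_series <- function(series, cfg = pipeline_config()) {
  stopifnot(inherits(series, "ct_series"))
  out <- series
  out$slices <- lapply(series$slices, enhance_slice, cfg = cfg)
  out
}

# batched group filtering: DFR sparse coding (optional) followed by the
# collaborative filter, vectorized over all groups of equal depth
.filter_groups <- function(groups, cfg, sigma) {
  n <- cfg$match$n_block
  lam <- cfg$lambda_3d * sigma
  depths <- vapply(groups, function(g) dim(g$stack)[3], 1L)
  estimates <- vector("list", length(groups))
  for (m in sort(unique(depths))) {
    gi <- which(depths == m)
    arr <- array(0, c(n, n, m, length(gi)))
    for (j in seq_along(gi)) arr[, , , j] <- groups[[gi[j]]]$stack
    flat <- matrix(arr, n * n, m * length(gi))
    dc <- colMeans(flat)

    if (cfg$method == "BM3D_DFR") {
      centered <- flat - rep(dc, each = n * n)
      dict_m <- truncate_dictionary(cfg$dict, m)
      codes <- omp_batch(matrix(centered, n * n * m, length(gi)), dict_m,
                         c_dfr = cfg$c_dfr, tol_rel = cfg$tol_rel)
      hq <- which(dict_m$labels == "HQ")
      coef <- matrix(0, ncol(dict_m$atoms), length(gi))
      for (j in seq_along(gi)) {
        idx <- codes$indices[[j]]
        if (length(idx)) coef[idx, j] <- codes$coeffs[[j]]
      }
      rec <- dict_m$atoms[, hq, drop = FALSE] %*%
        coef[hq, , drop = FALSE]                     # HQ atoms only
      flat <- matrix(rec, n * n, m * length(gi)) + rep(dc, each = n * n)
      arr <- array(flat, c(n, n, m, length(gi)))
    }

    # collaborative filter, batched: 2D transform on every block, stack
    # transform along depth, threshold, invert
    w2 <- .wavelet_matrix(n)
    ms <- stack_transform_matrix(m)
    co <- apply_2d_batch(array(arr, c(n, n, m * length(gi))), w2$analysis)
    co <- array(co, c(n * n, m, length(gi)))
    co <- array(apply(co, 3, function(x) x %*% t(ms)),
                c(n * n, m, length(gi)))
    keep <- abs(co) > lam
    co[!keep] <- 0
    retained <- apply(keep, 3, sum)
    co <- array(apply(co, 3, function(x) x %*% ms),
                c(n, n, m * length(gi)))
    filt <- apply_2d_batch(co, w2$synthesis)
    filt <- array(filt, c(n, n, m, length(gi)))

    for (j in seq_along(gi)) {
      estimates[[gi[j]]] <- list(
        stack = array(filt[, , , j], c(n, n, m)),
        members = groups[[gi[j]]]$members,
        weight = compute_weight(retained[j], sigma))
    }
  }
  estimates
}

# stable fingerprint of a configuration: position-weighted checksum of its
# serialized form (vectorized; exact in doubles below 2^53)
config_hash <- function(cfg) {
  b <- as.integer(serialize(cfg, NULL, version = 2))
  w <- (seq_along(b) %% 9973) + 1
  sprintf("%08x", as.integer(sum(b * w) %% 2147483647))
}
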