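#' Region-of-interest specification
#'
#' Circular or rectangular ROI on the pixel grid, used for the
#' contrast-to-noise ratio and the HU stability check. The ROI must lie
#' fully inside the image and contain at least 8 pixels.
#'
#' @param shape `"circle"` or `"rectangle"`.
#' @param center `(row, col)` center, 1-based pixel coordinates.
#' @param radius circle radius in pixels.
#' @param extents `(rows, cols)` half-extents for a rectangle.
#' @param role `"target"` or `"background"`.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(shape = c("circle", "rectangle"), center, radius = NULL,
                     extents = NULL, role = c("target", "background")) {
  shape <- match.arg(shape); role <- match.arg(role)
  if (shape == "circle" && (is.null(radius) || radius <= 0))
    stop("circle ROI needs a positive radius", call. = FALSE)
  if (shape == "rectangle" && (is.null(extents) || any(extents <= 0)))
    stop("rectangle ROI needs positive extents", call. = FALSE)
  structure(list(shape = shape, center = as.numeric(center),
                 radius = radius, extents = extents, role = role),
            class = "roi_spec")
}

#' @param img a `ct_image` or matrix the ROI is evaluated on.
#' @param roi an `roi_spec`.
#' @return `roi_mask` returns a logical matrix selecting the ROI pixels.
#' @rdname roi_spec
#' @export
roi_mask <- function(img, roi) {
  px <- if (inherits(img, "ct_image")) img$pixels else as.matrix(img)
  d <- dim(px)
  rr <- matrix(seq_len(d[1]), d[1], d[2])
  cc <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
  m <- if (roi$shape == "circle") {
    (rr - roi$center[1])^2 + (cc - roi$center[2])^2 <= roi$radius^2
  } else {
    abs(rr - roi$center[1]) <= roi$extents[1] &
      abs(cc - roi$center[2]) <= roi$extents[2]
  }
  if (roi$center[1] - (roi$radius %||% roi$extents[1]) < 1 ||
      roi$center[1] + (roi$radius %||% roi$extents[1]) > d[1] ||
      roi$center[2] - (roi$radius %||% roi$extents[2]) < 1 ||
      roi$center[2] + (roi$radius %||% roi$extents[2]) > d[2])
    stop("ROI extends outside the image", call. = FALSE)
  if (sum(m) < 8) stop("ROI must contain at least 8 pixels", call. = FALSE)
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Contrast-to-noise ratio between two ROIs
#'
#' `CNR = 2 |A_t - A_b| / sqrt(s_t^2 + s_b^2)` where `A` are the ROI
#' mean pixel values and `s` their standard deviations (population by
#' default). Computed on HU values, so results are comparable across
#' acquisitions; the measure is invariant under adding a constant to, or
#' positively rescaling, the whole image.
#'
#' @param img a [ct_image()] or numeric matrix.
#' @param target,background [roi_spec()] objects; must not overlap.
#' @param sd_type `"population"` (divide by n) or `"sample"` (n - 1).
#' @return An object of class `cnr_result` with fields `cnr`,
#'   `mean_target`, `mean_background`, `sd_target`, `sd_background`.
#' @export
cnr <- function(img, target, background,
                sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  mt <- roi_mask(img, target); mb <- roi_mask(img, background)
  if (any(mt & mb)) stop("target and background ROIs overlap", call. = FALSE)
  px <- if (inherits(img, "ct_image")) img$pixels else as.matrix(img)
  stat <- function(v) {
    n <- length(v)
    s2 <- if (sd_type == "population") sum((v - mean(v))^2) / n
          else stats::var(v)
    c(mean(v), sqrt(s2))
  }
  st <- stat(px[mt]); sb <- stat(px[mb])
  denom <- sqrt(st[2]^2 + sb[2]^2)
  value <- if (denom == 0 && st[1] == sb[1]) 0
           else 2 * abs(st[1] - sb[1]) / denom
  structure(list(cnr = value, mean_target = st[1], mean_background = sb[1],
                 sd_target = st[2], sd_background = sb[2]),
            class = "cnr_result")
}

#' @export
print.cnr_result <- function(x, ...) {
  cat(sprintf("CNR %.4f  (target %.1f +/- %.1f, background %.1f +/- %.1f)\n",
              x$cnr, x$mean_target, x$sd_target, x$mean_background,
              x$sd_background))
  invisible(x)
}

#' Canny edge map
#'
#' Deterministic Canny edge detection: Gaussian smoothing, Sobel
#' gradients, non-maximum suppression along the quantized gradient
#' direction, and hysteresis linking of weak edges to strong ones.
#' Thresholds are given as fractions of the maximum gradient magnitude.
#'
#' @param img a [ct_image()] or numeric matrix.
#' @param low,high hysteresis thresholds as fractions of the gradient
#'   maximum, `0 < low <= high`.
#' @param sigma_blur Gaussian smoothing standard deviation in pixels.
#' @return list with `edges` (logical matrix) and `edge_count`.
#' @export
edge_map <- function(img, low = 0.1, high = 0.2, sigma_blur = 1.4) {
  if (!(low > 0 && high >= low))
    stop("need 0 < low <= high", call. = FALSE)
  px <- if (inherits(img, "ct_image")) img$pixels else as.matrix(img)
  sm <- gaussian_blur(px, sigma_blur)
  gx <- conv2_same(sm, matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3))
  gy <- conv2_same(sm, matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3))
  mag <- sqrt(gx^2 + gy^2)
  gmax <- max(mag)
  # constant images leave only rounding residue in the gradients
  if (gmax <= 1e-9 * max(abs(sm), 1))
    return(list(edges = matrix(FALSE, nrow(px), ncol(px)), edge_count = 0L))

  # non-maximum suppression: compare against the two neighbours along
  # the gradient direction quantized to 0/45/90/135 degrees
  d <- dim(mag)
  ang <- atan2(gy, gx)
  sector <- (round(ang / (pi / 4)) %% 4)
  # gx runs along columns, gy along rows: sector 0 is a horizontal
  # gradient (vertical edge), sector 2 a vertical gradient
  off <- list(`0` = c(0, 1), `1` = c(1, 1), `2` = c(1, 0), `3` = c(1, -1))
  shift <- function(mat, dr, dc) {
    out <- matrix(0, d[1], d[2])
    rs <- seq_len(d[1]) + dr; cs <- seq_len(d[2]) + dc
    ok_r <- rs >= 1 & rs <= d[1]; ok_c <- cs >= 1 & cs <= d[2]
    out[ok_r, ok_c] <- mat[rs[ok_r], cs[ok_c]]
    out
  }
  nms <- matrix(FALSE, d[1], d[2])
  for (s in 0:3) {
    o <- off[[as.character(s)]]
    sel <- sector == s
    # strict on one side so an exact two-pixel tie keeps a single line
    nms[sel] <- mag[sel] > shift(mag, o[1], o[2])[sel] &
                mag[sel] >= shift(mag, -o[1], -o[2])[sel]
  }

  strong <- nms & mag >= high * gmax
  weak <- nms & mag >= low * gmax
  # hysteresis: grow strong edges through weak pixels to a fixed point
  edges <- strong
  repeat {
    grown <- edges
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      grown <- grown | shift(edges, dr, dc)
    }
    grown <- grown & weak
    if (identical(grown, edges)) break
    edges <- grown
  }
  list(edges = edges, edge_count = sum(edges))
}

gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  conv_sep(img, k)
}

# separable convolution with replicate borders
conv_sep <- function(img, k) {
  r <- (length(k) - 1L) / 2L
  pad_apply <- function(m) {
    n <- nrow(m)
    mp <- rbind(m[rep(1, r), , drop = FALSE], m,
                m[rep(n, r), , drop = FALSE])
    out <- matrix(0, n, ncol(m))
    for (i in seq_along(k)) out <- out + k[i] * mp[i:(i + n - 1), ,
                                                   drop = FALSE]
    out
  }
  t(pad_apply(t(pad_apply(img))))
}

conv2_same <- function(img, kern) {
  d <- dim(img); kr <- (nrow(kern) - 1L) / 2L
  idx <- function(v, n) pmin(pmax(v, 1L), n)
  out <- matrix(0, d[1], d[2])
  for (i in seq_len(nrow(kern))) for (j in seq_len(ncol(kern))) {
    if (kern[i, j] == 0) next
    out <- out + kern[i, j] *
      img[idx(seq_len(d[1]) + i - kr - 1L, d[1]),
          idx(seq_len(d[2]) + j - kr - 1L, d[2])]
  }
  out
}

#' Cohort CNR comparison with a paired t test
#'
#' Computes the CNR of every (original, enhanced) slice pair with the
#' given ROIs and compares the arms with a two-sided paired t test.
#'
#' @param pairs list of lists with elements `original` and `enhanced`
#'   ([ct_image()]s) — at least 2 pairs.
#' @param target,background [roi_spec()]s applied to every slice.
#' @return list with per-arm `mean` and `sd` of CNR, `t`, `p`, `n`, and
#'   the per-slice CNR vectors. Identical arms are reported as
#'   `no_difference = TRUE` with `t = NA`.
#' @export
batch_cnr <- function(pairs, target, background) {
  if (length(pairs) < 2) stop("need at least 2 pairs", call. = FALSE)
  v_orig <- vapply(pairs, function(p)
    cnr(p$original, target, background)$cnr, 1)
  v_enh <- vapply(pairs, function(p)
    cnr(p$enhanced, target, background)$cnr, 1)
  d <- v_enh - v_orig
  n <- length(d)
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    t_stat <- if (mean(d) == 0) NA_real_ else Inf * sign(mean(d))
    p <- if (mean(d) == 0) NA_real_ else 0
  } else {
    t_stat <- mean(d) / (sd_d / sqrt(n))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
  }
  list(original = list(mean = mean(v_orig), sd = stats::sd(v_orig)),
       enhanced = list(mean = mean(v_enh), sd = stats::sd(v_enh)),
       t = t_stat, p = p, n = n,
       no_difference = sd_d == 0 && mean(d) == 0,
       cnr_original = v_orig, cnr_enhanced = v_enh)
}

#' Density (HU) stability report
#'
#' Checks that enhancement leaves the calibrated density information
#' usable for dose calculation: per-ROI mean HU drift
#' (enhanced - original), plus RMS and maximum absolute HU difference
#' over a body mask.
#'
#' @param original,enhanced [ct_image()]s on the same grid.
#' @param rois list of [roi_spec()]s (uniform-density regions).
#' @param body_mask logical matrix; defaults to the whole image.
#' @param tol_hu drift tolerance in HU used for the `stable` flag.
#' @return An object of class `stability_report`: `roi_mean_diff`,
#'   `rms`, `max_abs`, `stable`.
#' @export
hu_stability <- function(original, enhanced, rois = list(),
                         body_mask = NULL, tol_hu = 5) {
  po <- if (inherits(original, "ct_image")) original$pixels
        else as.matrix(original)
  pe <- if (inherits(enhanced, "ct_image")) enhanced$pixels
        else as.matrix(enhanced)
  if (!all(dim(po) == dim(pe)))
    stop("original and enhanced must share the same grid", call. = FALSE)
  if (is.null(body_mask)) body_mask <- matrix(TRUE, nrow(po), ncol(po))
  diff <- pe - po
  roi_drift <- vapply(rois, function(r) mean(diff[roi_mask(po, r)]), 1)
  structure(list(
    roi_mean_diff = roi_drift,
    rms = sqrt(mean(diff[body_mask]^2)),
    max_abs = max(abs(diff[body_mask])),
    stable = all(abs(roi_drift) <= tol_hu),
    tol_hu = tol_hu), class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf(
    "HU stability: RMS %.2f, max |diff| %.2f, ROI drift %s HU -> %s\n",
    x$rms, x$max_abs,
    paste(sprintf("%.2f", x$roi_mean_diff), collapse = "/"),
    if (x$stable) "stable" else "NOT stable"))
  invisible(x)
}
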