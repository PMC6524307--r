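#' CT image and series containers
#'
#' `ct_image()` wraps a rectangular matrix of Hounsfield-unit (HU) pixel
#' values together with its pixel spacing and acquisition modality.
#' `ct_series()` holds an ordered stack of slices on an identical grid.
#' These are the objects every processing stage consumes and produces.
#'
#' @param pixels numeric matrix of HU values (rows x cols). Must be
#'   non-empty and finite.
#' @param spacing numeric length-2 vector, (row, col) pixel spacing in mm.
#' @param modality one of `"MVCT"`, `"KVCT"`, `"SYNTHETIC"`.
#' @param slice_index integer position of the slice within its series.
#' @return An object of class `ct_image`.
#' @export
ct_image <- function(pixels, spacing = c(1, 1),
                     modality = c("SYNTHETIC", "MVCT", "KVCT"),
                     slice_index = 1L) {
  modality <- match.arg(modality)
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels) || length(pixels) == 0L)
    stop("pixels must be a non-empty numeric matrix", call. = FALSE)
  if (!all(is.finite(pixels)))
    stop("pixel values must be finite HU", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 2L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be two strictly positive values (mm)", call. = FALSE)
  storage.mode(pixels) <- "double"
  structure(
    list(pixels = pixels, spacing = spacing, modality = modality,
         slice_index = as.integer(slice_index)),
    class = "ct_image")
}

#' @param slices list of `ct_image` objects with identical shape and
#'   spacing, `slice_index` strictly increasing.
#' @param reconstruction_interval slice-to-slice distance in mm.
#' @return An object of class `ct_series`.
#' @rdname ct_image
#' @export
ct_series <- function(slices, reconstruction_interval = 2) {
  if (!length(slices) || !all(vapply(slices, inherits, TRUE, "ct_image")))
    stop("slices must be a non-empty list of ct_image objects", call. = FALSE)
  dims <- vapply(slices, function(s) dim(s$pixels), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all slices must share the same shape", call. = FALSE)
  idx <- vapply(slices, function(s) s$slice_index, integer(1))
  if (any(diff(idx) <= 0))
    stop("slice_index must be strictly increasing", call. = FALSE)
  structure(
    list(slices = slices,
         reconstruction_interval = as.numeric(reconstruction_interval)),
    class = "ct_series")
}

#' @export
print.ct_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<ct_image> %dx%d %s, spacing %.3gx%.3g mm, HU [%g, %g]\n",
              d[1], d[2], x$modality, x$spacing[1], x$spacing[2],
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
print.ct_series <- function(x, ...) {
  d <- dim(x$slices[[1]]$pixels)
  cat(sprintf("<ct_series> %d slices of %dx%d, interval %g mm\n",
              length(x$slices), d[1], d[2], x$reconstruction_interval))
  invisible(x)
}

#' Display window specification
#'
#' A standard CT display window: HU values in
#' `[level - width/2, level + width/2]` are mapped linearly onto the
#' processing scale `[0, 255]`; values outside clip to 0 or 255. The
#' defaults (width 400 HU, level 40 HU) are the soft-tissue window the
#' enhancement pipeline operates in.
#'
#' @param width window width in HU, > 0.
#' @param level window level (center) in HU.
#' @return An object of class `windowing`.
#' @export
windowing <- function(width = 400, level = 40) {
  width <- as.numeric(width); level <- as.numeric(level)
  if (!is.finite(width) || width <= 0)
    stop("window width must be > 0 HU", call. = FALSE)
  structure(list(width = width, level = level), class = "windowing")
}

#' Map HU values onto the [0, 255] processing scale
#'
#' Linear windowing: `hu <= level - width/2` maps to 0,
#' `hu >= level + width/2` maps to 255, linear in between. The map is
#' monotone non-decreasing and invertible strictly inside the window.
#'
#' @param img a `ct_image`, or a bare numeric matrix/vector of HU values.
#' @param w a `windowing` spec.
#' @return Numeric array of the same shape on the `[0, 255]` scale.
#' @seealso [unwindow()]
#' @export
apply_window <- function(img, w = windowing()) {
  stopifnot(inherits(w, "windowing"))
  hu <- if (inherits(img, "ct_image")) img$pixels else img
  lo <- w$level - w$width / 2
  pmin(pmax((hu - lo) / w$width, 0), 1) * 255
}

#' Invert the display window
#'
#' Maps `[0, 255]` processing-scale values back to HU. Exact inverse of
#' [apply_window()] for HU values strictly inside the window; values are
#' clamped to `[0, 255]` before inversion.
#'
#' @param v numeric array on the `[0, 255]` scale.
#' @param w a `windowing` spec.
#' @return HU values.
#' @export
unwindow <- function(v, w = windowing()) {
  stopifnot(inherits(w, "windowing"))
  v <- pmin(pmax(v, 0), 255)
  (w$level - w$width / 2) + v / 255 * w$width
}
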