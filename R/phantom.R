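#' Digital phantom specification
#'
#' A Catphan-like quality-assurance scene: a uniform circular body disc
#' in air with circular plugs of differing HU inside it. The default is a
#' 256x256 image with a 100 px body at 0 HU and four plugs at -100, -40,
#' +40 and +120 HU — the +/-40 pair mimics low-contrast soft tissue.
#'
#' @param side image side in pixels.
#' @param body_center `(row, col)`, 1-based; defaults to the image
#'   center.
#' @param body_radius body disc radius in pixels.
#' @param body_hu body HU (water-like 0).
#' @param plugs data frame with columns `row`, `col`, `radius`, `hu`;
#'   every plug must lie fully inside the body.
#' @param air_hu background HU (air, -1000).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(side = 256L, body_center = NULL,
                         body_radius = 100, body_hu = 0,
                         plugs = NULL, air_hu = -1000) {
  side <- as.integer(side)
  if (is.null(body_center)) body_center <- c(side, side) / 2 + 0.5
  if (is.null(plugs)) {
    d <- 50
    plugs <- data.frame(
      row = body_center[1] + c(-d, 0, d, 0),
      col = body_center[2] + c(0, d, 0, -d),
      radius = 12,
      hu = c(-100, -40, 40, 120))
  }
  if (any(plugs$radius <= 0) || body_radius <= 0)
    stop("radii must be positive", call. = FALSE)
  dist <- sqrt((plugs$row - body_center[1])^2 +
               (plugs$col - body_center[2])^2)
  if (any(dist + plugs$radius > body_radius))
    stop("every plug must lie inside the body disc", call. = FALSE)
  structure(list(side = side, body_center = body_center,
                 body_radius = body_radius, body_hu = body_hu,
                 plugs = plugs, air_hu = air_hu),
            class = "phantom_spec")
}

#' MVCT degradation model
#'
#' The two MVCT degradations relative to a planning KVCT that the
#' simulator emulates: compressed soft-tissue contrast and amplified
#' noise, with optional detector blur. Applied in the order contrast
#' compression, Gaussian blur, additive Gaussian noise (all in HU).
#'
#' @param gaussian_sd additive noise standard deviation in HU.
#' @param blur_sd Gaussian blur standard deviation in pixels (0 = none).
#' @param contrast_scale multiplicative compression of soft-tissue
#'   contrast toward the soft-tissue mean, in `(0, 1]` (1 = none).
#' @param seed RNG seed for the noise.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(gaussian_sd = 20, blur_sd = 0.5,
                        contrast_scale = 0.85, seed = 1L) {
  if (gaussian_sd < 0) stop("gaussian_sd must be >= 0", call. = FALSE)
  if (blur_sd < 0) stop("blur_sd must be >= 0", call. = FALSE)
  if (contrast_scale <= 0 || contrast_scale > 1)
    stop("contrast_scale must be in (0, 1]", call. = FALSE)
  structure(list(gaussian_sd = gaussian_sd, blur_sd = blur_sd,
                 contrast_scale = contrast_scale, seed = as.integer(seed)),
            class = "noise_model")
}

#' Render the clean phantom image
#'
#' Piecewise-constant HU image of the phantom: air background, body
#' disc, plugs. Deterministic.
#'
#' @param spec a [phantom_spec()].
#' @return a clean [ct_image()] (modality `SYNTHETIC`).
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$side
  rr <- matrix(seq_len(n), n, n)
  cc <- matrix(seq_len(n), n, n, byrow = TRUE)
  hu <- matrix(spec$air_hu, n, n)
  body <- (rr - spec$body_center[1])^2 + (cc - spec$body_center[2])^2 <=
    spec$body_radius^2
  hu[body] <- spec$body_hu
  for (i in seq_len(nrow(spec$plugs))) {
    p <- spec$plugs[i, ]
    inplug <- (rr - p$row)^2 + (cc - p$col)^2 <= p$radius^2
    hu[inplug] <- p$hu
  }
  ct_image(hu, modality = "SYNTHETIC")
}

# body mask of a phantom (used by the stability report)
phantom_body_mask <- function(spec) {
  n <- spec$side
  rr <- matrix(seq_len(n), n, n)
  cc <- matrix(seq_len(n), n, n, byrow = TRUE)
  (rr - spec$body_center[1])^2 + (cc - spec$body_center[2])^2 <=
    spec$body_radius^2
}

.soft_range <- c(-400, 400)  # HU range treated as soft tissue

#' Simulate an MVCT or KVCT acquisition of a clean image
#'
#' Applies the [noise_model()] degradations to a clean HU image:
#' soft-tissue HU values (within -400..400) are compressed toward their
#' mean by `contrast_scale`, the image is blurred, and Gaussian noise is
#' added. Seeded and reproducible; the caller's RNG state is untouched.
#'
#' @param clean a [ct_image()].
#' @param noise a [noise_model()]; `simulate_kvct` defaults to a mild
#'   one (sd 3 HU, no blur, full contrast).
#' @return a degraded [ct_image()] with modality `MVCT` (or `KVCT`).
#' @export
simulate_mvct <- function(clean, noise = noise_model()) {
  .simulate(clean, noise, "MVCT")
}

#' @rdname simulate_mvct
#' @export
simulate_kvct <- function(clean,
                          noise = noise_model(gaussian_sd = 3, blur_sd = 0,
                                              contrast_scale = 1)) {
  .simulate(clean, noise, "KVCT")
}

.simulate <- function(clean, noise, modality) {
  stopifnot(inherits(clean, "ct_image"), inherits(noise, "noise_model"))
  hu <- clean$pixels
  soft <- hu >= .soft_range[1] & hu <= .soft_range[2]
  if (noise$contrast_scale < 1 && any(soft)) {
    m <- mean(hu[soft])
    hu[soft] <- m + noise$contrast_scale * (hu[soft] - m)
  }
  if (noise$blur_sd > 0) hu <- gaussian_blur(hu, noise$blur_sd)
  if (noise$gaussian_sd > 0) {
    hu <- hu + with_seed(noise$seed,
      matrix(stats::rnorm(length(hu), 0, noise$gaussian_sd), nrow(hu)))
  }
  ct_image(hu, spacing = clean$spacing, modality = modality,
           slice_index = clean$slice_index)
}

# run code under a temporary RNG seed, restoring the caller's state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Registered KVCT/MVCT training pairs from the phantom
#'
#' Builds `n_slices` phantom slices (with a small seeded jitter of the
#' plug positions from slice to slice, so the stack has structure along
#' z) and degrades each one twice: mildly (KVCT-like) and with the full
#' MVCT model. Each pair is pixel-registered by construction; noise is
#' independent per slice.
#'
#' @param spec a [phantom_spec()].
#' @param n_slices number of slices (at least the atom depth, usually 5).
#' @param noise the MVCT [noise_model()].
#' @param kvct_noise the KVCT [noise_model()].
#' @param seed master seed; per-slice seeds are derived from it.
#' @param slice_jitter maximum plug-center jitter between slices, pixels.
#' @return list of [training_pair()]s.
#' @export
make_training_pairs <- function(spec = phantom_spec(), n_slices = 5L,
                                noise = noise_model(),
                                kvct_noise = noise_model(gaussian_sd = 3,
                                  blur_sd = 0, contrast_scale = 1),
                                seed = 1L, slice_jitter = 2) {
  if (n_slices < 1) stop("n_slices must be >= 1", call. = FALSE)
  lapply(seq_len(n_slices), function(i) {
    sp <- spec
    if (slice_jitter > 0) {
      off <- with_seed((seed * 131 + i) %% 2147483647,
        matrix(stats::runif(2 * nrow(sp$plugs), -slice_jitter,
                            slice_jitter), ncol = 2))
      sp$plugs$row <- sp$plugs$row + off[, 1]
      sp$plugs$col <- sp$plugs$col + off[, 2]
    }
    clean <- make_phantom(sp)
    clean$slice_index <- i
    nz <- noise; nz$seed <- as.integer((seed * 7919 + i) %% 2147483647)
    kz <- kvct_noise
    kz$seed <- as.integer((seed * 7919 + 1000L + i) %% 2147483647)
    training_pair(hq = simulate_kvct(clean, kz),
                  lq = simulate_mvct(clean, nz))
  })
}

#' Evaluation scene: clean phantom, simulated MVCT, canonical ROIs
#'
#' The scene used for the quantitative checks: the default phantom, one
#' simulated MVCT slice, and two soft-tissue ROIs with a known true HU
#' gap — the +40 HU plug as target and an adjacent plain-body region as
#' background.
#'
#' @param spec a [phantom_spec()].
#' @param noise the MVCT [noise_model()].
#' @param seed noise seed.
#' @return list with `clean`, `mvct` ([ct_image()]s), `target` and
#'   `background` ([roi_spec()]s), `true_gap_hu` and `body_mask`.
#' @export
make_eval_scene <- function(spec = phantom_spec(), noise = noise_model(),
                            seed = 1L) {
  clean <- make_phantom(spec)
  nz <- noise; nz$seed <- as.integer(seed)
  mvct <- simulate_mvct(clean, nz)
  # target: the plug closest in HU to the body (lowest contrast)
  i <- which.min(abs(spec$plugs$hu - spec$body_hu))
  p <- spec$plugs[i, ]
  target <- roi_spec("circle", center = c(p$row, p$col),
                     radius = max(3, p$radius - 4), role = "target")
  bg_center <- spec$body_center + c(1, 1) * spec$body_radius / 2 / sqrt(2)
  background <- roi_spec("circle", center = bg_center,
                         radius = max(3, p$radius - 4),
                         role = "background")
  list(clean = clean, mvct = mvct, target = target,
       background = background,
       true_gap_hu = abs(p$hu - spec$body_hu),
       body_mask = phantom_body_mask(spec))
}
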