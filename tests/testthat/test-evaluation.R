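# deterministic image with prescribed ROI means/sds: checkerboard of
# mean +/- sd inside each rectangle (population sd exact for even counts)
two_roi_image <- function(mt, mb, st, sb) {
  img <- matrix(0, 32, 32)
  chk <- function(center, m, s) {
    rows <- (center[1] - 1):(center[1] + 2)
    cols <- (center[2] - 1):(center[2] + 2)
    vals <- matrix(m + s * c(1, -1), 4, 4)
    img[rows, cols] <<- vals
  }
  chk(c(8, 8), mt, st)
  chk(c(24, 24), mb, sb)
  list(img = img,
       target = roi_spec("rectangle", c(8.5, 8.5), extents = c(1.5, 1.5),
                         role = "target"),
       background = roi_spec("rectangle", c(24.5, 24.5),
                             extents = c(1.5, 1.5), role = "background"))
}

test_that("CNR matches the closed form on constructed ROIs", {
  f <- two_roi_image(100, 50, 10, 10)
  res <- cnr(f$img, f$target, f$background)
  expect_equal(res$mean_target, 100)
  expect_equal(res$mean_background, 50)
  expect_equal(res$sd_target, 10)
  expect_equal(res$cnr, 2 * 50 / sqrt(200), tolerance = 1e-10)
  # identical ROI content gives 0 (also when both variances vanish)
  g <- two_roi_image(80, 80, 0, 0)
  expect_equal(cnr(g$img, g$target, g$background)$cnr, 0)
})

test_that("CNR is affine invariant and symmetric in the ROIs", {
  f <- two_roi_image(90, 40, 12, 6)
  base <- cnr(f$img, f$target, f$background)$cnr
  expect_equal(cnr(f$img + 55, f$target, f$background)$cnr, base)
  expect_equal(cnr(f$img * 3.2, f$target, f$background)$cnr, base)
  swap_t <- f$background; swap_t$role <- "target"
  swap_b <- f$target; swap_b$role <- "background"
  expect_equal(cnr(f$img, swap_t, swap_b)$cnr, base)
})

test_that("CNR validates its ROIs", {
  f <- two_roi_image(1, 2, 1, 1)
  overlap <- roi_spec("rectangle", c(9, 9), extents = c(2, 2),
                      role = "background")
  expect_error(cnr(f$img, f$target, overlap), "overlap")
  outside <- roi_spec("circle", c(2, 2), radius = 5)
  expect_error(cnr(f$img, outside, f$background), "outside")
  tiny <- roi_spec("circle", c(16, 16), radius = 1)
  expect_error(cnr(f$img, tiny, f$background), "8 pixels")
})

test_that("canny finds a clean step edge and nothing on flat images", {
  flat <- edge_map(matrix(7, 32, 32))
  expect_equal(flat$edge_count, 0)
  step <- cbind(matrix(0, 32, 16), matrix(200, 32, 16))
  em <- edge_map(step, sigma_blur = 1)
  # a single one-pixel-wide vertical line along the step
  per_row <- rowSums(em$edges)
  expect_true(all(per_row == 1))
  cols <- unique(which(em$edges, arr.ind = TRUE)[, 2])
  expect_lte(length(cols), 2)
  expect_true(all(abs(cols - 16.5) <= 1.5))
  expect_error(edge_map(step, low = 0.3, high = 0.2), "low")
})

test_that("edge maps are a pure function of image and parameters", {
  set.seed(12)
  img <- matrix(stats::runif(40 * 40, 0, 255), 40)
  expect_identical(edge_map(img), edge_map(img))
})

test_that("denoising reduces spurious edges on a noisy phantom", {
  s <- enhanced_default_scene(1)
  plugs <- phantom_spec()$plugs
  # body-interior crop (no air): the plug rims set the gradient scale,
  # so noise texture is not masked by the huge body/air step
  rows <- 65:192; cols <- 65:192
  inside <- matrix(FALSE, 256, 256)
  rr <- matrix(1:256, 256, 256)
  cc <- t(rr)
  for (i in seq_len(nrow(plugs)))   # exclude plug boundary annuli
    inside <- inside | ((rr - plugs$row[i])^2 + (cc - plugs$col[i])^2 <=
                          (plugs$radius[i] + 4)^2)
  spurious <- function(img) {
    em <- edge_map(img$pixels[rows, cols])
    sum(em$edges & !inside[rows, cols])
  }
  expect_lt(spurious(s$dfr), spurious(s$scene$mvct))
})

test_that("batch CNR reproduces the closed-form paired t statistic", {
  f <- two_roi_image(1, 2, 1, 1)
  mk <- function(px) ct_image(px)
  set.seed(8)
  pairs <- lapply(1:6, function(i) {
    base <- two_roi_image(60 + stats::rnorm(1, 0, 2), 40, 10, 10)$img
    enh <- two_roi_image(75 + stats::rnorm(1, 0, 2), 40, 8, 8)$img
    list(original = mk(base), enhanced = mk(enh))
  })
  res <- batch_cnr(pairs, f$target, f$background)
  d <- res$cnr_enhanced - res$cnr_original
  expect_equal(res$t, mean(d) / (stats::sd(d) / sqrt(length(d))))
  oracle <- stats::t.test(res$cnr_enhanced, res$cnr_original,
                          paired = TRUE)
  expect_equal(res$t, unname(oracle$statistic))
  expect_equal(res$p, oracle$p.value)
  expect_gt(res$t, 0)
  # identical arms: no difference flagged instead of a t value
  same <- lapply(pairs, function(p) list(original = p$original,
                                         enhanced = p$original))
  res0 <- batch_cnr(same, f$target, f$background)
  expect_true(res0$no_difference)
  expect_true(is.na(res0$t))
  expect_error(batch_cnr(pairs[1], f$target, f$background), "2 pairs")
})

test_that("batch CNR t follows delta * sqrt(n) / s on synthetic cohorts", {
  f <- two_roi_image(1, 2, 1, 1)
  set.seed(19)
  n <- 24; delta <- 1.5
  cnr_orig <- stats::runif(n, 2, 4)
  noise <- stats::rnorm(n, 0, 0.3)
  pairs <- lapply(1:n, function(i) {
    o <- two_roi_image(50 + cnr_orig[i], 50, sqrt(2), sqrt(2))$img
    e <- two_roi_image(50 + cnr_orig[i] + delta + noise[i], 50,
                       sqrt(2), sqrt(2))$img
    list(original = ct_image(o), enhanced = ct_image(e))
  })
  res <- batch_cnr(pairs, f$target, f$background)
  d <- delta + noise
  expect_equal(res$t, mean(d) / (stats::sd(d) / sqrt(n)), tolerance = 1e-8)
})

test_that("HU stability reports drift, RMS and maximum difference", {
  set.seed(25)
  hu <- matrix(stats::runif(32 * 32, -100, 200), 32)
  img <- ct_image(hu)
  roi <- roi_spec("circle", c(16, 16), radius = 5)
  same <- hu_stability(img, img, rois = list(roi))
  expect_equal(same$rms, 0)
  expect_equal(same$max_abs, 0)
  expect_equal(unname(same$roi_mean_diff), 0)
  shifted <- hu_stability(img, ct_image(hu + 3), rois = list(roi))
  expect_equal(shifted$rms, 3)
  expect_equal(unname(shifted$roi_mean_diff), 3)
  expect_true(shifted$stable)   # 3 HU within the 5 HU tolerance
  expect_error(hu_stability(img, ct_image(matrix(0, 16, 16))), "grid")
})

test_that("a noiseless phantom passes through within round-trip error", {
  spec <- small_phantom_spec(64L)
  clean <- make_phantom(spec)
  out <- enhance_slice(clean, pipeline_config(method = "BM3D"))
  st <- hu_stability(clean, out,
                     body_mask = mvctenhance:::phantom_body_mask(spec))
  expect_lt(st$max_abs, 1e-5)
})
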