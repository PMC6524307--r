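test_that("the clean phantom is piecewise constant with exact plug HU", {
  spec <- phantom_spec()
  img <- make_phantom(spec)
  expect_s3_class(img, "ct_image")
  expect_equal(dim(img$pixels), c(256, 256))
  for (i in seq_len(nrow(spec$plugs)))
    expect_equal(img$pixels[round(spec$plugs$row[i]),
                            round(spec$plugs$col[i])], spec$plugs$hu[i])
  expect_equal(img$pixels[round(spec$body_center[1]),
                          round(spec$body_center[2]) + 25], spec$body_hu)
  expect_equal(img$pixels[1, 1], spec$air_hu)
  expect_setequal(unique(as.vector(img$pixels)),
                  c(spec$air_hu, spec$body_hu, spec$plugs$hu))
})

test_that("a phantom without plugs is a uniform disc of the right area", {
  spec <- phantom_spec(side = 128L, body_radius = 40,
                       plugs = data.frame(row = numeric(0),
                                          col = numeric(0),
                                          radius = numeric(0),
                                          hu = numeric(0)))
  img <- make_phantom(spec)
  expect_setequal(unique(as.vector(img$pixels)),
                  c(spec$air_hu, spec$body_hu))
  # discretized disc area within one perimeter of pixels of pi r^2
  area <- sum(img$pixels == spec$body_hu)
  expect_lt(abs(area - pi * 40^2), 2 * pi * 40 + 8)
  expect_identical(phantom_body_mask(spec), img$pixels == spec$body_hu)
})

test_that("plugs outside the body and bad radii are rejected", {
  expect_error(phantom_spec(side = 64L, body_radius = 20,
                            plugs = data.frame(row = 32, col = 50,
                                               radius = 5, hu = 40)),
               "inside the body")
  expect_error(phantom_spec(body_radius = -1), "positive")
  expect_error(noise_model(gaussian_sd = -1), "gaussian_sd")
  expect_error(noise_model(contrast_scale = 0), "contrast_scale")
  expect_error(noise_model(contrast_scale = 1.2), "contrast_scale")
})

test_that("the identity noise model leaves the image untouched", {
  clean <- make_phantom(small_phantom_spec())
  out <- simulate_mvct(clean, noise_model(gaussian_sd = 0, blur_sd = 0,
                                          contrast_scale = 1))
  expect_identical(out$pixels, clean$pixels)
  expect_equal(out$modality, "MVCT")
})

test_that("simulated noise has the requested standard deviation", {
  clean <- make_phantom(phantom_spec())
  nz <- noise_model(gaussian_sd = 20, blur_sd = 0, contrast_scale = 1,
                    seed = 3)
  out <- simulate_mvct(clean, nz)
  resid <- out$pixels - simulate_mvct(clean,
    noise_model(gaussian_sd = 0, blur_sd = 0, contrast_scale = 1))$pixels
  # 65536 samples: the sample sd is well within 5% of 20
  expect_equal(stats::sd(resid), 20, tolerance = 0.05)
  expect_lt(abs(mean(resid)), 1)
})

test_that("contrast compression scales the soft-tissue gap exactly", {
  spec <- small_phantom_spec(64L)
  clean <- make_phantom(spec)
  out <- simulate_mvct(clean, noise_model(gaussian_sd = 0, blur_sd = 0,
                                          contrast_scale = 0.85))
  p <- spec$plugs[1, ]
  gap0 <- clean$pixels[round(p$row), round(p$col)] -
    clean$pixels[8 + round(spec$body_center[1]), round(spec$body_center[2])]
  gap1 <- out$pixels[round(p$row), round(p$col)] -
    out$pixels[8 + round(spec$body_center[1]), round(spec$body_center[2])]
  expect_equal(gap1, 0.85 * gap0, tolerance = 1e-12)
  # air is outside the soft-tissue range and is not compressed
  expect_equal(out$pixels[1, 1], clean$pixels[1, 1])
})

test_that("simulation is seed-deterministic and leaves caller RNG alone", {
  clean <- make_phantom(small_phantom_spec())
  nz <- noise_model(seed = 11)
  a <- simulate_mvct(clean, nz)
  set.seed(42); before <- stats::runif(3)
  set.seed(42)
  b <- simulate_mvct(clean, nz)
  after <- stats::runif(3)   # caller stream unaffected by the simulation
  expect_identical(a$pixels, b$pixels)
  expect_identical(before, after)
  # different seeds: same geometry (clean support), different noise
  c2 <- simulate_mvct(clean, noise_model(seed = 12))
  expect_false(identical(b$pixels, c2$pixels))
  expect_equal(dim(c2$pixels), dim(b$pixels))
})

test_that("training pairs are pixel-registered by construction", {
  pairs <- make_training_pairs(small_phantom_spec(), n_slices = 4,
                               noise = noise_model(0, 0, 1),
                               kvct_noise = noise_model(0, 0, 1),
                               seed = 5)
  expect_length(pairs, 4)
  for (i in seq_along(pairs)) {
    expect_identical(pairs[[i]]$hq$pixels, pairs[[i]]$lq$pixels)
    expect_equal(pairs[[i]]$hq$slice_index, i)
    expect_equal(pairs[[i]]$hq$modality, "KVCT")
    expect_equal(pairs[[i]]$lq$modality, "MVCT")
  }
  # jitter gives the stack structure along z
  expect_false(identical(pairs[[1]]$hq$pixels, pairs[[2]]$hq$pixels))
  expect_error(make_training_pairs(n_slices = 0), "n_slices")
})

test_that("measured scene CNR matches 2 g c / sqrt(2 sd^2)", {
  cs <- 0.85; sdn <- 20
  vals <- vapply(1:8, function(seed) {
    scene <- make_eval_scene(noise = noise_model(gaussian_sd = sdn,
                                                 blur_sd = 0,
                                                 contrast_scale = cs),
                             seed = seed)
    cnr(scene$mvct, scene$target, scene$background)$cnr
  }, 1)
  expected <- 2 * 40 * cs / sqrt(2 * sdn^2)
  expect_equal(mean(vals), expected, tolerance = 0.08)
})

test_that("stronger degradation lowers the measured CNR", {
  worse <- 0
  for (seed in 1:5) {
    mild <- make_eval_scene(noise = noise_model(gaussian_sd = 5),
                            seed = seed)
    hard <- make_eval_scene(noise = noise_model(gaussian_sd = 20),
                            seed = seed)
    cm <- cnr(mild$mvct, mild$target, mild$background)$cnr
    ch <- cnr(hard$mvct, hard$target, hard$background)$cnr
    worse <- worse + (ch < cm)
  }
  expect_equal(worse, 5)
})
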