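test_that("match distance is symmetric, zero on identity, and scaled", {
  cfg <- match_config()
  a <- random_block(8, 1); b <- random_block(8, 2)
  expect_equal(prefilter_distance(a, a, cfg), 0)
  expect_equal(prefilter_distance(a, b, cfg), prefilter_distance(b, a, cfg))
  expect_equal(prefilter_distance(a, a + 1, cfg), 1)  # 64 * 1 / 64
  expect_error(prefilter_distance(a, matrix(0, 4, 4), cfg), "n_block")
  # with shrinkage enabled the transform-domain distance is still a
  # symmetric pseudometric
  cfg2 <- match_config(lambda_2d = 2, sigma = 5)
  expect_equal(prefilter_distance(a, b, cfg2),
               prefilter_distance(b, a, cfg2))
  expect_equal(prefilter_distance(a, a, cfg2), 0)
})

test_that("find_similar agrees with the exhaustive oracle", {
  set.seed(100)
  for (rep in 1:5) {
    img <- matrix(stats::runif(32 * 32, 0, 255), 32)
    cfg <- match_config(tau_match = if (rep %% 2) 400 else 1e9)
    ref <- c(sample(0:24, 1), sample(0:24, 1))
    g <- find_similar(img, ref, cfg)
    oracle <- brute_force_members(img, ref, cfg)
    expect_equal(unname(g$members), unname(oracle[, 1:2, drop = FALSE]))
    expect_equal(g$distances, unname(oracle[, 3]), tolerance = 1e-9)
  }
})

test_that("a planted duplicate is matched and window bounds are respected", {
  set.seed(41)
  # background far from the reference in intensity; only the duplicate
  # passes tau_match
  img <- matrix(200, 64, 64)
  ref_blk <- matrix(stats::runif(64, 0, 50), 8)
  img[21:28, 21:28] <- ref_blk
  img[31:38, 27:34] <- ref_blk            # duplicate inside the window
  cfg <- match_config(tau_match = 400)
  g <- find_similar(img, c(20, 20), cfg)
  expect_equal(unname(g$members),
               rbind(c(20, 20), c(30, 26)))
  expect_equal(g$distances[2], 0)
  # same duplicate moved outside the 39x39 window is not found
  img2 <- matrix(200, 64, 64)
  img2[21:28, 21:28] <- ref_blk
  img2[45:52, 21:28] <- ref_blk           # row anchor 44 > 20 + 19
  g2 <- find_similar(img2, c(20, 20), cfg)
  expect_equal(unname(g2$members), rbind(c(20, 20)))
})

test_that("constant images resolve ties by row-major scan order", {
  img <- matrix(5, 32, 32)
  g <- find_similar(img, c(12, 12), match_config())
  expect_true(all(g$distances == 0))
  # reference first, then the first four in-window anchors in scan order
  expect_equal(unname(g$members),
               rbind(c(12, 12), c(0, 0), c(0, 1), c(0, 2), c(0, 3)))
  expect_equal(dim(g$stack), c(8, 8, 5))
})

test_that("group stacks start with the reference block", {
  set.seed(8)
  img <- matrix(stats::runif(40 * 40, 0, 255), 40)
  g <- find_similar(img, c(5, 9), match_config())
  expect_identical(g$stack[, , 1], img[6:13, 10:17])
  expect_true(all(diff(g$distances) >= 0))
})

test_that("shrinking tau_match never grows the member set", {
  set.seed(77)
  img <- matrix(stats::runif(32 * 32, 0, 255), 32)
  sizes <- vapply(c(1e9, 1000, 400, 100, 10, 0),
                  function(tau) nrow(find_similar(img, c(10, 10),
                    match_config(tau_match = tau))$members), 1L)
  expect_true(all(diff(sizes) <= 0))
  expect_equal(sizes[length(sizes)], 1L)   # only the reference remains
})

test_that("the exact-depth policy always returns n_number blocks", {
  img <- matrix(c(0, 255), 32, 32)   # high-contrast stripes
  g <- find_similar(img, c(10, 10),
                    match_config(tau_match = 0, depth = "exact"))
  expect_equal(dim(g$stack)[3], 5)
})

test_that("reference anchors tile the image with a clamped last anchor", {
  a <- reference_anchors(64, 8, 3)
  expect_equal(a, c(seq(0, 54, 3), 56))
  expect_length(a, 20)
  groups <- iterate_references(matrix(0, 64, 64), match_config())
  expect_length(groups, 400)
  # degenerate step: anchors collapse to {0, side - n_block}
  expect_equal(reference_anchors(64, 8, 64), c(0, 56))
  # coverage: every pixel under at least one reference patch
  covered <- matrix(FALSE, 64, 64)
  for (r in a) for (c in a) covered[r + 1:8, c + 1:8] <- TRUE
  expect_true(all(covered))
})
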