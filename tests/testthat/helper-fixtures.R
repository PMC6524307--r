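# Shared fixtures. Heavy objects (dictionary, enhanced default-phantom
# scenes) are computed once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# small phantom for fast pipeline tests
small_phantom_spec <- function(side = 48L) {
  phantom_spec(side = side, body_radius = side * 0.4, body_hu = 0,
               plugs = data.frame(row = side / 2 + c(-8, 8),
                                  col = side / 2 + c(8, -8),
                                  radius = 5, hu = c(40, -40)))
}

small_training_dict <- function() {
  cached("small_dict", {
    pairs <- make_training_pairs(small_phantom_spec(64L), n_slices = 5,
                                 seed = 7)
    build_dictionary(pairs, k_hq = 64, k_na = 64)
  })
}

default_training_dict <- function() {
  cached("default_dict",
         build_dictionary(make_training_pairs(seed = 101)))
}

# original / BM3D / BM3D+DFR triplet on the default phantom, per seed
enhanced_default_scene <- function(seed) {
  cached(paste0("scene_", seed), {
    dict <- default_training_dict()
    scene <- make_eval_scene(seed = seed)
    list(scene = scene,
         bm3d = enhance_slice(scene$mvct, pipeline_config(method = "BM3D")),
         dfr = enhance_slice(scene$mvct,
                             pipeline_config(method = "BM3D_DFR",
                                             dict = dict)))
  })
}

random_block <- function(n = 8, seed = 1) {
  set.seed(seed)
  matrix(stats::rnorm(n * n, 128, 20), n, n)
}

# pure-R exhaustive reference for find_similar, used as the oracle
brute_force_members <- function(img, ref, cfg) {
  half <- (cfg$window - 1) %/% 2
  lim_r <- nrow(img) - cfg$n_block
  lim_c <- ncol(img) - cfg$n_block
  refblk <- img[(ref[1] + 1):(ref[1] + cfg$n_block),
                (ref[2] + 1):(ref[2] + cfg$n_block)]
  cand <- expand.grid(
    c = max(0, ref[2] - half):min(lim_c, ref[2] + half),
    r = max(0, ref[1] - half):min(lim_r, ref[1] + half))
  cand <- cand[order(cand$r, cand$c), c("r", "c")]   # row-major scan
  cand$d <- apply(cand, 1, function(x)
    prefilter_distance(refblk,
                       img[(x[1] + 1):(x[1] + cfg$n_block),
                           (x[2] + 1):(x[2] + cfg$n_block)], cfg))
  others <- cand[!(cand$r == ref[1] & cand$c == ref[2]), ]
  if (cfg$depth == "at_most") others <- others[others$d <= cfg$tau_match, ]
  others <- others[order(others$d), ]   # stable: scan order breaks ties
  keep <- utils::head(others, cfg$n_number - 1)
  rbind(c(ref, 0), as.matrix(cbind(keep$r, keep$c, keep$d)))
}
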