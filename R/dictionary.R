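#' Registered high-quality / low-quality training pair
#'
#' One KVCT-like (high-quality) slice and the MVCT-like (low-quality)
#' slice of the same anatomy on the same grid. Stacks of such pairs are
#' the training input for the discriminative dictionary.
#'
#' @param hq,lq `ct_image` objects with identical shape and spacing.
#' @return An object of class `training_pair`.
#' @export
training_pair <- function(hq, lq) {
  stopifnot(inherits(hq, "ct_image"), inherits(lq, "ct_image"))
  if (!all(dim(hq$pixels) == dim(lq$pixels)) ||
      !all(hq$spacing == lq$spacing))
    stop("hq and lq must share shape and spacing", call. = FALSE)
  structure(list(hq = hq, lq = lq), class = "training_pair")
}

.pairs_to_volumes <- function(pairs, w) {
  stopifnot(length(pairs) > 0,
            all(vapply(pairs, inherits, TRUE, "training_pair")))
  d <- dim(pairs[[1]]$hq$pixels)
  hq <- array(0, c(d, length(pairs)))
  lq <- hq
  for (i in seq_along(pairs)) {
    hq[, , i] <- apply_window(pairs[[i]]$hq, w)
    lq[, , i] <- apply_window(pairs[[i]]$lq, w)
  }
  list(hq = hq, lq = lq)
}

# per-slab DC removal of a 3D patch (one mean per 2D slice), matching the
# centering applied to matched groups at coding time
.remove_patch_dc <- function(patch) {
  for (k in seq_len(dim(patch)[3]))
    patch[, , k] <- patch[, , k] - mean(patch[, , k])
  patch
}

.sample_patches <- function(vol, dims, stride, jitter = FALSE,
                            rng = NULL) {
  d <- dim(vol)
  if (d[3] < dims[3])
    stop("training stack shallower than the atom depth", call. = FALSE)
  ar <- reference_anchors(d[1], dims[1], stride)
  ac <- reference_anchors(d[2], dims[2], stride)
  az <- reference_anchors(d[3], dims[3], dims[3])
  if (jitter) {
    jig <- function(a, side, n) {
      off <- as.integer(floor(stats::runif(length(a), 0, stride)))
      pmin(pmax(a + off, 0L), side - n)
    }
    ar <- unique(jig(ar, d[1], dims[1]))
    ac <- unique(jig(ac, d[2], dims[2]))
  }
  out <- matrix(0, prod(dims), length(ar) * length(ac) * length(az))
  energy <- numeric(ncol(out))
  i <- 0L
  for (z in az) for (r in ar) for (c in ac) {
    i <- i + 1L
    p <- .remove_patch_dc(vol[(r + 1):(r + dims[1]),
                              (c + 1):(c + dims[2]),
                              (z + 1):(z + dims[3]), drop = FALSE])
    out[, i] <- as.vector(p)
    energy[i] <- sqrt(sum(p^2))
  }
  list(patches = out, energy = energy)
}

#' Extract dictionary candidate patches from training pairs
#'
#' Samples 3D patches on a regular anchor grid from two volumes built by
#' stacking the windowed training slices: the high-quality (KVCT-like)
#' volume itself, and the voxelwise difference `hq - lq`, which is what
#' the noise-model atoms are drawn from (the content that must be removed
#' from an MVCT). Each candidate has its per-slab DC removed and its
#' pre-normalization l2 energy recorded.
#'
#' @param pairs list of [training_pair()] objects.
#' @param dims atom dimensions `(n_x, n_y, n_z)`; the stack of pairs must
#'   be at least `n_z` deep.
#' @param stride in-plane anchor stride in pixels (defaults to half the
#'   atom side).
#' @param jitter add a seeded random offset to the anchor grid.
#' @param seed RNG seed for the jitter.
#' @param w display [windowing()] mapping HU onto the processing scale.
#' @return list with elements `hq` and `na`, each a list of `patches`
#'   (columns = vectorized candidates) and `energy`.
#' @export
extract_candidates <- function(pairs, dims = c(8L, 8L, 5L),
                               stride = dims[1] %/% 2L, jitter = FALSE,
                               seed = 1L, w = windowing()) {
  vols <- .pairs_to_volumes(pairs, w)
  if (jitter) set.seed(seed)
  hq <- .sample_patches(vols$hq, dims, stride, jitter)
  if (jitter) set.seed(seed)
  na <- .sample_patches(vols$hq - vols$lq, dims, stride, jitter)
  list(hq = hq, na = na, dims = as.integer(dims))
}

#' Greedy maximum-energy, minimum-redundancy atom selection
#'
#' Candidates are visited in order of decreasing energy; a candidate is
#' admitted unless the absolute inner product of its normalized form with
#' an already selected atom exceeds `rho_max`. Selection stops at `k`
#' atoms or when the candidates are exhausted (with a warning). Returned
#' atoms are unit l2 norm.
#'
#' @param candidates list with `patches` (matrix, one column per
#'   candidate) and `energy`, as produced by [extract_candidates()].
#' @param k number of atoms wanted.
#' @param rho_max redundancy cap in (0, 1]; 1 disables the cap.
#' @return matrix of selected unit-norm atoms (columns).
#' @export
select_atoms <- function(candidates, k, rho_max = 0.9) {
  stopifnot(k >= 1, rho_max > 0, rho_max <= 1)
  energy <- candidates$energy
  live <- which(energy > 1e-12)
  if (!length(live))
    stop("degenerate training set: no candidate with nonzero energy",
         call. = FALSE)
  ord <- live[order(energy[live], decreasing = TRUE)]
  sel <- matrix(0, nrow(candidates$patches), 0)
  for (i in ord) {
    a <- candidates$patches[, i] / energy[i]
    if (ncol(sel) && rho_max < 1 &&
        max(abs(crossprod(sel, a))) > rho_max) next
    sel <- cbind(sel, a)
    if (ncol(sel) == k) break
  }
  if (ncol(sel) < k)
    warning("only ", ncol(sel), " of ", k, " requested atoms admissible")
  sel
}

#' Build the discriminative feature dictionary
#'
#' Concatenates a high-quality sub-dictionary (atoms sampled from the
#' KVCT-like volume) and a noise-model sub-dictionary (atoms sampled from
#' the KVCT minus MVCT difference volume), each chosen by
#' [select_atoms()]. At reconstruction time only the high-quality atoms
#' are kept, which is what enhances the image.
#'
#' @inheritParams extract_candidates
#' @param k_hq,k_na atoms per sub-dictionary.
#' @param rho_max redundancy cap, see [select_atoms()].
#' @return An object of class `feature_dictionary` with fields `atoms`
#'   (matrix, unit-norm zero-mean columns), `labels` (`"HQ"`/`"NA"`),
#'   `atom_dims` and `selection_meta`.
#' @export
build_dictionary <- function(pairs, dims = c(8L, 8L, 5L), k_hq = 256L,
                             k_na = 256L, rho_max = 0.9,
                             stride = dims[1] %/% 2L, jitter = FALSE,
                             seed = 1L, w = windowing()) {
  cand <- extract_candidates(pairs, dims = dims, stride = stride,
                             jitter = jitter, seed = seed, w = w)
  hq <- select_atoms(cand$hq, k_hq, rho_max)
  na <- select_atoms(cand$na, k_na, rho_max)
  feature_dictionary(
    atoms = cbind(hq, na),
    labels = c(rep("HQ", ncol(hq)), rep("NA", ncol(na))),
    atom_dims = as.integer(dims),
    selection_meta = list(k_hq = k_hq, k_na = k_na, rho_max = rho_max,
                          stride = stride, jitter = jitter, seed = seed,
                          window_width = w$width, window_level = w$level))
}

#' @param atoms matrix of vectorized atoms (columns), each zero mean and
#'   unit l2 norm.
#' @param labels character vector, `"HQ"` or `"NA"` per atom.
#' @param atom_dims integer `(n_x, n_y, n_z)`.
#' @param selection_meta list of parameters used to build the dictionary.
#' @rdname build_dictionary
#' @export
feature_dictionary <- function(atoms, labels, atom_dims,
                               selection_meta = list()) {
  atoms <- as.matrix(atoms)
  dimnames(atoms) <- NULL
  if (nrow(atoms) != prod(atom_dims))
    stop("atom length does not match atom_dims", call. = FALSE)
  if (length(labels) != ncol(atoms))
    stop("one label per atom required", call. = FALSE)
  if (!all(labels %in% c("HQ", "NA")))
    stop("labels must be HQ or NA", call. = FALSE)
  if (!any(labels == "HQ"))
    stop("dictionary needs at least one HQ atom", call. = FALSE)
  nrm <- sqrt(colSums(atoms^2))
  mu <- colMeans(atoms)
  if (any(abs(nrm - 1) > 1e-8) || any(abs(mu) > 1e-8))
    stop("atoms must be zero mean and unit norm", call. = FALSE)
  structure(list(atoms = atoms, labels = labels,
                 atom_dims = as.integer(atom_dims),
                 selection_meta = selection_meta),
            class = "feature_dictionary")
}

#' @export
print.feature_dictionary <- function(x, ...) {
  cat(sprintf("<feature_dictionary> %d HQ + %d NA atoms of %s\n",
              sum(x$labels == "HQ"), sum(x$labels == "NA"),
              paste(x$atom_dims, collapse = "x")))
  invisible(x)
}

#' Save / load a dictionary
#'
#' The atom matrix is stored as flat 64-bit little-endian floats in
#' `<path>.bin` with a JSON sidecar `<path>.json` carrying dimensions,
#' labels and selection metadata; a save/load round trip is bit
#' identical.
#'
#' @param dict a `feature_dictionary`.
#' @param path destination base path (no extension).
#' @return `load_dictionary` returns the `feature_dictionary`.
#' @export
save_dictionary <- function(dict, path) {
  stopifnot(inherits(dict, "feature_dictionary"))
  meta <- list(format_version = 1L,
               atom_dims = dict$atom_dims,
               n_atoms = ncol(dict$atoms),
               labels = dict$labels,
               selection_meta = dict$selection_meta)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  writeBin(as.numeric(dict$atoms), paste0(path, ".bin"), size = 8L,
           endian = "little")
  invisible(path)
}

#' @rdname save_dictionary
#' @export
load_dictionary <- function(path) {
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  d <- prod(meta$atom_dims)
  v <- readBin(paste0(path, ".bin"), "numeric", n = d * meta$n_atoms,
               size = 8L, endian = "little")
  if (length(v) != d * meta$n_atoms)
    stop("dictionary payload truncated", call. = FALSE)
  feature_dictionary(matrix(v, d, meta$n_atoms), meta$labels,
                     meta$atom_dims,
                     as.list(meta$selection_meta))
}

# dictionary restricted to the first m slabs of every atom, for groups
# pruned below the nominal depth; truncated atoms are renormalized and
# all-zero ones dropped
truncate_dictionary <- function(dict, m) {
  if (m == dict$atom_dims[3]) return(dict)
  d <- dict$atom_dims
  keep <- seq_len(d[1] * d[2] * m)
  atoms <- dict$atoms[keep, , drop = FALSE]
  nrm <- sqrt(colSums(atoms^2))
  ok <- nrm > 1e-10
  atoms <- sweep(atoms[, ok, drop = FALSE], 2, nrm[ok], "/")
  structure(list(atoms = atoms, labels = dict$labels[ok],
                 atom_dims = c(d[1], d[2], as.integer(m)),
                 selection_meta = dict$selection_meta),
            class = "feature_dictionary")
}
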