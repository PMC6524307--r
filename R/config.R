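#' Run configuration and its defaults
#'
#' The single source of truth for every tunable of the method. The
#' defaults are the standard parameter set of the combined algorithm:
#' 8x8 patches, groups of 5 blocks, 39x39 search window, sliding
#' interval 3, match threshold 400, sparsity cap 10, 8x8x5 dictionary
#' atoms, and a 400/40 HU display window.
#'
#' @param ... overrides of individual keys (see [run_config_defaults()]).
#' @return An object of class `run_config` (a validated named list).
#' @export
run_config <- function(...) {
  overrides <- list(...)
  cfg <- run_config_defaults()
  for (k in names(overrides)) {
    if (!k %in% names(cfg))
      stop("unknown configuration key: ", k, call. = FALSE)
    cfg[[k]] <- overrides[[k]]
  }
  validate_run_config(cfg)
}

#' @rdname run_config
#' @export
run_config_defaults <- function() {
  list(
    n_block = 8L,          # patch side, pixels
    n_number = 5L,         # group depth
    window = 39L,          # search window side L
    step = 3L,             # sliding interval, pixels
    tau_match = 400,       # match threshold on the 0-255 scale
    lambda_2d = 0,         # prefilter shrinkage coefficient
    lambda_3d = 2.7,       # 3D hard-threshold coefficient
    sigma = "auto",        # noise sd on the 0-255 scale, or "auto"
    c_dfr = 10L,           # sparsity cap
    atom_nx = 8L, atom_ny = 8L, atom_nz = 5L,
    k_hq = 256L, k_na = 256L, rho_max = 0.9,
    window_width = 400,    # display window, HU
    window_level = 40,
    method = "bm3d+dfr",   # bm3d | bm3d+dfr
    depth = "at_most",     # group depth policy
    seed = 1L,
    verbosity = 1L)
}

validate_run_config <- function(cfg) {
  chk <- function(ok, key, what) {
    if (!ok) stop("invalid value for ", key, ": ", what, call. = FALSE)
  }
  ints <- c("n_block", "n_number", "window", "step", "c_dfr", "atom_nx",
            "atom_ny", "atom_nz", "k_hq", "k_na", "seed", "verbosity")
  for (k in ints) cfg[[k]] <- as.integer(cfg[[k]])
  chk(cfg$n_block >= 2, "n_block", "must be >= 2")
  chk(cfg$n_number >= 1, "n_number", "must be >= 1")
  chk(cfg$window >= cfg$n_block, "window", "must be >= n_block")
  chk(cfg$step >= 1, "step", "must be >= 1")
  chk(cfg$tau_match >= 0, "tau_match", "must be >= 0")
  chk(cfg$lambda_2d >= 0, "lambda_2d", "must be >= 0")
  chk(cfg$lambda_3d >= 0, "lambda_3d", "must be >= 0")
  chk(identical(cfg$sigma, "auto") ||
        (is.finite(as.numeric(cfg$sigma)) && as.numeric(cfg$sigma) >= 0),
      "sigma", "must be 'auto' or a number >= 0")
  chk(cfg$c_dfr >= 1, "c_dfr", "must be >= 1")
  chk(cfg$rho_max > 0 && cfg$rho_max <= 1, "rho_max", "must be in (0, 1]")
  chk(cfg$window_width > 0, "window_width", "must be > 0")
  chk(cfg$method %in% c("bm3d", "bm3d+dfr"), "method",
      "must be bm3d or bm3d+dfr")
  chk(cfg$depth %in% c("at_most", "exact"), "depth",
      "must be at_most or exact")
  structure(cfg, class = "run_config")
}

#' Read / write a flat key = value configuration file
#'
#' Lines of the form `key = value`; blank lines and `#` comments are
#' ignored. Unknown keys are rejected with the offending key named.
#' `load_config(dump_config(cfg))` reproduces `cfg`.
#'
#' @param path file to read, or a character vector of lines.
#' @param overrides named list applied on top of the file.
#' @return a validated [run_config()].
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- run_config_defaults()
  if (!is.null(path)) {
    lines <- if (length(path) == 1L && file.exists(path)) readLines(path)
             else path
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2)
        stop("cannot parse config line: ", ln, call. = FALSE)
      key <- trimws(kv[1]); val <- trimws(kv[2])
      if (!key %in% names(cfg))
        stop("unknown configuration key: ", key, call. = FALSE)
      cfg[[key]] <- .coerce_like(cfg[[key]], val, key)
    }
  }
  for (k in names(overrides)) {
    if (!k %in% names(cfg))
      stop("unknown configuration key: ", k, call. = FALSE)
    cfg[[k]] <- overrides[[k]]
  }
  validate_run_config(cfg)
}

.coerce_like <- function(template, val, key) {
  if (key == "sigma") {
    if (identical(val, "auto")) return("auto")
    return(as.numeric(val))
  }
  if (is.integer(template)) {
    out <- suppressWarnings(as.integer(val))
    if (is.na(out)) stop("invalid value for ", key, ": ", val,
                         call. = FALSE)
    return(out)
  }
  if (is.numeric(template)) {
    out <- suppressWarnings(as.numeric(val))
    if (is.na(out)) stop("invalid value for ", key, ": ", val,
                         call. = FALSE)
    return(out)
  }
  val
}

#' @param cfg a [run_config()].
#' @param path optional file to write; when `NULL` the lines are
#'   returned.
#' @rdname load_config
#' @export
dump_config <- function(cfg, path = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  lines <- vapply(names(cfg), function(k)
    paste0(k, " = ", format(cfg[[k]], scientific = FALSE)), "")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(path))
  }
  lines
}

# bridge the flat run_config to the typed configs of the pipeline
as_match_config <- function(cfg) {
  match_config(n_block = cfg$n_block, n_number = cfg$n_number,
               window = cfg$window, step = cfg$step,
               tau_match = cfg$tau_match, lambda_2d = cfg$lambda_2d,
               sigma = if (identical(cfg$sigma, "auto")) 0
                       else as.numeric(cfg$sigma),
               depth = cfg$depth)
}

as_pipeline_config <- function(cfg, dict = NULL) {
  pipeline_config(
    match = as_match_config(cfg),
    method = if (cfg$method == "bm3d") "BM3D" else "BM3D_DFR",
    dict = dict, lambda_3d = cfg$lambda_3d,
    sigma = if (identical(cfg$sigma, "auto")) NULL
            else as.numeric(cfg$sigma),
    c_dfr = cfg$c_dfr,
    w = windowing(cfg$window_width, cfg$window_level))
}
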