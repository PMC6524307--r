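#' Read a CT slice series from disk
#'
#' Supported formats:
#' \describe{
#'   \item{`"RAW"`}{a flat 32-bit little-endian float binary `<path>.raw`
#'     (C order: slice, row, column) plus a JSON sidecar `<path>.json`
#'     with fields `shape`, `spacing`, `modality`, and optionally
#'     `reconstruction_interval` and `slice_indices`. This is the fixture
#'     format the phantom generator writes.}
#'   \item{`"NIfTI"`}{a `.nii`/`.nii.gz` volume (read via RNifti); pixel
#'     values are taken as HU, spacing from `pixdim`, modality
#'     `SYNTHETIC` unless overridden by an accompanying `<path>.json`.}
#'   \item{`"DICOM"`}{a directory of single-frame uncompressed
#'     explicit-VR little-endian DICOM files. Stored values are converted
#'     to HU via RescaleSlope/RescaleIntercept; slices are ordered by the
#'     z component of ImagePositionPatient, ties broken by
#'     InstanceNumber. Compressed or implicit-VR files are rejected.}
#' }
#'
#' @param path file (RAW/NIfTI base path) or directory (DICOM).
#' @param format `"RAW"`, `"NIfTI"` or `"DICOM"`; default guesses from
#'   the path.
#' @return A [ct_series()].
#' @export
read_series <- function(path, format = c("auto", "RAW", "NIfTI", "DICOM")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "DICOM"
      else if (grepl("\\.nii(\\.gz)?$", path)) "NIfTI"
      else "RAW"
  }
  switch(format,
    RAW = read_series_raw(path),
    NIfTI = read_series_nifti(path),
    DICOM = read_series_dicom(path))
}

#' Write a CT slice series to disk
#'
#' Counterpart of [read_series()]; see that page for the formats. RAW
#' stores pixels as 32-bit floats, so a write/read round trip is exact
#' for float32-representable HU values (in particular for anything this
#' package itself produced from a RAW or DICOM read).
#'
#' @param series a [ct_series()].
#' @param path destination base path (RAW/NIfTI) or directory (DICOM).
#' @param format `"RAW"`, `"NIfTI"` or `"DICOM"`.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path, format = c("RAW", "NIfTI", "DICOM")) {
  stopifnot(inherits(series, "ct_series"))
  format <- match.arg(format)
  switch(format,
    RAW = write_series_raw(series, path),
    NIfTI = write_series_nifti(series, path),
    DICOM = write_series_dicom(series, path))
  invisible(path)
}

series_pixel_array <- function(series) {
  d <- dim(series$slices[[1]]$pixels)
  arr <- array(0, c(length(series$slices), d[1], d[2]))
  for (i in seq_along(series$slices)) arr[i, , ] <- series$slices[[i]]$pixels
  arr
}

series_from_array <- function(arr, spacing, modality, interval, idx = NULL) {
  n <- dim(arr)[1]
  if (is.null(idx)) idx <- seq_len(n)
  ct_series(lapply(seq_len(n), function(i)
    ct_image(arr[i, , ], spacing = spacing, modality = modality,
             slice_index = idx[i])), reconstruction_interval = interval)
}

## ---- RAW + JSON fixture format ----

read_series_raw <- function(path) {
  raw_file <- paste0(path, ".raw"); json_file <- paste0(path, ".json")
  if (!file.exists(raw_file) || !file.exists(json_file))
    stop("RAW fixture needs both ", raw_file, " and ", json_file,
         call. = FALSE)
  meta <- jsonlite::fromJSON(json_file)
  shape <- as.integer(meta$shape)
  if (length(shape) == 2L) shape <- c(1L, shape)
  n <- prod(shape)
  v <- readBin(raw_file, "numeric", n = n, size = 4L, endian = "little")
  if (length(v) != n)
    stop("RAW payload truncated: expected ", n, " floats, got ", length(v),
         call. = FALSE)
  # payload is C order (slice, row, col); aperm from R's column-major fill
  arr <- aperm(array(v, rev(shape)), 3:1)
  series_from_array(arr,
    spacing = as.numeric(meta$spacing),
    modality = if (is.null(meta$modality)) "SYNTHETIC" else meta$modality,
    interval = if (is.null(meta$reconstruction_interval)) 2
               else meta$reconstruction_interval,
    idx = if (is.null(meta$slice_indices)) NULL
          else as.integer(meta$slice_indices))
}

write_series_raw <- function(series, path) {
  arr <- series_pixel_array(series)
  s1 <- series$slices[[1]]
  meta <- list(
    shape = dim(arr), order = "C",
    dtype = "float32", endian = "little",
    spacing = s1$spacing, modality = s1$modality,
    reconstruction_interval = series$reconstruction_interval,
    slice_indices = vapply(series$slices, function(s) s$slice_index, 1L))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  writeBin(as.numeric(aperm(arr, 3:1)), paste0(path, ".raw"),
           size = 4L, endian = "little")
}

## ---- NIfTI via RNifti ----

read_series_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  pd <- RNifti::pixdim(img)
  modality <- "SYNTHETIC"
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  if (file.exists(side)) {
    m <- jsonlite::fromJSON(side)
    if (!is.null(m$modality)) modality <- m$modality
  }
  # store as (x, y, z); we map x->row, y->col, z->slice
  arr <- aperm(arr, c(3, 1, 2))
  series_from_array(arr, spacing = pd[1:2], modality = modality,
                    interval = if (length(pd) >= 3) pd[3] else 2)
}

write_series_nifti <- function(series, path) {
  arr <- aperm(series_pixel_array(series), c(2, 3, 1))
  s1 <- series$slices[[1]]
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(s1$spacing, series$reconstruction_interval)
  RNifti::writeNifti(img, path)
  jsonlite::write_json(list(modality = s1$modality),
                       sub("\\.nii(\\.gz)?$", ".json", path),
                       auto_unbox = TRUE)
}

## ---- minimal DICOM subset ----
## Single-frame, 16-bit signed, MONOCHROME2, explicit VR little endian.
## No installed R package reads DICOM, so the subset needed for CT slice
## interchange is implemented here directly.

dcm_uint <- function(x, size) {
  writeBin(as.integer(x), raw(), size = size, endian = "little")
}

dcm_element <- function(group, elem, vr, value_raw) {
  len <- length(value_raw)
  if (vr %in% c("OB", "OW", "UN", "UT", "SQ")) {
    c(dcm_uint(group, 2), dcm_uint(elem, 2), charToRaw(vr), as.raw(c(0, 0)),
      dcm_uint(len, 4), value_raw)
  } else {
    c(dcm_uint(group, 2), dcm_uint(elem, 2), charToRaw(vr),
      dcm_uint(len, 2), value_raw)
  }
}

dcm_str <- function(s) {
  r <- charToRaw(s)
  if (length(r) %% 2 == 1) r <- c(r, charToRaw(" "))
  r
}

dcm_ui <- function(s) {          # UIDs pad with NUL, not space
  r <- charToRaw(s)
  if (length(r) %% 2 == 1) r <- c(r, as.raw(0))
  r
}

write_dicom_slice <- function(img, file, z_position, instance_number) {
  px <- round(img$pixels)
  if (any(px < -32768 | px > 32767))
    stop("HU out of int16 range for DICOM writer", call. = FALSE)
  # stored = HU - intercept with slope 1; intercept -1024 keeps typical
  # stored values non-negative, matching CT convention
  intercept <- -1024
  stored <- matrix(as.integer(px - intercept), nrow(px), ncol(px))
  d <- dim(px)
  # pixel data row-major
  pixel_raw <- writeBin(as.integer(t(stored)), raw(), size = 2L,
                        endian = "little")
  sop_uid <- paste0("1.2.826.0.1.3680043.9999.", instance_number, ".",
                    d[1], ".", d[2])
  ds <- c(
    dcm_element(0x0008, 0x0016, "UI",
                dcm_ui("1.2.840.10008.5.1.4.1.1.2")),
    dcm_element(0x0008, 0x0018, "UI", dcm_ui(sop_uid)),
    dcm_element(0x0008, 0x0060, "CS", dcm_str(
      if (img$modality == "KVCT") "CT" else "CT")),
    dcm_element(0x0009, 0x0010, "LO", dcm_str(img$modality)),
    dcm_element(0x0020, 0x0013, "IS", dcm_str(as.character(instance_number))),
    dcm_element(0x0020, 0x0032, "DS", dcm_str(
      sprintf("0\\0\\%.6g", z_position))),
    dcm_element(0x0028, 0x0002, "US", dcm_uint(1, 2)),
    dcm_element(0x0028, 0x0004, "CS", dcm_str("MONOCHROME2")),
    dcm_element(0x0028, 0x0010, "US", dcm_uint(d[1], 2)),
    dcm_element(0x0028, 0x0011, "US", dcm_uint(d[2], 2)),
    dcm_element(0x0028, 0x0030, "DS", dcm_str(
      sprintf("%.6g\\%.6g", img$spacing[1], img$spacing[2]))),
    dcm_element(0x0028, 0x0100, "US", dcm_uint(16, 2)),
    dcm_element(0x0028, 0x0101, "US", dcm_uint(16, 2)),
    dcm_element(0x0028, 0x0102, "US", dcm_uint(15, 2)),
    dcm_element(0x0028, 0x0103, "US", dcm_uint(1, 2)),
    dcm_element(0x0028, 0x1052, "DS", dcm_str(as.character(intercept))),
    dcm_element(0x0028, 0x1053, "DS", dcm_str("1")),
    dcm_element(0x7FE0, 0x0010, "OW", pixel_raw))
  meta_body <- c(
    dcm_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    dcm_element(0x0002, 0x0002, "UI",
                dcm_ui("1.2.840.10008.5.1.4.1.1.2")),
    dcm_element(0x0002, 0x0003, "UI", dcm_ui(sop_uid)),
    dcm_element(0x0002, 0x0010, "UI", dcm_ui("1.2.840.10008.1.2.1")))
  meta <- c(dcm_element(0x0002, 0x0000, "UL",
                        dcm_uint(length(meta_body), 4)), meta_body)
  con <- file(file, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, ds), con)
}

read_dicom_slice <- function(file) {
  buf <- readBin(file, "raw", n = file.info(file)$size)
  if (length(buf) < 160 || rawToChar(buf[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", file, call. = FALSE)
  pos <- 133L
  u16 <- function(p) sum(as.integer(buf[p:(p + 1)]) * c(1, 256))
  u32 <- function(p) sum(as.integer(buf[p:(p + 3)]) * c(1, 256, 65536, 16777216))
  tags <- list()
  while (pos + 7 <= length(buf)) {
    group <- u16(pos); elem <- u16(pos + 2L)
    vr <- rawToChar(buf[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("implicit-VR or unsupported DICOM encoding in ", file,
           call. = FALSE)
    if (vr %in% c("OB", "OW", "UN", "UT", "SQ")) {
      len <- u32(pos + 8L); vpos <- pos + 12L
    } else {
      len <- u16(pos + 6L); vpos <- pos + 8L
    }
    if (len == 4294967295)
      stop("undefined-length DICOM elements are unsupported", call. = FALSE)
    key <- sprintf("%04X,%04X", group, elem)
    tags[[key]] <- list(vr = vr, start = vpos, len = len)
    pos <- vpos + len
  }
  get_str <- function(key, default = NULL) {
    t <- tags[[key]]
    if (is.null(t)) return(default)
    trimws(rawToChar(buf[t$start:(t$start + t$len - 1L)]))
  }
  get_us <- function(key) { t <- tags[[key]]; u16(t$start) }
  ts <- get_str("0002,0010")
  if (!is.null(ts) && ts != "1.2.840.10008.1.2.1")
    stop("unsupported transfer syntax ", ts,
         " (only explicit VR little endian)", call. = FALSE)
  rows <- get_us("0028,0010"); cols <- get_us("0028,0011")
  bits <- get_us("0028,0100")
  if (bits != 16L) stop("only 16-bit DICOM pixel data supported", call. = FALSE)
  signed <- get_us("0028,0103") == 1L
  slope <- as.numeric(get_str("0028,1053", "1"))
  intercept <- as.numeric(get_str("0028,1052", "0"))
  pd <- tags[["7FE0,0010"]]
  if (is.null(pd)) stop("missing PixelData in ", file, call. = FALSE)
  stored <- readBin(buf[pd$start:(pd$start + pd$len - 1L)], "integer",
                    n = rows * cols, size = 2L, signed = signed,
                    endian = "little")
  hu <- matrix(slope * stored + intercept, nrow = rows, ncol = cols,
               byrow = TRUE)
  ipp <- get_str("0020,0032", "0\\0\\0")
  z <- as.numeric(strsplit(ipp, "\\\\")[[1]][3])
  spacing <- as.numeric(strsplit(get_str("0028,0030", "1\\1"), "\\\\")[[1]])
  modality <- get_str("0009,0010", "MVCT")
  if (!modality %in% c("MVCT", "KVCT", "SYNTHETIC")) modality <- "MVCT"
  list(hu = hu, z = z,
       instance = as.integer(get_str("0020,0013", "0")),
       spacing = spacing, modality = modality)
}

read_series_dicom <- function(path) {
  files <- list.files(path, pattern = "\\.dcm$", full.names = TRUE)
  if (!length(files)) stop("no .dcm files under ", path, call. = FALSE)
  parsed <- lapply(files, read_dicom_slice)
  z <- vapply(parsed, `[[`, 1, "z")
  inst <- vapply(parsed, `[[`, 1L, "instance")
  parsed <- parsed[order(z, inst)]
  slices <- lapply(seq_along(parsed), function(i) {
    p <- parsed[[i]]
    ct_image(p$hu, spacing = p$spacing, modality = p$modality,
             slice_index = i)
  })
  zs <- sort(z)
  interval <- if (length(zs) > 1) stats::median(diff(zs)) else 2
  ct_series(slices, reconstruction_interval = interval)
}

write_series_dicom <- function(series, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(series$slices)) {
    write_dicom_slice(series$slices[[i]],
                      file.path(path, sprintf("slice%04d.dcm", i)),
                      z_position = (i - 1) * series$reconstruction_interval,
                      instance_number = i)
  }
}
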