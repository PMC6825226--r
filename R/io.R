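#' Read and write voxel image stacks
#'
#' Two interchange formats are supported, chosen by file extension:
#' \describe{
#'   \item{NRRD (`.nrrd`)}{Single file, raw little-endian doubles, with the
#'     voxel size in the header (`spacings`) and the image type and origin in
#'     key-value fields. Lossless for both label and grayscale images.}
#'   \item{TIFF stack (`.tif`/`.tiff`)}{One multi-page file, one slice per z
#'     plane, 8-bit for label images and 16-bit for grayscale. TIFF carries no
#'     physical metadata, so a YAML sidecar `<path>.yml` stores the voxel
#'     size, origin, type, and integer value scale. Grayscale values must be
#'     integers in `[0, 65535]` to round-trip exactly.}
#' }
#'
#' @param path file path ending in `.nrrd`, `.tif` or `.tiff`.
#' @param image a `voxel_image`.
#' @return `read_image_stack` returns a `voxel_image`;
#'   `write_image_stack` returns `path` invisibly.
#' @examples
#' img <- voxel_image(array(round(65535 * stats::runif(8)), c(2, 2, 2)),
#'                    voxel_size = 10)
#' p <- tempfile(fileext = ".nrrd")
#' write_image_stack(img, p)
#' identical(read_image_stack(p)$data, img$data)
#' @export
read_image_stack <- function(path) {
  if (!file.exists(path)) stop_pf("file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    nrrd = read_nrrd(path),
    tif = ,
    tiff = read_tiff_stack(path),
    stop_pf("unsupported image format '.%s' (use .nrrd, .tif or .tiff)", ext)
  )
}

#' @rdname read_image_stack
#' @export
write_image_stack <- function(image, path) {
  if (!inherits(image, "voxel_image")) stop_pf("`image` must be a voxel_image")
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    nrrd = write_nrrd(image, path),
    tif = ,
    tiff = write_tiff_stack(image, path),
    stop_pf("unsupported image format '.%s' (use .nrrd, .tif or .tiff)", ext)
  )
  invisible(path)
}

# -- NRRD ---------------------------------------------------------------
# Minimal NRRD0004 reader/writer: raw encoding, little endian, type double.
# The subset written here is exactly the subset read back; no installed R
# package parses NRRD, so the (simple, line-oriented) header is handled
# directly.

write_nrrd <- function(image, path) {
  d <- dim(image$data)
  con <- file(path, open = "wb")
  on.exit(close(con))
  hdr <- c(
    "NRRD0004",
    "# voxel image written by poreflow",
    "type: double",
    "dimension: 3",
    sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
    sprintf("spacings: %.17g %.17g %.17g",
            image$voxel_size, image$voxel_size, image$voxel_size),
    "space units: \"um\" \"um\" \"um\"",
    "encoding: raw",
    "endian: little",
    sprintf("image_type:=%s", image$type),
    sprintf("origin_um:=%.17g %.17g %.17g",
            image$origin[1], image$origin[2], image$origin[3]),
    ""
  )
  writeLines(hdr, con, sep = "\n")
  writeBin(as.vector(image$data), con, size = 8, endian = "little")
  invisible(path)
}

read_nrrd <- function(path) {
  con <- file(path, open = "rb")
  on.exit(close(con))
  lines <- character()
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) stop_pf("truncated NRRD header in %s", path)
    if (ln == "") break
    lines <- c(lines, ln)
  }
  if (!grepl("^NRRD", lines[1])) stop_pf("%s is not an NRRD file", path)
  field <- function(key) {
    hit <- grep(paste0("^", key, ": "), lines, value = TRUE)
    if (length(hit) == 0L) return(NULL)
    sub(paste0("^", key, ": "), "", hit[1])
  }
  kv <- function(key) {
    hit <- grep(paste0("^", key, ":="), lines, value = TRUE)
    if (length(hit) == 0L) return(NULL)
    sub(paste0("^", key, ":="), "", hit[1])
  }
  type <- field("type")
  if (is.null(type) || type != "double")
    stop_pf("unsupported NRRD type '%s' (only 'double' raw is supported)",
            type %||% "<missing>")
  if ((field("encoding") %||% "") != "raw")
    stop_pf("unsupported NRRD encoding (only 'raw')")
  sizes <- as.integer(strsplit(field("sizes") %||%
                                 stop_pf("NRRD missing sizes"), " +")[[1]])
  if (length(sizes) != 3L) stop_pf("NRRD must be 3-dimensional")
  spac <- field("spacings")
  if (is.null(spac))
    stop_pf("NRRD %s lacks 'spacings' (voxel size metadata required)", path)
  spac <- as.numeric(strsplit(spac, " +")[[1]])
  if (length(unique(round(spac, 12))) != 1L)
    stop_pf("anisotropic voxels are not supported (spacings: %s)",
            paste(spac, collapse = " "))
  n <- prod(sizes)
  raw <- readBin(con, what = "double", n = n, size = 8, endian = "little")
  if (length(raw) != n) stop_pf("truncated NRRD data in %s", path)
  origin <- kv("origin_um")
  origin <- if (is.null(origin)) c(0, 0, 0) else
    as.numeric(strsplit(origin, " +")[[1]])
  voxel_image(array(raw, dim = sizes), voxel_size = spac[1],
              origin = origin, type = kv("image_type"))
}

# -- TIFF stack ---------------------------------------------------------

tiff_sidecar <- function(path) paste0(path, ".yml")

write_tiff_stack <- function(image, path) {
  d <- dim(image$data)
  if (image$type == "label") {
    bits <- 8L
    scale <- 255
  } else {
    bits <- 16L
    scale <- 65535
    if (any(image$data < 0 | image$data > scale) ||
        any(image$data != round(image$data)))
      stop_pf(paste0("grayscale TIFF export requires integer values in ",
                     "[0, 65535]; rescale first or use NRRD"))
  }
  slices <- lapply(seq_len(d[3]), function(k) image$data[, , k] / scale)
  tiff::writeTIFF(slices, path, bits.per.sample = bits, compression = "none")
  yaml::write_yaml(
    list(voxel_size_um = image$voxel_size,
         origin_um = as.numeric(image$origin),
         image_type = image$type, value_scale = scale),
    tiff_sidecar(path)
  )
  invisible(path)
}

read_tiff_stack <- function(path) {
  side <- tiff_sidecar(path)
  if (!file.exists(side))
    stop_pf(paste0("TIFF stack %s has no sidecar %s; voxel-size metadata is ",
                   "required (write with write_image_stack, or use NRRD)"),
            path, side)
  meta <- yaml::read_yaml(side)
  if (is.null(meta$voxel_size_um))
    stop_pf("sidecar %s lacks voxel_size_um", side)
  slices <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(slices)) slices <- list(slices)
  dims <- vapply(slices, function(s) dim(s)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop_pf("inconsistent slice shapes in %s", path)
  scale <- meta$value_scale %||% 1
  data <- array(0, c(dims[1, 1], dims[2, 1], length(slices)))
  for (k in seq_along(slices)) data[, , k] <- round(slices[[k]] * scale)
  voxel_image(data, voxel_size = meta$voxel_size_um,
              origin = meta$origin_um %||% c(0, 0, 0),
              type = meta$image_type)
}
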