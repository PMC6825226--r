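#' Voxel image container
#'
#' A `voxel_image` is a 3D scalar lattice (grayscale intensities or binary
#' labels with 0 = solid, 1 = fluid) together with its physical voxel size.
#' The z axis is, by convention, the perfusion/flow axis. Voxel indices are
#' 1-based in R; physical boxes are half-open `[lo, hi)` with the origin at
#' the outer corner of voxel (1,1,1).
#'
#' @param data numeric or logical 3D array. Label images must contain only
#'   values 0 and 1.
#' @param voxel_size isotropic voxel edge length in micrometres (> 0).
#' @param origin physical position (um) of the corner of voxel (1,1,1);
#'   length-3 numeric.
#' @param type `"grayscale"` or `"label"`; guessed from `data` if omitted.
#'
#' @return An object of class `voxel_image` with fields `data`, `voxel_size`
#'   (um), `origin` (um) and `type`.
#' @examples
#' img <- voxel_image(array(1, c(4, 4, 4)), voxel_size = 10)
#' dim(img)
#' porosity(img)
#' @export
voxel_image <- function(data, voxel_size, origin = c(0, 0, 0), type = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop_pf("`data` must be a 3D array")
  if (any(dim(data) < 1L)) stop_pf("all three dimensions must be >= 1")
  check_number(voxel_size, "voxel_size", lo = .Machine$double.eps)
  if (length(origin) != 3L || !is.numeric(origin))
    stop_pf("`origin` must be a length-3 numeric vector")
  storage.mode(data) <- "double"
  if (is.null(type)) {
    type <- if (all(data %in% c(0, 1))) "label" else "grayscale"
  }
  type <- match.arg(type, c("grayscale", "label"))
  if (type == "label" && !all(data %in% c(0, 1)))
    stop_pf("label images may contain only 0 (solid) and 1 (fluid)")
  structure(
    list(data = data, voxel_size = as.numeric(voxel_size),
         origin = as.numeric(origin), type = type),
    class = "voxel_image"
  )
}

#' @export
dim.voxel_image <- function(x) dim(x$data)

#' @export
print.voxel_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_image> %d x %d x %d voxels @ %g um (%s)\n",
              d[1], d[2], d[3], x$voxel_size, x$type))
  cat(sprintf("  extent: %.1f x %.1f x %.1f um, origin (%g, %g, %g) um\n",
              d[1] * x$voxel_size, d[2] * x$voxel_size, d[3] * x$voxel_size,
              x$origin[1], x$origin[2], x$origin[3]))
  if (x$type == "label")
    cat(sprintf("  fluid fraction: %.3f\n", mean(x$data)))
  invisible(x)
}

is_label_image <- function(x) {
  inherits(x, "voxel_image") && x$type == "label"
}

#' Fluid volume fraction of a label image
#'
#' @param image a binary `voxel_image` (1 = fluid, 0 = solid).
#' @return fraction of fluid voxels in `[0, 1]`.
#' @export
porosity <- function(image) {
  if (!is_label_image(image)) stop_pf("`image` must be a label voxel_image")
  mean(image$data)
}

assert_grayscale <- function(image) {
  if (!inherits(image, "voxel_image")) stop_pf("expected a voxel_image")
  if (image$type != "grayscale")
    stop_pf("expected a grayscale voxel_image; got labels")
  invisible(image)
}
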