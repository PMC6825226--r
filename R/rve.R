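#' Representative volume element (RVE) specification
#'
#' An axis-aligned physical box (um, half-open `[lo, hi)`) inside a parent
#' scaffold image. RVEs span the full scaffold height in z so that the
#' vertical pressure drop of the macro model maps one-to-one onto the
#' micro model.
#'
#' @param index identifier (integer).
#' @param lo,hi length-3 numeric corners in um, `lo < hi` componentwise.
#' @return an object of class `rve_spec`.
#' @export
rve_spec <- function(index, lo, hi) {
  if (length(lo) != 3L || length(hi) != 3L || any(hi <= lo))
    stop_pf("`lo` and `hi` must be length-3 with hi > lo componentwise")
  structure(list(index = as.integer(index), lo = as.numeric(lo),
                 hi = as.numeric(hi)),
            class = "rve_spec")
}

#' @export
print.rve_spec <- function(x, ...) {
  cat(sprintf("<rve_spec #%d> [%g, %g) x [%g, %g) x [%g, %g) um\n",
              x$index, x$lo[1], x$hi[1], x$lo[2], x$hi[2], x$lo[3], x$hi[3]))
  invisible(x)
}

# voxel index range (1-based, inclusive) of a physical interval
bbox_to_voxels <- function(image, spec) {
  h <- image$voxel_size
  lo <- round((spec$lo - image$origin) / h)
  hi <- round((spec$hi - image$origin) / h)
  if (any(abs((spec$lo - image$origin) / h - lo) > 1e-6) ||
      any(abs((spec$hi - image$origin) / h - hi) > 1e-6))
    stop_pf("RVE bbox is not aligned to the voxel grid")
  d <- dim(image$data)
  if (any(lo < 0) || any(hi > d) || any(hi <= lo))
    stop_pf("RVE bbox lies outside the parent image")
  list(lo = as.integer(lo) + 1L, hi = as.integer(hi))
}

#' Crop an RVE out of a voxel image
#'
#' @param image parent `voxel_image`.
#' @param spec an [rve_spec()] whose box lies within the image and is aligned
#'   to the voxel grid.
#' @return cropped `voxel_image` with its origin moved to the box corner.
#' @export
extract_rve <- function(image, spec) {
  if (!inherits(image, "voxel_image")) stop_pf("`image` must be a voxel_image")
  if (!inherits(spec, "rve_spec")) stop_pf("`spec` must be an rve_spec")
  ix <- bbox_to_voxels(image, spec)
  voxel_image(
    image$data[ix$lo[1]:ix$hi[1], ix$lo[2]:ix$hi[2], ix$lo[3]:ix$hi[3],
               drop = FALSE],
    image$voxel_size, origin = spec$lo, type = image$type
  )
}

#' Lay out a regular grid of RVEs over a scaffold
#'
#' Places `nx * ny` equal-sized ("isometric") RVEs on a regular grid over the
#' inscribed square of the scaffold footprint, each spanning the full
#' scaffold height. The grid samples representative locations; it does not
#' tile the footprint.
#'
#' @param scaffold parent `voxel_image`.
#' @param grid integer pair `(nx, ny)` of grid positions.
#' @param rve_xy lateral RVE edge length in um.
#' @return list of [rve_spec()] objects, row-major over the grid.
#' @export
partition_rves <- function(scaffold, grid, rve_xy) {
  if (!inherits(scaffold, "voxel_image"))
    stop_pf("`scaffold` must be a voxel_image")
  if (length(grid) != 2L || any(grid < 1)) stop_pf("`grid` must be (nx, ny)")
  grid <- as.integer(grid)
  h <- scaffold$voxel_size
  d <- dim(scaffold$data)
  side_vox <- min(d[1], d[2])          # inscribed square of the footprint
  n_rve <- round(rve_xy / h)
  if (abs(rve_xy / h - n_rve) > 1e-6)
    stop_pf("`rve_xy` must be a whole number of voxels")
  if (n_rve < 1 || n_rve * max(grid) > side_vox)
    stop_pf("rve_xy = %g um does not fit a %d x %d grid in the footprint",
            rve_xy, grid[1], grid[2])
  centre <- c(d[1], d[2]) / 2
  specs <- list()
  idx <- 0L
  for (gy in seq_len(grid[2])) {
    for (gx in seq_len(grid[1])) {
      idx <- idx + 1L
      # grid cell centres across the inscribed square, snapped to voxels
      cx <- centre[1] + side_vox * ((gx - 0.5) / grid[1] - 0.5)
      cy <- centre[2] + side_vox * ((gy - 0.5) / grid[2] - 0.5)
      x0 <- round(cx - n_rve / 2); y0 <- round(cy - n_rve / 2)
      x0 <- min(max(x0, 0L), d[1] - n_rve)
      y0 <- min(max(y0, 0L), d[2] - n_rve)
      specs[[idx]] <- rve_spec(
        idx,
        lo = scaffold$origin + c(x0, y0, 0) * h,
        hi = scaffold$origin + c(x0 + n_rve, y0 + n_rve, d[3]) * h
      )
    }
  }
  specs
}

#' Build the computational fluid domain of a scaffold
#'
#' Takes the complement of the solid phase, removes fluid voxels that are not
#' 6-connected to both the inlet (-z) and outlet (+z) faces (trapped
#' porosity, which carries no flow), and records the boundary-face tags
#' implied by the staggered-grid solver: inlet/outlet at the -z/+z box faces,
#' lateral at the x/y box faces, and wall at every fluid-solid interface
#' face.
#'
#' @param scaffold binary label `voxel_image` (1 = fluid).
#' @return an object of class `fluid_domain` with fields `mask` (logical
#'   array of percolating fluid), `voxel_size` (um), `origin`,
#'   `trapped_fraction` (fraction of the raw fluid phase removed), and
#'   `face_counts` (named tag counts).
#' @export
build_fluid_domain <- function(scaffold) {
  if (!is_label_image(scaffold)) stop_pf("`scaffold` must be a label image")
  fluid <- scaffold$data == 1
  if (!any(fluid)) stop_pf("scaffold not permeable: no fluid phase")
  span <- spanning_fluid(fluid)
  if (!any(span))
    stop_pf("scaffold not permeable: no z-spanning fluid path")
  trapped <- sum(fluid) - sum(span)
  dom <- structure(
    list(mask = span, voxel_size = scaffold$voxel_size,
         origin = scaffold$origin,
         trapped_fraction = trapped / sum(fluid)),
    class = "fluid_domain"
  )
  dom$face_counts <- count_boundary_faces(dom)
  dom
}

#' @export
print.fluid_domain <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("<fluid_domain> %d x %d x %d voxels @ %g um\n",
              d[1], d[2], d[3], x$voxel_size))
  cat(sprintf("  fluid fraction %.3f, trapped porosity removed %.4f\n",
              mean(x$mask), x$trapped_fraction))
  cat("  faces:", paste(names(x$face_counts), x$face_counts, sep = "=",
                        collapse = ", "), "\n")
  invisible(x)
}

# Tag counts for the domain boundary:
#   inlet/outlet: fluid cells on the -z/+z box faces
#   lateral:      fluid cells touching the x/y box faces
#   wall:         fluid-solid interface faces (6-neighbourhood)
count_boundary_faces <- function(dom) {
  m <- dom$mask
  d <- dim(m)
  lateral <- sum(m[1, , ]) + sum(m[d[1], , ]) + sum(m[, 1, ]) + sum(m[, d[2], ])
  offs <- neighbour_offsets()
  wall <- 0L
  for (r in seq_len(nrow(offs))) {
    nb <- shift_array(m, offs[r, 1], offs[r, 2], offs[r, 3], fill = NA)
    wall <- wall + sum(m & !nb, na.rm = TRUE)  # fluid face against solid
  }
  c(inlet = sum(m[, , 1]), outlet = sum(m[, , d[3]]),
    lateral = lateral, wall = wall)
}
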