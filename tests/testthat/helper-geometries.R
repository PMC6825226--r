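# Shared fixture builders: all geometry is generated in code at test time.

# Parallel-plate duct: solid walls at x = 1 and x = nx, thin periodic-like y
# (symmetric laterals make the flow invariant in y), flow along z.
plates_image <- function(gap = 20, nz = 3 * gap, ny = 3, voxel = 10) {
  nx <- gap + 2
  mask <- array(1, c(nx, ny, nz))
  mask[1, , ] <- 0
  mask[nx, , ] <- 0
  voxel_image(mask, voxel_size = voxel)
}

# Cylindrical channel of radius R voxels carved through a solid block,
# axis on the centre of the middle voxel column.
cylinder_image <- function(R = 10, nz = 48, pad = 2, voxel = 10) {
  n <- 2 * (ceiling(R) + pad) + 1
  mid <- (n + 1) / 2
  x <- seq_len(n) - mid
  circ <- outer(x, x, function(a, b) a^2 + b^2 <= R^2)
  mask <- array(0, c(n, n, nz))
  for (k in seq_len(nz)) mask[, , k] <- circ
  voxel_image(mask, voxel_size = voxel)
}

# small irregular scaffold for generic solver checks
small_scaffold <- function(size = 24, porosity = 0.8, pore = 80, seed = 7) {
  generate_scaffold(porosity, pore, rep(size, 3), 10, seed = seed)
}

# mean axial velocity across the plate gap from the through-flow
plate_mean_velocity <- function(field) {
  d <- dim(field$domain$mask)
  h <- field$domain$voxel_size * 1e-6
  gap_area <- (d[1] - 2) * d[2] * h^2
  flow_rate(field, floor(d[3] / 2)) / gap_area
}

# hand-built WSS field for histogram / subregion unit tests
toy_wss_field <- function(wss_mpa, x = NULL, y = NULL, area = 1) {
  n <- length(wss_mpa)
  elements <- data.frame(
    x = x %||% seq_len(n), y = y %||% rep(1, n), z = 0,
    nx = 1L, ny = 0L, nz = 0L,
    area = rep(area, length.out = n), wss = wss_mpa / 1000
  )
  structure(list(elements = elements, total_area = sum(elements$area),
                 voxel_size = 1, inlet_kind = "test"),
            class = "wss_field")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
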