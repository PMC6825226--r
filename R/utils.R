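# Internal helpers shared across modules. All physical quantities are SI
# internally (m, m/s, Pa, Pa.s); voxel sizes at the user surface are in um.

UM <- 1e-6  # metres per micrometre

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Shift a 3D array by (dx, dy, dz) voxels, filling exposed planes with `fill`.
# shift_array(a, 1, 0, 0)[i, , ] == a[i - 1, , ].
shift_array <- function(a, dx, dy, dz, fill = 0) {
  d <- dim(a)
  out <- array(fill, dim = d)
  src <- list(
    seq_len(d[1]) - dx, seq_len(d[2]) - dy, seq_len(d[3]) - dz
  )
  keep <- lapply(seq_len(3), function(ax) {
    which(src[[ax]] >= 1 & src[[ax]] <= d[ax])
  })
  if (any(vapply(keep, length, 1L) == 0L)) return(out)
  out[keep[[1]], keep[[2]], keep[[3]]] <-
    a[src[[1]][keep[[1]]], src[[2]][keep[[2]]], src[[3]][keep[[3]]]]
  out
}

# 6-neighbourhood offsets as a 6 x 3 integer matrix
neighbour_offsets <- function() {
  rbind(
    c(-1L, 0L, 0L), c(1L, 0L, 0L),
    c(0L, -1L, 0L), c(0L, 1L, 0L),
    c(0L, 0L, -1L), c(0L, 0L, 1L)
  )
}

# Flood fill over a logical mask from a logical seed array, 6-connectivity.
# Returns the logical array of voxels reachable from the seed within mask.
# Breadth-first over vectorised index frontiers: O(N) work overall.
flood_fill6 <- function(mask, seed) {
  d <- dim(mask)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  reached <- as.vector(seed & mask)
  maskv <- as.vector(mask)
  frontier <- which(reached)
  nxy <- nx * ny
  while (length(frontier) > 0L) {
    i0 <- (frontier - 1L) %% nx
    j0 <- ((frontier - 1L) %/% nx) %% ny
    k0 <- (frontier - 1L) %/% nxy
    cand <- c(
      frontier[i0 > 0L] - 1L,
      frontier[i0 < nx - 1L] + 1L,
      frontier[j0 > 0L] - nx,
      frontier[j0 < ny - 1L] + nx,
      frontier[k0 > 0L] - nxy,
      frontier[k0 < nz - 1L] + nxy
    )
    cand <- unique(cand[maskv[cand] & !reached[cand]])
    reached[cand] <- TRUE
    frontier <- cand
  }
  array(reached, dim = d)
}

# Label 6-connected components of a logical mask. Returns an integer array
# (0 = background). Intended for small/test geometries; percolation checks in
# the pipeline use flood_fill6 directly.
label_components6 <- function(mask) {
  lab <- array(0L, dim = dim(mask))
  remaining <- mask
  k <- 0L
  while (any(remaining)) {
    k <- k + 1L
    seed <- array(FALSE, dim = dim(mask))
    seed[which(remaining)[1]] <- TRUE
    comp <- flood_fill6(remaining, seed)
    lab[comp] <- k
    remaining <- remaining & !comp
  }
  lab
}

stop_pf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi)
    stop_pf("`%s` must be a single finite number in [%g, %g]", name, lo, hi)
  invisible(x)
}
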