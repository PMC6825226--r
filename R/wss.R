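#' Wall shear stress on the fluid-solid interface
#'
#' Evaluates the tangential viscous traction tau = mu dv_t/dn on every wall
#' face of the staggered grid (the staircase fluid-solid interface). The
#' surface normal is estimated locally from the gradient of a Gaussian-
#' smoothed solid indicator, so oblique walls are treated by their true
#' orientation rather than the voxel face axis. The tangential speed is
#' sampled by trilinear interpolation at three depths along the inward
#' normal from the face centre; a quadratic profile
#' q(s) = c0 + c1 s + c2 s^2 is fitted through the three samples and
#' differentiated at its own near-wall root, so the effective no-slip
#' plane of the staircase discretization is located by the velocity field
#' itself (sub-voxel wall-position errors are otherwise amplified by
#' one-sided gradients). The scheme is exact for plane-Poiseuille and tube
#' profiles.
#'
#' @param field a converged `flow_field`.
#' @param sample_depths three increasing sampling distances along the inward
#'   normal, in voxels. The default `c(2, 3.5, 5)` starts just outside the
#'   staircase boundary layer (whose corner-retarded velocities extend
#'   about two voxels from the wall) while staying within about half a
#'   pore radius of typical scaffold pores; shallower depths read the
#'   retarded layer and bias smooth-wall WSS low.
#' @return a `wss_field`: data frame `elements` with face-centre positions
#'   `x`, `y`, `z` (um), the outward (fluid-to-solid) local unit normals
#'   `nx`, `ny`, `nz`, the face `area` (um^2; the voxel face projected onto
#'   the local surface orientation, so areas sum to an estimate of the
#'   smooth interface area) and `wss` (Pa), plus `total_area` (um^2) and
#'   provenance. Domains without walls yield an empty field with a warning.
#' @export
compute_wss <- function(field, sample_depths = c(2, 3.5, 5)) {
  if (!inherits(field, "flow_field")) stop_pf("`field` must be a flow_field")
  if (length(sample_depths) != 3L || any(diff(sample_depths) <= 0) ||
      sample_depths[1] <= 0)
    stop_pf("`sample_depths` must be three increasing positive distances")
  m <- field$domain$mask
  d <- dim(m)
  h_um <- field$domain$voxel_size
  h <- h_um * UM
  mu <- field$props$mu

  # cell-centre velocities
  cc <- list(
    (field$u[1:d[1], , , drop = FALSE] +
       field$u[2:(d[1] + 1), , , drop = FALSE]) / 2,
    (field$v[, 1:d[2], , drop = FALSE] +
       field$v[, 2:(d[2] + 1), , drop = FALSE]) / 2,
    (field$w[, , 1:d[3], drop = FALSE] +
       field$w[, , 2:(d[3] + 1), drop = FALSE]) / 2
  )

  # smoothed solid indicator for local surface normals
  phi <- convolve_axis(convolve_axis(convolve_axis(
    (!m) + 0, norm_gauss(1.2, 3), -3:3, 1, "replicate"),
    norm_gauss(1.2, 3), -3:3, 2, "replicate"),
    norm_gauss(1.2, 3), -3:3, 3, "replicate")
  gphi <- lapply(1:3, function(j) {
    e <- unit3(j)
    pp <- shift_array(phi, -e[1], -e[2], -e[3], fill = NA)
    pm <- shift_array(phi, e[1], e[2], e[3], fill = NA)
    pp[is.na(pp)] <- phi[is.na(pp)]
    pm[is.na(pm)] <- phi[is.na(pm)]
    (pp - pm) / 2
  })

  rows <- list()
  offs <- neighbour_offsets()
  for (r in seq_len(nrow(offs))) {
    e <- offs[r, ]
    # wall: fluid cell whose neighbour in direction e is a solid voxel
    nb <- shift_array(m, -e[1], -e[2], -e[3], fill = TRUE)
    wall <- m & !nb
    if (!any(wall)) next
    idx <- which(wall, arr.ind = TRUE)
    axis_n <- which(e != 0)

    # local outward normal from the smoothed indicator at the wall cell,
    # oriented along the face axis; fallback to the face normal
    nvec <- cbind(gphi[[1]][wall], gphi[[2]][wall], gphi[[3]][wall])
    nn <- sqrt(rowSums(nvec^2))
    ok <- nn > 1e-10 & (nvec[, axis_n] * e[axis_n]) > 0
    nvec[!ok, ] <- matrix(rep(e, sum(!ok)), ncol = 3, byrow = TRUE)
    nvec <- nvec / sqrt(rowSums(nvec^2))

    # tangential speed sampled along the inward normal
    pos_vox <- sweep(idx, 2, c(0.5, 0.5, 0.5))        # cell centres
    pos_vox[, axis_n] <- pos_vox[, axis_n] + sign(e[axis_n]) * 0.5
    q <- sapply(sample_depths, function(s) {
      p <- pos_vox - s * nvec
      v <- sapply(1:3, function(i) trilinear_sample(cc[[i]], p))
      if (is.null(dim(v))) v <- matrix(v, ncol = 3)
      vn <- rowSums(v * nvec)
      sqrt(pmax(rowSums(v^2) - vn^2, 0))
    })
    if (is.null(dim(q))) q <- matrix(q, ncol = 3)

    # quadratic fit q(s) = c0 + c1 s + c2 s^2, slope at its near-wall root
    s1 <- sample_depths[1]; s2 <- sample_depths[2]; s3 <- sample_depths[3]
    c2 <- ((q[, 3] - q[, 1]) / (s3 - s1) - (q[, 2] - q[, 1]) / (s2 - s1)) /
      (s3 - s2)
    c1 <- (q[, 2] - q[, 1]) / (s2 - s1) - c2 * (s1 + s2)
    c0 <- q[, 1] - c1 * s1 - c2 * s1^2
    s0 <- ifelse(abs(c1) > 1e-300, -c0 / c1, 0)
    s0 <- pmin(pmax(s0, -1), 1)
    wss <- mu * abs(c1 + 2 * c2 * s0) / h

    pos <- (idx - 0.5) * h_um
    pos[, axis_n] <- pos[, axis_n] + sign(e[axis_n]) * h_um / 2
    # projected face area: the staircase face contributes its projection
    # onto the local surface orientation, so total area estimates the
    # smooth interface area instead of the (4/pi-inflated) staircase area
    proj <- abs(nvec[, axis_n])
    rows[[length(rows) + 1L]] <- data.frame(
      x = field$domain$origin[1] + pos[, 1],
      y = field$domain$origin[2] + pos[, 2],
      z = field$domain$origin[3] + pos[, 3],
      nx = nvec[, 1], ny = nvec[, 2], nz = nvec[, 3],
      area = h_um^2 * proj, wss = wss
    )
  }
  if (length(rows) == 0L) {
    warning("domain has no fluid-solid walls; returning empty WSS field")
    elements <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                           nx = integer(0), ny = integer(0), nz = integer(0),
                           area = numeric(0), wss = numeric(0))
  } else {
    elements <- do.call(rbind, rows)
  }
  structure(list(elements = elements, total_area = sum(elements$area),
                 voxel_size = h_um, inlet_kind = field$bc$inlet_kind),
            class = "wss_field")
}

#' @export
print.wss_field <- function(x, ...) {
  cat(sprintf("<wss_field> %d wall elements, total area %.3g um^2\n",
              nrow(x$elements), x$total_area))
  if (nrow(x$elements) > 0)
    cat(sprintf("  WSS (mPa): mean %.3g, median %.3g, max %.3g\n",
                1000 * mean(x$elements$wss),
                1000 * stats::median(x$elements$wss),
                1000 * max(x$elements$wss)))
  invisible(x)
}

#' @export
summary.wss_field <- function(object, ...) {
  w <- object$elements$wss * 1000
  a <- object$elements$area
  c(n = nrow(object$elements), area_um2 = object$total_area,
    mean_mPa = if (length(w)) sum(w * a) / sum(a) else NA_real_,
    max_mPa = if (length(w)) max(w) else NA_real_)
}

#' Histogram of a WSS field
#'
#' Right-open bins `[k w, (k+1) w)` from 0 to `max`, plus an overflow bin
#' `[max, Inf)`. Weights are wall areas (default; the surface-fraction view)
#' or element counts.
#'
#' @param wss a `wss_field`.
#' @param bin_width bin width in mPa (> 0).
#' @param max upper edge of the regular bins in mPa.
#' @param weighting `"area"` or `"count"`.
#' @return a `wss_histogram`: `bin_edges` (mPa, last edge `Inf`) and
#'   `weights` (um^2 or counts; they sum to the total area/count).
#' @export
wss_histogram <- function(wss, bin_width = 5, max = 100,
                          weighting = c("area", "count")) {
  if (!inherits(wss, "wss_field")) stop_pf("`wss` must be a wss_field")
  weighting <- match.arg(weighting)
  check_number(bin_width, "bin_width", lo = 1e-12)
  check_number(max, "max", lo = bin_width)
  edges <- c(seq(0, max, by = bin_width), Inf)
  w_mpa <- wss$elements$wss * 1000
  bin <- findInterval(w_mpa, edges, rightmost.closed = FALSE)
  bin[bin < 1L] <- 1L
  wgt <- if (weighting == "area") wss$elements$area else rep(1, length(w_mpa))
  weights <- vapply(seq_len(length(edges) - 1L),
                    function(k) sum(wgt[bin == k]), 1)
  structure(list(bin_edges = edges, weights = weights, weighting = weighting),
            class = "wss_histogram")
}

#' @export
print.wss_histogram <- function(x, ...) {
  cat(sprintf("<wss_histogram> %d bins (%s-weighted), total %.4g\n",
              length(x$weights), x$weighting, sum(x$weights)))
  invisible(x)
}

#' Surface-area fraction within a WSS band
#'
#' Fraction of the wall surface area experiencing WSS in `[lo, hi)` mPa,
#' the quantity used to judge how much of a scaffold surface lies inside a
#' mechanobiological stimulation window (e.g., 10-30 mPa for mineralized
#' matrix production).
#'
#' @param wss a `wss_field`.
#' @param lo,hi band edges in mPa, `lo < hi` (use `hi = Inf` for open bands).
#' @return area fraction in `[0, 1]`.
#' @export
area_fraction_in_band <- function(wss, lo, hi) {
  if (!inherits(wss, "wss_field")) stop_pf("`wss` must be a wss_field")
  if (!(lo < hi)) stop_pf("`lo` must be < `hi`")
  if (wss$total_area == 0) return(NA_real_)
  w <- wss$elements$wss * 1000
  sum(wss$elements$area[w >= lo & w < hi]) / wss$total_area
}

#' Average WSS in concentric boundary subregions
#'
#' Splits the lateral footprint of an RVE into `n_regions` square annuli of
#' equal `width`, counted inward from the RVE boundary (region 1 is
#' outermost), and reports the area-weighted mean WSS per region. Used to
#' localise the error that symmetric lateral boundaries introduce near the
#' RVE sides. Elements deeper than `n_regions * width` are ignored.
#'
#' @param wss a `wss_field`.
#' @param rve_footprint footprint as `list(lo = c(x0, y0), hi = c(x1, y1))`
#'   in um, or an [rve_spec()].
#' @param n_regions number of annular regions (>= 1).
#' @param width region width in um; `n_regions * width` must not exceed half
#'   the smaller footprint side.
#' @return numeric vector of per-region mean WSS in mPa (NA for empty
#'   regions), outermost first.
#' @export
subregion_average_wss <- function(wss, rve_footprint, n_regions = 5,
                                  width = 50) {
  if (!inherits(wss, "wss_field")) stop_pf("`wss` must be a wss_field")
  fp <- footprint_2d(rve_footprint)
  side <- min(fp$hi - fp$lo)
  if (side <= 0) stop_pf("degenerate RVE footprint")
  check_number(n_regions, "n_regions", lo = 1)
  check_number(width, "width", lo = 1e-12)
  if (n_regions * width > side / 2 + 1e-9)
    stop_pf("n_regions * width (%g um) exceeds half the footprint side (%g um)",
            n_regions * width, side / 2)
  el <- wss$elements
  dist <- pmin(el$x - fp$lo[1], fp$hi[1] - el$x,
               el$y - fp$lo[2], fp$hi[2] - el$y)
  region <- floor(dist / width) + 1
  vapply(seq_len(n_regions), function(k) {
    sel <- region == k & dist >= 0
    if (!any(sel)) return(NA_real_)
    1000 * sum(el$wss[sel] * el$area[sel]) / sum(el$area[sel])
  }, 1)
}

# Trilinear interpolation of a cell-centred array at points given in voxel
# units (cell i centred at i - 0.5). Border values are replicated; solid
# cells hold zero velocity, which is the no-slip-consistent extension.
trilinear_sample <- function(arr, pts) {
  d <- dim(arr)
  g1 <- pts[, 1] - 0.5; g2 <- pts[, 2] - 0.5; g3 <- pts[, 3] - 0.5
  i0 <- pmin(pmax(floor(g1), 0), d[1] - 1); f1 <- pmin(pmax(g1 - i0, 0), 1)
  j0 <- pmin(pmax(floor(g2), 0), d[2] - 1); f2 <- pmin(pmax(g2 - j0, 0), 1)
  k0 <- pmin(pmax(floor(g3), 0), d[3] - 1); f3 <- pmin(pmax(g3 - k0, 0), 1)
  cl <- function(i, n) pmin(pmax(i, 1L), n)
  out <- numeric(nrow(pts))
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    w <- (if (di) f1 else 1 - f1) * (if (dj) f2 else 1 - f2) *
         (if (dk) f3 else 1 - f3)
    ii <- cl(as.integer(i0) + di + 1L, d[1])
    jj <- cl(as.integer(j0) + dj + 1L, d[2])
    kk <- cl(as.integer(k0) + dk + 1L, d[3])
    out <- out + w * arr[cbind(ii, jj, kk)]
  }
  out
}

footprint_2d <- function(fp) {
  if (inherits(fp, "rve_spec")) return(list(lo = fp$lo[1:2], hi = fp$hi[1:2]))
  if (is.list(fp) && !is.null(fp$lo) && !is.null(fp$hi))
    return(list(lo = as.numeric(fp$lo[1:2]), hi = as.numeric(fp$hi[1:2])))
  stop_pf("`rve_footprint` must be an rve_spec or list(lo, hi)")
}
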