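#' Darcy permeability of a solved pore-scale flow
#'
#' Applies Darcy's law, Q = kappa * A / mu * dp / H, to a converged
#' pore-scale flow: Q is the through-flow, A the full RVE cross-section
#' (solid plus fluid), H the RVE height, and dp the axial pressure drop over
#' the scaffold height. dp is the least-squares slope of the plane-averaged
#' pressure profile over the interior layers (the central 80% of the
#' height), times H: exact for the linear mean-pressure profile of
#' developed/Darcy flow, and insensitive both to entrance losses of the
#' plug inlet and to the half-voxel offset of open pressure boundaries.
#'
#' @param field converged `flow_field` with positive axial through-flow.
#' @param props a [fluid_props()] (viscosity used in Darcy's law).
#' @return a `permeability_result`: `kappa` (m^2) plus the `Q` (m^3/s),
#'   `A` (m^2), `H` (m), `mu` (Pa.s) and `dp` (Pa) that produced it; Darcy's
#'   law holds exactly among the stored fields.
#' @export
compute_permeability <- function(field, props = field$props) {
  if (!inherits(field, "flow_field")) stop_pf("`field` must be a flow_field")
  d <- dim(field$domain$mask)
  if (d[3] < 2L) stop_pf("domain must span at least 2 voxels in z")
  h <- field$domain$voxel_size * UM
  q <- (field$Q_in + field$Q_out) / 2
  area <- prod(d[1:2]) * h^2
  height <- d[3] * h
  prof <- plane_pressure_profile(field)
  dp <- -axial_pressure_slope(prof) * d[3]
  if (!is.finite(dp) || dp <= 0)
    stop_pf("non-physical axial pressure drop (dp = %g Pa)", dp)
  kappa <- q * props$mu * height / (area * dp)
  structure(list(kappa = kappa, Q = q, A = area, H = height,
                 mu = props$mu, dp = dp, rve_index = NA_integer_),
            class = "permeability_result")
}

# mean pressure over fluid cells of every z layer (Pa)
plane_pressure_profile <- function(field) {
  p <- field$p
  apply(p, 3, function(sl) mean(sl[!is.na(sl)]))
}

# least-squares dp/dk (Pa per layer) over the interior of the profile,
# excluding the entrance/exit 10% of layers where plug-inlet and outflow
# truncation perturb the mean pressure
axial_pressure_slope <- function(prof) {
  n <- length(prof)
  k <- seq_len(n)
  use <- k >= max(2, floor(0.1 * n)) & k <= min(n - 1, ceiling(0.9 * n))
  if (sum(use) < 3) use <- rep(TRUE, n)
  stats::coef(stats::lm(prof[use] ~ k[use]))[[2]]
}

#' @export
print.permeability_result <- function(x, ...) {
  cat(sprintf("<permeability_result> kappa = %.4e m^2\n", x$kappa))
  cat(sprintf("  Q = %.3e m^3/s, A = %.3e m^2, H = %.3e m, dp = %.4g Pa\n",
              x$Q, x$A, x$H, x$dp))
  invisible(x)
}

#' Aggregate RVE permeabilities
#'
#' Arithmetic mean of per-RVE permeability values, the plain average used to
#' homogenize a scaffold from several RVE sections. (Harmonic or geometric
#' means would be the natural choices for strictly serial or log-normally
#' distributed resistances; for parallel full-height RVE columns the
#' arithmetic mean is the consistent one.)
#'
#' @param results nonempty list of `permeability_result` objects.
#' @return mean permeability in m^2.
#' @export
average_permeability <- function(results) {
  if (length(results) == 0L) stop_pf("empty permeability list")
  if (inherits(results, "permeability_result")) results <- list(results)
  ks <- vapply(results, function(r) {
    if (!inherits(r, "permeability_result"))
      stop_pf("all elements must be permeability_result objects")
    r$kappa
  }, 1)
  mean(ks)
}
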