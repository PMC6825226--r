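#' Generate a synthetic irregular scaffold
#'
#' Emulates the irregular, non-repetitive, interconnected pore network of
#' salt-leached protein scaffolds (e.g., silk fibroin) by thresholding a
#' correlated Gaussian random field. White noise is smoothed with a periodic
#' Gaussian kernel whose width is calibrated so that the mean intercept
#' length of the fluid phase matches `mean_pore_diameter`, then thresholded
#' at the quantile matching the target porosity. Fluid voxels that do not
#' belong to a z-spanning (inlet-to-outlet) 6-connected component are
#' converted to solid and the threshold is re-adjusted until the spanning
#' fluid fraction is within +/- 0.02 of the target.
#'
#' @param porosity target fluid volume fraction in `[0.3, 0.95]`.
#' @param mean_pore_diameter target mean pore size in um
#'   (>= 3 * `voxel_size`).
#' @param shape integer voxel dimensions `(nx, ny, nz)`; z is the flow axis.
#' @param voxel_size voxel edge length in um.
#' @param seed integer seed; the generator is a pure function of its
#'   arguments (the global RNG state is saved and restored).
#' @return binary `voxel_image` whose fluid fraction is within +/- 0.02 of
#'   `porosity` and whose fluid phase percolates along z.
#' @examples
#' sc <- generate_scaffold(0.85, 200, c(32, 32, 32), 10, seed = 1)
#' porosity(sc)
#' @export
generate_scaffold <- function(porosity, mean_pore_diameter, shape,
                              voxel_size, seed) {
  check_number(porosity, "porosity", lo = 0.3, hi = 0.95)
  check_number(voxel_size, "voxel_size", lo = .Machine$double.eps)
  check_number(mean_pore_diameter, "mean_pore_diameter",
               lo = 3 * voxel_size)
  if (length(shape) != 3L || any(shape < 4))
    stop_pf("`shape` must be three voxel counts, each >= 4")
  shape <- as.integer(shape)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(as.integer(seed))

  # Kernel width from the level-crossing rate of a stationary Gaussian field:
  # for correlation rho(r) = exp(-r^2 / (4 s^2)) the mean intercept length of
  # the fluid phase {f > t} is 2 * pi * sqrt(2) * phi * s * exp(t^2 / 2).
  d_vox <- mean_pore_diameter / voxel_size
  t0 <- stats::qnorm(1 - porosity)
  s <- d_vox * exp(-t0^2 / 2) / (2 * sqrt(2) * pi * porosity)
  s <- max(s, 0.35)
  support <- max(1L, as.integer(ceiling(3 * s)))

  noise <- voxel_image(array(stats::rnorm(prod(shape)), dim = shape),
                       voxel_size, type = "grayscale")
  field <- gaussian_filter_3d(noise, sigma = s, support = support,
                              padding = "periodic")$data

  q <- porosity
  tol <- 0.02
  for (it in 1:25) {
    thr <- stats::quantile(field, probs = max(min(1 - q, 1), 0), names = FALSE)
    fluid <- field > thr
    span <- spanning_fluid(fluid)
    frac <- mean(span)
    if (abs(frac - porosity) <= tol * 0.75 && any(span))
      return(voxel_image(array(as.numeric(span), dim = shape),
                         voxel_size, type = "label"))
    if (!any(span) && q >= 0.999) break
    q <- min(q + (porosity - frac), 0.999)
  }
  stop_pf(paste0("could not generate a percolating scaffold with porosity ",
                 "%.2f and pore size %.0f um at this resolution"),
          porosity, mean_pore_diameter)
}

# Fluid voxels 6-connected to both the -z (inlet) and +z (outlet) faces
spanning_fluid <- function(fluid) {
  d <- dim(fluid)
  seed_lo <- array(FALSE, d); seed_lo[, , 1] <- TRUE
  seed_hi <- array(FALSE, d); seed_hi[, , d[3]] <- TRUE
  flood_fill6(fluid, seed_lo) & flood_fill6(fluid, seed_hi)
}
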