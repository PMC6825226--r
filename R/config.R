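#' Default run configuration
#'
#' The configuration is a nested list with explicit unit suffixes in the key
#' names; everything is converted to SI internally. Unknown keys are
#' rejected by [validate_run_config()]. Defaults describe the scaled
#' validation workflow on synthetic scaffolds; the shipped YAML examples
#' (`system.file("extdata", ...)`) cover full experimental-scale setups.
#'
#' @return nested list of configuration defaults:
#' \describe{
#'   \item{fluid}{`mu_mpa_s` (dynamic viscosity, mPa.s; culture medium =
#'     1.0), `rho_kg_m3` (density).}
#'   \item{geometry}{synthetic-generator parameters: `porosity`,
#'     `mean_pore_diameter_um`, `shape` (voxels), `voxel_size_um`, `seed`;
#'     or `file` to read an image stack.}
#'   \item{rve}{`grid` (nx, ny) and lateral size `xy_um` (`NULL`: half the
#'     footprint).}
#'   \item{micro}{`inlet_velocity_um_s` for the permeability solves,
#'     solver `tol`.}
#'   \item{macro}{`channel_diameter_um`, `porous_diameter_um`,
#'     `entrance_um`, `exit_um` (`NULL`: one scaffold height each),
#'     `inlet_velocity_um_s` or `flow_rate_ml_min`, `outlet_pressure_pa`,
#'     `resolution` (cells over porous height), `channel_shape`, `tol`.}
#'   \item{wss}{histogram `bin_width_mpa`, `max_mpa`, `weighting`, and
#'     stimulation `bands` (list of `c(lo, hi)` mPa).}
#'   \item{subregions}{`n_regions` boundary annuli of `width_um` (`NULL`:
#'     footprint side / (2 n), tiling the half-footprint).}
#'   \item{direct}{`memory_budget_gb` guard for [run_direct()].}
#'   \item{output_dir}{artifact directory or `NULL`.}
#' }
#' @export
default_run_config <- function() {
  list(
    fluid = list(mu_mpa_s = 1.0, rho_kg_m3 = 1000),
    geometry = list(source = "generator", porosity = 0.8,
                    mean_pore_diameter_um = 100, shape = c(64, 64, 64),
                    voxel_size_um = 10, seed = 1, file = NULL),
    rve = list(grid = c(1, 1), xy_um = NULL),
    micro = list(inlet_velocity_um_s = 500, tol = 1e-4),
    macro = list(channel_diameter_um = NULL, porous_diameter_um = NULL,
                 entrance_um = NULL, exit_um = NULL,
                 inlet_velocity_um_s = NULL, flow_rate_ml_min = NULL,
                 outlet_pressure_pa = 0, resolution = 20,
                 channel_shape = "box", tol = NULL),
    wss = list(bin_width_mpa = 5, max_mpa = 100, weighting = "area",
               bands = list(c(10, 30))),
    subregions = list(n_regions = 5, width_um = NULL),
    direct = list(memory_budget_gb = 4),
    output_dir = NULL
  )
}

# deep-merge user config over defaults, validating keys
merge_config <- function(config) {
  if (inherits(config, "run_config")) return(config)
  cfg <- modify_list_strict(default_run_config(), config, path = "config")
  validate_run_config(cfg)
  class(cfg) <- c("run_config", class(cfg))
  cfg
}

modify_list_strict <- function(base, override, path) {
  if (is.null(override)) return(base)
  if (!is.list(override)) stop_pf("`%s` must be a list", path)
  for (nm in names(override)) {
    if (!nm %in% names(base))
      stop_pf("unknown configuration key '%s.%s'", path, nm)
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      base[[nm]] <- modify_list_strict(base[[nm]], override[[nm]],
                                       paste(path, nm, sep = "."))
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Validate a run configuration
#'
#' Checks types, positivity and unit-bearing fields; called automatically by
#' the pipeline entry points.
#'
#' @param cfg configuration list (after merging with defaults).
#' @return the configuration, invisibly; errors list the offending keys.
#' @export
validate_run_config <- function(cfg) {
  bad <- character()
  chk <- function(ok, key) if (!isTRUE(ok)) bad <<- c(bad, key)
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  chk(num1(cfg$fluid$mu_mpa_s) && cfg$fluid$mu_mpa_s > 0, "fluid.mu_mpa_s")
  chk(num1(cfg$fluid$rho_kg_m3) && cfg$fluid$rho_kg_m3 > 0,
      "fluid.rho_kg_m3")
  geo <- cfg$geometry
  if (is.null(geo$file)) {
    chk(num1(geo$porosity) && geo$porosity >= 0.3 && geo$porosity <= 0.95,
        "geometry.porosity")
    chk(num1(geo$mean_pore_diameter_um) && geo$mean_pore_diameter_um > 0,
        "geometry.mean_pore_diameter_um")
    chk(is.numeric(geo$shape) && length(geo$shape) == 3, "geometry.shape")
    chk(num1(geo$voxel_size_um) && geo$voxel_size_um > 0,
        "geometry.voxel_size_um")
  }
  chk(is.numeric(cfg$rve$grid) && length(cfg$rve$grid) == 2 &&
        all(cfg$rve$grid >= 1), "rve.grid")
  chk(num1(cfg$micro$inlet_velocity_um_s), "micro.inlet_velocity_um_s")
  chk(num1(cfg$micro$tol) && cfg$micro$tol > 0 && cfg$micro$tol < 1,
      "micro.tol")
  chk(num1(cfg$wss$bin_width_mpa) && cfg$wss$bin_width_mpa > 0,
      "wss.bin_width_mpa")
  chk(num1(cfg$wss$max_mpa) && cfg$wss$max_mpa > 0, "wss.max_mpa")
  chk(cfg$wss$weighting %in% c("area", "count"), "wss.weighting")
  chk(num1(cfg$subregions$n_regions) && cfg$subregions$n_regions >= 1,
      "subregions.n_regions")
  if (!is.null(cfg$macro$flow_rate_ml_min))
    chk(num1(cfg$macro$flow_rate_ml_min) && cfg$macro$flow_rate_ml_min > 0,
        "macro.flow_rate_ml_min")
  chk(cfg$macro$channel_shape %in% c("box", "cylinder"),
      "macro.channel_shape")
  if (length(bad))
    stop_pf("invalid configuration key(s): %s", paste(bad, collapse = ", "))
  invisible(cfg)
}

#' Read a YAML run configuration
#'
#' @param path YAML file; keys as in [default_run_config()]. `wss.bands`
#'   may be a list of two-element `[lo, hi]` arrays.
#' @return validated `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_pf("config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$wss$bands))
    raw$wss$bands <- lapply(raw$wss$bands, as.numeric)
  if (!is.null(raw$geometry$shape))
    raw$geometry$shape <- as.numeric(raw$geometry$shape)
  if (!is.null(raw$rve$grid)) raw$rve$grid <- as.numeric(raw$rve$grid)
  merge_config(raw)
}
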