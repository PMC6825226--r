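#' Run the full multiscale WSS pipeline
#'
#' Orchestrates the micro -> macro -> micro loop on a scaffold image:
#' \enumerate{
#'   \item lay out RVEs ([partition_rves()]) and build their fluid domains;
#'   \item solve pore-scale creeping flow per RVE with a velocity inlet and
#'     symmetric lateral boundaries, and homogenize to a Darcy permeability
#'     ([compute_permeability()]);
#'   \item average the permeabilities and solve the macro channel model
#'     ([solve_macro()]);
#'   \item extract each RVE's (p_top, p_bottom) pressure pair
#'     ([extract_pressure_bcs()]) and re-solve each RVE pressure-driven;
#'   \item recover the wall shear stress field per RVE ([compute_wss()]).
#' }
#' The run is a pure function of (scaffold, config): no randomness enters
#' after scaffold generation.
#'
#' @param scaffold binary label `voxel_image`.
#' @param config a configuration list, see [default_run_config()]; missing
#'   entries take defaults.
#' @return a `multiscale_run` with per-RVE permeabilities, the homogenized
#'   `kappa_bar`, the `macro` solution, per-RVE pressure pairs and
#'   `wss` fields, and the config snapshot.
#' @export
run_multiscale <- function(scaffold, config = list()) {
  cfg <- merge_config(config)
  if (!is_label_image(scaffold)) stop_pf("`scaffold` must be a label image")
  props <- fluid_props(mu = cfg$fluid$mu_mpa_s * 1e-3,
                       rho = cfg$fluid$rho_kg_m3)
  h <- scaffold$voxel_size
  d <- dim(scaffold$data)
  rve_xy <- cfg$rve$xy_um %||% (min(d[1:2]) %/% 2 * h)
  specs <- partition_rves(scaffold, cfg$rve$grid, rve_xy)
  u_in <- cfg$micro$inlet_velocity_um_s * 1e-6  # um/s -> m/s
  tol <- cfg$micro$tol

  stage <- function(what, i, expr) {
    tryCatch(expr, error = function(e)
      stop_pf("stage '%s' failed for RVE %d: %s", what, i,
              conditionMessage(e)))
  }

  domains <- list(); perms <- list()
  for (i in seq_along(specs)) {
    img <- stage("extract_rve", i, extract_rve(scaffold, specs[[i]]))
    domains[[i]] <- stage("build_fluid_domain", i, build_fluid_domain(img))
    # configured inlet velocities are superficial (empty-channel) values;
    # scale by the inlet-plane fluid fraction so the RVE carries u_in * A
    phi_in <- mean(domains[[i]]$mask[, , 1])
    f <- stage("stokes_permeability", i, solve_stokes(
      domains[[i]], micro_bc("velocity", u_in / phi_in,
                             lateral_kind = "symmetric"),
      props, tol = tol))
    pr <- stage("compute_permeability", i, compute_permeability(f, props))
    pr$rve_index <- i
    perms[[i]] <- pr
  }
  kappa_bar <- average_permeability(perms)

  mc <- cfg$macro
  model <- macro_model(
    channel_diameter = mc$channel_diameter_um %||% (min(d[1:2]) * h),
    porous_diameter = mc$porous_diameter_um %||%
      mc$channel_diameter_um %||% (min(d[1:2]) * h),
    porous_height = d[3] * h,
    entrance_length = mc$entrance_um %||% (d[3] * h),
    exit_length = mc$exit_um %||% (d[3] * h),
    kappa = kappa_bar, props = props,
    inlet_kind = if (!is.null(mc$flow_rate_ml_min)) "flow_rate" else "velocity",
    inlet_value = if (!is.null(mc$flow_rate_ml_min))
      mc$flow_rate_ml_min * 1e-6 / 60 else
      (mc$inlet_velocity_um_s %||% cfg$micro$inlet_velocity_um_s) * 1e-6,
    outlet_pressure = mc$outlet_pressure_pa %||% 0,
    resolution = mc$resolution %||% 20,
    channel_shape = mc$channel_shape %||% "box"
  )
  macro <- tryCatch(solve_macro(model, tol = mc$tol %||% tol),
                    error = function(e)
                      stop_pf("stage 'solve_macro' failed: %s",
                              conditionMessage(e)))

  extent <- d[1:2] * h
  pressure_pairs <- list(); wss <- list()
  for (i in seq_along(specs)) {
    pb <- stage("extract_pressure_bcs", i,
                extract_pressure_bcs(macro, specs[[i]],
                                     scaffold_extent = extent))
    pressure_pairs[[i]] <- pb
    fw <- stage("stokes_wss", i, solve_stokes(
      domains[[i]],
      micro_bc("pressure", pb[["p_top"]], outlet_pressure = pb[["p_bottom"]],
               lateral_kind = "symmetric"),
      props, tol = tol))
    wss[[i]] <- stage("compute_wss", i, compute_wss(fw))
    wss[[i]]$micro_superficial_velocity <-
      (fw$Q_in + fw$Q_out) / 2 / (prod(dim(domains[[i]]$mask)[1:2]) *
                                    (h * UM)^2)
  }

  run <- structure(
    list(scaffold_dim = d, voxel_size = h, rves = specs,
         permeability = perms, kappa_bar = kappa_bar, macro = macro,
         pressure_pairs = pressure_pairs, wss = wss, config = cfg),
    class = "multiscale_run"
  )
  if (!is.null(cfg$output_dir)) persist_run(run, cfg$output_dir)
  run
}

#' @export
print.multiscale_run <- function(x, ...) {
  cat(sprintf("<multiscale_run> %d RVE(s), kappa_bar = %.4e m^2\n",
              length(x$rves), x$kappa_bar))
  cat(sprintf("  macro dp = %.4g Pa (p_top %.4g, p_bottom %.4g)\n",
              x$macro$dp, x$macro$p_top, x$macro$p_bottom))
  for (i in seq_along(x$wss))
    cat(sprintf("  RVE %d: kappa %.3e m^2, mean WSS %.3g mPa\n", i,
                x$permeability[[i]]$kappa,
                summary(x$wss[[i]])[["mean_mPa"]]))
  invisible(x)
}

#' Direct (single-scale) pore-scale solve of a whole scaffold
#'
#' Solves the full scaffold in one pore-scale CFD model with a velocity
#' inlet, no-slip outer side walls and a zero-pressure outlet - the
#' reference against which the multiscale approach is validated. A memory
#' estimate guards against domains too large for the configured budget, in
#' which case the multiscale route is advised.
#'
#' @param scaffold binary label `voxel_image`.
#' @param config configuration list (see [default_run_config()]); the ROI
#'   for comparisons is the central RVE footprint.
#' @return list with the `flow_field`, the full `wss_field`, the ROI-
#'   restricted `roi_wss`, and the ROI `rve_spec`.
#' @export
run_direct <- function(scaffold, config = list()) {
  cfg <- merge_config(config)
  if (!is_label_image(scaffold)) stop_pf("`scaffold` must be a label image")
  h <- scaffold$voxel_size
  d <- dim(scaffold$data)
  n_fluid <- sum(scaffold$data)
  est_gb <- 1500 * n_fluid / 1e9
  budget <- cfg$direct$memory_budget_gb %||% 4
  if (est_gb > budget)
    stop_pf(paste0("direct solve estimated at %.1f GB exceeds the %.1f GB ",
                   "budget; use run_multiscale() on RVEs instead"),
            est_gb, budget)
  props <- fluid_props(mu = cfg$fluid$mu_mpa_s * 1e-3,
                       rho = cfg$fluid$rho_kg_m3)
  u_in <- cfg$micro$inlet_velocity_um_s * 1e-6
  dom <- build_fluid_domain(scaffold)
  # superficial inlet velocity: the whole scaffold carries u_in * A, the
  # same perfusion rate the macro model of the multiscale route prescribes
  phi_in <- mean(dom$mask[, , 1])
  f <- solve_stokes(dom, micro_bc("velocity", u_in / phi_in,
                                  lateral_kind = "no_slip"),
                    props, tol = cfg$micro$tol)
  wss <- compute_wss(f)
  roi <- partition_rves(scaffold, c(1, 1),
                        cfg$rve$xy_um %||% (min(d[1:2]) %/% 2 * h))[[1]]
  list(field = f, wss = wss, roi_wss = restrict_wss(wss, roi), roi = roi)
}

# keep only wall elements whose lateral position lies in the footprint
restrict_wss <- function(wss, footprint) {
  fp <- footprint_2d(footprint)
  el <- wss$elements
  keep <- el$x >= fp$lo[1] & el$x < fp$hi[1] &
    el$y >= fp$lo[2] & el$y < fp$hi[2]
  out <- wss
  out$elements <- el[keep, , drop = FALSE]
  out$total_area <- sum(out$elements$area)
  out
}

#' Compare multiscale and direct WSS fields
#'
#' Builds area- (or count-) weighted WSS histograms of both fields on
#' identical bins, computes the Pearson correlation between the paired bin
#' weights, and compares area-weighted average WSS in concentric boundary
#' subregions, with the direct solution as the reference denominator of the
#' percent errors.
#'
#' @param multiscale `wss_field` from the multiscale RVE solve.
#' @param direct `wss_field` from the direct solve, restricted to the
#'   matching ROI.
#' @param footprint the shared RVE/ROI footprint ([rve_spec()] or
#'   `list(lo, hi)`).
#' @param config configuration list for binning/subregions (see
#'   [default_run_config()]).
#' @return a `validation_report`: `histograms`, `pearson_r`,
#'   `region_averages` (matrix, rows = multiscale/direct),
#'   `percent_errors`, and the band fractions of both fields.
#' @export
compare_wss <- function(multiscale, direct, footprint, config = list()) {
  cfg <- merge_config(config)
  if (nrow(multiscale$elements) == 0L || nrow(direct$elements) == 0L)
    stop_pf("cannot compare empty WSS fields")
  bw <- cfg$wss$bin_width_mpa
  mx <- cfg$wss$max_mpa
  wt <- cfg$wss$weighting
  hm <- wss_histogram(multiscale, bw, mx, wt)
  hd <- wss_histogram(direct, bw, mx, wt)
  r <- safe_pearson(hm$weights, hd$weights)

  fp <- footprint_2d(footprint)
  n_reg <- cfg$subregions$n_regions
  width <- cfg$subregions$width_um %||%
    (min(fp$hi - fp$lo) / (2 * n_reg))
  reg_m <- subregion_average_wss(multiscale, fp, n_reg, width)
  reg_d <- subregion_average_wss(direct, fp, n_reg, width)
  perr <- abs(reg_m - reg_d) / reg_d * 100

  bands <- cfg$wss$bands
  band_tab <- NULL
  if (length(bands)) {
    band_tab <- do.call(rbind, lapply(bands, function(b) data.frame(
      lo_mpa = b[1], hi_mpa = b[2],
      multiscale = area_fraction_in_band(multiscale, b[1], b[2]),
      direct = area_fraction_in_band(direct, b[1], b[2])
    )))
  }
  structure(
    list(histograms = list(multiscale = hm, direct = hd),
         pearson_r = r,
         region_averages = rbind(multiscale = reg_m, direct = reg_d),
         percent_errors = perr,
         region_width_um = width,
         band_fractions = band_tab),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> Pearson r = %.3f (histogram weights)\n",
              x$pearson_r))
  cat("  region (outermost -> innermost) average WSS [mPa] and % error:\n")
  for (k in seq_len(ncol(x$region_averages)))
    cat(sprintf("   region %d: multiscale %.3g, direct %.3g, error %.2f%%\n",
                k, x$region_averages[1, k], x$region_averages[2, k],
                x$percent_errors[k]))
  invisible(x)
}

safe_pearson <- function(a, b) {
  if (isTRUE(all.equal(a, b))) return(1)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' One-shot validation study on a synthetic scaffold
#'
#' Generates a scaffold, runs the multiscale pipeline with a single central
#' RVE, runs the direct reference solve, and compares the two WSS fields.
#'
#' @param seed generator seed.
#' @param size scaffold edge length in voxels (cube).
#' @param config configuration overrides (see [default_run_config()]).
#' @return list with the `multiscale_run`, the `run_direct()` output, and
#'   the `validation_report`.
#' @export
run_validation <- function(seed = 1, size = 64, config = list()) {
  cfg <- merge_config(config)
  geo <- cfg$geometry
  scaffold <- generate_scaffold(
    porosity = geo$porosity, mean_pore_diameter = geo$mean_pore_diameter_um,
    shape = rep(size, 3), voxel_size = geo$voxel_size_um, seed = seed
  )
  ms <- run_multiscale(scaffold, cfg)
  dr <- run_direct(scaffold, cfg)
  rep <- compare_wss(ms$wss[[1]], dr$roi_wss, ms$rves[[1]], cfg)
  list(multiscale = ms, direct = dr, report = rep, scaffold = scaffold,
       seed = seed)
}

# write per-RVE permeability and WSS summary tables + a manifest
persist_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  perm <- data.frame(
    rve = vapply(run$permeability, function(p) p$rve_index, 1L),
    kappa_m2 = vapply(run$permeability, function(p) p$kappa, 1),
    Q_m3_s = vapply(run$permeability, function(p) p$Q, 1),
    dp_Pa = vapply(run$permeability, function(p) p$dp, 1)
  )
  utils::write.csv(perm, file.path(dir, "permeability.csv"),
                   row.names = FALSE)
  wss_sum <- do.call(rbind, lapply(seq_along(run$wss), function(i) {
    s <- summary(run$wss[[i]])
    data.frame(rve = i, n_elements = s[["n"]], area_um2 = s[["area_um2"]],
               mean_wss_mPa = s[["mean_mPa"]], max_wss_mPa = s[["max_mPa"]],
               p_top_Pa = run$pressure_pairs[[i]][["p_top"]],
               p_bottom_Pa = run$pressure_pairs[[i]][["p_bottom"]])
  }))
  utils::write.csv(wss_sum, file.path(dir, "wss_summary.csv"),
                   row.names = FALSE)
  manifest <- list(
    kappa_bar_m2 = run$kappa_bar, macro_dp_Pa = run$macro$dp,
    p_top_Pa = run$macro$p_top, p_bottom_Pa = run$macro$p_bottom,
    n_rves = length(run$rves), scaffold_dim = run$scaffold_dim,
    voxel_size_um = run$voxel_size, config = run$config
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
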