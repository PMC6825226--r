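#' Macro-scale bioreactor/channel model with a homogenized porous scaffold
#'
#' Describes a cylindrical channel (the bioreactor lumen) containing a
#' centred cylindrical porous region (the homogenized scaffold) with free
#' fluid entrance/exit segments above and below. The macro flow is solved as
#' a single-domain Darcy-Brinkman (penalized) momentum equation,
#' mu * lap(v) - (mu / kappa_loc) v - grad p = 0, with kappa_loc = `kappa`
#' inside the porous region and the drag term off in the free fluid; mass-
#' flux continuity across the porous/free interface then holds by
#' construction. Channel side walls are no-slip.
#'
#' @param channel_diameter channel (lumen) diameter in um (side length for
#'   `channel_shape = "box"`).
#' @param porous_diameter scaffold diameter (or side) in um (<= channel
#'   diameter; equal means a press-fit scaffold).
#' @param channel_shape `"cylinder"` (bioreactor lumen) or `"box"` (square
#'   duct; the natural macro counterpart of box-shaped synthetic scaffolds
#'   and of direct pore-scale models with no-slip side walls).
#' @param porous_height scaffold height in um.
#' @param entrance_length,exit_length free-fluid segment lengths in um
#'   (default: one scaffold height each).
#' @param kappa homogenized permeability in m^2.
#' @param props a [fluid_props()].
#' @param inlet_kind `"velocity"` (superficial velocity, m/s) or
#'   `"flow_rate"` (m^3/s).
#' @param inlet_value inlet magnitude in the units of `inlet_kind`.
#' @param outlet_pressure outlet reference pressure (Pa).
#' @param resolution grid cells across the porous height (>= 4; default 20).
#' @return a `macro_model` object.
#' @export
macro_model <- function(channel_diameter, porous_diameter = channel_diameter,
                        porous_height,
                        entrance_length = porous_height,
                        exit_length = porous_height,
                        kappa, props = fluid_props(),
                        inlet_kind = c("velocity", "flow_rate"),
                        inlet_value, outlet_pressure = 0, resolution = 20,
                        channel_shape = c("cylinder", "box")) {
  inlet_kind <- match.arg(inlet_kind)
  channel_shape <- match.arg(channel_shape)
  check_number(channel_diameter, "channel_diameter", lo = 1e-9)
  check_number(porous_diameter, "porous_diameter", lo = 1e-9,
               hi = channel_diameter)
  check_number(porous_height, "porous_height", lo = 1e-9)
  check_number(entrance_length, "entrance_length", lo = 0)
  check_number(exit_length, "exit_length", lo = 0)
  check_number(kappa, "kappa", lo = 1e-30)
  check_number(inlet_value, "inlet_value")
  check_number(resolution, "resolution", lo = 4)
  structure(list(channel_diameter = channel_diameter,
                 porous_diameter = porous_diameter,
                 porous_height = porous_height,
                 entrance_length = entrance_length,
                 exit_length = exit_length,
                 kappa = kappa, props = props, inlet_kind = inlet_kind,
                 inlet_value = inlet_value,
                 outlet_pressure = outlet_pressure,
                 resolution = as.integer(resolution),
                 channel_shape = channel_shape),
            class = "macro_model")
}

#' @export
print.macro_model <- function(x, ...) {
  cat(sprintf(paste0("<macro_model> channel %g um dia; porous %g um dia x ",
                     "%g um, kappa %.3e m^2\n"),
              x$channel_diameter, x$porous_diameter, x$porous_height,
              x$kappa))
  cat(sprintf("  inlet %s = %g, outlet %g Pa, %d cells over porous height\n",
              x$inlet_kind, x$inlet_value, x$outlet_pressure, x$resolution))
  invisible(x)
}

# voxelize the macro geometry; returns mask, invk, cell size (um), and the
# porous z layer range
voxelize_macro <- function(model) {
  h_um <- model$porous_height / model$resolution
  nxy <- max(3L, as.integer(round(model$channel_diameter / h_um)))
  nz_ent <- as.integer(round(model$entrance_length / h_um))
  nz_por <- model$resolution
  nz_exit <- as.integer(round(model$exit_length / h_um))
  nz <- nz_ent + nz_por + nz_exit
  xc <- (seq_len(nxy) - 0.5) - nxy / 2
  if (model$channel_shape == "cylinder") {
    r2 <- outer(xc^2, xc^2, `+`)
    lumen <- r2 <= (model$channel_diameter / h_um / 2)^2
    porous2d <- r2 <= (model$porous_diameter / h_um / 2)^2
  } else {
    inside <- abs(xc) <= model$channel_diameter / h_um / 2
    lumen <- outer(inside, inside, `&`)
    insp <- abs(xc) <= model$porous_diameter / h_um / 2
    porous2d <- outer(insp, insp, `&`)
  }
  mask <- array(FALSE, c(nxy, nxy, nz))
  invk <- array(0, c(nxy, nxy, nz))
  por_range <- nz_ent + seq_len(nz_por)
  for (k in seq_len(nz)) {
    mask[, , k] <- lumen
    if (k %in% por_range) invk[, , k][porous2d] <- 1 / model$kappa
  }
  list(mask = mask, invk = invk, h_um = h_um, por_range = por_range,
       porous2d = porous2d)
}

#' Solve the macro free-fluid/porous-media model
#'
#' Voxelizes the channel, assembles the Brinkman-penalized Stokes system on
#' the same staggered grid as the pore-scale solver, and solves it. Reports
#' the plane-averaged pressures at the porous region's upstream ("top") and
#' downstream ("bottom") faces, obtained by linear extrapolation of the two
#' adjacent interior porous layers (exact for the linear Darcy profile).
#'
#' @param model a [macro_model()].
#' @param tol relative residual tolerance (default 1e-4).
#' @param maxit optional iteration cap.
#' @return a `macro_solution`: the underlying `flow_field`, the voxelization,
#'   `p_top`, `p_bottom` and `dp = p_top - p_bottom` (Pa), and the superficial
#'   (Darcy) velocity through the porous region `darcy_velocity` (m/s).
#' @export
solve_macro <- function(model, tol = 1e-4, maxit = NULL) {
  if (!inherits(model, "macro_model")) stop_pf("`model` must be a macro_model")
  vox <- voxelize_macro(model)
  h <- vox$h_um * UM
  n_in <- sum(vox$mask[, , 1])
  a_channel <- if (model$channel_shape == "cylinder")
    pi * (model$channel_diameter * UM)^2 / 4 else
    (model$channel_diameter * UM)^2
  u_in <- switch(model$inlet_kind,
    velocity = model$inlet_value * a_channel / (n_in * h^2),
    flow_rate = model$inlet_value / (n_in * h^2)
  )
  bc <- micro_bc("velocity", u_in, outlet_pressure = model$outlet_pressure,
                 lateral_kind = "no_slip")
  sys <- assemble_stokes(vox$mask, h, model$props$mu, bc, invk = vox$invk)
  sol <- solve_saddle(sys, tol = tol, maxit = maxit)
  dom <- structure(list(mask = vox$mask, voxel_size = vox$h_um,
                        origin = c(0, 0, 0), trapped_fraction = 0),
                   class = "fluid_domain")
  field <- build_flow_field(dom, bc, model$props, sys, sol, tol)
  field <- audit_flow_field(field, tol)

  pres <- porous_face_pressures(field, vox)
  q_por <- flow_rate(field, as.integer(vox$por_range[1]))
  a_por <- sum(vox$porous2d) * h^2
  structure(list(field = field, model = model, vox = vox,
                 p_top = pres$top, p_bottom = pres$bottom,
                 dp = pres$top - pres$bottom,
                 darcy_velocity = q_por / a_por),
            class = "macro_solution")
}

#' @export
print.macro_solution <- function(x, ...) {
  cat(sprintf("<macro_solution> dp over scaffold = %.4g Pa (p_top %.4g, p_bottom %.4g)\n",
              x$dp, x$p_top, x$p_bottom))
  cat(sprintf("  Darcy velocity %.4g um/s, Q %.3e m^3/s\n",
              x$darcy_velocity / UM, x$field$Q_in))
  invisible(x)
}

# plane-averaged pressures extrapolated to the porous faces, optionally
# restricted to a lateral footprint mask
porous_face_pressures <- function(field, vox, footprint = NULL) {
  pr <- vox$por_range
  if (length(pr) < 2L) stop_pf("porous region must span >= 2 macro layers")
  sel2d <- if (is.null(footprint)) vox$porous2d else footprint & vox$porous2d
  if (!any(sel2d)) stop_pf("RVE footprint lies outside the porous region")
  layer_mean <- function(k) {
    sl <- field$p[, , k]
    mean(sl[sel2d & !is.na(sl)])
  }
  k1 <- pr[1]; k2 <- pr[2]
  kn <- pr[length(pr)]; kn1 <- pr[length(pr) - 1L]
  # top face = upstream (inlet side, -z); bottom = downstream
  top <- layer_mean(k1) + 0.5 * (layer_mean(k1) - layer_mean(k2))
  bottom <- layer_mean(kn) + 0.5 * (layer_mean(kn) - layer_mean(kn1))
  list(top = top, bottom = bottom)
}

#' Extract the pressure pair handed to a micro model
#'
#' Plane-averaged pressures over an RVE's lateral footprint at the porous
#' region's top (upstream) and bottom (downstream) faces. These become the
#' inlet pressure and outlet pressure of the pore-scale WSS solve, which is
#' valid because RVEs span the full scaffold height.
#'
#' @param sol a `macro_solution`.
#' @param rve an [rve_spec()] in the scaffold's coordinate frame, or `NULL`
#'   for the full porous cross-section.
#' @param scaffold_extent physical (x, y) extent of the scaffold image in um
#'   (needed to centre the scaffold frame on the channel axis); defaults to
#'   the porous diameter.
#' @return named numeric `c(p_top, p_bottom)` in Pa.
#' @export
extract_pressure_bcs <- function(sol, rve = NULL, scaffold_extent = NULL) {
  if (!inherits(sol, "macro_solution")) stop_pf("`sol` must be a macro_solution")
  footprint <- NULL
  if (!is.null(rve)) {
    fp <- footprint_2d(rve)
    ext <- scaffold_extent %||% rep(sol$model$porous_diameter, 2)
    h_um <- sol$vox$h_um
    nxy <- dim(sol$vox$mask)[1]
    # scaffold frame -> macro frame: both centred on the channel axis
    centre_off <- (nxy * h_um) / 2 - ext / 2
    xc <- (seq_len(nxy) - 0.5) * h_um - centre_off[1]
    yc <- (seq_len(nxy) - 0.5) * h_um - centre_off[2]
    footprint <- outer(xc >= fp$lo[1] & xc < fp$hi[1],
                       yc >= fp$lo[2] & yc < fp$hi[2], `&`)
  }
  pres <- porous_face_pressures(sol$field, sol$vox, footprint)
  c(p_top = pres$top, p_bottom = pres$bottom)
}
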