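test_that("uniform Brinkman column reproduces the Darcy pressure drop", {
  # symmetric laterals + uniform drag: exact plug flow, p linear
  kappa <- 7.47e-10
  mask <- array(TRUE, c(8, 8, 20))
  h <- 50e-6
  invk <- array(1 / kappa, dim(mask))
  bc <- list(inlet_kind = "velocity", inlet_value = 500e-6,
             outlet_pressure = 0, lateral_kind = "symmetric")
  sys <- poreflow:::assemble_stokes(mask, h, 1e-3, bc, invk = invk)
  sol <- poreflow:::solve_saddle(sys, tol = 1e-10)
  p <- sol$p[sys$cid[4, 4, ]]
  dp <- -(p[20] - p[1]) * 20 / 19
  dp_th <- 1e-3 * 500e-6 * 20 * h / kappa
  expect_equal(dp, dp_th, tolerance = 1e-6)
})

test_that("the macro channel model approaches Darcy from above", {
  mm <- macro_model(channel_diameter = 1500, porous_height = 1000,
                    kappa = 7.47e-10, inlet_kind = "velocity",
                    inlet_value = 500e-6, resolution = 16)
  sol <- solve_macro(mm, tol = 1e-6)
  dp_darcy <- 1e-3 * 500e-6 * 1e-3 / 7.47e-10  # 0.669 Pa
  expect_gt(sol$dp, dp_darcy * 0.99)           # walls only add resistance
  expect_lt(sol$dp, dp_darcy * 1.10)
  expect_gt(sol$p_top, sol$p_bottom)
  # mass conserved across every z plane
  d <- dim(sol$field$domain$mask)
  qs <- vapply(seq_len(d[3] + 1L), function(k) flow_rate(sol$field, k), 1)
  expect_lt(max(abs(qs - qs[1])) / abs(qs[1]), 10 * 1e-6)
})

test_that("vanishing Darcy resistance removes the porous pressure drop", {
  lo <- solve_macro(macro_model(channel_diameter = 1000,
                                porous_height = 500, kappa = 1e-10,
                                inlet_kind = "velocity",
                                inlet_value = 500e-6, resolution = 10),
                    tol = 1e-8)
  hi <- solve_macro(macro_model(channel_diameter = 1000,
                                porous_height = 500, kappa = 1e-4,
                                inlet_kind = "velocity",
                                inlet_value = 500e-6, resolution = 10),
                    tol = 1e-8)
  expect_lt(hi$dp, lo$dp / 100)
})

test_that("macro response is linear in the inlet flow", {
  mk <- function(v) solve_macro(
    macro_model(channel_diameter = 800, porous_height = 400, kappa = 5e-10,
                inlet_kind = "velocity", inlet_value = v, resolution = 8),
    tol = 1e-12)
  s1 <- mk(250e-6); s2 <- mk(500e-6)
  expect_equal(s2$dp / s1$dp, 2, tolerance = 1e-8)
})

test_that("strong penalization blocks flow through penalized cells", {
  # penalize half of the cross-section to kappa = 1e-20 m^2: velocity
  # inside the penalized block must be negligible vs the open half
  mask <- array(TRUE, c(10, 10, 16))
  invk <- array(0, dim(mask))
  invk[1:5, , 5:12] <- 1e20
  bc <- list(inlet_kind = "velocity", inlet_value = 500e-6,
             outlet_pressure = 0, lateral_kind = "no_slip")
  sys <- poreflow:::assemble_stokes(mask, 20e-6, 1e-3, bc, invk = invk)
  sol <- poreflow:::solve_saddle(sys, tol = 1e-10)
  wid <- sys$fids[[3]]
  w <- array(0, dim(wid)); w[wid > 0] <- sol$u[wid[wid > 0]]
  expect_lt(max(abs(w[1:4, , 7:10])), 1e-6 * 500e-6)
})

test_that("pressure handoff is laterally uniform away from walls", {
  mm <- macro_model(channel_diameter = 1200, porous_height = 600,
                    kappa = 1e-10, inlet_kind = "velocity",
                    inlet_value = 500e-6, resolution = 16,
                    channel_shape = "box")
  sol <- solve_macro(mm, tol = 1e-8)
  ext <- c(1200, 1200)
  centre <- extract_pressure_bcs(
    sol, rve_spec(1, c(450, 450, 0), c(750, 750, 600)),
    scaffold_extent = ext)
  whole <- extract_pressure_bcs(sol)
  expect_lt(abs(centre[["p_top"]] - whole[["p_top"]]) / whole[["p_top"]],
            0.01)
  # two RVEs at mirror positions see identical pressure pairs
  a <- extract_pressure_bcs(sol, rve_spec(1, c(150, 450, 0),
                                          c(450, 750, 600)),
                            scaffold_extent = ext)
  b <- extract_pressure_bcs(sol, rve_spec(2, c(750, 450, 0),
                                          c(1050, 750, 600)),
                            scaffold_extent = ext)
  expect_equal(a[["p_top"]], b[["p_top"]], tolerance = 1e-6)
  expect_gt(a[["p_top"]], a[["p_bottom"]])
  expect_error(
    extract_pressure_bcs(sol, rve_spec(3, c(-900, 0, 0), c(-600, 300, 600)),
                         scaffold_extent = ext),
    "footprint")
})
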