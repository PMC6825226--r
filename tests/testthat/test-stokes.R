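props <- fluid_props(mu = 1e-3, rho = 1000)

test_that("plane-Poiseuille flow matches the closed form", {
  img <- plates_image(gap = 20, nz = 60)
  dom <- build_fluid_domain(img)
  f <- solve_stokes(dom, micro_bc("velocity", 500e-6), props, tol = 1e-8)
  d <- dim(dom$mask)
  k <- round(0.75 * d[3])          # past the entrance region
  prof <- f$w[, 2, k]
  u_mean <- sum(prof) / (d[1] - 2)
  expect_lt(abs(max(prof) - 1.5 * u_mean) / (1.5 * u_mean), 0.03)
})

test_that("pressure-driven tube flow matches Hagen-Poiseuille", {
  R <- 10; nz <- 48
  img <- cylinder_image(R = R, nz = nz)
  dom <- build_fluid_domain(img)
  h <- img$voxel_size * 1e-6
  dp <- 0.05
  f <- solve_stokes(dom, micro_bc("pressure", dp), props, tol = 1e-8)
  Q <- flow_rate(f, floor(nz / 2))
  # prescribed pressures act half a voxel outside the column
  Q_th <- pi * (R * h)^4 * dp / (8 * props$mu * (nz + 1) * h)
  expect_lt(abs(Q - Q_th) / Q_th, 0.05)
})

test_that("null forcing yields the identically zero field", {
  dom <- build_fluid_domain(small_scaffold(16))
  f <- solve_stokes(dom, micro_bc("velocity", 0), props)
  expect_equal(max(abs(f$w)), 0)
  expect_equal(max(abs(f$u)), 0)
  expect_equal(f$Q_in, 0)
})

test_that("flow_rate is face velocity times area, constant along z", {
  plug <- build_fluid_domain(voxel_image(array(1, c(10, 10, 10)), 10))
  f <- solve_stokes(plug, micro_bc("velocity", 1e-3), props, tol = 1e-8)
  # uniform plug through 100 voxels of (10 um)^2: Q = 1e-3 * 1e-8 m^3/s
  expect_equal(flow_rate(f, 1), 1e-3 * 100 * (10e-6)^2, tolerance = 1e-10)

  tol <- 1e-6
  dom <- build_fluid_domain(small_scaffold(20))
  fs <- solve_stokes(dom, micro_bc("velocity", 500e-6), props, tol = tol)
  qs <- vapply(seq_len(dim(dom$mask)[3] + 1L),
               function(k) flow_rate(fs, k), 1)
  expect_lt(max(abs(qs - qs[1])) / abs(qs[1]), 10 * tol)
  expect_error(flow_rate(fs, 99), "range")
})

test_that("Stokes linearity: fields scale exactly with the inlet", {
  dom <- build_fluid_domain(small_scaffold(16))
  f1 <- solve_stokes(dom, micro_bc("velocity", 200e-6), props, tol = 1e-10)
  f5 <- solve_stokes(dom, micro_bc("velocity", 1000e-6), props, tol = 1e-10)
  rel <- function(a, b) max(abs(a - b)) / max(abs(b))
  expect_lt(rel(5 * f1$w, f5$w), 1e-8)
  expect_lt(rel(5 * f1$u, f5$u), 1e-8)
  p1 <- f1$p[!is.na(f1$p)]; p5 <- f5$p[!is.na(f5$p)]
  expect_lt(rel(5 * p1, p5), 1e-8)
})

test_that("mirror-symmetric geometry gives a mirror-symmetric field", {
  half <- small_scaffold(12, seed = 11)$data
  mirrored <- array(0, c(24, 12, 12))
  mirrored[1:12, , ] <- half
  mirrored[24:13, , ] <- half
  img <- voxel_image(mirrored, 10)
  dom <- build_fluid_domain(img)
  tol <- 1e-8
  f <- solve_stokes(dom, micro_bc("velocity", 500e-6), props, tol = tol)
  asym <- max(abs(f$w - f$w[dim(f$w)[1]:1, , ])) / max(abs(f$w))
  expect_lt(asym, 10 * tol)
})

test_that("solver reports its Reynolds audit and failure modes", {
  dom <- build_fluid_domain(small_scaffold(16))
  expect_warning(solve_stokes(dom, micro_bc("velocity", 0.5), props),
                 "Reynolds")
  expect_error(
    solve_stokes(dom, micro_bc("velocity", 500e-6), props, tol = 1e-10,
                 maxit = 2),
    "converge")
})

test_that("schur and minres solution paths agree", {
  dom <- build_fluid_domain(small_scaffold(14, seed = 3))
  f1 <- solve_stokes(dom, micro_bc("velocity", 500e-6), props, tol = 1e-8,
                     method = "schur")
  f2 <- solve_stokes(dom, micro_bc("velocity", 500e-6), props, tol = 1e-8,
                     method = "minres")
  expect_lt(max(abs(f1$w - f2$w)) / max(abs(f1$w)), 1e-5)
  expect_equal(f1$Q_out, f2$Q_out, tolerance = 1e-6)
})
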