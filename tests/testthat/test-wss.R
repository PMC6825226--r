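props <- fluid_props()

test_that("plate-wall WSS matches 6 mu u_mean / h", {
  gap <- 20
  img <- plates_image(gap = gap, nz = 60)
  dom <- build_fluid_domain(img)
  f <- solve_stokes(dom, micro_bc("velocity", 500e-6), props, tol = 1e-8)
  wss <- compute_wss(f)
  h_gap <- gap * img$voxel_size * 1e-6
  u_mean <- plate_mean_velocity(f)
  tau_th <- 6 * props$mu * u_mean / h_gap
  # use the developed mid-section only
  el <- wss$elements
  zmid <- el$z > 150 & el$z < 450
  tau <- mean(el$wss[zmid])
  expect_lt(abs(tau - tau_th) / tau_th, 0.05)
})

test_that("tube-wall WSS matches 4 mu u_mean / R", {
  # R resolves the staircase boundary layer; pressure drive + central
  # window keep entrance development out of the measurement
  R <- 16; nz <- 72
  img <- cylinder_image(R = R, nz = nz, pad = 3)
  dom <- build_fluid_domain(img)
  f <- solve_stokes(dom, micro_bc("pressure", 0.02), props, tol = 1e-8)
  wss <- compute_wss(f)
  h <- img$voxel_size * 1e-6
  u_mean <- flow_rate(f, nz %/% 2) / (pi * (R * h)^2)
  tau_th <- 4 * props$mu * u_mean / (R * h)
  el <- wss$elements
  zmid <- el$z > 0.4 * nz * 10 & el$z < 0.6 * nz * 10
  tau <- sum(el$wss[zmid] * el$area[zmid]) / sum(el$area[zmid])
  expect_lt(abs(tau - tau_th) / tau_th, 0.05)
})

test_that("zero flow gives zero WSS; wall-free domains warn", {
  dom <- build_fluid_domain(small_scaffold(16))
  f <- solve_stokes(dom, micro_bc("velocity", 0), props)
  expect_equal(max(compute_wss(f)$elements$wss), 0)

  open_dom <- build_fluid_domain(voxel_image(array(1, c(6, 6, 6)), 10))
  fo <- solve_stokes(open_dom, micro_bc("velocity", 1e-4), props)
  expect_warning(w0 <- compute_wss(fo), "no fluid-solid walls")
  expect_equal(nrow(w0$elements), 0L)
})

test_that("WSS scales linearly with the inlet velocity", {
  dom <- build_fluid_domain(small_scaffold(16, seed = 2))
  w1 <- compute_wss(solve_stokes(dom, micro_bc("velocity", 100e-6), props,
                                 tol = 1e-10))
  w3 <- compute_wss(solve_stokes(dom, micro_bc("velocity", 300e-6), props,
                                 tol = 1e-10))
  expect_lt(max(abs(3 * w1$elements$wss - w3$elements$wss)) /
              max(w3$elements$wss), 1e-8)
})

test_that("histograms bin right-open, conserve weight, and merge", {
  wf <- toy_wss_field(c(7, 2, 12.5, 99, 150), area = c(1, 2, 3, 4, 5))
  hist5 <- wss_histogram(wf, bin_width = 5, max = 100)
  expect_equal(sum(hist5$weights), wf$total_area)
  expect_equal(hist5$weights[2], 1)        # 7 mPa lands in [5, 10)
  expect_equal(hist5$weights[21], 5)       # overflow bin
  # doubling the bin width merges adjacent bins exactly
  hist10 <- wss_histogram(wf, bin_width = 10, max = 100)
  merged <- vapply(seq_len(10), function(k)
    sum(hist5$weights[(2 * k - 1):(2 * k)]), 1)
  expect_equal(hist10$weights[1:10], merged)

  cnt <- wss_histogram(wf, 5, 100, weighting = "count")
  expect_equal(sum(cnt$weights), 5)
})

test_that("band fractions partition and agree with a brute-force scan", {
  sc <- small_scaffold(16, seed = 9)
  f <- solve_stokes(build_fluid_domain(sc), micro_bc("velocity", 500e-6),
                    props, tol = 1e-6)
  wss <- compute_wss(f)
  expect_equal(area_fraction_in_band(wss, 0, Inf), 1)
  x <- 15
  expect_equal(area_fraction_in_band(wss, 0, x) +
                 area_fraction_in_band(wss, x, Inf), 1)
  # independent element scan
  el <- wss$elements
  brute <- sum(el$area[el$wss * 1000 >= 10 & el$wss * 1000 < 30]) /
    sum(el$area)
  expect_identical(area_fraction_in_band(wss, 10, 30), brute)
  expect_error(area_fraction_in_band(wss, 30, 10), "lo")
})

test_that("subregion averages follow the annulus geometry", {
  # uniform WSS: every region average equals the value
  n <- 20
  xy <- expand.grid(x = seq(12.5, 487.5, by = 25),
                    y = seq(12.5, 487.5, by = 25))
  wf <- toy_wss_field(rep(8, nrow(xy)), x = xy$x, y = xy$y)
  fp <- list(lo = c(0, 0), hi = c(500, 500))
  avg <- subregion_average_wss(wf, fp, n_regions = 5, width = 50)
  expect_equal(avg, rep(8, 5))

  # 5 x 50 um regions tile a 0.5 mm footprint; brute-force classification
  wss_vals <- seq_len(nrow(xy))
  wf2 <- toy_wss_field(wss_vals, x = xy$x, y = xy$y)
  avg2 <- subregion_average_wss(wf2, fp, 5, 50)
  d <- pmin(xy$x, 500 - xy$x, xy$y, 500 - xy$y)
  brute <- vapply(1:5, function(k) {
    sel <- d >= (k - 1) * 50 & d < k * 50
    mean(wss_vals[sel])
  }, 1)
  expect_equal(avg2, brute)
  expect_false(anyNA(avg2))

  expect_error(subregion_average_wss(wf, fp, 6, 50), "exceeds")
})

test_that("WSS and permeability errors shrink under grid refinement", {
  # pressure-driven slot flow is developed everywhere, so the measured
  # errors are pure discretization error
  errs <- matrix(0, 2, 3)
  gaps <- c(10, 20, 40)
  for (g in 1:3) {
    gap <- gaps[g]
    img <- plates_image(gap = gap, nz = 3 * gap)
    dom <- build_fluid_domain(img)
    f <- solve_stokes(dom, micro_bc("pressure", 0.02), props, tol = 1e-9)
    h <- img$voxel_size * 1e-6
    u_mean <- plate_mean_velocity(f)
    tau_th <- 6 * props$mu * u_mean / (gap * h)
    el <- compute_wss(f)$elements
    zin <- el$z > 0.25 * 3 * gap * 10 & el$z < 0.75 * 3 * gap * 10
    errs[1, g] <- abs(mean(el$wss[zin]) - tau_th) / tau_th
    pr <- compute_permeability(f)
    # slot of width b = gap*h in cross-section A: kappa = b^3 W / (12 A)
    kappa_th <- (gap * h)^3 * (dim(img)[2] * h) / (12 * pr$A)
    errs[2, g] <- abs(pr$kappa - kappa_th) / kappa_th
  }
  expect_true(all(diff(errs[1, ]) < 0))
  expect_true(all(diff(errs[2, ]) < 0))
})
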