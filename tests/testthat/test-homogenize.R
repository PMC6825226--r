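props <- fluid_props()

test_that("Darcy's law holds exactly among the stored fields", {
  img <- cylinder_image(R = 10, nz = 40)
  dom <- build_fluid_domain(img)
  f <- solve_stokes(dom, micro_bc("velocity", 500e-6), props, tol = 1e-8)
  pr <- compute_permeability(f, props)
  expect_equal(pr$Q, pr$kappa * pr$A / pr$mu * pr$dp / pr$H,
               tolerance = 1e-12)
  expect_gt(pr$kappa, 0)
})

test_that("cylindrical-channel permeability matches pi R^4 / (8 A)", {
  R <- 10; nz <- 48
  img <- cylinder_image(R = R, nz = nz)
  dom <- build_fluid_domain(img)
  f <- solve_stokes(dom, micro_bc("velocity", 500e-6), props, tol = 1e-8)
  pr <- compute_permeability(f, props)
  h <- img$voxel_size * 1e-6
  A <- prod(dim(img)[1:2]) * h^2
  kappa_th <- pi * (R * h)^4 / (8 * A)
  expect_lt(abs(pr$kappa - kappa_th) / kappa_th, 0.05)
})

test_that("permeability is invariant to the prescribed inlet velocity", {
  dom <- build_fluid_domain(small_scaffold(20, seed = 5))
  ks <- vapply(c(50e-6, 500e-6, 5000e-6), function(u) {
    compute_permeability(
      solve_stokes(dom, micro_bc("velocity", u), props, tol = 1e-8),
      props)$kappa
  }, 1)
  expect_lt(diff(range(ks)) / mean(ks), 0.005)
})

test_that("permeability decreases with porosity on seed-matched scaffolds", {
  ks <- vapply(c(0.9, 0.75, 0.6), function(phi) {
    sc <- generate_scaffold(phi, 100, c(28, 28, 28), 10, seed = 4)
    f <- solve_stokes(build_fluid_domain(sc), micro_bc("velocity", 500e-6),
                      props, tol = 1e-6)
    compute_permeability(f, props)$kappa
  }, 1)
  expect_true(all(diff(ks) < 0))
})

test_that("average_permeability is the arithmetic mean", {
  mk <- function(k) structure(list(kappa = k), class = "permeability_result")
  expect_equal(average_permeability(list(mk(2e-10), mk(6e-10))), 4e-10)
  expect_equal(average_permeability(list(mk(3e-10))), 3e-10)
  xs <- list(mk(1e-10), mk(2e-10), mk(7e-10))
  expect_equal(average_permeability(xs), average_permeability(rev(xs)))
  expect_error(average_permeability(list()), "empty")
})
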