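test_that("generated scaffolds hit the target porosity and percolate", {
  # headline conditions: porosity 0.85, 200 um pores, 64^3 at 10 um
  sc <- generate_scaffold(0.85, 200, c(64, 64, 64), 10, seed = 1)
  expect_gte(porosity(sc), 0.83)
  expect_lte(porosity(sc), 0.87)

  # determinism: same seed, bit-identical image
  sc2 <- generate_scaffold(0.85, 200, c(64, 64, 64), 10, seed = 1)
  expect_identical(sc$data, sc2$data)
  sc3 <- generate_scaffold(0.85, 200, c(64, 64, 64), 10, seed = 2)
  expect_false(identical(sc$data, sc3$data))

  # porosity within +/- 0.02 of target for every seed 1..10
  for (seed in 1:10) {
    g <- generate_scaffold(0.8, 100, c(40, 40, 40), 10, seed = seed)
    expect_lte(abs(porosity(g) - 0.8), 0.02)
    # fluid percolates: a path connects inlet to outlet
    span <- poreflow:::spanning_fluid(g$data == 1)
    expect_true(any(span[, , 1]) && any(span[, , 40]))
  }
})

test_that("high-porosity scaffolds are a single spanning component", {
  g <- generate_scaffold(0.95, 150, c(32, 32, 32), 10, seed = 3)
  labs <- poreflow:::label_components6(g$data == 1)
  expect_equal(max(labs), 1L)  # connected-component oracle
})

test_that("generator rejects invalid requests explicitly", {
  expect_error(generate_scaffold(0.2, 100, c(32, 32, 32), 10, 1), "porosity")
  expect_error(generate_scaffold(0.8, 20, c(32, 32, 32), 10, 1),
               "mean_pore_diameter")
  expect_error(generate_scaffold(0.8, 100, c(2, 2, 2), 10, 1), "shape")
})

test_that("the generator does not disturb the global RNG stream", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(generate_scaffold(0.8, 100, c(16, 16, 16), 10, seed = 5))
  expect_identical(runif(1), before)
})
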