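test_that("gaussian filter is a renormalized truncated kernel", {
  const <- voxel_image(array(3.7, c(6, 6, 6)), 10)
  expect_equal(gaussian_filter_3d(const, 0.8, 1)$data, const$data)

  # unit impulse reproduces the truncated renormalized kernel (oracle:
  # evaluate the separable kernel directly)
  imp <- array(0, c(7, 7, 7)); imp[4, 4, 4] <- 1
  out <- gaussian_filter_3d(voxel_image(imp, 10, type = "grayscale"),
                            0.8, 1)$data
  w1 <- exp(-(-1:1)^2 / (2 * 0.8^2)); w1 <- w1 / sum(w1)
  kern <- outer(outer(w1, w1), w1)
  expect_equal(sum(out), 1, tolerance = 1e-12)
  expect_equal(out[3:5, 3:5, 3:5], array(kern, c(3, 3, 3)),
               tolerance = 1e-12)

  # sigma -> 0 limit: identity within floating tolerance
  img <- voxel_image(array(rnorm(5^3), c(5, 5, 5)), 10)
  expect_equal(gaussian_filter_3d(img, 1e-6, 1)$data, img$data,
               tolerance = 1e-12)

  # periodic padding preserves the global mean to 1e-12 relative
  sm <- gaussian_filter_3d(img, 1.3, 3, padding = "periodic")
  expect_equal(mean(sm$data), mean(img$data), tolerance = 1e-12)

  expect_error(gaussian_filter_3d(img, -1, 1), "sigma")
  lab <- voxel_image(array(1, c(2, 2, 2)), 10)
  expect_error(gaussian_filter_3d(lab, 0.8, 1), "grayscale")
})

test_that("segment applies inclusive window thresholds", {
  two <- voxel_image(array(c(100, 2000), c(4, 4, 2)), 10)
  seg <- segment(two, 50, 150, phase = "fluid")
  expect_identical(seg$data == 1, two$data == 100)

  const <- voxel_image(array(75, c(3, 3, 3)), 10)
  expect_equal(segment(const, 50, 100, "fluid")$data,
               array(1, c(3, 3, 3)))

  expect_warning(empty <- segment(const, 200, 300, "fluid"), "no voxels")
  expect_equal(sum(empty$data), 0)
  expect_error(segment(const, 10, 5), "lo")
})

test_that("label smoothing preserves topology of compact solids", {
  # solid ball radius 10 in a 26^3 box
  n <- 26; mid <- (n + 1) / 2
  co <- (1:n) - mid
  dist2 <- array(outer(outer(co^2, co^2, `+`), co^2, `+`), c(n, n, n))
  lab <- array(as.numeric(dist2 > 10^2), c(n, n, n))  # fluid outside ball
  img <- voxel_image(lab, 10)

  expect_identical(smooth_labels(img, 0, 0.4)$data, img$data)

  sm <- smooth_labels(img, 4, 0.4)
  solid <- sm$data == 0
  labs <- poreflow:::label_components6(solid)
  expect_equal(max(labs), 1L)  # still one 6-connected solid component

  allsolid <- voxel_image(array(0, c(5, 5, 5)), 10)
  expect_identical(smooth_labels(allsolid, 4, 0.4)$data, allsolid$data)

  # eroding away a 1-voxel filament trips the volume guard
  thin <- array(1, c(12, 12, 12)); thin[6, 6, ] <- 0
  expect_error(smooth_labels(voxel_image(thin, 10), 4, 0.4), "10%")
})
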