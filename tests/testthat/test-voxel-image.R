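test_that("voxel_image validates its invariants", {
  img <- voxel_image(array(1, c(4, 4, 4)), voxel_size = 10)
  expect_s3_class(img, "voxel_image")
  expect_equal(dim(img), c(4L, 4L, 4L))
  expect_identical(img$type, "label")
  expect_equal(porosity(img), 1)

  expect_error(voxel_image(matrix(1, 2, 2), 10), "3D")
  expect_error(voxel_image(array(1, c(2, 2, 2)), -1), "voxel_size")
  expect_error(voxel_image(array(0.5, c(2, 2, 2)), 10, type = "label"),
               "label")
  gs <- voxel_image(array(0.5, c(2, 2, 2)), 10)
  expect_identical(gs$type, "grayscale")
  expect_error(porosity(gs), "label")
})

test_that("rve extraction is exact voxel arithmetic", {
  dat <- array(as.numeric(seq_len(6 * 6 * 10) %% 2), c(6, 6, 10))
  img <- voxel_image(dat, voxel_size = 10)

  full <- extract_rve(img, rve_spec(1, c(0, 0, 0), c(60, 60, 100)))
  expect_identical(full$data, img$data)

  # a 0.5 x 0.5 x 1.0 mm box at 10 um voxels is 50 x 50 x 100 voxels
  big <- voxel_image(array(1, c(150, 150, 100)), 10)
  crop <- extract_rve(big, rve_spec(1, c(500, 500, 0), c(1000, 1000, 1000)))
  expect_equal(dim(crop), c(50L, 50L, 100L))
  expect_equal(crop$origin, c(500, 500, 0))

  expect_error(extract_rve(img, rve_spec(1, c(0, 0, 0), c(70, 60, 100))),
               "outside")

  # a centred crop of a mirror-symmetric image is mirror-symmetric
  sym <- array(0, c(8, 4, 4))
  sym[c(2, 7), , ] <- 1
  simg <- voxel_image(sym, 10)
  cr <- extract_rve(simg, rve_spec(1, c(10, 0, 0), c(70, 40, 40)))
  expect_identical(cr$data, cr$data[dim(cr$data)[1]:1, , ])
})

test_that("partition_rves places equal disjoint full-height specs", {
  sc <- voxel_image(array(1, c(500, 500, 200)), 10)  # 5 x 5 x 2 mm
  specs <- partition_rves(sc, c(3, 3), 400)
  expect_length(specs, 9L)
  for (s in specs) {
    expect_equal(s$hi[1:2] - s$lo[1:2], c(400, 400))
    expect_equal(c(s$lo[3], s$hi[3]), c(0, 2000))  # full height
  }
  # pairwise disjoint lateral boxes (interval-overlap oracle)
  overlap1d <- function(a, b) a$lo < b$hi && b$lo < a$hi
  for (i in 1:8) for (j in (i + 1):9) {
    a <- specs[[i]]; b <- specs[[j]]
    expect_false(
      overlap1d(list(lo = a$lo[1], hi = a$hi[1]),
                list(lo = b$lo[1], hi = b$hi[1])) &&
      overlap1d(list(lo = a$lo[2], hi = a$hi[2]),
                list(lo = b$lo[2], hi = b$hi[2]))
    )
  }

  one <- partition_rves(sc, c(1, 1), 3000)
  expect_length(one, 1L)
  expect_equal(one[[1]]$lo[1:2], c(1000, 1000))  # centred

  expect_error(partition_rves(sc, c(3, 3), 2000), "fit")
})

test_that("build_fluid_domain removes trapped pores and tags faces", {
  all_fluid <- voxel_image(array(1, c(4, 4, 6)), 10)
  dom <- build_fluid_domain(all_fluid)
  expect_equal(dom$face_counts[["wall"]], 0L)
  expect_equal(dom$face_counts[["inlet"]], 16L)
  expect_equal(dom$trapped_fraction, 0)

  blocked <- array(1, c(4, 4, 6)); blocked[, , 3] <- 0
  expect_error(build_fluid_domain(voxel_image(blocked, 10)),
               "not permeable")

  # straight channel: fluid mask is exactly the channel, walls all around
  chan <- array(0, c(5, 5, 8)); chan[3, 3, ] <- 1
  cd <- build_fluid_domain(voxel_image(chan, 10))
  expect_equal(sum(cd$mask), 8L)
  expect_equal(cd$face_counts[["wall"]], 4L * 8L)

  # an isolated bubble is trapped porosity and gets removed
  bub <- array(1, c(6, 6, 6)); bub[2:5, 2:5, 2:5] <- 1
  bub[, , ] <- 0; bub[3, 3, ] <- 1; bub[5, 5, 3] <- 1
  bd <- build_fluid_domain(voxel_image(bub, 10))
  expect_false(bd$mask[5, 5, 3])
  expect_equal(bd$trapped_fraction, 1 / 7)
  # mask + solid + trapped partition the box
  expect_equal(sum(bd$mask) + 1L + sum(bub == 0), length(bub))
})
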