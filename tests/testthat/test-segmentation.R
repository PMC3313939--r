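test_that("assign_hard classifies voxels to the nearest centroid", {
  v <- gray_volume(matrix(c(100L, 60L, 90L, 180L), 2, 2))
  lab <- assign_hard(v, c(GM = 60, WM = 120, CSF = 180), background_low = NULL)
  expect_equal(lab[1, 1, 1], 2L)  # distances 40, 20, 80
  expect_equal(lab[1, 2, 1], 1L)  # exactly at a centroid
  expect_equal(lab[1, 1, 2], 1L)  # 90 equidistant from 60/120: lowest index
  expect_equal(lab[1, 2, 2], 3L)

  # background cutoff labels dark voxels 0
  v2 <- gray_volume(matrix(c(10L, 44L, 45L, 200L), 2, 2))
  lab2 <- assign_hard(v2, c(60, 120, 180))
  expect_equal(as.vector(lab2[1, , ]), c(0L, 0L, 1L, 3L))

  expect_error(assign_hard(v, tibble::tibble(plane = 2L, region = "GM",
                                             centroid = 60)),
               "missing centroids")
})

test_that("assign_hard equals the brute-force per-voxel oracle exactly", {
  set.seed(13)
  for (i in 1:5) {
    plane <- matrix(sample(0:255, 64 * 64, replace = TRUE), 64, 64)
    cen <- sort(sample(0:255, 3))
    got <- assign_hard(gray_volume(plane), cen, background_low = NULL)
    expect_identical(matrix(got[1, , ], 64, 64), oracle_assign_plane(plane, cen))
    gotbg <- assign_hard(gray_volume(plane), cen, background_low = 45)
    expect_identical(matrix(gotbg[1, , ], 64, 64),
                     oracle_assign_plane(plane, cen, background_low = 45))
  }
})

test_that("the voxel pass never updates the centroids", {
  ph <- generate_phantom(shape = c(2, 32, 32), seed = 4)
  cen <- auto_centroids(ph$volume)
  before <- cen$centroid
  invisible(assign_hard(ph$volume, cen))
  invisible(assign_soft(ph$volume, cen))
  expect_identical(cen$centroid, before)
})

test_that("soft memberships normalize, peak at centroids, and agree with hard labels", {
  v <- gray_volume(matrix(c(60L, 90L, 143L, 201L), 2, 2))
  m <- assign_soft(v, c(60, 120, 180))
  # exact centroid hit -> membership ~1
  expect_equal(m[1, 1, 1, 1], 1, tolerance = 1e-6)
  # equidistant voxel 90 (row 2, col 1) -> equal first two memberships
  expect_equal(m[1, 2, 1, 1], m[1, 2, 1, 2], tolerance = 1e-12)

  set.seed(21)
  vol <- gray_volume(array(sample(0:255, 4 * 16 * 16, replace = TRUE), c(4, 16, 16)))
  cen <- c(60, 120, 180)
  mm <- assign_soft(vol, cen)
  sums <- apply(mm, 1:3, sum)
  expect_lt(max(abs(sums - 1)), 1e-9)
  expect_true(all(mm >= 0))

  hard <- assign_hard(vol, cen, background_low = NULL)
  amax <- apply(mm, 1:3, which.max)
  tied <- array(abs(abs(vol - 60) - abs(vol - 120)) < 1e-9 |
                  abs(abs(vol - 120) - abs(vol - 180)) < 1e-9, dim = dim(vol))
  expect_identical(amax[!tied], as.integer(hard)[!tied])
})

test_that("extract_region keeps intensities hard and scales them soft", {
  ph <- generate_phantom(shape = c(1, 32, 32), noise_sigma = 0, seed = 1)
  cen <- c(GM = 65, WM = 110, CSF = 180)
  lab <- assign_hard(ph$volume, cen)
  gm <- extract_region(ph$volume, lab, "GM")
  expect_true(all(gm[lab == 1L] == ph$volume[lab == 1L]))
  expect_true(all(gm[lab != 1L] == 0L))

  m <- assign_soft(ph$volume, cen)
  zero_m <- m
  zero_m[, , , 2] <- 0
  expect_true(all(extract_region(ph$volume, zero_m, 2, mode = "soft") == 0L))

  # soft extractions over all regions re-add to the volume within rounding
  total <- array(0, dim = dim(ph$volume))
  for (r in 1:3) total <- total + unclass(extract_region(ph$volume, m, r, "soft"))
  fg <- ph$labels > 0
  expect_lte(max(abs(total[fg] - unclass(ph$volume)[fg])), 2)

  expect_error(extract_region(ph$volume, lab, "bone"), "unknown region")
})

test_that("render_hard applies the purple/dark-pink/yellow convention", {
  lab <- structure(array(1L, c(1, 4, 4)), class = c("label_map", "array"),
                   regions = c("GM", "WM", "CSF"))
  img <- render_hard(lab)[[1]]
  expect_true(all(img[, , 1] == 128L & img[, , 2] == 0L & img[, , 3] == 128L))

  bg <- structure(array(0L, c(1, 4, 4)), class = c("label_map", "array"),
                  regions = c("GM", "WM", "CSF"))
  expect_true(all(render_hard(bg)[[1]] == 0L))

  bad <- structure(array(9L, c(1, 2, 2)), class = c("label_map", "array"),
                   regions = c("GM", "WM", "CSF"))
  expect_error(render_hard(bad), "no color")
})

test_that("hard segmentation with true centroids recovers noisy phantoms", {
  for (seed in 1:3) {
    ph <- generate_phantom(shape = c(1, 128, 128), noise_sigma = 5, seed = seed)
    lab <- assign_hard(ph$volume, c(GM = 65, WM = 110, CSF = 180))
    fg <- ph$labels > 0
    expect_gte(mean(lab[fg] == ph$labels[fg]), 0.99)
  }
})

test_that("region volumes count labels exactly and partition the volume", {
  lab <- structure(array(1L, c(1, 10, 10)), class = c("label_map", "array"),
                   regions = c("GM", "WM", "CSF"))
  expect_equal(region_volume(lab, "GM"), 100L)
  expect_equal(region_volume(lab, "CSF"), 0L)
  expect_error(region_volume(lab, "bone"), "unknown region")

  ph <- generate_phantom(shape = c(2, 48, 48), seed = 9)
  vols <- region_volumes(ph$labels)
  expect_equal(sum(vols$voxels), length(ph$labels))
})
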