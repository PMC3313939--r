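test_that("compute_histogram counts exactly and conserves pixel count", {
  h <- compute_histogram(matrix(c(0L, 0L, 255L, 255L), 2, 2))
  expect_equal(h$count[h$gray == 0], 2L)
  expect_equal(h$count[h$gray == 255], 2L)
  expect_equal(sum(h$count), 4L)

  h7 <- compute_histogram(matrix(7L, 4, 4))
  expect_equal(h7$count[h7$gray == 7], 16L)
  expect_equal(sum(h7$count), 16L)

  set.seed(2)
  for (i in 1:5) {
    p <- matrix(sample(0:255, 300, replace = TRUE), 15, 20)
    expect_equal(sum(compute_histogram(p)$count), 300L)
  }
})

test_that("find_peaks returns strict local maxima with plateau midpoints", {
  # counts [0,5,2,7,1] on levels 0..4
  p <- find_peaks(hist_tbl(counts_at(0:4, c(0L, 5L, 2L, 7L, 1L))))
  expect_equal(p, peaks_tbl(c(1L, 3L), c(5L, 7L)))

  # plateau [0,4,4,4,0] -> single peak at the plateau midpoint
  p2 <- find_peaks(hist_tbl(counts_at(0:4, c(0L, 4L, 4L, 4L, 0L))))
  expect_equal(p2, peaks_tbl(2L, 4L))

  # strictly increasing histogram has no interior maxima
  expect_equal(nrow(find_peaks(hist_tbl(0:255))), 0L)

  # gray levels 0 and 255 are never peaks
  edge <- integer(256); edge[1] <- 100L; edge[256] <- 100L; edge[129] <- 7L
  expect_equal(find_peaks(hist_tbl(edge))$gray, 128L)
})

test_that("find_peaks matches the run-enumeration oracle on random histograms", {
  set.seed(99)
  for (i in 1:20) {
    counts <- as.integer(rpois(256, lambda = sample(c(1, 5, 50), 1)))
    expect_equal(find_peaks(hist_tbl(counts)), oracle_find_peaks(counts))
  }
})

test_that("prune_peaks drops peaks below the fraction of the highest peak", {
  p <- peaks_tbl(c(10L, 12L, 50L), c(100L, 3L, 80L))
  expect_equal(prune_peaks(p), peaks_tbl(c(10L, 50L), c(100L, 80L)))
  one <- peaks_tbl(40L, 9L)
  expect_equal(prune_peaks(one), one)
  flat <- peaks_tbl(c(10L, 60L, 200L), c(5L, 5L, 5L))
  expect_equal(prune_peaks(flat), flat)
  expect_error(prune_peaks(p, fraction = 0), "0, 1")
  expect_error(prune_peaks(p, fraction = 1), "0, 1")
  expect_equal(nrow(prune_peaks(peaks_tbl(integer(), integer()))), 0L)
})

test_that("merge_peaks keeps the higher peak of close pairs, rescanning from it", {
  expect_equal(merge_peaks(peaks_tbl(c(10L, 12L, 50L), c(100L, 60L, 80L))),
               peaks_tbl(c(10L, 50L), c(100L, 80L)))
  far <- peaks_tbl(c(10L, 20L, 90L), c(5L, 9L, 2L))
  expect_equal(merge_peaks(far), far)
  # chain: survivor of the first merge absorbs the next close peak
  expect_equal(merge_peaks(peaks_tbl(c(10L, 15L, 19L), c(50L, 60L, 40L))),
               peaks_tbl(15L, 60L))
  # count tie breaks to the lower gray level
  expect_equal(merge_peaks(peaks_tbl(c(30L, 35L), c(7L, 7L))), peaks_tbl(30L, 7L))
  expect_error(merge_peaks(far, min_separation = 0), ">= 1")
})

test_that("prune and merge are idempotent and merge output is separated", {
  set.seed(7)
  for (i in 1:10) {
    counts <- as.integer(rpois(256, 20))
    p <- find_peaks(hist_tbl(counts))
    pr <- prune_peaks(p)
    expect_equal(prune_peaks(pr), pr)
    m <- merge_peaks(pr)
    expect_equal(merge_peaks(m), m)
    if (nrow(m) > 1L) expect_true(all(diff(m$gray) >= 10))
  }
})

test_that("select_centroids picks the highest in-range peak with stated fallbacks", {
  peaks <- peaks_tbl(c(60L, 120L, 180L), c(500L, 800L, 200L))
  cen <- select_centroids(peaks)
  expect_equal(cen$centroid, c(60L, 120L, 180L))
  expect_equal(cen$region, c("GM", "WM", "CSF"))
  expect_equal(cen$source, rep("peak", 3))

  # no CSF peak but raw counts present -> argmax of the raw histogram there
  h <- counts_at(c(60L, 120L, 170L, 200L), c(500L, 800L, 30L, 44L))
  cen2 <- select_centroids(peaks_tbl(c(60L, 120L), c(500L, 800L)),
                           h = hist_tbl(h))
  expect_equal(cen2$centroid[cen2$region == "CSF"], 200L)
  expect_equal(cen2$source[cen2$region == "CSF"], "raw-argmax")

  # empty CSF range -> midpoint 198 with a warning
  h0 <- counts_at(c(60L, 120L), c(500L, 800L))
  expect_warning(
    cen3 <- select_centroids(peaks_tbl(c(60L, 120L), c(500L, 800L)),
                             h = hist_tbl(h0)),
    "CSF.*midpoint")
  expect_equal(cen3$centroid[cen3$region == "CSF"], 198L)

  # count tie inside a range breaks to the lower gray level
  tie <- suppressWarnings(select_centroids(peaks_tbl(c(50L, 70L), c(10L, 10L))))
  expect_equal(tie$centroid[tie$region == "GM"], 50L)
})

test_that("auto_centroids runs the per-plane pipeline deterministically", {
  # noiseless three-delta plane
  plane <- matrix(rep(c(65L, 110L, 180L), length.out = 400), 20, 20)
  arr <- array(0L, c(2, 20, 20))
  arr[1, , ] <- plane; arr[2, , ] <- plane
  v <- gray_volume(arr)
  suppressWarnings(cen <- auto_centroids(v))
  expect_equal(cen$centroid, rep(c(65L, 110L, 180L), 2))
  # two identical planes give identical centroid rows
  expect_equal(cen$centroid[cen$plane == 1], cen$centroid[cen$plane == 2])

  # uniform plane: GM/CSF fall back, WM keeps the single histogram spike
  u <- gray_volume(matrix(100L, 16, 16))
  w <- capture_warnings(cu <- auto_centroids(u))
  expect_length(w, 2L)  # GM and CSF midpoint fallbacks
  expect_match(w, "midpoint", all = TRUE)
  expect_equal(cu$centroid[cu$region == "WM"], 100L)
  expect_equal(cu$source[cu$region == "GM"], "midpoint")
  expect_equal(cu$centroid[cu$region == "GM"], 65L)
  expect_equal(cu$centroid[cu$region == "CSF"], 198L)
})

test_that("centroids recover phantom class modes under noise", {
  for (seed in 1:3) {
    ph <- generate_phantom(shape = c(1, 128, 128), noise_sigma = 5, seed = seed)
    cen <- auto_centroids(ph$volume)
    expect_equal(cen$region, c("GM", "WM", "CSF"))
    expect_true(all(abs(cen$centroid - c(65, 110, 180)) <= 3),
                info = sprintf("seed %d: centroids %s", seed,
                               paste(cen$centroid, collapse = ",")))
  }
})

test_that("selected centroids always lie inside their region ranges", {
  set.seed(31)
  rr <- region_ranges()
  for (i in 1:5) {
    v <- gray_volume(matrix(sample(0:255, 1024, replace = TRUE), 32, 32))
    cen <- suppressWarnings(auto_centroids(v))
    for (j in seq_len(nrow(rr))) {
      ci <- cen$centroid[cen$region == rr$region[j]]
      expect_true(ci >= rr$low[j] && ci <= rr$high[j])
    }
  }
})
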