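test_that("LoG kernel satisfies its center, zero-crossing and zero-sum identities", {
  for (sigma in c(1, 2, 4)) {
    k <- log_kernel(sigma, radius = max(ceiling(6 * sigma), ceiling(3 * sigma)))
    ctr <- k$radius + 1L
    expect_equal(k$weights[ctr, ctr], -2 / sigma^2)
    expect_lt(abs(sum(k$weights)), 1e-3)
  }
  k1 <- log_kernel(1, radius = 6)
  expect_equal(k1$weights[k1$radius + 2L, k1$radius + 2L], 0)  # (1,1): x^2+y^2 = 2
  expect_error(log_kernel(2, radius = 3), class = "nucseg_config_error")
})

test_that("blob detection localizes dark Gaussian spots at the right scale", {
  h <- 64
  spot <- function(r0, c0, sd = 3, amp = 0.6) {
    outer(1:h, 1:h, function(r, c) amp * exp(-((r - r0)^2 + (c - c0)^2) / (2 * sd^2)))
  }
  gray <- 1 - spot(30, 34)
  hits <- detect_blobs(gray, sigmas = c(1.5, 2, 3, 4.5, 6), threshold = 0.5)
  expect_equal(nrow(hits), 1L)
  expect_lte(max(abs(c(hits$row - 30, hits$col - 34))), 1)
  expect_gte(hits$sigma, 2); expect_lte(hits$sigma, 4.5)

  expect_equal(nrow(detect_blobs(matrix(0.5, 32, 32), c(2, 3))), 0L)

  gray2 <- 1 - spot(16, 16) - spot(48, 44)
  hits2 <- detect_blobs(gray2, sigmas = c(1.5, 2, 3, 4.5, 6), threshold = 0.5)
  expect_equal(nrow(hits2), 2L)
  expect_lte(max(abs(sort(hits2$row) - c(16, 48))), 1)
  expect_lte(max(abs(sort(hits2$col) - c(16, 44))), 1)
})

test_that("component labeling matches a flood-fill oracle under both connectivities", {
  m <- matrix(FALSE, 8, 8); m[2:6, 2:6] <- TRUE
  expect_equal(max(label_components(m)), 1L)

  diagp <- matrix(FALSE, 4, 4); diagp[1, 1] <- TRUE; diagp[2, 2] <- TRUE
  expect_equal(max(label_components(diagp, 8L)), 1L)
  expect_equal(max(label_components(diagp, 4L)), 2L)

  for (s in 1:30) {
    m <- random_mask(32, 32, 0.45, seed = 600 + s)
    for (conn in c(4L, 8L)) {
      expect_true(same_partition(label_components(m, conn),
                                 flood_fill_oracle(m, conn)),
                  label = sprintf("conn %d seed %d", conn, s))
    }
  }
})

test_that("labels are numbered in row-major order of each component's first pixel", {
  m <- matrix(FALSE, 6, 6)
  m[5, 1] <- TRUE      # first pixel column-major, but later row-major
  m[2, 4] <- TRUE      # first pixel row-major
  lab <- label_components(m, 8L)
  expect_equal(lab[2, 4], 1L)
  expect_equal(lab[5, 1], 2L)
})

test_that("labeling agrees with EBImage's 4-connected bwlabel", {
  for (s in 1:5) {
    m <- random_mask(32, 32, 0.5, seed = 700 + s)
    ref <- matrix(as.integer(EBImage::imageData(EBImage::bwlabel(
      EBImage::Image(m * 1)))), 32, 32)
    expect_true(same_partition(label_components(m, 4L), ref))
  }
})

test_that("component masks partition the foreground and report exact statistics", {
  m <- matrix(FALSE, 12, 12)
  m[4:6, 7:9] <- TRUE
  m[9:10, 2:3] <- TRUE
  lab <- label_components(m, 8L)
  cm <- component_masks(lab, min_area = 1L)
  expect_length(cm, 2L)
  tab <- component_table(cm)
  expect_equal(tab$area, c(9L, 4L))
  expect_equal(tab$centroid_r[1], 5)
  expect_equal(tab$centroid_c[1], 8)
  expect_equal(unlist(tab[1, c("r0", "c0", "r1", "c1")], use.names = FALSE),
               c(4L, 7L, 7L, 10L))
  # masks are disjoint and union to the foreground
  expect_identical(cm[[1]]$mask | cm[[2]]$mask, m)
  expect_false(any(cm[[1]]$mask & cm[[2]]$mask))

  expect_length(component_masks(lab, min_area = 100L), 0L)
  expect_length(component_masks(lab, min_area = 5L), 1L)
})

test_that("seeds derive from sure-foreground blobs with a distance-peak fallback", {
  # dumbbell: two disks merged by a bar, two separate sure-fg cores
  m <- matrix(FALSE, 30, 60)
  m[outer(1:30, 1:60, function(r, c) (r - 15)^2 + (c - 18)^2 <= 81)] <- TRUE
  m[outer(1:30, 1:60, function(r, c) (r - 15)^2 + (c - 42)^2 <= 81)] <- TRUE
  m[14:16, 18:42] <- TRUE
  lab <- label_components(m, 8L)
  expect_equal(max(lab), 1L)
  mk <- extract_markers(m, fg_fraction = 0.6)
  cm <- component_masks(lab, min_area = 10L)
  seeds <- seed_markers_from_components(cm, mk)
  expect_equal(max(seeds), 2L)
  expect_true(all(seeds[!mk$sure_fg] == 0L))

  # isolated disk: one seed
  d1 <- matrix(FALSE, 24, 24)
  d1[outer(1:24, 1:24, function(r, c) (r - 12)^2 + (c - 12)^2 <= 49)] <- TRUE
  s1 <- seed_markers_from_components(
    component_masks(label_components(d1, 8L), 10L), extract_markers(d1))
  expect_equal(max(s1), 1L)

  # component with no sure-fg at all: 1-px peak fallback plus warning
  mk_empty <- extract_markers(d1)
  mk_empty$sure_fg[] <- FALSE
  expect_warning(
    s2 <- seed_markers_from_components(
      component_masks(label_components(d1, 8L), 10L), mk_empty),
    "distance peak")
  expect_equal(sum(s2 > 0L), 1L)
  expect_true(d1[which(s2 > 0L)])
})

test_that("distance-peak seed points separate touching nuclei and stay disjoint", {
  # two circles with a 20% overlap: one seed inside each
  fx <- two_nuclei_fixture()
  mask <- fx$in1 | fx$in2
  seeds <- detect_seed_points(mask)
  expect_equal(max(seeds), 2L)
  ownership <- sapply(1:2, function(k) {
    px <- which(seeds == k)
    unique(fx$truth[px][fx$truth[px] > 0L])
  })
  expect_setequal(unlist(ownership), 1:2)

  expect_equal(max(detect_seed_points(matrix(FALSE, 10, 10))), 0L)

  # seed disks never overlap each other and lie inside the mask
  sc <- generate_scene(seed = 31)
  sep <- separate_stains(sc$image)
  mask <- binary_threshold(to_gray(sep$h_only), "otsu")
  seeds <- detect_seed_points(mask, gray = to_gray(sep$h_only))
  expect_true(all(mask[seeds > 0L]))
  expect_gte(max(seeds), 8L)
})

test_that("split_labels_by_seeds partitions multi-seed objects by nearest seed", {
  lab <- matrix(0L, 10, 20)
  lab[3:8, 2:18] <- 1L                      # one merged object
  seeds <- matrix(0L, 10, 20)
  seeds[5, 5] <- 1L; seeds[5, 15] <- 2L
  out <- split_labels_by_seeds(lab, seeds)
  expect_equal(max(out), 2L)
  expect_equal(out[5, 4], out[5, 5])
  expect_equal(out[5, 16], out[5, 15])
  expect_false(out[5, 5] == out[5, 15])
  expect_identical(out > 0L, lab > 0L)      # foreground unchanged

  # single-seed objects pass through unchanged (up to renumbering)
  lab2 <- matrix(0L, 6, 6); lab2[2:4, 2:4] <- 1L
  seeds2 <- matrix(0L, 6, 6); seeds2[3, 3] <- 1L
  expect_identical(split_labels_by_seeds(lab2, seeds2), lab2)
})
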