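test_that("histograms tally pixels exactly", {
  h <- build_histogram(c(0, 0, 255), n_bins = 256, range = c(0, 255))
  expect_equal(h$counts[1], 2)
  expect_equal(h$counts[256], 1)
  expect_equal(sum(h$counts), 3)

  hc <- build_histogram(rep(7, 10))
  expect_equal(sum(hc$counts > 0), 1)
  expect_equal(sum(hc$counts), 10)

  set.seed(31)
  v <- sample(0:255, 5000, TRUE)
  h <- build_histogram(v, 256, range = c(0, 256))
  tallied <- sapply(0:255, function(l) sum(v == l))
  # unit-width integer bins: level l lands in bin l+1
  expect_equal(h$counts, tallied)
  expect_error(build_histogram(numeric(0)), "zero pixels")
})

test_that("Otsu and max-entropy thresholds match exhaustive search on random histograms", {
  set.seed(32)
  for (i in 1:150) {
    h <- random_histogram(64)  # smaller bins here; the full-size sweep runs in the acceptance suite
    expect_equal(otsu_threshold(h)$k, oracle_otsu(h$counts), info = paste("otsu case", i))
    expect_equal(max_entropy_threshold(h)$k, oracle_max_entropy(h$counts),
                 info = paste("maxent case", i))
  }
})

test_that("thresholds are invariant under histogram duplication and break ties low", {
  set.seed(33)
  for (i in 1:25) {
    h <- random_histogram(64)
    h2 <- h; h2$counts <- h$counts * 2L
    expect_equal(otsu_threshold(h)$k, otsu_threshold(h2)$k)
    expect_equal(max_entropy_threshold(h)$k, max_entropy_threshold(h2)$k)
  }
  # two equal deltas at the extreme bins: every interior split is equivalent,
  # so the tie rule must pick the smallest
  h <- build_histogram(rep(c(10, 200), 50), n_bins = 256, range = c(0, 256))
  expect_equal(otsu_threshold(h)$k, 11)   # first split with all low mass below
  expect_equal(max_entropy_threshold(h)$k, 11)
  expect_equal(otsu_threshold(h)$k, oracle_otsu(h$counts))
  expect_equal(max_entropy_threshold(h)$k, oracle_max_entropy(h$counts))
})

test_that("degenerate histograms are rejected", {
  expect_error(otsu_threshold(build_histogram(rep(5, 9))), "degenerate")
  expect_error(max_entropy_threshold(build_histogram(rep(5, 9))), "degenerate")
})

test_that("the max-entropy criterion at the returned split dominates all others", {
  set.seed(34)
  h <- random_histogram(256)
  th <- max_entropy_threshold(h)
  p <- h$counts / sum(h$counts)
  shannon <- function(q) { tot <- sum(q); if (tot == 0) return(0)
    q <- q[q > 0] / tot; -sum(q * log(q)) }
  crits <- sapply(1:255, function(k) shannon(p[1:k]) + shannon(p[(k + 1):256]))
  expect_gte(crits[th$k] + 1e-12, max(crits))
})

test_that("mean filter equals the double-loop oracle and stays within input range", {
  f <- matrix(5, 7, 7)
  expect_equal(mean_filter(f, 2), f)

  # single bright pixel, r = 1: 5-member cross kernel
  g <- matrix(0, 7, 7); g[4, 4] <- 10
  mf <- mean_filter(g, 1)
  expect_equal(mf[4, 4], 2)
  expect_equal(mf[3, 4], 2)
  expect_equal(mf[4, 5], 2)
  expect_equal(mf[3, 3], 0)

  set.seed(35)
  r <- matrix(sample(0:255, 15 * 12, TRUE), 15, 12)
  for (rad in c(1, 2, 3)) {
    got <- mean_filter(r, rad)
    expect_equal(got, oracle_mean_filter(r, rad))
    expect_true(all(got >= min(r) - 1e-12 & got <= max(r) + 1e-12))
  }
})

test_that("contrast stretch maps the range linearly and preserves ranks", {
  f <- matrix(c(10, 110, 10, 110), 2, 2)
  expect_equal(sort(unique(as.vector(contrast_stretch(f)))), c(0, 255))
  full <- matrix(c(0, 255, 100, 30), 2, 2)
  expect_equal(contrast_stretch(full), full)
  expect_warning(contrast_stretch(matrix(4, 3, 3)), "constant")

  set.seed(36)
  g <- matrix(sample(0:10000, 100), 10, 10)
  expect_identical(order(contrast_stretch(g)), order(g))
})

test_that("component labelling and selection match the flood-fill oracle", {
  set.seed(37)
  for (i in 1:10) {
    m <- random_blob_mask()
    lab <- label_components(m)
    ref <- oracle_label(m)
    # same partition: relabel both canonically by first-pixel order
    expect_equal(lab > 0, ref > 0)
    expect_equal(max(lab), max(ref))
    for (l in seq_len(max(ref)))
      expect_equal(length(unique(lab[ref == l])), 1L)
  }

  two <- matrix(FALSE, 20, 20)
  two[2:7, 2:6] <- TRUE     # 30 px
  two[14:17, 14:16] <- TRUE # 12 px
  big <- mask_to_roi(two, "largest_component")
  expect_equal(roi_area(big), 30)
  near_small <- mask_to_roi(two, "nearest_to_seed", seed_point = c(15, 15))
  expect_equal(roi_area(near_small), 12)
  expect_error(mask_to_roi(matrix(FALSE, 5, 5)), "no foreground")
})

test_that("diagonally touching pixels join one 8-connected component but not a 4-connected one", {
  m <- matrix(FALSE, 4, 4)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE
  expect_equal(max(label_components(m, 8L)), 1L)
  expect_equal(max(label_components(m, 4L)), 2L)
})

test_that("ROI expansion is a clipped Chebyshev dilation, monotone in k", {
  f_dim <- c(21L, 21L)
  centre <- roi_rect(11, 11, 1, 1)
  ex5 <- expand_roi(centre, 5, f_dim)
  expect_equal(roi_area(ex5), 121)

  border <- roi_rect(1, 1, 2, 2)
  exb <- expand_roi(border, 5, f_dim)
  expect_lt(roi_area(exb), 11 * 11 + 121 - 36)  # clipped below the unclipped value
  expect_true(all(roi_to_mask(border, f_dim) <= roi_to_mask(exb, f_dim)))

  set.seed(38)
  for (i in 1:6) {
    m <- random_blob_mask(25, 25, 2)
    roi <- roi_mask(m)
    for (k in c(1, 3)) {
      got <- roi_to_mask(expand_roi(roi, k, dim(m)), dim(m))
      expect_equal(got, oracle_dilate(m, k))
    }
    e1 <- roi_to_mask(expand_roi(roi, 1, dim(m)), dim(m))
    e3 <- roi_to_mask(expand_roi(roi, 3, dim(m)), dim(m))
    expect_true(all(e1 <= e3))
  }
})

test_that("entropy thresholds select the same pixels on raw and min-max-stretched data", {
  # the stretch is monotone and bins follow the data range, so the selected
  # pixel set is unchanged
  set.seed(39)
  f <- matrix(sample(0:4095, 1600, TRUE), 40, 40)
  raw_mask <- apply_threshold(f, max_entropy_threshold(build_histogram(f)))
  g <- contrast_stretch(f)
  stretch_mask <- apply_threshold(g, max_entropy_threshold(build_histogram(g)))
  expect_equal(raw_mask, stretch_mask)
})
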