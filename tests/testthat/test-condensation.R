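test_that("the condensation parameter follows the rescale-and-count definition", {
  cfg <- condensation_config()
  expect_equal(cfg$threshold, 102)  # 0.4 of the rescaled maximum 255

  expect_equal(condensation_parameter(rep(7, 441), cfg), 0)   # diffuse limit
  expect_equal(condensation_parameter(c(0, 0, 9, 9), cfg), 0.5)
  # {10, 20, 30, 110} rescales to {0, 25.5, 51, 255}: three below 102
  expect_equal(condensation_parameter(c(10, 20, 30, 110), cfg), 0.75)
  expect_error(condensation_parameter(numeric(1)), "2 pixels")
})

test_that("the parameter is affine-invariant, bounded, and equals the rescaled ECDF at the cut", {
  set.seed(51)
  cfg <- condensation_config()
  for (i in 1:200) {
    v <- runif(50, 0, sample(c(1, 255, 65535), 1))
    p <- condensation_parameter(v, cfg)
    expect_gte(p, 0); expect_lte(p, 1)
    a <- runif(1, 0.01, 100); b <- runif(1, -50, 50)
    expect_equal(condensation_parameter(a * v + b, cfg), p)
    # direct bound: p is the ECDF of the rescaled values just below the cut
    r <- (v - min(v)) / (max(v) - min(v)) * 255
    expect_equal(p, mean(r < 102))
  }
})

test_that("concentrating contrast toward the extremes never lowers the parameter", {
  cfg <- condensation_config()
  # move mid-range mass down below min + 0.4*range: parameter must not decrease
  v <- c(0, 40, 120, 130, 255)
  w <- c(0, 40, 20, 30, 255)   # the two mid values moved below the cut
  expect_gte(condensation_parameter(w, cfg), condensation_parameter(v, cfg))
})

test_that("locate_pronucleus finds a synthetic nucleus to within a pixel", {
  xs <- matrix(rep(1:160, each = 160), 160)
  ys <- t(xs)
  frame <- 100 + 800 * exp(-((xs - 100)^2 + (ys - 120)^2) / (2 * 6^2))
  ctr <- locate_pronucleus(frame)
  expect_lte(abs(ctr[["x"]] - 100), 1)
  expect_lte(abs(ctr[["y"]] - 120), 1)

  two <- frame + 500 * exp(-((xs - 30)^2 + (ys - 30)^2) / (2 * 4^2))
  near_small <- locate_pronucleus(two, seed_point = c(33, 28))
  expect_lte(abs(near_small[["x"]] - 30), 1)
  expect_lte(abs(near_small[["y"]] - 30), 1)

  expect_error(locate_pronucleus(matrix(5, 30, 30)), "constant")
})

test_that("time courses align NEB to time zero and track compaction", {
  sim <- simulate_condensing_nucleus(n_frames = 50, neb_frame = 30, seed = 5)
  cur <- condensation_timecourse(sim$series, neb_frame = 30,
                                 seed_point = c(128, 128))
  expect_equal(cur$times_s[30], 0)
  expect_equal(diff(cur$times_s), rep(10, 49))
  expect_true(all(cur$values >= 0 & cur$values <= 1))
  smoothed <- loess_smooth(cur$times_s, cur$values, 0.4)
  expect_gt(cor(smoothed, sim$truth$compaction, method = "spearman"), 0.9)
})

test_that("a static diffuse nucleus yields a flat low-variance curve", {
  sim <- simulate_condensing_nucleus(n_frames = 40, neb_frame = 20,
                                     compaction_rate = 0, seed = 6)
  cur <- condensation_timecourse(sim$series, 20, c(128, 128))
  expect_lt(sd(cur$values), 0.05)
})

test_that("aggregation reports per-timepoint mean, sd and n", {
  mk <- function(vals, id) structure(
    list(embryo_id = id, times_s = (seq_along(vals) - 1) * 10, values = vals,
         centres = NULL, neb_frame = 1L, dt_s = 10),
    class = "condensation_curve")
  one <- aggregate_curves(list(mk(c(0.1, 0.2, 0.3), "a")))
  expect_equal(one$mean, c(0.1, 0.2, 0.3))
  expect_equal(one$sd, c(0, 0, 0))
  expect_equal(one$n, c(1, 1, 1))

  twin <- aggregate_curves(list(mk(c(0.4, 0.5, 0.6), "a"), mk(c(0.4, 0.5, 0.6), "b")))
  expect_equal(twin$sd, c(0, 0, 0))

  pair <- aggregate_curves(list(mk(c(0.2, 0.2, 0.2), "a"), mk(c(0.4, 0.4, 0.4), "b")))
  expect_equal(pair$mean, rep(0.3, 3))
  expect_equal(pair$sd, rep(sd(c(0.2, 0.4)), 3))
  expect_equal(pair$sd[1], 0.1414, tolerance = 1e-3)
})

test_that("loess smoothing is exact on lines, local elsewhere, and matches a WLS oracle", {
  x <- seq(0, 9)
  expect_equal(loess_smooth(x, 2 * x + 1, 0.4), 2 * x + 1)
  expect_equal(loess_smooth(x, 2 * x + 1, 1.0), 2 * x + 1)
  expect_equal(loess_smooth(x, rep(3.3, 10), 0.5), rep(3.3, 10))
  expect_error(loess_smooth(1:2, 1:2), "3 points")

  set.seed(52)
  xx <- sort(runif(10, 0, 5)); yy <- xx^2 + rnorm(10, 0, 0.2)
  fit <- loess_smooth(xx, yy, 0.6)
  expect_equal(fit[4], oracle_wls_fit(xx, yy, xx[4], 0.6))
  expect_equal(fit[9], oracle_wls_fit(xx, yy, xx[9], 0.6))

  # cross-check against the reference local-regression implementation
  xx <- sort(runif(50, 0, 10)); yy <- sin(xx / 2) + rnorm(50, 0, 0.1)
  ref <- predict(stats::loess(yy ~ xx, span = 0.4, degree = 1,
                              family = "gaussian", surface = "direct"))
  expect_equal(loess_smooth(xx, yy, 0.4), unname(ref), tolerance = 1e-8)
})
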