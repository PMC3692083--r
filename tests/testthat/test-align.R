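test_that("warp_profile with the identity transform is exact", {
  set.seed(11)
  p <- rnorm(500)
  expect_identical(warp_profile(p, linear_transform(0, 1)), p)
})

test_that("opposite shifts invert each other on a band-limited profile", {
  p <- band_profile(2000L, seq(200, 1800, by = 100), rep(1000, 17),
                    sigma = 25)
  q <- warp_profile(p, linear_transform(10, 1))
  back <- warp_profile(q, linear_transform(-10, 1))
  interior <- 100:1900
  expect_lt(max(abs(back[interior] - p[interior])), 1e-9)
})

test_that("scaling relocates a narrow peak to scale * p + shift", {
  p <- band_profile(4000L, 700, 1000, sigma = 6)
  w <- warp_profile(p, linear_transform(shift = 50, scale = 2))
  expect_lte(abs(which.max(w) - (2 * 700 + 50)), 1)
})

test_that("non-monotone anchors are rejected", {
  expect_error(warp_transform(anchors = cbind(c(1, 100, 50),
                                              c(1, 100, 200))),
               "increasing")
  t_bad <- warp_transform()
  t_bad$anchors <- cbind(c(1, 100, 50), c(1, 100, 200))
  expect_error(warp_profile(rnorm(300), t_bad), "monotone")
})

test_that("self-alignment returns the exact identity with score 1", {
  set.seed(12)
  p <- band_profile(3000L, seq(300, 2700, by = 60), runif(41, 200, 1500))
  t <- fit_linear(p, p)
  expect_identical(t$shift, 0)
  expect_identical(t$scale, 1)
  expect_identical(t$score, 1)
})

test_that("fit_linear recovers the transform that undoes a displacement", {
  set.seed(13)
  p <- band_profile(4000L, seq(400, 3400, by = 55), runif(55, 300, 1500))
  p2 <- warp_profile(p, linear_transform(25, 1))
  t <- fit_linear(p2, p)
  # the aligning transform inverts the applied one: warp by +25 is undone
  # by shift -25 at scale 1
  expect_lte(abs(t$shift - (-25)), 1)
  expect_lte(abs(t$scale - 1), 0.001)
  expect_gt(t$score, 0.99)
  expect_lt(max(abs(warp_profile(p2, t)[500:3400] - p[500:3400])),
            0.05 * max(p))
})

test_that("degenerate inputs to fit_linear raise alignment errors", {
  p <- band_profile(1000L, c(200, 700), c(500, 900))
  expect_error(fit_linear(p, rep(3, 1000)), "variance")
  expect_error(fit_linear(rep(1, 1000), p), "variance")
})

test_that("within-batch alignment designates lane 1 as the reference", {
  set.seed(14)
  base <- band_profile(4000L, seq(400, 3400, by = 50),
                       runif(61, 300, 1500))
  l2 <- warp_profile(base, linear_transform(40, 1.002))
  l3 <- warp_profile(base, linear_transform(-70, 0.998))
  tr <- mini_traces(cbind(base, l2, l3), cbind(base, l2, l3))
  tw <- align_within_batch(tr, coarse_smooth = 1L)
  expect_identical(tw[[1]]$shift, 0)
  expect_identical(tw[[1]]$score, 1)
  # aligning transform = inverse of the applied distortion
  expect_lte(abs(tw[[2]]$shift - (-40 / 1.002)), 1)
  expect_lte(abs(tw[[2]]$scale - 1 / 1.002), 0.001)
  expect_lte(abs(tw[[3]]$shift - (70 / 0.998)), 1)
  expect_lte(abs(tw[[3]]$scale - 1 / 0.998), 0.001)
})

test_that("two identical lanes both get the identity by tie-break", {
  p <- band_profile(2000L, seq(200, 1800, by = 80), rep(800, 21))
  tr <- mini_traces(cbind(p, p))
  tw <- align_within_batch(tr)
  expect_identical(tw[[2]]$shift, 0)
  expect_identical(tw[[2]]$scale, 1)
})

test_that("between-batch alignment recovers a planted batch shift", {
  set.seed(15)
  base <- band_profile(4000L, seq(400, 3400, by = 50),
                       runif(61, 300, 1500))
  b2 <- warp_profile(base, linear_transform(40, 1))
  tr <- trace_set(cbind(base, base, b2, b2), cbind(base, base, b2, b2),
                  data.frame(capillary_id = paste0("c", 1:4),
                             batch_id = c("b1", "b1", "b2", "b2"),
                             batch_ordinal = c(1L, 2L, 1L, 2L)))
  tw <- align_within_batch(tr, coarse_smooth = 1L)
  tb <- align_between_batches(tr, tw, coarse_smooth = 1L)
  expect_identical(tb[[1]]$shift, 0)   # batch 1 is the global reference
  expect_lte(abs(tb[[3]]$shift - (-40)), 1)
  expect_lte(abs(tb[[3]]$scale - 1), 0.001)
})

test_that("affine composition equals sequential application on shifts", {
  p <- band_profile(2000L, seq(200, 1800, by = 80), rep(900, 21))
  t1 <- linear_transform(13, 1)
  t2 <- linear_transform(-5, 1)
  seq_applied <- warp_profile(warp_profile(p, t1), t2)
  composed <- warp_profile(p, compose_linear(t1, t2))
  interior <- 60:1940
  expect_lt(max(abs(seq_applied[interior] - composed[interior])), 1e-9)
})

test_that("smooth baseline filter removes slow drift, preserves peaks", {
  set.seed(16)
  n <- 6000L
  centers <- seq(500, 5500, by = 120)  # sparse bands
  amps <- runif(length(centers), 500, 1500)
  bands <- band_profile(n, centers, amps, sigma = 10)
  drift <- 300 * sin(2 * pi * seq_len(n) / 8000)
  out <- subtract_smooth_baseline(bands + drift, window = 201L)
  resid_drift <- out - bands
  interior <- 300:5700
  expect_lt(max(abs(resid_drift[interior])), 0.10 * 300)
  peak_idx <- round(centers)
  expect_lt(max(abs(out[peak_idx] - bands[peak_idx]) / amps), 0.05)
})

test_that("smooth baseline of a zero or sparse profile is near-identity", {
  expect_equal(subtract_smooth_baseline(rep(0, 1000), 201L), rep(0, 1000))
  set.seed(17)
  p <- band_profile(4000L, seq(400, 3600, by = 200), rep(1000, 17),
                    sigma = 8)
  out <- subtract_smooth_baseline(p, 201L)
  expect_lt(max(abs(out - p)), 0.01 * 1000)
})

test_that("smooth baseline window is validated", {
  expect_error(subtract_smooth_baseline(rnorm(100), 200L), "odd")
  expect_error(subtract_smooth_baseline(rnorm(100), 201L), "exceeds")
})

test_that("piecewise DP equals exhaustive enumeration on small instances", {
  set.seed(18)
  roi <- region_of_interest(1, 120)
  for (case in 1:6) {
    reference <- rnorm(130)
    profile <- rnorm(130)
    t <- fit_piecewise(profile, reference, window = 30L, max_offset = 2L,
                       step = 1L, lambda = 0.01, roi = roi)
    oracle <- pw_oracle(profile, reference, 30L, -2:2, 0.01, roi)
    expect_equal(attr(t, "objective"), oracle$objective, tolerance = 1e-9)
    expect_equal(attr(t, "offsets"), oracle$path)
  }
})

test_that("piecewise alignment of a profile to itself is the zero path", {
  set.seed(19)
  p <- band_profile(1500L, seq(100, 1400, by = 60), runif(22, 300, 1200))
  t <- fit_piecewise(p, p, window = 100L, max_offset = 20L,
                     roi = region_of_interest(1, 1500))
  expect_true(all(attr(t, "offsets") == 0))
  expect_equal(attr(t, "objective"), 15, tolerance = 1e-9)
})

test_that("a dominant transition penalty forces the best constant path", {
  set.seed(20)
  reference <- band_profile(900L, seq(80, 820, by = 40), runif(19, 5, 15))
  profile <- warp_profile(reference, warp_transform(
    anchors = cbind(c(1, 450, 900) + 3, c(1, 450, 900))))
  roi <- region_of_interest(1, 900)
  t <- fit_piecewise(profile, reference, window = 100L, max_offset = 5L,
                     lambda = 1e6, roi = roi)
  d <- attr(t, "offsets")
  expect_true(all(d == d[1]))
  # oracle: best single global offset by summed window correlation
  scores <- vapply(-5:5, function(s) {
    idx <- 1:900
    sum(vapply(seq(1, 801, by = 100), function(st) {
      src <- (st:(st + 99)) + s
      pw <- ifelse(src >= 1 & src <= 900, profile[pmin(pmax(src, 1), 900)],
                   0)
      rw <- reference[st:(st + 99)]
      if (sd(pw) == 0 || sd(rw) == 0) 0 else cor(pw, rw)
    }, 0))
  }, 0)
  expect_equal(d[1], (-5:5)[which.max(scores)])
})

test_that("piecewise window must admit the offset range", {
  expect_error(fit_piecewise(rnorm(500), rnorm(500), window = 40L,
                             max_offset = 30L), "2 \\* max_offset")
})

test_that("fitted warps are always monotone (bands are never reordered)", {
  set.seed(21)
  for (i in 1:5) {
    reference <- band_profile(2000L, seq(150, 1850, by = 50),
                              runif(35, 200, 1500))
    profile <- warp_profile(reference, warp_transform(
      anchors = cbind(seq(1, 2000, length.out = 7) +
                        runif(7, -12, 12) * c(0, 1, 1, 1, 1, 1, 0),
                      seq(1, 2000, length.out = 7))))
    t <- fit_piecewise(profile, reference, window = 100L, max_offset = 20L,
                       roi = region_of_interest(1, 2000))
    expect_true(all(diff(t$anchors[, 1]) > 0))
    expect_true(all(diff(t$anchors[, 2]) > 0))
  }
})

test_that("align_all on an undistorted dataset returns identity transforms", {
  set.seed(22)
  p <- band_profile(3000L, seq(300, 2700, by = 60), runif(41, 300, 1500))
  tr <- mini_traces(cbind(p, p, p), cbind(p, p, p),
                    roi = region_of_interest(200, 2900))
  res <- align_all(tr)
  for (t in res$transforms) {
    expect_identical(t$linear$shift, 0)
    expect_identical(t$linear$scale, 1)
    expect_true(all(attr(t, "offsets") == 0))
  }
  expect_equal(res$report$shift, rep(0, 3))
})

test_that("the alignment report serializes as tab-delimited text", {
  rep_df <- data.frame(lane = c("a", "b"), batch = "b1",
                       shift = c(0, -12.3), scale = c(1, 1.0015),
                       score = c(1, 0.987), mean_abs_offset = c(0, 1.5))
  f <- tempfile(fileext = ".tsv")
  write_alignment_report(rep_df, f)
  back <- read.table(f, sep = "\t", header = TRUE)
  expect_equal(back$shift, c(0, -12.3))
  expect_equal(nrow(back), 2L)
})
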