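test_that("rolling-ball background removes constant and gradient backgrounds, keeps spots", {
  expect_equal(rolling_ball_background(matrix(5, 30, 30), 6),
               matrix(0, 30, 30))
  # small bright spot on constant background
  img <- gaussian_frame(40, 40, cbind(20, 20), amp = 1, bg = 2)
  out <- rolling_ball_background(img, 8)
  expect_true(all(out >= -1e-12))
  expect_equal(max(out), 1, tolerance = 0.05)   # spot preserved within 5%
  off_spot <- out[1:8, 1:8]
  expect_lt(max(off_spot), 0.02)                # background removed
  # gradient background + spot: residual background near zero
  grad <- outer(seq(0, 1, length.out = 40), seq(0, 0.5, length.out = 40),
                `+`)
  img2 <- grad + gaussian_frame(40, 40, cbind(20, 20), amp = 1)
  out2 <- rolling_ball_background(img2, 8)
  expect_lt(max(out2[1:8, 1:8]), 0.1)
  expect_equal(max(out2), 1, tolerance = 0.08)
  expect_error(rolling_ball_background(matrix(0, 10, 10), 25), "too large")
})

test_that("simple-ratio bleach correction flattens frame means and is idempotent", {
  set.seed(2)
  base <- matrix(1 + runif(400), 20, 20)
  stack <- array(0, dim = c(20, 20, 8))
  for (f in 1:8) stack[, , f] <- base * exp(-0.05 * (f - 1))
  corr <- bleach_correct_simple_ratio(stack)
  mus <- apply(corr, 3, mean)
  expect_equal(mus, rep(mean(base), 8), tolerance = 1e-6)
  expect_equal(bleach_correct_simple_ratio(corr), corr, tolerance = 1e-12)
  # no bleaching: unchanged
  flat <- array(rep(base, 3), dim = c(20, 20, 3))
  expect_equal(bleach_correct_simple_ratio(flat), flat)
  bad <- stack; bad[, , 2] <- 0
  expect_error(bleach_correct_simple_ratio(bad), "positive frame means")
})

test_that("1-1-1 running mean smooths interiors and averages pairs at edges", {
  expect_equal(running_mean_111(rep(4, 10)), rep(4, 10))
  expect_equal(running_mean_111(c(0, 3, 0)), c(1.5, 1, 1.5))
  ramp <- seq(2, 20, by = 2)
  sm <- running_mean_111(ramp)
  expect_equal(sm[2:9], ramp[2:9])  # linear: interior unchanged
  expect_equal(sm[1], mean(ramp[1:2]))
  expect_error(running_mean_111(c(1, 2)), ">= 3")
})

test_that("median-of-minima background is the median of per-trajectory minima", {
  expect_equal(median_minima_background(list(c(5, 2, 9), c(4, 7), c(6, 8))),
               4)
  expect_equal(median_minima_background(list(c(3, 1, 2))), 1)
  # robust to one outlier trajectory
  clean <- list(c(2, 5), c(3, 6), c(2.5, 4))
  expect_equal(median_minima_background(c(clean, list(c(100, 200)))),
               median(c(2, 3, 2.5, 100)))
})

test_that("dataset scaling sets each experiment's brightest strain to 1 and averages across experiments", {
  pk <- data.frame(
    strain = rep(c("wt", "mut"), each = 4),
    experiment = rep(c("e1", "e1", "e2", "e2"), 2),
    corrected_peak = c(100, 100, 120, 120, 71, 71, 90, 90))
  s <- scale_dataset(pk)
  expect_equal(s$mean_peak_AU[s$strain == "wt"], 1.0)
  expect_equal(s$mean_peak_AU[s$strain == "mut"],
               mean(c(71 / 100, 90 / 120)))
  expect_equal(s$n_events, c(4, 4))
  expect_equal(s$n_experiments, c(2, 2))
  # all strains identical: every summary 1.0
  pk2 <- data.frame(strain = rep(c("a", "b"), 2),
                    experiment = rep(c("e1", "e2"), each = 2),
                    corrected_peak = 50)
  expect_equal(scale_dataset(pk2)$mean_peak_AU, c(1, 1))
  expect_error(scale_dataset(pk[0, ]), "empty")
})

test_that("peak records recover noise-free amplitudes", {
  # plateau of >= 3 frame-aligned samples: the 1-1-1 smoothed maximum equals
  # the amplitude and recovery is exact
  trs <- lapply(1:4, function(i) {
    k <- patch_kinetics(20, 5, 4, 5, amplitude = 0.5 + 0.1 * i,
                        baseline = 0.1)
    v <- kinetic_template(k, 0:59)
    patch_trajectory(data.frame(frame = 0:59, x = 0, y = 0, intensity = v),
                     id = i)
  })
  pk <- peak_records(trs, strain = "s")
  expect_equal(pk$background, rep(0.1, 4))
  expect_equal(pk$corrected_peak, 0.5 + 0.1 * (1:4), tolerance = 1e-12)
  # preset trajectories (2 s plateau): smoothing may shave the peak slightly
  ts <- simulate_trajectories("WT-Bzz1", 12, seed = 31, noise_sigma = 0)
  pk2 <- peak_records(ts, strain = "WT-Bzz1")
  expect_equal(pk2$background, rep(0.1, 12))
  expect_equal(pk2$corrected_peak, ts$truth$amplitude, tolerance = 0.02)
})

test_that("dataset scaling absorbs a global gain applied to one experiment", {
  set.seed(6)
  mk <- function(gain, exp_label) {
    rbind(
      data.frame(strain = "wt", experiment = exp_label,
                 corrected_peak = gain * rnorm(50, 1.0, 0.1)),
      data.frame(strain = "dim", experiment = exp_label,
                 corrected_peak = gain * rnorm(50, 0.7, 0.1)))
  }
  s_ref <- scale_dataset(rbind(mk(1, "e1"), mk(1, "e2")))
  set.seed(6)
  s_gain <- scale_dataset(rbind(mk(1, "e1"), mk(1, "e2")))
  # same draws, second experiment scaled by 13x after regeneration
  set.seed(6)
  a <- mk(1, "e1"); b <- mk(1, "e2"); b$corrected_peak <- 13 * b$corrected_peak
  s_gain <- scale_dataset(rbind(a, b))
  expect_equal(s_gain$mean_peak_AU, s_ref$mean_peak_AU, tolerance = 1e-12)
})
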