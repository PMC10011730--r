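test_that("a single noise-free Gaussian spot is localized within 0.1 px", {
  img <- gaussian_frame(60, 60, cbind(20.0, 30.0), amp = 1, bg = 0.1)
  d <- detect_particles(img, spot_radius = 3)
  expect_equal(nrow(d), 1)
  expect_lt(abs(d$x - 20.0), 0.1)
  expect_lt(abs(d$y - 30.0), 0.1)
})

test_that("sub-pixel centers are localized within 0.1 px", {
  img <- gaussian_frame(60, 60, cbind(20.4, 29.7), amp = 1, bg = 0)
  d <- detect_particles(img, spot_radius = 3)
  expect_equal(nrow(d), 1)
  expect_lt(abs(d$x - 20.4), 0.1)
  expect_lt(abs(d$y - 29.7), 0.1)
})

test_that("two spots separated by 4x the radius give exactly two detections", {
  img <- gaussian_frame(60, 60, rbind(c(20, 20), c(32, 20)), amp = 1)
  d <- detect_particles(img, spot_radius = 3)
  expect_equal(nrow(d), 2)
})

test_that("flat and empty images give zero detections without error", {
  expect_equal(nrow(detect_particles(matrix(0, 20, 20), 3)), 0)
  expect_equal(nrow(detect_particles(matrix(5, 20, 20), 3)), 0)
})

test_that("a moving spot links into one trajectory", {
  det <- do.call(rbind, lapply(0:9, function(f)
    data.frame(frame = f, x = 10 + f, y = 10, intensity = 1)))
  trajs <- link_trajectories(det, max_displacement = 3)
  expect_length(trajs, 1)
  expect_equal(nrow(trajs[[1]]$detections), 10)
})

test_that("two stationary distant spots keep their identities", {
  det <- do.call(rbind, lapply(0:5, function(f)
    data.frame(frame = f, x = c(5, 25), y = c(5, 25),
               intensity = c(1, 2))))
  trajs <- link_trajectories(det, max_displacement = 3)
  expect_length(trajs, 2)
  for (tr in trajs) {
    expect_equal(nrow(tr$detections), 6)
    expect_equal(length(unique(tr$detections$x)), 1)  # no identity swap
  }
})

test_that("a one-frame disappearance is bridged when max_gap allows", {
  frames <- c(0, 1, 2, 4, 5)  # frame 3 missing
  det <- data.frame(frame = frames, x = 10, y = 10, intensity = 1)
  expect_length(link_trajectories(det, 3, max_gap = 1), 1)
  expect_length(link_trajectories(det, 3, max_gap = 0), 2)
})

test_that("linking conserves detections: each in exactly one trajectory", {
  set.seed(11)
  det <- do.call(rbind, lapply(0:7, function(f)
    data.frame(frame = f, x = runif(5, 0, 50), y = runif(5, 0, 50),
               intensity = runif(5))))
  trajs <- link_trajectories(det, max_displacement = 4, max_gap = 1)
  linked <- do.call(rbind, lapply(trajs, function(tr) tr$detections))
  expect_equal(nrow(linked), nrow(det))
  key <- function(d) sort(sprintf("%d|%.6f|%.6f", d$frame, d$x, d$y))
  expect_identical(key(linked), key(det))
})

test_that("greedy linking equals exhaustive optimal assignment on sparse scenes", {
  # regime of the movies: inter-patch spacing larger than per-frame motion
  set.seed(7)
  for (rep in 1:25) {
    k <- sample(1:4, 1)
    base <- data.frame(x = runif(k, 0, 100), y = runif(k, 0, 100))
    while (k > 1 && min(dist(base)) < 12) {
      base <- data.frame(x = runif(k, 0, 100), y = runif(k, 0, 100))
    }
    p1 <- base
    p2 <- data.frame(x = base$x + runif(k, -2, 2),
                     y = base$y + runif(k, -2, 2))
    det <- rbind(cbind(frame = 0L, p1, intensity = 1),
                 cbind(frame = 1L, p2, intensity = 1))
    trajs <- link_trajectories(det, max_displacement = 3)
    greedy_links <- link_set(trajs)
    oracle <- optimal_assignment(p1, p2, max_disp = 3)
    oracle_links <- sort(vapply(oracle, function(pr)
      sprintf("0:%.4f,%.4f->1:%.4f,%.4f", p1$x[pr[1]], p1$y[pr[1]],
              p2$x[pr[2]], p2$y[pr[2]]), character(1)))
    expect_identical(greedy_links, oracle_links)
  }
})

test_that("noise-free rendered movies yield exact lifetime recovery", {
  mv <- render_movie(scene_from_preset("Myo5", 9, seed = 21,
                                       noise_sigma = 0))
  trajs <- track_movie(mv, spot_radius = 3, max_displacement = 3,
                       max_gap = 1, min_frames = 3)
  expect_length(trajs, 9)
  lt <- sort(vapply(trajs, lifetime, numeric(1)))
  # true event occupies exactly `lifetime` frames for non-integer onsets
  expect_equal(lt, rep(10, 9))
})
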