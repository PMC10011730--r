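cell <- cell_record(x = 10, y = 10, radius = 2, membrane_band = 0.3)

boundary_track <- function(frames, dt = 10)
  patch_trajectory(data.frame(frame = frames, x = 10 + 1.9, y = 10,
                              intensity = 1), frame_interval = dt)

test_that("membrane-hugging tracks classify by lifetime, interior tracks as cytoplasmic", {
  movie <- 290
  # spans the whole movie -> persistent
  expect_equal(assign_patch_class(boundary_track(0:29), cell, movie),
               "persistent-PM")
  # 30 s of a 290 s movie -> transient
  expect_equal(assign_patch_class(boundary_track(0:2), cell, movie),
               "transient-PM")
  # interior track 1 um from the boundary -> cytoplasmic
  inner <- patch_trajectory(data.frame(frame = 0:5, x = 11, y = 10,
                                       intensity = 1), frame_interval = 10)
  expect_equal(assign_patch_class(inner, cell, movie), "cytoplasmic")
  # outside the cell -> unassigned
  outer_tr <- patch_trajectory(data.frame(frame = 0:5, x = 15, y = 10,
                                          intensity = 1),
                               frame_interval = 10)
  expect_equal(assign_patch_class(outer_tr, cell, movie), "unassigned")
  # too short for transient -> discarded
  stub <- patch_trajectory(data.frame(frame = 0:1, x = 11.9, y = 10,
                                      intensity = 1), frame_interval = 10)
  expect_equal(assign_patch_class(stub, cell, movie, min_frames = 3),
               "discarded")
})

test_that("per-cell summaries count occurrence fractions, not patch fractions", {
  asg <- data.frame(
    cell_id = c(1, 1, 1, 2, 2, 3, 4, 5),
    class = c("persistent-PM", "persistent-PM", "cytoplasmic",
              "persistent-PM", "transient-PM", "persistent-PM",
              "discarded", "unassigned"))
  s <- summarize_cells(asg, cells = 10, condition = "demo")
  expect_equal(s$fraction_persistent_pm, 0.3)  # cells 1, 2, 3
  expect_equal(s$fraction_transient_pm, 0.1)
  expect_equal(s$fraction_cytoplasmic, 0.1)
  expect_equal(s$patches_per_cell, 6 / 10)     # discarded/unassigned dropped
  # no patches at all
  s0 <- summarize_cells(asg[0, ], cells = 5)
  expect_equal(s0$fraction_persistent_pm, 0)
  expect_equal(s0$patches_per_cell, 0)
})

test_that("class fractions are recovered within the binomial CI on a 300-cell population", {
  probs <- c(0.8, 0.3, 0.5)
  pop <- simulate_cell_population(300, probs, seed = 5)
  cl <- classify_population(pop, movie_duration = 290)
  truth_frac <- vapply(c("persistent-PM", "transient-PM", "cytoplasmic"),
                       function(k)
                         length(unique(pop$truth$cell_id[
                           pop$truth$true_class == k])) / 300, numeric(1))
  got <- unlist(cl$summary[c("fraction_persistent_pm",
                             "fraction_transient_pm",
                             "fraction_cytoplasmic")])
  # classification itself is exact on the generator's geometry
  expect_equal(unname(got), unname(truth_frac))
  # and the generated fractions sit inside the binomial 95% CI of the probs
  for (i in 1:3) {
    half <- 1.96 * sqrt(probs[i] * (1 - probs[i]) / 300)
    expect_lt(abs(truth_frac[i] - probs[i]), half + 1e-12)
  }
})

test_that("class-fraction recovery is unbiased over repeated populations", {
  probs <- c(0.8, 0.3, 0.5)
  seeds <- 1:25
  rec <- sapply(seeds, function(s) {
    pop <- simulate_cell_population(120, probs, seed = s)
    cl <- classify_population(pop, movie_duration = 290)
    unlist(cl$summary[c("fraction_persistent_pm", "fraction_transient_pm",
                        "fraction_cytoplasmic")])
  })
  bias <- rowMeans(rec) - probs
  expect_true(all(abs(bias) < 0.02))
})

test_that("scission detection fires on the drop+movement signature and never on pure growth", {
  # stationary constant-intensity track: absent
  flat <- patch_trajectory(data.frame(frame = 0:20, x = 5, y = 5,
                                      intensity = 1), frame_interval = 1)
  expect_true(is.na(detect_scission(flat)))
  # monotone-assembling stationary track: absent
  grow <- patch_trajectory(data.frame(frame = 0:20, x = 5, y = 5,
                                      intensity = seq(0.1, 1, length.out = 21)),
                           frame_interval = 1)
  expect_true(is.na(detect_scission(grow)))
  # constructed scission at frame 10: intensity collapse + 0.1 um/frame move
  n <- 21
  inten <- c(seq(0.2, 1, length.out = 11), seq(0.8, 0.1, length.out = 10))
  x <- c(rep(5, 11), 5 + cumsum(rep(0.1, 10)))
  tr <- patch_trajectory(data.frame(frame = 0:20, x = x, y = 5,
                                    intensity = inten), frame_interval = 1)
  # detected within the first fast-and-dropped step (sub-frame refined)
  det <- detect_scission(tr)
  expect_gte(det, 11)
  expect_lt(det, 12)
})

test_that("trajectory onset extrapolation is unbiased for linear assembly", {
  ts <- simulate_trajectories("Rvs167-WT", 30, seed = 3, noise_sigma = 0)
  on_hat <- vapply(ts$trajectories, trajectory_onset, numeric(1))
  expect_lt(max(abs(on_hat - ts$truth$onset)), 0.6)
  ts8 <- simulate_trajectories("Rvs167-abp1SH3D", 30, seed = 3,
                               noise_sigma = 0)
  on8 <- vapply(ts8$trajectories, trajectory_onset, numeric(1))
  # slower assembly (8 s vs 5 s) does not bias the extrapolated onset
  expect_lt(abs(median(on8 - ts8$truth$onset) -
                  median(on_hat - ts$truth$onset)), 0.3)
})

test_that("recovered scission delay between Rvs167 presets matches the 3 s ground truth", {
  rel <- function(ts) vapply(ts$trajectories, function(tr)
    detect_scission(tr) - trajectory_onset(tr), numeric(1))
  wt <- simulate_trajectories("Rvs167-WT", 60, seed = 19)
  mu <- simulate_trajectories("Rvs167-abp1SH3D", 60, seed = 20)
  rwt <- rel(wt); rmu <- rel(mu)
  expect_lt(mean(is.na(rwt)), 0.05)
  expect_lt(mean(is.na(rmu)), 0.05)
  delay <- median(rmu, na.rm = TRUE) - median(rwt, na.rm = TRUE)
  expect_lt(abs(delay - 3), 1 + 1e-9)
})
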