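sg_trial <- list(condition = "standard_guilty", item_type = "irrelevant")
cm_probe <- list(condition = "countermeasures", item_type = "probe")

test_that("planned fixation counts reproduce the emulated condition means", {
  set.seed(21)
  n_sg <- replicate(6000, nrow(simulate_scanpath(sg_trial)) - 1L)
  expect_equal(mean(n_sg), 1.95, tolerance = 0.05)
  set.seed(22)
  n_cm <- replicate(2500, nrow(simulate_scanpath(cm_probe)) - 1L)
  expect_equal(mean(n_cm), 9.8, tolerance = 0.05)
})

test_that("zero effects make probe and irrelevant trials indistinguishable", {
  set.seed(23)
  eff0 <- zero_effects()
  afd_of <- function(item) {
    tr <- list(condition = "standard_guilty", item_type = item)
    replicate(2000, {
      p <- simulate_scanpath(tr, effects = eff0)
      mean(p$duration[-1])
    })
  }
  a_probe <- afd_of("probe"); a_irr <- afd_of("irrelevant")
  expect_gt(suppressWarnings(stats::ks.test(a_probe, a_irr)$p.value), 0.01)
})

test_that("probe shifts move durations and counts as configured", {
  set.seed(24)
  eff <- familiarity_effects(afd_effect = 1.5, afd_effect_sd = 0)
  probe_tr <- list(condition = "standard_guilty", item_type = "probe")
  a_probe <- replicate(1500, {
    p <- simulate_scanpath(probe_tr, effects = eff)
    mean(p$duration[-1])
  })
  a_irr <- replicate(1500, {
    p <- simulate_scanpath(sg_trial, effects = eff)
    mean(p$duration[-1])
  })
  d_hat <- (mean(a_probe) - mean(a_irr)) / sd(a_irr)
  expect_equal(d_hat, 1.5, tolerance = 0.25)
})

test_that("the CM model walks the instructed sequence", {
  set.seed(25)
  params <- generative_params(cm_skip = c(forehead = 0, right_ear = 0,
                                          right_eye = 0, left_eye = 0,
                                          left_ear = 0, nose = 0, mouth = 0,
                                          chin = 0))
  p <- simulate_scanpath(list(condition = "countermeasures",
                              item_type = "irrelevant"), params)
  seq8 <- params$cm_sequence
  k <- nrow(p) - 1L
  expect_identical(p$region[-1],
                   rep(seq8, length.out = k))
})

test_that("rendering honours durations, counts and the onset convention", {
  plan <- data.frame(region = "nose", cx = 700, cy = 450, duration = 200)
  params <- generative_params(noise_sd = 0, dropout = 0)
  set.seed(26)
  sm <- render_samples(plan, params)
  expect_identical(nrow(sm), 12L)  # ceiling(200 / 16.7)
  expect_true(all(sm$x == 700 & sm$y == 450))
  expect_error(render_samples(plan[0, ], params), "plan")
  # with a leading cross fixation, its samples all precede stimulus onset
  plan2 <- rbind(data.frame(region = "cross", cx = 720, cy = 450,
                            duration = 500), plan)
  sm2 <- render_samples(plan2, params)
  expect_identical(sum(sm2$t < 0), 30L)
  expect_identical(max(sm2$t[seq_len(30)]), -1000 / 60)
})

test_that("render + detect round-trip recovers planned fixations exactly", {
  params <- generative_params(noise_sd = 0, dropout = 0)
  set.seed(27)
  for (case in 1:60) {
    trial <- list(
      condition = sample(c("standard_guilty", "countermeasures"), 1),
      item_type = sample(c("irrelevant", "probe", "target"), 1))
    plan <- simulate_scanpath(trial, params)
    sm <- render_samples(plan, params)
    fx <- detect_fixations(sm)
    expect_identical(nrow(fx), nrow(plan))
    # post-onset fixation count is the planned count
    expect_identical(sum(fx$onset >= 0), nrow(plan) - 1L)
    # centroids near the plan (trailing saccade samples may be absorbed
    # into a window, pulling the centroid slightly toward the next target)
    expect_true(all(abs(fx$cx - plan$cx) + abs(fx$cy - plan$cy) < 40))
    # durations at least the sample-quantised planned durations
    expect_true(all(fx$duration >=
                      ceiling(plan$duration / (1000 / 60)) * 1000 / 60 -
                      1e-9))
  }
})

test_that("response errors follow the per-item-type rates", {
  p0 <- generative_params(error_rates = c(probe = 0, irrelevant = 0,
                                          target = 0, buffer = 0))
  set.seed(28)
  expect_true(all(replicate(200, simulate_response("probe", p0)$correct)))
  p <- generative_params()
  set.seed(29)
  err_p <- mean(!replicate(12000, simulate_response("probe", p)$correct))
  expect_lt(abs(err_p - 23 / 288), 0.01)
  err_i <- mean(!replicate(12000,
                           simulate_response("irrelevant", p)$correct))
  expect_lt(abs(err_i - 17 / 1152), 0.005)
  # targets require a yes; an error is a "no"
  set.seed(30)
  r <- simulate_response("target", p0)
  expect_identical(r$answer, "yes")
})

test_that("cohort generation is deterministic and complete", {
  cfg <- study_config(n_per_group = 2)
  c1 <- generate_cohort(cfg, seed = 31)
  expect_identical(sort(unique(c1$trials$participant)),
                   sort(unique(c1$schedule$participant)))
  expect_identical(nrow(c1$trials), 4L * 80L)
  c2 <- generate_cohort(cfg, seed = 31)
  expect_identical(c1$samples, c2$samples)
  expect_identical(c1$trials, c2$trials)
  c3 <- generate_cohort(cfg, seed = 32)
  expect_false(identical(c1$schedule$image_id, c3$schedule$image_id))
  # written files are reproducible byte for byte
  d1 <- tempfile(); d2 <- tempfile()
  generate_cohort(cfg, seed = 31, dir = d1)
  generate_cohort(cfg, seed = 31, dir = d2)
  expect_identical(readLines(file.path(d1, "raw_samples.csv")),
                   readLines(file.path(d2, "raw_samples.csv")))
  expect_identical(readLines(file.path(d1, "trials.csv")),
                   readLines(file.path(d2, "trials.csv")))
  unlink(c(d1, d2), recursive = TRUE)
})
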