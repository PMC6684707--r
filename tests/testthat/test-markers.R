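lay <- face_layout()
nose_pt <- c(mean(lay$regions$nose[c("xmin", "xmax")]),
             mean(lay$regions$nose[c("ymin", "ymax")]))

test_that("a single nose fixation gives the canonical marker vector", {
  fx <- data.frame(onset = 10, duration = 200, cx = nose_pt[1],
                   cy = nose_pt[2])
  mk <- compute_markers(fx, lay)
  expect_identical(mk$num_fixations, 1L)
  expect_identical(mk$ias_visited, 1L)
  expect_equal(mk$prop_inner, 1)
  expect_equal(mk$prop_nose, 1)
  expect_equal(mk$afd, 200)
  expect_equal(mk$first_afd, 200)
  expect_true(mk$valid)
})

test_that("AFD is total fixation time over fixation count", {
  fx <- data.frame(onset = seq(0, 800, by = 200),
                   duration = c(100, 150, 200, 250, 300),
                   cx = nose_pt[1], cy = nose_pt[2])
  expect_equal(compute_markers(fx, lay)$afd, 200)
})

test_that("the pre-onset (cross) fixation is excluded from markers", {
  fx <- data.frame(onset = c(-500, 20, 300),
                   duration = c(500, 150, 250),
                   cx = c(720, nose_pt[1], 100),
                   cy = c(450, nose_pt[2], 100))
  mk <- compute_markers(fx, lay)
  expect_identical(mk$num_fixations, 2L)
  expect_equal(mk$first_afd, 150)
  expect_equal(mk$afd, 200)
  expect_equal(mk$prop_inner, 0.5)   # the off-face fixation stays in the
  expect_equal(mk$prop_outer, 0)     # denominator but adds no IA
  expect_identical(mk$ias_visited, 1L)
})

test_that("no post-onset fixation flags the trial invalid", {
  fx <- data.frame(onset = -400, duration = 380, cx = 720, cy = 450)
  mk <- compute_markers(fx, lay)
  expect_false(mk$valid)
  expect_identical(mk$reason, "no_fixations")
  expect_identical(mk$num_fixations, 0L)
})

test_that("markers equal an independent tally on random fixation lists", {
  set.seed(41)
  for (case in 1:50) {
    n <- sample(1:12, 1)
    fx <- data.frame(onset = sort(runif(n, -300, 1500)),
                     duration = runif(n, 80, 600),
                     cx = runif(n, 0, 1440), cy = runif(n, 0, 900))
    mk <- compute_markers(fx, lay)
    post <- fx[fx$onset >= 0, ]
    if (nrow(post) == 0) {
      expect_false(mk$valid)
      next
    }
    lab <- assign_region(post$cx, post$cy, lay)
    ias <- c("left_eye", "right_eye", "nose", "mouth", "outer")
    expect_identical(mk$num_fixations, nrow(post))
    expect_identical(mk$ias_visited, length(intersect(ias, lab)))
    expect_equal(mk$afd, sum(post$duration) / nrow(post))
    expect_equal(mk$first_afd, post$duration[1])
    expect_equal(mk$prop_inner,
                 sum(lab %in% c("left_eye", "right_eye", "nose", "mouth")) /
                   nrow(post))
    expect_equal(mk$prop_inner, mk$prop_eyes + mk$prop_nose + mk$prop_mouth)
    # shares over all six labels sum to one
    off <- mean(lab == "off_face")
    expect_equal(mk$prop_inner + mk$prop_outer + off, 1)
    expect_gte(mk$first_afd, min(post$duration))
    expect_lte(mk$first_afd, max(post$duration))
  }
})

test_that("marker identities hold on a generated cohort", {
  coh <- cached_cohort("small", generate_cohort(study_config(n_per_group = 3),
                                                seed = 42))
  fx <- detect_fixations_cohort(coh$samples)
  mk <- compute_marker_table(fx, coh$trials, lay)
  expect_identical(nrow(mk), nrow(coh$trials))
  ok <- mk$valid
  expect_true(all(mk$prop_inner[ok] >= 0 & mk$prop_inner[ok] <= 1))
  expect_equal(mk$prop_inner[ok],
               mk$prop_eyes[ok] + mk$prop_nose[ok] + mk$prop_mouth[ok])
  expect_true(all(mk$afd[ok] > 0))
  expect_true(all(mk$num_fixations[ok] >= 1))
})

test_that("trial exclusions follow the rules and conserve counts", {
  coh <- cached_cohort("small", generate_cohort(study_config(n_per_group = 3),
                                                seed = 42))
  fx <- detect_fixations_cohort(coh$samples)
  mk <- compute_marker_table(fx, coh$trials, lay)
  flt <- filter_trials(coh$trials, mk)
  expect_identical(nrow(flt$retained) + nrow(flt$exclusions), nrow(mk))
  expect_false(any(flt$retained$item_type == "buffer"))
  expect_true(all(flt$exclusions$reason %in%
                    c("buffer", "incorrect_probe", "incorrect_irrelevant",
                      "incorrect_target", "no_fixations")))
  # every buffer trial is excluded as such
  expect_identical(sum(flt$exclusions$reason == "buffer"),
                   sum(coh$trials$item_type == "buffer"))
  # an incorrect probe ("yes" to the denied face) is excluded as such
  tr2 <- coh$trials
  probe_row <- which(tr2$item_type == "probe")[1]
  tr2$correct[probe_row] <- FALSE
  tr2$answer[probe_row] <- "yes"
  flt2 <- filter_trials(tr2, mk)
  key <- paste(tr2$participant, tr2$block, tr2$trial)[probe_row]
  ekey <- paste(flt2$exclusions$participant, flt2$exclusions$block,
                flt2$exclusions$trial)
  expect_identical(flt2$exclusions$reason[ekey == key], "incorrect_probe")
})

test_that("all-correct responses leave only buffer/empty exclusions", {
  coh <- cached_cohort("small", generate_cohort(study_config(n_per_group = 3),
                                                seed = 42))
  fx <- detect_fixations_cohort(coh$samples)
  mk <- compute_marker_table(fx, coh$trials, lay)
  tr <- coh$trials
  tr$correct <- TRUE
  flt <- filter_trials(tr, mk)
  expect_true(all(flt$exclusions$reason %in% c("buffer", "no_fixations")))
})

test_that("mismatched keys are rejected", {
  coh <- cached_cohort("small", generate_cohort(study_config(n_per_group = 3),
                                                seed = 42))
  fx <- detect_fixations_cohort(coh$samples)
  mk <- compute_marker_table(fx, coh$trials, lay)
  expect_error(filter_trials(coh$trials[-1, ], mk), "absent")
})
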