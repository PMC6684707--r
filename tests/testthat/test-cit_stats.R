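test_that("block standardization matches hand arithmetic", {
  set.seed(51)
  # probe equal to the retained mean gives z = 0
  irr <- c(1, 2, 3, 4, 5, 6)
  sb <- standardize_block(3.5, irr, n_reps = 50, details = TRUE)
  for (r in 1:50) {
    ret <- irr[-sb$removed[, r]]
    expect_equal(sb$m[r], mean(ret))
    expect_equal(sb$s[r], sd(ret))
    expect_equal(sb$z_probe[1, r], (3.5 - mean(ret)) / sd(ret))
    expect_equal(sb$z_innocent[, r],
                 (irr[sb$removed[, r]] - mean(ret)) / sd(ret))
    # retained irrelevants have mean 0 and SD 1 by construction
    z_ret <- (ret - sb$m[r]) / sb$s[r]
    expect_lt(abs(mean(z_ret)), 1e-9)
    expect_lt(abs(sd(z_ret) - 1), 1e-9)
  }
})

test_that("constant irrelevants flag the rep degenerate", {
  sb <- standardize_block(c(2, 2), rep(5, 8), n_reps = 3)
  expect_true(all(sb$degenerate))
  expect_true(all(is.na(sb$z_probe)))
  expect_error(standardize_block(numeric(0), 1:10), "probe")
  expect_error(standardize_block(1:3, 1:4), "irrelevant")
})

test_that("mean probe z over removals matches exhaustive enumeration", {
  irr <- 1:12
  probes <- c(14, 14, 14)
  # oracle: enumerate all C(12,3) = 220 removal sets
  combos <- utils::combn(12, 3)
  z_all <- apply(combos, 2, function(rm) {
    ret <- irr[-rm]
    c(probe = (14 - mean(ret)) / sd(ret),
      innocent = mean((irr[rm] - mean(ret)) / sd(ret)))
  })
  exact_probe <- mean(z_all["probe", ])
  exact_innocent <- mean(z_all["innocent", ])
  mc_se <- sd(z_all["probe", ]) / sqrt(1000)
  set.seed(52)
  sb <- standardize_block(probes, irr, n_reps = 1000)
  expect_lt(abs(mean(sb$z_probe) - exact_probe), 5 * mc_se)
  expect_lt(abs(mean(sb$z_innocent) - exact_innocent),
            5 * sd(z_all["innocent", ]) / sqrt(1000))
})

make_marker_frame <- function(n_part = 8, n_blocks = 4, n_probe = 3,
                              n_irr = 12, gen = function(n) rnorm(n)) {
  rows <- expand.grid(trial = seq_len(n_probe + n_irr),
                      block = seq_len(n_blocks),
                      participant = sprintf("P%02d", seq_len(n_part)))
  rows$item_type <- rep(c(rep("probe", n_probe), rep("irrelevant", n_irr)),
                        n_blocks * n_part)
  rows$condition <- "standard_guilty"
  rows$afd <- gen(nrow(rows))
  rows$num_fixations <- gen(nrow(rows))
  rows
}

# Recompute participant P01's block means under seed `seed` by replaying
# the same RNG stream order as resample_detection.
with_seed_oracle <- function(seed, block, mf, blk) {
  set.seed(seed)
  # resample_detection draws one sample.int(n, k) per block in order
  for (b in seq_len(block)) idx <- sample.int(12, 3)
  ret <- blk$afd[blk$item_type == "irrelevant"][-idx]
  (mean(blk$afd[blk$item_type == "probe"]) - mean(ret)) / sd(ret)
}

test_that("resampled scores are deterministic and correctly shaped", {
  set.seed(53)
  mf <- make_marker_frame()
  sc1 <- resample_detection(mf, c("afd", "num_fixations"), n_reps = 20,
                            seed = 7)
  sc2 <- resample_detection(mf, c("afd", "num_fixations"), n_reps = 20,
                            seed = 7)
  expect_identical(sc1$scores, sc2$scores)
  expect_identical(dim(sc1$scores$afd$z_probe), c(8L, 20L))
  # a single rep reproduces one standardize_block pass per block
  sc3 <- resample_detection(mf, "afd", n_reps = 1, seed = 8)
  p1 <- mf[mf$participant == "P01", ]
  zb <- numeric(4)
  for (b in 1:4) {
    blk <- p1[p1$block == b, ]
    sb <- with_seed_oracle(8, b, mf, blk)
    zb[b] <- sb
  }
  expect_equal(sc3$scores$afd$z_probe[1, 1], mean(zb))
})

test_that("Cohen's d matches hand values and is scale invariant", {
  # differences {1, 2, 3}: d = mean/SD = 2
  sc <- structure(list(scores = list(afd = list(
    z_probe = matrix(c(2, 4, 6), 3, 1),
    z_innocent = matrix(c(1, 2, 3), 3, 1))),
    participants = paste0("P", 1:3), markers = "afd", n_reps = 1L),
    class = "cit_scores")
  d <- cohens_d(sc, "afd", n_boot = 50, seed = 1)
  expect_equal(d$d, 2)
  # all differences zero: d defined as 0
  sc0 <- sc
  sc0$scores$afd$z_innocent <- sc0$scores$afd$z_probe
  expect_equal(cohens_d(sc0, "afd", n_boot = 10, seed = 1)$d, 0)
  # scale invariance through the whole resampling pipeline
  set.seed(54)
  mf <- make_marker_frame()
  mf3 <- mf; mf3$afd <- mf3$afd * 3
  d1 <- cohens_d(resample_detection(mf, "afd", 50, seed = 9), "afd",
                 n_boot = 20, seed = 2)
  d3 <- cohens_d(resample_detection(mf3, "afd", 50, seed = 9), "afd",
                 n_boot = 20, seed = 2)
  expect_equal(d1$d, d3$d, tolerance = 1e-12)
  expect_true(d1$ci[1] <= d1$d && d1$d <= d1$ci[2])
})

test_that("AUC equals exhaustive cross-pair counting", {
  # degenerate cases
  sc <- function(g, h) structure(list(scores = list(m = list(
    z_probe = matrix(g), z_innocent = matrix(h))),
    participants = seq_along(g), markers = "m", n_reps = 1L),
    class = "cit_scores")
  expect_equal(roc_auc(sc(c(1, 2, 3), c(1, 2, 3)), "m", n_boot = 10,
                       seed = 1)$auc, 0.5)
  expect_equal(roc_auc(sc(c(5, 6), c(1, 2)), "m", n_boot = 10,
                       seed = 1)$auc, 1)
  set.seed(55)
  for (case in 1:200) {
    n <- sample(3:24, 1)
    g <- round(rnorm(n), sample(0:2, 1))  # rounding induces ties
    h <- round(rnorm(n), 1)
    got <- roc_auc(sc(g, h), "m", n_boot = 2, seed = 1)$auc
    expect_equal(got, oracle_auc(g, h), tolerance = 1e-12)
  }
})

test_that("direction percentages are a sign tally over participants", {
  sc <- structure(list(scores = list(afd = list(
    z_probe = matrix(c(2, 4, 6, 1), 4, 1),
    z_innocent = matrix(c(1, 2, 7, 1), 4, 1))),
    participants = paste0("P", 1:4), markers = "afd", n_reps = 1L),
    class = "cit_scores")
  expect_equal(direction_percentages(sc, "afd", 1), 50)   # 2 of 4 positive
  expect_equal(direction_percentages(sc, "afd", -1), 25)  # 1 negative
  expect_error(direction_percentages(sc, "afd", 0), "predicted_sign")
})

test_that("doubling reps shrinks the Monte-Carlo SE of d by about sqrt(2)", {
  set.seed(56)
  mf <- make_marker_frame(n_part = 6,
                          gen = function(n) rnorm(n, 0.2 *
                              rep(c(1, 0), c(3, 12))[seq_len(n) %% 15 + 1]))
  d_at <- function(reps, seed) {
    sc <- resample_detection(mf, "afd", reps, seed = seed)
    mean(apply(sc$scores$afd$z_probe - sc$scores$afd$z_innocent, 2,
               function(x) mean(x) / sd(x)))
  }
  d50 <- vapply(1:50, function(s) d_at(25, 1000 + s), 0)
  d100 <- vapply(1:50, function(s) d_at(50, 2000 + s), 0)
  ratio <- sd(d50) / sd(d100)
  expect_gt(ratio, 1.05)
  expect_lt(ratio, 2.0)
})

test_that("the cit_detect fit returns a coherent results object", {
  set.seed(57)
  mf <- make_marker_frame(n_part = 10)
  mf$ias_visited <- rnorm(nrow(mf))
  fit <- cit_detect(mf, markers = c("afd", "num_fixations"),
                    n_reps = 40, n_boot = 40, seed = 5)
  expect_s3_class(fit, "cit_detection")
  r <- fit$results
  expect_identical(nrow(r), 2L)
  expect_true(all(r$auc >= 0 & r$auc <= 1))
  expect_true(all(r$d_lo <= r$d & r$d <= r$d_hi))
  expect_true(all(r$auc_lo <= r$auc & r$auc <= r$auc_hi))
  expect_true(all(r$pct_direction >= 0 & r$pct_direction <= 100))
  # pure function of seed
  fit2 <- cit_detect(mf, markers = c("afd", "num_fixations"),
                     n_reps = 40, n_boot = 40, seed = 5)
  expect_identical(fit$results, fit2$results)
  # methods run
  expect_output(print(fit), "detection efficiency")
  expect_output(print(summary(fit)), "AUC")
  expect_identical(rownames(coef(fit))[1], "standard_guilty.afd")
})
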