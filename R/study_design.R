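#' Screen geometry of the presentation display
#'
#' Describes the physical display the stimuli were shown on. Pixels are
#' assumed square; the physical width is derived from the diagonal and the
#' resolution aspect ratio. The default is the 22-inch 1440 x 900 monitor
#' viewed at 70 cm used throughout the package.
#'
#' @param diagonal_in Screen diagonal in inches.
#' @param resolution Integer vector `c(horizontal, vertical)` in pixels.
#' @param distance_cm Viewing distance in cm.
#' @return An object of class `"screen_geometry"`: a list with the inputs
#'   plus `width_cm`, `height_cm` and `pitch_cm` (cm per pixel).
#' @examples
#' scr <- screen_geometry()
#' scr$pitch_cm
#' @export
screen_geometry <- function(diagonal_in = 22, resolution = c(1440L, 900L),
                            distance_cm = 70) {
  check_pos(diagonal_in, "diagonal_in")
  check_pos(distance_cm, "distance_cm")
  if (length(resolution) != 2L || any(!is.finite(resolution)) ||
      any(resolution <= 0))
    stop_bad_arg("resolution", "must be two positive pixel counts")
  diag_px <- sqrt(sum(as.numeric(resolution)^2))
  width_cm <- diagonal_in * 2.54 * resolution[1] / diag_px
  height_cm <- diagonal_in * 2.54 * resolution[2] / diag_px
  structure(list(diagonal_in = diagonal_in,
                 resolution_h = as.integer(resolution[1]),
                 resolution_v = as.integer(resolution[2]),
                 distance_cm = distance_cm,
                 width_cm = width_cm, height_cm = height_cm,
                 pitch_cm = width_cm / resolution[1]),
            class = "screen_geometry")
}

#' Visual angle subtended by a pixel extent
#'
#' Converts an on-screen extent in pixels to degrees of visual angle using
#' the full (non-small-angle) formula
#' \eqn{2 \arctan\{(e \cdot p / 2) / D\}}, where \eqn{e} is the extent in
#' pixels, \eqn{p} the pixel pitch and \eqn{D} the viewing distance.
#'
#' With the default geometry the 595 x 420 px face images subtend 15.9
#' degrees horizontally and 11.3 degrees vertically.
#'
#' @param extent_px Extent in pixels (>= 0); vectorised.
#' @param screen A [screen_geometry()] object.
#' @return Visual angle(s) in degrees.
#' @examples
#' round(visual_angle(c(595, 420)), 1)
#' @export
visual_angle <- function(extent_px, screen = screen_geometry()) {
  if (!inherits(screen, "screen_geometry"))
    stop_bad_arg("screen", "must be a screen_geometry object")
  if (any(!is.finite(extent_px)) || any(extent_px < 0))
    stop_bad_arg("extent_px", "must be finite and non-negative")
  2 * atan((extent_px * screen$pitch_cm / 2) / screen$distance_cm) * 180 / pi
}

#' Per-group sample size for a matched-pairs design
#'
#' Smallest integer \eqn{n} such that a one-sample t-test on standardized
#' difference scores (noncentrality \eqn{d\sqrt{n}}, \eqn{n-1} df) attains
#' the requested power at the requested alpha, computed with the noncentral
#' t distribution (no normal approximation). One-tailed by default.
#'
#' @param effect Standardized effect size \eqn{d_z} (> 0).
#' @param alpha Type-I error probability.
#' @param power Target power.
#' @param tails `"one"` or `"two"`.
#' @return Required participants per group (integer).
#' @examples
#' required_sample_size(0.7, 0.05, 0.95, "one")  # 24
#' @export
required_sample_size <- function(effect, alpha = 0.05, power = 0.95,
                                 tails = c("one", "two")) {
  if (!is.numeric(effect) || length(effect) != 1L || !is.finite(effect) ||
      effect <= 0)
    stop_bad_arg("effect", "must be a single finite positive number")
  check_prob(alpha, "alpha")
  check_prob(power, "power")
  tails <- match.arg(tails)
  a <- if (tails == "two") alpha / 2 else alpha
  n <- 2L
  repeat {
    if (power_paired_t(n, effect, alpha, tails) >= power) return(n)
    n <- n + 1L
    if (n > 1e6L) stop("sample-size search did not converge", call. = FALSE)
  }
}

#' Power of the matched-pairs t-test at a given sample size
#'
#' Exact power of the one-sample t-test on difference scores, using the
#' noncentral t distribution. For two tails the (negligible) probability
#' mass in the wrong-direction rejection region is included.
#'
#' @inheritParams required_sample_size
#' @param n Number of pairs (>= 2).
#' @return Power in (0, 1).
#' @export
power_paired_t <- function(n, effect, alpha = 0.05, tails = c("one", "two")) {
  tails <- match.arg(tails)
  if (!is.numeric(n) || any(n < 2))
    stop_bad_arg("n", "must be >= 2")
  check_prob(alpha, "alpha")
  ncp <- effect * sqrt(n)
  df <- n - 1
  if (tails == "one") {
    pt(qt(1 - alpha, df), df, ncp = ncp, lower.tail = FALSE)
  } else {
    crit <- qt(1 - alpha / 2, df)
    pt(crit, df, ncp = ncp, lower.tail = FALSE) + pt(-crit, df, ncp = ncp)
  }
}

#' Empirical power of the one-tailed paired t-test by simulation
#'
#' Draws `n_sim` experiments of `n` normal difference scores with mean
#' `effect` and unit SD, applies a one-sample t-test, and returns the
#' fraction rejecting. A Monte-Carlo check of [power_paired_t()].
#'
#' @inheritParams required_sample_size
#' @param n Pairs per experiment.
#' @param n_sim Number of simulated experiments.
#' @param seed Optional RNG seed.
#' @return Rejection rate (scalar).
#' @examples
#' empirical_power(24, 0.7, n_sim = 2000, seed = 1)
#' @export
empirical_power <- function(n, effect, alpha = 0.05,
                            tails = c("one", "two"), n_sim = 5000,
                            seed = NULL) {
  tails <- match.arg(tails)
  check_pos(n_sim, "n_sim")
  with_seed(seed, {
    x <- matrix(rnorm(n * n_sim, mean = effect, sd = 1), nrow = n)
    m <- colMeans(x)
    s <- sqrt(colSums((x - rep(m, each = n))^2) / (n - 1))
    tstat <- m / (s / sqrt(n))
    if (tails == "one") {
      mean(tstat > qt(1 - alpha, n - 1))
    } else {
      mean(abs(tstat) > qt(1 - alpha / 2, n - 1))
    }
  })
}

#' Study configuration for a single-probe sequential CIT
#'
#' Encodes the factorial design: two between-subject conditions
#' (standard-guilty `"SG"` and countermeasures `"CM"`), four blocks per
#' participant, and per block 2 unfamiliar buffers followed by 18 test
#' trials (12 irrelevants, 3 probe images of one identity, 3 target images
#' of a second identity) in random order, sampled at 60 Hz.
#'
#' @param n_per_group Participants per condition.
#' @param conditions Condition labels.
#' @param n_blocks Blocks per participant.
#' @param n_irrelevants,n_probes,n_targets,n_buffers Trials per block.
#' @param sampling_rate Tracker sampling rate, Hz.
#' @param screen A [screen_geometry()].
#' @return An object of class `"study_config"`.
#' @examples
#' cfg <- study_config()
#' cfg$n_irrelevants + cfg$n_probes + cfg$n_targets  # 18 test trials
#' @export
study_config <- function(n_per_group = 24L,
                         conditions = c("standard_guilty", "countermeasures"),
                         n_blocks = 4L, n_irrelevants = 12L, n_probes = 3L,
                         n_targets = 3L, n_buffers = 2L,
                         sampling_rate = 60, screen = screen_geometry()) {
  for (nm in c("n_per_group", "n_blocks", "n_irrelevants", "n_probes",
               "n_targets", "n_buffers")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0 ||
        v != round(v))
      stop_bad_arg(nm, "must be a non-negative integer")
  }
  if (n_per_group < 1) stop_bad_arg("n_per_group", "must be >= 1")
  if (n_irrelevants + n_probes + n_targets < 1)
    stop_bad_arg("n_irrelevants", "a block must contain at least one test trial")
  check_pos(sampling_rate, "sampling_rate")
  if (!length(conditions)) stop_bad_arg("conditions", "must be non-empty")
  structure(list(n_per_group = as.integer(n_per_group),
                 conditions = as.character(conditions),
                 n_blocks = as.integer(n_blocks),
                 n_irrelevants = as.integer(n_irrelevants),
                 n_probes = as.integer(n_probes),
                 n_targets = as.integer(n_targets),
                 n_buffers = as.integer(n_buffers),
                 sampling_rate = sampling_rate,
                 screen = screen),
            class = "study_config")
}

#' Build a seeded trial schedule
#'
#' Produces one row per trial for every participant in every condition.
#' Each block opens with the buffer trials, followed by the test trials in
#' a seeded random permutation. Irrelevant and buffer image ids are unique
#' within a session; probe and target ids repeat as different images of one
#' identity per block. The yes/no key mapping is counterbalanced by
#' participant parity and carried as a pass-through field.
#'
#' @param config A [study_config()].
#' @param seed RNG seed; identical seeds give identical schedules.
#' @return A data frame with columns `participant`, `condition`, `block`,
#'   `trial`, `item_type` (buffer/irrelevant/probe/target), `image_id`,
#'   `key_mapping`.
#' @examples
#' sched <- build_trial_schedule(study_config(), seed = 1)
#' table(sched$item_type) / (2 * 24)  # per-participant trial counts
#' @export
build_trial_schedule <- function(config = study_config(), seed = NULL) {
  if (!inherits(config, "study_config"))
    stop_bad_arg("config", "must be a study_config object")
  with_seed(seed, {
    out <- vector("list", length(config$conditions) * config$n_per_group)
    i <- 0L
    for (cond in config$conditions) {
      for (p in seq_len(config$n_per_group)) {
        i <- i + 1L
        out[[i]] <- schedule_one(config, cond, p)
      }
    }
    do.call(rbind, out)
  })
}

schedule_one <- function(config, cond, p) {
  pid <- sprintf("%s_%02d", abbreviate_condition(cond), p)
  key <- if (p %% 2L == 1L) "z_yes" else "m_yes"
  blocks <- vector("list", config$n_blocks)
  for (b in seq_len(config$n_blocks)) {
    test_types <- c(rep("irrelevant", config$n_irrelevants),
                    rep("probe", config$n_probes),
                    rep("target", config$n_targets))
    test_ids <- c(sprintf("irr_b%d_%02d", b, seq_len(config$n_irrelevants)),
                  sprintf("probe_id%d_img%d", b, seq_len(config$n_probes)),
                  sprintf("target_id%d_img%d", b, seq_len(config$n_targets)))
    ord <- sample.int(length(test_types))
    types <- c(rep("buffer", config$n_buffers), test_types[ord])
    ids <- c(sprintf("buffer_b%d_%02d", b, seq_len(config$n_buffers)),
             test_ids[ord])
    blocks[[b]] <- data.frame(participant = pid, condition = cond,
                              block = b, trial = seq_along(types),
                              item_type = types, image_id = ids,
                              key_mapping = key,
                              stringsAsFactors = FALSE)
  }
  do.call(rbind, blocks)
}

abbreviate_condition <- function(cond) {
  switch(cond,
         standard_guilty = "SG",
         countermeasures = "CM",
         toupper(substr(cond, 1, 2)))
}

#' @export
print.study_config <- function(x, ...) {
  cat("Single-probe CIT study design\n")
  cat(sprintf("  %d participants per group; conditions: %s\n",
              x$n_per_group, paste(x$conditions, collapse = ", ")))
  cat(sprintf("  %d blocks of %d buffers + %d irrelevants + %d probes + %d targets\n",
              x$n_blocks, x$n_buffers, x$n_irrelevants, x$n_probes,
              x$n_targets))
  cat(sprintf("  sampling rate %g Hz; screen %d x %d px\n",
              x$sampling_rate, x$screen$resolution_h, x$screen$resolution_v))
  invisible(x)
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf("%.0f-inch display, %d x %d px, viewed at %g cm (pitch %.4f cm/px)\n",
              x$diagonal_in, x$resolution_h, x$resolution_v, x$distance_cm,
              x$pitch_cm))
  invisible(x)
}
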