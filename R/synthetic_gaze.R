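#' Generative scanpath parameters
#'
#' Parameters of the generative model that stands in for recorded gaze
#' data. Fixation counts per trial are `1 + NegBin(mu, size)` (truncation
#' at one fixation); fixation durations are log-normal with a floor;
#' region selection is condition-specific: the standard-guilty (SG) group
#' draws regions from a categorical distribution (free viewing with few
#' fixations), the countermeasures (CM) group walks the instructed fixed
#' sequence forehead -> right ear -> right eye -> left eye -> left ear ->
#' nose -> mouth -> chin, skipping each station with a per-region
#' probability and cycling until the drawn fixation count is reached.
#'
#' Count means are calibrated to the study conditions the generator
#' emulates (about 2 fixations per trial under SG, about 10 under CM);
#' dispersion ("size") values reproduce the corresponding SDs (1.18 and
#' 3.6) through `Var = mu + mu^2/size` of the shifted negative binomial.
#'
#' @param count Per-condition list of `mean` (fixations per trial) and
#'   `size` (negative-binomial dispersion).
#' @param duration `median_ms`, `log_sd` and `floor_ms` of the log-normal
#'   fixation-duration model.
#' @param aoi_probs Named categorical probabilities over landing regions
#'   for SG trials (must sum to 1).
#' @param cm_sequence Instructed fixation sequence for CM trials.
#' @param cm_skip Per-region skip probability along the CM sequence.
#' @param noise_sd Coordinate noise SD, px.
#' @param dropout Per-sample probability of an invalid (lost) sample.
#' @param error_rates Named per-item-type response error probabilities.
#' @param cross_duration_ms Duration of the pre-stimulus central fixation.
#' @param saccade_samples Possible numbers of transition samples between
#'   fixations.
#' @param min_separation Minimum city-block distance (px) between
#'   consecutive planned centroids, so that planned fixations stay
#'   separable at the default dispersion threshold.
#' @return An object of class `"generative_params"`.
#' @export
generative_params <- function(
    count = list(standard_guilty = list(mean = 1.95, size = 2.04),
                 countermeasures = list(mean = 9.84, size = 19)),
    duration = list(median_ms = 250, log_sd = 0.35, floor_ms = 100),
    aoi_probs = c(right_eye = 0.16, left_eye = 0.16, nose = 0.25,
                  mouth = 0.01, outer = 0.32, off_face = 0.10),
    cm_sequence = c("forehead", "right_ear", "right_eye", "left_eye",
                    "left_ear", "nose", "mouth", "chin"),
    cm_skip = c(forehead = 0.1, right_ear = 0.1, right_eye = 0.1,
                left_eye = 0.1, left_ear = 0.1, nose = 0.1, mouth = 0.1,
                chin = 0.1),
    noise_sd = 8, dropout = 0.02,
    error_rates = c(probe = 23 / 288, irrelevant = 17 / 1152,
                    target = 0.05, buffer = 17 / 1152),
    cross_duration_ms = 500, saccade_samples = 1:2,
    min_separation = 110) {
  for (cond in names(count)) {
    if (count[[cond]]$mean < 1)
      stop_bad_arg("count", "mean fixation count must be >= 1")
    check_pos(count[[cond]]$size, "count$size")
  }
  check_pos(duration$median_ms, "duration$median_ms")
  check_pos(duration$log_sd, "duration$log_sd")
  check_pos(duration$floor_ms, "duration$floor_ms")
  if (abs(sum(aoi_probs) - 1) > 1e-8)
    stop_bad_arg("aoi_probs", "must sum to 1")
  if (any(aoi_probs < 0) || any(cm_skip < 0) || any(cm_skip > 1))
    stop_bad_arg("aoi_probs", "probabilities must lie in [0, 1]")
  check_prob(dropout, "dropout", open = FALSE)
  if (any(error_rates < 0) || any(error_rates > 1))
    stop_bad_arg("error_rates", "must lie in [0, 1]")
  check_pos(noise_sd + 1, "noise_sd")  # zero allowed
  if (noise_sd < 0) stop_bad_arg("noise_sd", "must be >= 0")
  structure(list(count = count, duration = duration, aoi_probs = aoi_probs,
                 cm_sequence = cm_sequence, cm_skip = cm_skip,
                 noise_sd = noise_sd, dropout = dropout,
                 error_rates = error_rates,
                 cross_duration_ms = cross_duration_ms,
                 saccade_samples = saccade_samples,
                 min_separation = min_separation),
            class = "generative_params")
}

#' Familiarity effects applied to probe trials
#'
#' Encodes how recognition of the familiar probe changes gaze behaviour
#' relative to unfamiliar irrelevants. With all fields zero, probe and
#' irrelevant trials are identically distributed.
#'
#' @param afd_effect Standardized shift (in within-condition per-trial AFD
#'   SD units, i.e. \eqn{d_z}) of probe-trial log fixation durations;
#'   positive means longer fixations on recognised faces. Default 0.7, the
#'   design effect size the study was powered for.
#' @param eyes_bias Additive probability shift toward the eye regions on
#'   probe trials; applies to the SG free-viewing model only.
#' @param inner_skip_bias Additive skip probability on the nose and mouth
#'   stations on probe trials; applies to the CM fixed-sequence model only.
#' @param fixcount_shift Additive shift of the mean fixation count on probe
#'   trials, per condition (scalar recycled). Defaults reproduce the
#'   emulated probe/irrelevant count means (+0.35 under SG, -0.02 under CM).
#' @param afd_effect_sd Between-participant SD of the AFD shift (same
#'   units). Individual effects are drawn once per participant, so a
#'   realistic fraction of participants shows no, or a reversed, duration
#'   marker.
#' @return An object of class `"familiarity_effects"`.
#' @seealso [zero_effects()] for the exact null.
#' @export
familiarity_effects <- function(afd_effect = 0.7, eyes_bias = 0.15,
                                inner_skip_bias = 0.2,
                                fixcount_shift = c(standard_guilty = 0.35,
                                                   countermeasures = -0.02),
                                afd_effect_sd = 0.9) {
  vals <- c(afd_effect, eyes_bias, inner_skip_bias, fixcount_shift,
            afd_effect_sd)
  if (any(!is.finite(vals)))
    stop_bad_arg("familiarity_effects", "all fields must be finite")
  if (afd_effect_sd < 0)
    stop_bad_arg("afd_effect_sd", "must be >= 0")
  structure(list(afd_effect = afd_effect, eyes_bias = eyes_bias,
                 inner_skip_bias = inner_skip_bias,
                 fixcount_shift = fixcount_shift,
                 afd_effect_sd = afd_effect_sd),
            class = "familiarity_effects")
}

#' Null familiarity effects
#'
#' All effect fields zero (including the between-participant SD): probe
#' and irrelevant trials are generated from identical distributions.
#' @return A [familiarity_effects()] object.
#' @export
zero_effects <- function() {
  familiarity_effects(afd_effect = 0, eyes_bias = 0, inner_skip_bias = 0,
                      fixcount_shift = c(standard_guilty = 0,
                                         countermeasures = 0),
                      afd_effect_sd = 0)
}

probe_count_shift <- function(effects, condition) {
  s <- effects$fixcount_shift
  if (length(s) == 1L && is.null(names(s))) return(unname(s))
  if (!is.null(names(s)) && condition %in% names(s))
    return(unname(s[[condition]]))
  unname(s[[1L]])
}

# Analytic per-trial AFD scale of irrelevant trials under `params` in
# `condition`: mean and SD of the mean of N iid log-normal durations,
# N ~ 1 + NegBin. Used to convert the standardized afd_effect into a
# log-scale duration shift.
afd_scale <- function(params, condition) {
  dm <- params$duration$median_ms
  ls <- params$duration$log_sd
  m_dur <- dm * exp(ls^2 / 2)
  v_dur <- m_dur^2 * (exp(ls^2) - 1)
  cp <- params$count[[condition]]
  mu <- max(cp$mean - 1, 1e-8)
  n <- 1:200
  pn <- stats::dnbinom(n - 1, mu = mu, size = cp$size)
  e_inv_n <- sum(pn / n) / sum(pn)
  list(mean = m_dur, sd = sqrt(v_dur * e_inv_n))
}

# Log-duration shift implementing a standardized AFD difference `theta`
# (in irrelevant per-trial AFD SD units). Durations are multiplied by
# exp(delta), so the mean AFD moves by m*(exp(delta)-1) = theta*s.
afd_log_shift <- function(theta, params, condition) {
  sc <- afd_scale(params, condition)
  log(pmax(1 + theta * sc$sd / sc$mean, 0.05))
}

#' Simulate the planned scanpath of one trial
#'
#' Draws the planned fixation sequence for a single trial: a central
#' fixation anchored at the fixation cross that ends at stimulus onset,
#' followed by the condition's region sequence with log-normal durations.
#' Probe trials receive the familiarity effect shifts. Consecutive planned
#' centroids are kept at least `min_separation` px apart (city-block), so
#' every planned fixation is recoverable by I-DT at the default thresholds.
#'
#' @param trial A list or one-row data frame with at least `condition` and
#'   `item_type`.
#' @param params A [generative_params()].
#' @param effects A [familiarity_effects()].
#' @param layout A [face_layout()].
#' @param screen A [screen_geometry()] (fixation cross at its centre).
#' @param afd_theta Participant-level AFD shift; defaults to
#'   `effects$afd_effect` (no heterogeneity).
#' @param afd_log_delta Optional precomputed log-duration shift for probe
#'   trials (overrides the conversion of `afd_theta`); used internally to
#'   avoid recomputing the analytic AFD scale per trial.
#' @return Data frame of planned fixations: `region`, `cx`, `cy`,
#'   `duration` (ms), with the pre-onset central fixation in row one
#'   (`region == "cross"`).
#' @export
simulate_scanpath <- function(trial, params = generative_params(),
                              effects = familiarity_effects(),
                              layout = face_layout(),
                              screen = screen_geometry(),
                              afd_theta = NULL, afd_log_delta = NULL) {
  condition <- as.character(trial$condition)
  item_type <- as.character(trial$item_type)
  if (!condition %in% names(params$count))
    stop_bad_arg("trial", sprintf("no count model for condition '%s'",
                                  condition))
  is_probe <- identical(item_type, "probe")
  cp <- params$count[[condition]]
  mu <- cp$mean - 1
  if (is_probe) mu <- mu + probe_count_shift(effects, condition)
  n_fix <- 1L + rnbinom(1L, mu = max(mu, 1e-8), size = cp$size)

  regions <- if (condition == "countermeasures") {
    skip <- params$cm_skip
    if (is_probe) {
      skip[c("nose", "mouth")] <-
        pmin(skip[c("nose", "mouth")] + effects$inner_skip_bias, 1)
    }
    draw_cm_regions(n_fix, params$cm_sequence, skip)
  } else {
    p <- params$aoi_probs
    if (is_probe && effects$eyes_bias != 0) {
      eyes <- intersect(EYE_REGIONS, names(p))
      p[eyes] <- p[eyes] + effects$eyes_bias / length(eyes)
      p <- pmax(p, 0)
      p <- p / sum(p)
    }
    sample(names(p), n_fix, replace = TRUE, prob = p)
  }

  # durations: truncated log-normal, probe trials shifted on the log scale
  mu_log <- log(params$duration$median_ms)
  if (is_probe) {
    delta <- afd_log_delta %||%
      afd_log_shift(afd_theta %||% effects$afd_effect, params, condition)
    mu_log <- mu_log + delta
  }
  durs <- rlnorm(n_fix, meanlog = mu_log, sdlog = params$duration$log_sd)
  durs <- pmax(durs, params$duration$floor_ms)

  cross <- c(x = unname(screen$resolution_h / 2),
             y = unname(screen$resolution_v / 2))
  pos <- matrix(NA_real_, n_fix, 2)
  prev <- cross
  for (k in seq_len(n_fix)) {
    pos[k, ] <- place_fixation(regions[k], prev, layout, screen,
                               params$min_separation)
    prev <- pos[k, ]
  }
  quick_df(list(region = c("cross", regions),
                cx = unname(c(cross[1], pos[, 1])),
                cy = unname(c(cross[2], pos[, 2])),
                duration = c(params$cross_duration_ms, durs)))
}

draw_cm_regions <- function(n_fix, sequence, skip) {
  out <- character(0)
  guard <- 0L
  while (length(out) < n_fix) {
    keep <- runif(length(sequence)) >= skip[sequence]
    out <- c(out, sequence[keep])
    guard <- guard + 1L
    if (guard > 1000L) {  # all-skip pathological parameters
      out <- c(out, sequence)
    }
  }
  out[seq_len(n_fix)]
}

# Draw a landing position for `region`, at city-block distance greater
# than `min_sep` from the previous centroid.
place_fixation <- function(region, prev, layout, screen, min_sep) {
  for (attempt in 1:40) {
    cand <- draw_in_region(region, layout, screen,
                           jitter_sd = 12 * (1 + attempt / 10))
    if (sum(abs(cand - prev)) > min_sep) return(cand)
  }
  # deterministic fallback: step away from `prev` along the wider axis
  cand <- draw_in_region(region, layout, screen, jitter_sd = 12)
  dir <- if (prev[1] < screen$resolution_h / 2) 1 else -1
  cand[1] <- min(max(prev[1] + dir * (min_sep + 1), 1),
                 screen$resolution_h - 1)
  cand
}

draw_in_region <- function(region, layout, screen, jitter_sd = 12) {
  b <- layout$box
  if (region %in% names(layout$regions)) {
    r <- layout$regions[[region]]
    return(c(runif(1, r["xmin"], r["xmax"]), runif(1, r["ymin"], r["ymax"])))
  }
  if (region %in% rownames(layout$anchors)) {
    a <- layout$anchors[region, ]
    return(c(a[1] + rnorm(1, 0, jitter_sd), a[2] + rnorm(1, 0, jitter_sd)))
  }
  if (region == "outer") {
    for (i in 1:50) {
      cand <- c(runif(1, b["xmin"], b["xmax"]), runif(1, b["ymin"], b["ymax"]))
      inner_hit <- FALSE
      for (r in layout$regions) {
        if (cand[1] >= r[["xmin"]] && cand[1] <= r[["xmax"]] &&
            cand[2] >= r[["ymin"]] && cand[2] <= r[["ymax"]]) {
          inner_hit <- TRUE
          break
        }
      }
      if (!inner_hit) return(cand)
    }
    return(c(b["xmin"] + 5, b["ymin"] + 5))
  }
  if (region == "off_face") {
    for (i in 1:50) {
      cand <- c(runif(1, 1, screen$resolution_h),
                runif(1, 1, screen$resolution_v))
      if (cand[1] < b["xmin"] || cand[1] > b["xmax"] ||
          cand[2] < b["ymin"] || cand[2] > b["ymax"]) return(cand)
    }
    return(c(b["xmin"] / 2, b["ymin"] / 2))
  }
  stop_bad_arg("region", sprintf("unknown region '%s'", region))
}

#' Render a planned scanpath into raw gaze samples
#'
#' Turns a fixation plan into a 60 Hz (by default) sample stream: each
#' planned fixation contributes `ceiling(duration / interval)` samples
#' jittered around its centroid, consecutive fixations are joined by one
#' or two saccadic transition samples at interpolated positions, and
#' samples are dropped (flagged invalid with missing coordinates) with the
#' dropout probability. Time zero is stimulus onset: the leading central
#' fixation ends at the last sample before 0.
#'
#' @param plan Output of [simulate_scanpath()] (non-empty).
#' @param params A [generative_params()].
#' @param sampling_rate Samples per second.
#' @return Data frame of samples: `t` (ms), `x`, `y` (px; `NA` when
#'   invalid), `valid`.
#' @export
render_samples <- function(plan, params = generative_params(),
                           sampling_rate = 60) {
  if (is.null(plan) || nrow(plan) == 0L)
    stop_bad_arg("plan", "must contain at least one planned fixation")
  check_cols(plan, c("cx", "cy", "duration"), "plan")
  interval <- 1000 / sampling_rate
  nf <- nrow(plan)
  n_samp <- pmax(ceiling(plan$duration / interval), 1)
  n_trans <- if (nf > 1L)
    sample(params$saccade_samples, nf - 1L, replace = TRUE) else integer(0)

  pre <- if (plan$region[1] == "cross") 1L else 0L
  xs <- vector("list", 2L * nf); ys <- xs; ns <- integer(2L * nf)
  k <- 0L
  for (f in seq_len(nf)) {
    k <- k + 1L
    xs[[k]] <- rep(plan$cx[f], n_samp[f]) +
      rnorm(n_samp[f], 0, params$noise_sd)
    ys[[k]] <- rep(plan$cy[f], n_samp[f]) +
      rnorm(n_samp[f], 0, params$noise_sd)
    ns[k] <- n_samp[f]
    if (f < nf && n_trans[f] > 0L) {
      k <- k + 1L
      w <- seq_len(n_trans[f]) / (n_trans[f] + 1)
      xs[[k]] <- plan$cx[f] + w * (plan$cx[f + 1] - plan$cx[f])
      ys[[k]] <- plan$cy[f] + w * (plan$cy[f + 1] - plan$cy[f])
      ns[k] <- n_trans[f]
    }
  }
  x <- unlist(xs[seq_len(k)]); y <- unlist(ys[seq_len(k)])
  total <- length(x)
  # align the time grid so the pre-onset fixation ends at -interval
  n_pre <- if (pre) n_samp[1] else 0L
  t <- (seq_len(total) - n_pre - 1L) * interval
  valid <- runif(total) >= params$dropout
  x[!valid] <- NA_real_; y[!valid] <- NA_real_
  quick_df(list(t = t, x = x, y = y, valid = valid))
}

#' Simulate the behavioural yes/no response of one trial
#'
#' Independent Bernoulli response errors with per-item-type rates. The
#' protocol-correct answer is "no" for probes (the lie the task demands),
#' irrelevants and buffers, and "yes" for targets.
#'
#' @param item_type One of `buffer`, `irrelevant`, `probe`, `target`.
#' @param params A [generative_params()] (field `error_rates`).
#' @return List with `answer` ("yes"/"no") and `correct` (logical).
#' @export
simulate_response <- function(item_type, params = generative_params()) {
  item_type <- as.character(item_type)
  rate <- params$error_rates[[item_type]] %||% 0
  correct_answer <- if (item_type == "target") "yes" else "no"
  err <- runif(1) < rate
  answer <- if (err) setdiff(c("yes", "no"), correct_answer) else
    correct_answer
  list(answer = answer, correct = !err)
}

#' Generate a full synthetic cohort
#'
#' Builds a seeded trial schedule, simulates every trial's scanpath,
#' renders raw gaze samples and behavioural responses, and returns (and
#' optionally writes) the raw-sample and trial tables. Deterministic given
#' `seed`. Participant-level AFD effects are drawn once per participant
#' from `N(afd_effect, afd_effect_sd^2)`.
#'
#' @param config A [study_config()].
#' @param params A [generative_params()].
#' @param effects A [familiarity_effects()].
#' @param layout A [face_layout()].
#' @param seed Master seed for the cohort.
#' @param dir If non-NULL, directory (created if needed) where
#'   `raw_samples.csv` and `trials.csv` are written.
#' @return Invisibly when writing, otherwise visibly: a list with
#'   `samples` (participant, condition, block, trial, item_type, t_ms,
#'   x_px, y_px, valid), `trials` (participant, condition, block, trial,
#'   item_type, answer, correct), `schedule`, and `participant_effects`.
#' @examples
#' coh <- generate_cohort(study_config(n_per_group = 2), seed = 1)
#' nrow(coh$trials)  # 2 participants x 2 conditions x 80 trials
#' @export
generate_cohort <- function(config = study_config(),
                            params = generative_params(),
                            effects = familiarity_effects(),
                            layout = face_layout(), seed = NULL,
                            dir = NULL) {
  schedule <- build_trial_schedule(config, seed = derive_seed(seed, 1L))
  res <- with_seed(derive_seed(seed, 2L), {
    parts <- unique(schedule$participant)
    theta <- rnorm(length(parts), effects$afd_effect, effects$afd_effect_sd)
    names(theta) <- parts
    # precompute the per-participant log-duration shift once per condition
    scales <- lapply(setNames(nm = config$conditions), function(cond)
      afd_scale(params, cond))
    part_cond <- schedule$condition[match(parts, schedule$participant)]
    delta <- vapply(seq_along(parts), function(i) {
      sc <- scales[[part_cond[i]]]
      log(max(1 + theta[i] * sc$sd / sc$mean, 0.05))
    }, 0)
    names(delta) <- parts
    n_tr <- nrow(schedule)
    samp_list <- vector("list", n_tr)
    answer <- character(n_tr); correct <- logical(n_tr)
    for (i in seq_len(n_tr)) {
      tr <- schedule[i, ]
      plan <- simulate_scanpath(tr, params, effects, layout, config$screen,
                                afd_theta = theta[[tr$participant]],
                                afd_log_delta = delta[[tr$participant]])
      samp_list[[i]] <- render_samples(plan, params, config$sampling_rate)
      resp <- simulate_response(tr$item_type, params)
      answer[i] <- resp$answer; correct[i] <- resp$correct
    }
    lens <- vapply(samp_list, nrow, 0L)
    samples <- data.frame(
      participant = rep(schedule$participant, lens),
      condition = rep(schedule$condition, lens),
      block = rep(schedule$block, lens),
      trial = rep(schedule$trial, lens),
      item_type = rep(schedule$item_type, lens),
      t_ms = unlist(lapply(samp_list, `[[`, "t")),
      x_px = unlist(lapply(samp_list, `[[`, "x")),
      y_px = unlist(lapply(samp_list, `[[`, "y")),
      valid = unlist(lapply(samp_list, `[[`, "valid")),
      stringsAsFactors = FALSE)
    trials <- data.frame(schedule[c("participant", "condition", "block",
                                    "trial", "item_type")],
                         answer = answer, correct = correct,
                         stringsAsFactors = FALSE)
    list(samples = samples, trials = trials, schedule = schedule,
         participant_effects = theta)
  })
  res$seed <- seed
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write.csv(res$samples, file.path(dir, "raw_samples.csv"),
              row.names = FALSE)
    write.csv(res$trials, file.path(dir, "trials.csv"), row.names = FALSE)
    return(invisible(res))
  }
  res
}
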