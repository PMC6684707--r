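#' Virtual-innocent standardization of one block
#'
#' Implements the removal-resampling standardization for a single block:
#' `k = length(probe_values)` irrelevant trials are removed uniformly at
#' random (the "virtual innocent" responses), the mean `m` and SD `s` of
#' the remaining irrelevants are computed, and both the probe values and
#' the removed values are z-scored against `(m, s)`. The retained
#' irrelevants then have mean 0 and SD 1 by construction.
#'
#' @param probe_values Marker values of the block's valid probe trials.
#' @param irrelevant_values Marker values of the retained irrelevant
#'   trials; must number at least `length(probe_values) + 2` so that two
#'   or more remain after removal.
#' @param n_reps Number of independent removal draws.
#' @param details If `TRUE`, also return the removal indices and retained
#'   statistics per rep.
#' @return List with `z_probe` (k_probe x n_reps), `z_innocent`
#'   (k x n_reps), and `degenerate` (logical per rep; `TRUE` when the
#'   retained SD is zero, in which case that rep's z-scores are `NA`).
#'   With `details = TRUE` also `removed` (k x n_reps indices into
#'   `irrelevant_values`), `m` and `s`.
#' @examples
#' standardize_block(c(14, 14, 14), 1:12, n_reps = 2)
#' @export
standardize_block <- function(probe_values, irrelevant_values, n_reps = 1,
                              details = FALSE) {
  k <- length(probe_values)
  n <- length(irrelevant_values)
  if (k < 1L) stop_bad_arg("probe_values", "need at least one probe value")
  if (n < k + 2L)
    stop_bad_arg("irrelevant_values",
                 "need at least two retained irrelevants beyond the removed set")
  check_pos(n_reps, "n_reps")
  w <- as.numeric(irrelevant_values)
  idx <- vapply(seq_len(n_reps), function(r) sample.int(n, k), integer(k))
  idx <- matrix(idx, nrow = k)
  wm <- matrix(w[idx], nrow = k)
  rem_sum <- .colSums(wm, k, n_reps)
  rem_ssq <- .colSums(wm^2, k, n_reps)
  m <- (sum(w) - rem_sum) / (n - k)
  s2 <- (sum(w^2) - rem_ssq - (n - k) * m^2) / (n - k - 1L)
  s <- sqrt(pmax(s2, 0))
  degenerate <- s < 1e-9
  s[degenerate] <- NA_real_
  z_probe <- (matrix(probe_values, length(probe_values), n_reps) -
                matrix(m, length(probe_values), n_reps, byrow = TRUE)) /
    matrix(s, length(probe_values), n_reps, byrow = TRUE)
  z_innocent <- (wm - matrix(m, k, n_reps, byrow = TRUE)) /
    matrix(s, k, n_reps, byrow = TRUE)
  out <- list(z_probe = z_probe, z_innocent = z_innocent,
              degenerate = degenerate)
  if (details) {
    out$removed <- idx
    out$m <- m
    out$s <- s
  }
  out
}

#' Removal-resampling standardized scores for a cohort
#'
#' Runs the virtual-innocent standardization over every participant and
#' block of one condition's retained marker table, `n_reps` times, and
#' averages z-scores within participant across blocks (probe and innocent
#' separately, blocks weighted equally). The same removal draws are shared
#' by all markers, mirroring an analysis that removes irrelevant *trials*
#' once per rep and then scores every measure.
#'
#' Blocks without a valid probe trial, or with fewer than
#' `k + 2` retained irrelevants, contribute nothing (a warning summarises
#' how many); participants with no contributing block are excluded with a
#' warning. Reps in which a block's retained SD is zero drop that block
#' from that rep only.
#'
#' @param data Retained marker table (one condition) from
#'   [filter_trials()].
#' @param markers Character vector of marker columns to standardize.
#' @param n_reps Number of removal-resampling repetitions.
#' @param seed Optional seed; identical seeds give identical scores.
#' @return Object of class `"cit_scores"`: list with `scores` (per marker,
#'   a list of `z_probe` and `z_innocent` participant x rep matrices),
#'   `participants`, `markers`, `n_reps`.
#' @export
resample_detection <- function(data, markers = c("num_fixations",
                                                 "ias_visited",
                                                 "prop_inner", "afd",
                                                 "first_afd", "prop_eyes"),
                               n_reps = 1000, seed = NULL) {
  check_cols(data, c("participant", "block", "trial", "item_type", markers),
             "data")
  check_pos(n_reps, "n_reps")
  n_reps <- as.integer(n_reps)
  parts <- unique(data$participant)
  if (length(parts) < 2L)
    stop_bad_arg("data", "need at least two participants")
  M <- length(markers)
  with_seed(seed, {
    zp <- lapply(markers, function(m)
      matrix(NA_real_, length(parts), n_reps))
    zi <- zp
    names(zp) <- names(zi) <- markers
    skipped_blocks <- 0L
    contributed <- logical(length(parts))
    for (pi in seq_along(parts)) {
      prows <- data[data$participant == parts[pi], , drop = FALSE]
      acc_p <- matrix(0, M, n_reps); acc_i <- matrix(0, M, n_reps)
      cnt <- matrix(0L, M, n_reps)
      for (b in unique(prows$block)) {
        brows <- prows[prows$block == b, , drop = FALSE]
        pv <- brows[brows$item_type == "probe", markers, drop = FALSE]
        iv <- brows[brows$item_type == "irrelevant", markers, drop = FALSE]
        k <- nrow(pv); n <- nrow(iv)
        if (k < 1L || n < k + 2L) {
          skipped_blocks <- skipped_blocks + 1L
          next
        }
        idx <- matrix(vapply(seq_len(n_reps),
                             function(r) sample.int(n, k), integer(k)),
                      nrow = k)
        for (mi in seq_len(M)) {
          w <- as.numeric(iv[[mi]])
          v_mean <- mean(as.numeric(pv[[mi]]))
          wm <- matrix(w[idx], nrow = k)
          rem_sum <- .colSums(wm, k, n_reps)
          rem_ssq <- .colSums(wm^2, k, n_reps)
          m <- (sum(w) - rem_sum) / (n - k)
          s2 <- (sum(w^2) - rem_ssq - (n - k) * m^2) / (n - k - 1L)
          s <- sqrt(pmax(s2, 0))
          ok <- s >= 1e-9
          zpb <- (v_mean - m) / s
          zib <- (rem_sum / k - m) / s
          acc_p[mi, ok] <- acc_p[mi, ok] + zpb[ok]
          acc_i[mi, ok] <- acc_i[mi, ok] + zib[ok]
          cnt[mi, ok] <- cnt[mi, ok] + 1L
        }
      }
      if (any(cnt > 0L)) contributed[pi] <- TRUE
      for (mi in seq_len(M)) {
        has <- cnt[mi, ] > 0L
        zp[[mi]][pi, has] <- acc_p[mi, has] / cnt[mi, has]
        zi[[mi]][pi, has] <- acc_i[mi, has] / cnt[mi, has]
      }
    }
    if (skipped_blocks > 0L)
      warning(sprintf("%d participant-block(s) skipped (no valid probe or too few irrelevants)",
                      skipped_blocks), call. = FALSE)
    if (any(!contributed)) {
      warning(sprintf("participant(s) excluded (no usable blocks): %s",
                      paste(parts[!contributed], collapse = ", ")),
              call. = FALSE)
      zp <- lapply(zp, function(m) m[contributed, , drop = FALSE])
      zi <- lapply(zi, function(m) m[contributed, , drop = FALSE])
      parts <- parts[contributed]
    }
    structure(list(scores = setNames(lapply(seq_len(M), function(mi)
      list(z_probe = zp[[mi]], z_innocent = zi[[mi]])), markers),
      participants = parts, markers = markers, n_reps = n_reps),
      class = "cit_scores")
  })
}

get_scores <- function(scores, marker) {
  if (!inherits(scores, "cit_scores"))
    stop_bad_arg("scores", "must be a cit_scores object")
  if (!marker %in% scores$markers)
    stop_bad_arg("marker", sprintf("'%s' not among standardized markers",
                                   marker))
  scores$scores[[marker]]
}

d_of <- function(x) {
  m <- mean(x, na.rm = TRUE)
  s <- sd(x, na.rm = TRUE)
  if (!is.finite(s) || s < 1e-12) {
    if (is.finite(m) && abs(m) < 1e-12) return(0)
    return(NA_real_)
  }
  m / s
}

auc_of <- function(g, h) {
  ok <- is.finite(g) & is.finite(h)
  g <- g[ok]; h <- h[ok]
  ng <- length(g); nh <- length(h)
  if (ng == 0L || nh == 0L)
    stop_bad_arg("scores", "empty score set in AUC computation")
  r <- rank(c(g, h))
  (sum(r[seq_len(ng)]) - ng * (ng + 1) / 2) / (ng * nh)
}

#' Cohen's d on standardized difference scores
#'
#' For each removal rep, computes per-participant differences
#' `z_probe - z_innocent` and their Cohen's \eqn{d_z} (mean over SD across
#' participants); the point estimate is the mean of the per-rep values.
#' The confidence interval is a percentile bootstrap over participants
#' (resampled with replacement), each bootstrap replicate paired with a
#' fresh removal draw (a different rep column), so both sampling layers
#' enter the interval.
#'
#' @param scores A `"cit_scores"` object from [resample_detection()].
#' @param marker Which marker to summarise.
#' @param n_boot Bootstrap resamples.
#' @param conf Confidence level.
#' @param seed Optional seed for the bootstrap.
#' @return List with `d`, `ci` (length-2), and `d_reps` (per-rep values).
#' @export
cohens_d <- function(scores, marker, n_boot = 1000, conf = 0.95,
                     seed = NULL) {
  sc <- get_scores(scores, marker)
  diff <- sc$z_probe - sc$z_innocent
  d_reps <- apply(diff, 2L, d_of)
  d <- mean(d_reps, na.rm = TRUE)
  P <- nrow(diff); R <- ncol(diff)
  ci <- with_seed(seed, {
    db <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(P, P, replace = TRUE)
      d_of(diff[idx, ((b - 1L) %% R) + 1L])
    }, 0)
    quantile(db, c((1 - conf) / 2, 1 - (1 - conf) / 2), na.rm = TRUE,
             names = FALSE)
  })
  list(d = d, ci = ci, d_reps = d_reps)
}

#' ROC area under the curve of the standardized scores
#'
#' Per rep, the guilty set is the participants' mean probe z-scores and
#' the innocent set their mean virtual-innocent z-scores; the AUC is the
#' Mann-Whitney probability \eqn{P(guilty > innocent) + P(tie)/2} over all
#' cross pairs. The point estimate is the mean over reps; the CI is the
#' same participant bootstrap as in [cohens_d()].
#'
#' @inheritParams cohens_d
#' @return List with `auc`, `ci`, and `auc_reps`.
#' @export
roc_auc <- function(scores, marker, n_boot = 1000, conf = 0.95,
                    seed = NULL) {
  sc <- get_scores(scores, marker)
  R <- ncol(sc$z_probe); P <- nrow(sc$z_probe)
  auc_reps <- vapply(seq_len(R), function(r)
    auc_of(sc$z_probe[, r], sc$z_innocent[, r]), 0)
  a <- mean(auc_reps, na.rm = TRUE)
  ci <- with_seed(seed, {
    ab <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(P, P, replace = TRUE)
      r <- ((b - 1L) %% R) + 1L
      auc_of(sc$z_probe[idx, r], sc$z_innocent[idx, r])
    }, 0)
    quantile(ab, c((1 - conf) / 2, 1 - (1 - conf) / 2), na.rm = TRUE,
             names = FALSE)
  })
  list(auc = a, ci = ci, auc_reps = auc_reps)
}

#' Percentage of participants in the predicted direction
#'
#' Fraction of participants whose rep-averaged `z_probe - z_innocent`
#' difference has the predicted sign, as a percentage. An exact zero
#' difference counts as not in the predicted direction.
#'
#' @inheritParams cohens_d
#' @param predicted_sign `+1` (probe scores predicted higher, e.g. AFD) or
#'   `-1` (predicted lower, e.g. fixation counts).
#' @return Percentage in `[0, 100]`.
#' @export
direction_percentages <- function(scores, marker, predicted_sign) {
  if (!predicted_sign %in% c(-1, 1))
    stop_bad_arg("predicted_sign", "must be +1 or -1")
  sc <- get_scores(scores, marker)
  diff <- rowMeans(sc$z_probe - sc$z_innocent, na.rm = TRUE)
  100 * mean(sign(diff) == predicted_sign, na.rm = TRUE)
}

#' Default predicted directions of the six markers
#'
#' Recognition of the familiar probe is expected to lengthen fixation
#' durations (`afd`, `first_afd`, `+1`), attract fixations to the eyes
#' (`prop_eyes`, `+1`), and reduce fixation counts, interest areas visited
#' and inner-region proportions (`-1`).
#' @return Named numeric vector of signs.
#' @export
predicted_directions <- function() {
  c(num_fixations = -1, ias_visited = -1, prop_inner = -1,
    afd = 1, first_afd = 1, prop_eyes = 1)
}

#' Fit the CIT detection-efficiency model
#'
#' The core estimator: for each condition and marker it runs the
#' virtual-innocent removal resampling ([resample_detection()]), then
#' summarises detection efficiency as Cohen's *d* on standardized
#' difference scores and the Mann-Whitney AUC, each with a percentile
#' bootstrap confidence interval, plus the percentage of participants
#' whose difference lies in the predicted direction.
#'
#' @param data Retained marker table (both conditions allowed) from
#'   [filter_trials()].
#' @param markers Marker columns to analyse.
#' @param n_reps Removal-resampling repetitions (the classical choice is
#'   1000).
#' @param n_boot Bootstrap resamples for the CIs.
#' @param seed Master seed; the removal and bootstrap streams are derived
#'   from it by fixed offsets, so a full fit is a pure function of
#'   `(data, seed)`.
#' @param predicted Named sign vector, see [predicted_directions()].
#' @param conf Confidence level for the intervals.
#' @return An object of class `"cit_detection"` with components `results`
#'   (data frame: condition, marker, d, d_lo, d_hi, auc, auc_lo, auc_hi,
#'   pct_direction, n_participants), `scores` (per-condition
#'   `"cit_scores"`), `n_reps`, `n_boot`, `seed`, `call`. Methods:
#'   `print`, `summary`, `coef`, `plot`.
#' @examples
#' \donttest{
#' coh <- generate_cohort(study_config(n_per_group = 6), seed = 1)
#' an <- cit_analyze(coh$samples, coh$trials, n_reps = 50, n_boot = 50,
#'                   seed = 1)
#' an$fit
#' }
#' @export
cit_detect <- function(data, markers = names(predicted_directions()),
                       n_reps = 1000, n_boot = 1000, seed = NULL,
                       predicted = predicted_directions(), conf = 0.95) {
  check_cols(data, c("participant", "condition", "block", "trial",
                     "item_type"), "data")
  conditions <- unique(data$condition)
  rows <- list(); all_scores <- list()
  off <- 100L
  for (ci in seq_along(conditions)) {
    cond <- conditions[ci]
    sub <- data[data$condition == cond, , drop = FALSE]
    scores <- resample_detection(sub, markers, n_reps,
                                 seed = derive_seed(seed, off + ci))
    all_scores[[cond]] <- scores
    for (mi in seq_along(markers)) {
      mk <- markers[mi]
      bseed <- derive_seed(seed, 1000L + 37L * ci + mi)
      dd <- cohens_d(scores, mk, n_boot, conf, seed = bseed)
      aa <- roc_auc(scores, mk, n_boot, conf, seed = bseed)
      sign_mk <- if (mk %in% names(predicted)) predicted[[mk]] else 1
      pct <- direction_percentages(scores, mk, sign_mk)
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, marker = mk,
        d = dd$d, d_lo = dd$ci[1], d_hi = dd$ci[2],
        auc = aa$auc, auc_lo = aa$ci[1], auc_hi = aa$ci[2],
        pct_direction = pct,
        n_participants = length(scores$participants),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(results = do.call(rbind, rows), scores = all_scores,
                 markers = markers, conditions = conditions,
                 n_reps = n_reps, n_boot = n_boot, seed = seed,
                 predicted = predicted, conf = conf,
                 call = match.call()),
            class = "cit_detection")
}

#' @export
print.cit_detection <- function(x, digits = 2, ...) {
  cat("Concealed-information detection efficiency",
      sprintf("(%d removal reps, %d bootstrap resamples)\n",
              x$n_reps, x$n_boot))
  r <- x$results
  out <- data.frame(condition = r$condition, marker = r$marker,
                    d = round(r$d, digits),
                    auc = round(r$auc, digits),
                    pct_dir = round(r$pct_direction, 1))
  print(out, row.names = FALSE)
  invisible(x)
}

#' @export
summary.cit_detection <- function(object, ...) {
  r <- object$results
  r$auc_above_chance <- r$auc_lo > 0.5 | r$auc_hi < 0.5
  structure(list(results = r, n_reps = object$n_reps,
                 n_boot = object$n_boot, conf = object$conf,
                 conditions = object$conditions),
            class = "summary.cit_detection")
}

#' @export
print.summary.cit_detection <- function(x, digits = 2, ...) {
  cat(sprintf("Detection efficiency per condition and marker (%d%% CIs, %d reps, %d boot)\n",
              round(100 * x$conf), x$n_reps, x$n_boot))
  r <- x$results
  fmt <- function(v) formatC(v, digits = digits, format = "f")
  tab <- data.frame(
    condition = r$condition, marker = r$marker,
    d = sprintf("%s [%s, %s]", fmt(r$d), fmt(r$d_lo), fmt(r$d_hi)),
    AUC = sprintf("%s [%s, %s]%s", fmt(r$auc), fmt(r$auc_lo),
                  fmt(r$auc_hi), ifelse(r$auc_above_chance, " *", "")),
    pct_dir = sprintf("%.1f%%", r$pct_direction))
  print(tab, row.names = FALSE)
  cat("* AUC confidence interval excludes 0.5 (classification over chance)\n")
  invisible(x)
}

#' @export
coef.cit_detection <- function(object, ...) {
  r <- object$results
  m <- as.matrix(r[, c("d", "auc", "pct_direction")])
  rownames(m) <- paste(r$condition, r$marker, sep = ".")
  m
}

#' Forest-style plot of effect sizes per marker
#'
#' One panel per condition: Cohen's *d* per marker with its bootstrap
#' confidence interval; the dashed line at zero separates effects in and
#' against the predicted direction.
#'
#' @param x A `"cit_detection"` object.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.cit_detection <- function(x, ...) {
  r <- x$results
  conds <- x$conditions
  old <- par(mfrow = c(1, length(conds)), mar = c(4, 8, 2, 1))
  on.exit(par(old))
  for (cond in conds) {
    rc <- r[r$condition == cond, ]
    yy <- rev(seq_len(nrow(rc)))
    xlim <- range(c(rc$d_lo, rc$d_hi, 0))
    plot(rc$d, yy, xlim = xlim, ylim = c(0.5, nrow(rc) + 0.5),
         pch = 19, xlab = "Cohen's d (probe - innocent)", ylab = "",
         yaxt = "n", main = cond, ...)
    axis(2, at = yy, labels = rc$marker, las = 1)
    segments(rc$d_lo, yy, rc$d_hi, yy)
    abline(v = 0, lty = 2)
  }
  invisible(x)
}
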