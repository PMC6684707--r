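#' Dispersion-threshold (I-DT) fixation detection
#'
#' Parses a time-ordered stream of gaze samples into fixations with the
#' dispersion-threshold identification algorithm: a moving window is
#' initialised to cover the minimum duration; while its dispersion
#' \eqn{D = (\max x - \min x) + (\max y - \min y)} stays at or below
#' `max_dispersion` the window grows, and on violation the window is
#' emitted as a fixation (the violating sample starts the next window).
#' If the initial window already violates the threshold, it slides by one
#' sample. Defaults are an 80 ms minimum duration and a 100 px dispersion
#' ceiling.
#'
#' A fixation's duration is `(t_last - t_first) + sample_interval`, the
#' convention of sample-based trackers; a 5-sample window at 60 Hz
#' (~83 ms) therefore meets the 80 ms minimum. Invalid samples never
#' contribute; gaps between consecutive valid samples longer than
#' `max_gap` (blinks, tracking loss) terminate any open window, while
#' shorter gaps are bridged.
#'
#' @param samples Data frame with columns `t` (ms, strictly increasing
#'   within the stream), `x`, `y` (px) and optionally `valid` (logical).
#' @param min_duration Minimum fixation duration, ms.
#' @param max_dispersion Maximum window dispersion, px.
#' @param max_gap Maximum bridgeable gap between valid samples, ms.
#' @param sample_interval Nominal sampling interval, ms; by default the
#'   median spacing of the valid samples (16.7 ms at 60 Hz).
#' @return Data frame with one row per fixation: `onset`, `offset` (ms; the
#'   first/last member-sample times), `duration` (ms), `cx`, `cy` (centroid
#'   px, arithmetic mean of member samples) and `n_samples`.
#' @examples
#' tr <- data.frame(t = seq(0, 500, by = 1000 / 60), x = 700, y = 450)
#' detect_fixations(tr)
#' @export
detect_fixations <- function(samples, min_duration = 80,
                             max_dispersion = 100, max_gap = 75,
                             sample_interval = NULL) {
  check_cols(samples, c("t", "x", "y"), "samples")
  check_pos(min_duration, "min_duration")
  check_pos(max_dispersion, "max_dispersion")
  check_pos(max_gap, "max_gap")
  empty <- data.frame(onset = numeric(0), offset = numeric(0),
                      duration = numeric(0), cx = numeric(0),
                      cy = numeric(0), n_samples = integer(0))
  if (nrow(samples) == 0L) return(empty)
  t_all <- samples$t
  bad <- which(diff(t_all) <= 0)
  if (length(bad))
    stop(sprintf("timestamps not strictly increasing at sample index %d",
                 bad[1] + 1L), call. = FALSE)
  valid <- if ("valid" %in% names(samples)) samples$valid else
    rep(TRUE, nrow(samples))
  valid <- valid & is.finite(samples$x) & is.finite(samples$y)
  t <- t_all[valid]; x <- samples$x[valid]; y <- samples$y[valid]
  if (length(t) == 0L) return(empty)
  if (is.null(sample_interval))
    sample_interval <- if (length(t) > 1L) stats::median(diff(t)) else
      min_duration
  # split into runs of valid samples whose spacing never exceeds max_gap
  seg_id <- c(0, cumsum(diff(t) > max_gap))
  out <- lapply(split(seq_along(t), seg_id), function(idx) {
    idt_segment(t[idx], x[idx], y[idx], min_duration, max_dispersion,
                sample_interval)
  })
  fixmat_to_df(do.call(rbind, out[!vapply(out, is.null, TRUE)]))
}

# Core I-DT pass over one gap-free run of valid samples; returns a
# 6-column matrix (onset, offset, duration, cx, cy, n_samples) or NULL.
# Running min/max are maintained while the window grows; they are
# recomputed only when the window is re-anchored.
idt_segment <- function(t, x, y, min_dur, max_disp, interval) {
  n <- length(t)
  res <- vector("list", 8L); nres <- 0L
  i <- 1L
  while (i <= n) {
    j <- i
    while (j <= n && (t[j] - t[i] + interval) < min_dur) j <- j + 1L
    if (j > n) break
    xmin <- min(x[i:j]); xmax <- max(x[i:j])
    ymin <- min(y[i:j]); ymax <- max(y[i:j])
    if ((xmax - xmin) + (ymax - ymin) <= max_disp) {
      while (j < n) {
        nx_min <- min(xmin, x[j + 1L]); nx_max <- max(xmax, x[j + 1L])
        ny_min <- min(ymin, y[j + 1L]); ny_max <- max(ymax, y[j + 1L])
        if ((nx_max - nx_min) + (ny_max - ny_min) > max_disp) break
        j <- j + 1L
        xmin <- nx_min; xmax <- nx_max; ymin <- ny_min; ymax <- ny_max
      }
      nres <- nres + 1L
      if (nres > length(res)) res <- c(res, vector("list", length(res)))
      res[[nres]] <- c(t[i], t[j], t[j] - t[i] + interval,
                       mean(x[i:j]), mean(y[i:j]), j - i + 1L)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (nres == 0L) return(NULL)
  do.call(rbind, res[seq_len(nres)])
}

fixmat_to_df <- function(m) {
  if (is.null(m))
    return(data.frame(onset = numeric(0), offset = numeric(0),
                      duration = numeric(0), cx = numeric(0),
                      cy = numeric(0), n_samples = integer(0)))
  data.frame(onset = m[, 1], offset = m[, 2], duration = m[, 3],
             cx = m[, 4], cy = m[, 5], n_samples = as.integer(m[, 6]))
}

#' Detect fixations for every trial of a cohort
#'
#' Applies [detect_fixations()] to each (participant, block, trial) group
#' of a raw-sample table and binds the results with the trial keys.
#'
#' @param samples Raw-sample data frame with columns `participant`,
#'   `condition`, `block`, `trial`, `item_type`, `t_ms`, `x_px`, `y_px`,
#'   `valid` (the dialect written by [generate_cohort()]).
#' @inheritParams detect_fixations
#' @return Data frame of fixations with the trial keys prepended.
#' @export
detect_fixations_cohort <- function(samples, min_duration = 80,
                                    max_dispersion = 100, max_gap = 75,
                                    sample_interval = NULL) {
  check_cols(samples, c("participant", "condition", "block", "trial",
                        "item_type", "t_ms", "x_px", "y_px", "valid"),
             "samples")
  if (is.null(sample_interval)) {
    dt <- diff(samples$t_ms)
    sample_interval <- stats::median(dt[dt > 0])
  }
  key <- paste(samples$participant, samples$block, samples$trial, sep = "\r")
  idx <- split(seq_len(nrow(samples)), key)
  out <- vector("list", length(idx))
  first_row <- integer(length(idx))
  for (k in seq_along(idx)) {
    rows <- idx[[k]]
    first_row[k] <- rows[1]
    valid <- samples$valid[rows] & is.finite(samples$x_px[rows])
    rows <- rows[valid]
    if (!length(rows)) next
    t <- samples$t_ms[rows]; x <- samples$x_px[rows]; y <- samples$y_px[rows]
    seg_id <- c(0, cumsum(diff(t) > max_gap))
    fx <- do.call(rbind, lapply(split(seq_along(t), seg_id), function(i)
      idt_segment(t[i], x[i], y[i], min_duration, max_dispersion,
                  sample_interval)))
    out[[k]] <- fx
  }
  keep <- !vapply(out, is.null, TRUE)
  if (!any(keep))
    return(data.frame(participant = character(0), condition = character(0),
                      block = integer(0), trial = integer(0),
                      item_type = character(0), onset = numeric(0),
                      offset = numeric(0), duration = numeric(0),
                      cx = numeric(0), cy = numeric(0),
                      n_samples = integer(0)))
  lens <- vapply(out[keep], nrow, 0L)
  r1 <- first_row[keep]
  out <- cbind(data.frame(participant = rep(samples$participant[r1], lens),
                          condition = rep(samples$condition[r1], lens),
                          block = rep(samples$block[r1], lens),
                          trial = rep(samples$trial[r1], lens),
                          item_type = rep(samples$item_type[r1], lens),
                          stringsAsFactors = FALSE),
               fixmat_to_df(do.call(rbind, out[keep])))
  ord <- order(out$participant, out$block, out$trial, out$onset)
  out <- out[ord, ]
  rownames(out) <- NULL
  out
}
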