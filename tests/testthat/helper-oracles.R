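# Independent oracles used by the property tests. These deliberately avoid
# the package's internals: dispersion is recomputed from scratch with
# range(), AUC is an explicit double loop over pairs, markers are tallied
# by hand.

# Textbook dispersion-threshold scan, recomputing the window dispersion
# from scratch at every step.
oracle_idt <- function(samples, min_duration = 80, max_dispersion = 100,
                       max_gap = 75, sample_interval = 1000 / 60) {
  valid <- if ("valid" %in% names(samples)) samples$valid else
    rep(TRUE, nrow(samples))
  valid <- valid & is.finite(samples$x) & is.finite(samples$y)
  s <- samples[valid, , drop = FALSE]
  out <- list()
  if (nrow(s)) {
    for (sg in split(s, c(0, cumsum(diff(s$t) > max_gap)))) {
      n <- nrow(sg)
      disp <- function(a, b)
        diff(range(sg$x[a:b])) + diff(range(sg$y[a:b]))
      i <- 1
      while (i <= n) {
        j <- i
        while (j <= n && sg$t[j] - sg$t[i] + sample_interval < min_duration)
          j <- j + 1
        if (j > n) break
        if (disp(i, j) <= max_dispersion) {
          while (j < n && disp(i, j + 1) <= max_dispersion) j <- j + 1
          out[[length(out) + 1]] <- data.frame(
            onset = sg$t[i], offset = sg$t[j],
            duration = sg$t[j] - sg$t[i] + sample_interval,
            cx = mean(sg$x[i:j]), cy = mean(sg$y[i:j]),
            n_samples = j - i + 1L)
          i <- j + 1
        } else {
          i <- i + 1
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(onset = numeric(0), offset = numeric(0),
                      duration = numeric(0), cx = numeric(0),
                      cy = numeric(0), n_samples = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Exhaustive cross-pair AUC with half-credit for ties.
oracle_auc <- function(g, h) {
  tot <- 0
  for (gi in g) for (hj in h)
    tot <- tot + (gi > hj) + 0.5 * (gi == hj)
  tot / (length(g) * length(h))
}

# Random gaze trace: a few stationary clusters at random locations with
# random lengths, joined by transition samples, with occasional dropouts.
random_trace <- function(n_clusters = NULL, interval = 1000 / 60) {
  if (is.null(n_clusters)) n_clusters <- sample(1:6, 1)
  t <- numeric(0); x <- numeric(0); y <- numeric(0); valid <- logical(0)
  cur_t <- 0
  px <- runif(1, 100, 1300); py <- runif(1, 100, 800)
  for (k in seq_len(n_clusters)) {
    len <- sample(2:20, 1)
    t <- c(t, cur_t + seq_len(len) * interval)
    x <- c(x, px + rnorm(len, 0, runif(1, 0, 25)))
    y <- c(y, py + rnorm(len, 0, runif(1, 0, 25)))
    valid <- c(valid, runif(len) > 0.05)
    cur_t <- cur_t + len * interval
    n_tr <- sample(0:2, 1)
    if (n_tr > 0) {
      npx <- px + sample(c(-1, 1), 1) * runif(1, 30, 400)
      npy <- py + sample(c(-1, 1), 1) * runif(1, 30, 300)
      w <- seq_len(n_tr) / (n_tr + 1)
      t <- c(t, cur_t + seq_len(n_tr) * interval)
      x <- c(x, px + w * (npx - px)); y <- c(y, py + w * (npy - py))
      valid <- c(valid, rep(TRUE, n_tr))
      cur_t <- cur_t + n_tr * interval
      px <- npx; py <- npy
    } else {
      # a long gap instead of a saccade
      cur_t <- cur_t + runif(1, 20, 150)
      px <- px + runif(1, -300, 300); py <- py + runif(1, -200, 200)
    }
  }
  data.frame(t = t, x = x, y = y, valid = valid)
}

# Memoised small synthetic cohorts shared across test files.
.cohort_cache <- new.env(parent = emptyenv())
cached_cohort <- function(tag, expr) {
  if (!exists(tag, envir = .cohort_cache))
    assign(tag, expr, envir = .cohort_cache)
  get(tag, envir = .cohort_cache)
}
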