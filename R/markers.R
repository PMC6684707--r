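#' Per-trial markers of recognition
#'
#' Computes the marker vector of one trial from its detected fixations.
#' Only fixations whose onset is at or after stimulus onset are counted;
#' the fixation carried over from the pre-stimulus central cross is
#' excluded, so the "first fixation" is the first one launched onto the
#' stimulus. Markers:
#'
#' * `num_fixations` — count of (post-onset) fixations;
#' * `ias_visited` — distinct interest areas among the five categories
#'   left eye, right eye, nose, mouth, outer (off-face fixations do not
#'   add a category);
#' * `prop_inner`, `prop_eyes`, `prop_nose`, `prop_mouth`, `prop_outer` —
#'   proportions of all counted fixations (off-face fixations stay in the
#'   denominator);
#' * `afd` — average fixation duration: total fixation time divided by the
#'   number of fixations;
#' * `first_afd` — duration of the first counted fixation.
#'
#' @param fixations Data frame of fixations (columns `onset`, `duration`,
#'   `cx`, `cy`), time-ordered.
#' @param layout A [face_layout()].
#' @param onset Stimulus onset time, ms (default 0).
#' @return One-row data frame with the marker fields plus `valid` and
#'   `reason` (`valid = FALSE`, reason `"no_fixations"` when no fixation
#'   survives the onset filter).
#' @examples
#' fx <- data.frame(onset = 10, duration = 200, cx = 720, cy = 450)
#' compute_markers(fx)
#' @export
compute_markers <- function(fixations, layout = face_layout(), onset = 0) {
  check_cols(fixations, c("onset", "duration", "cx", "cy"), "fixations")
  if (nrow(fixations) > 1L && any(diff(fixations$onset) < 0))
    stop_bad_arg("fixations", "must be time-ordered by onset")
  fx <- fixations[fixations$onset >= onset, , drop = FALSE]
  n <- nrow(fx)
  if (n == 0L) {
    return(data.frame(num_fixations = 0L, ias_visited = 0L,
                      prop_inner = NA_real_, prop_eyes = NA_real_,
                      prop_nose = NA_real_, prop_mouth = NA_real_,
                      prop_outer = NA_real_, afd = NA_real_,
                      first_afd = NA_real_, valid = FALSE,
                      reason = "no_fixations", stringsAsFactors = FALSE))
  }
  lab <- assign_region(fx$cx, fx$cy, layout)
  data.frame(num_fixations = n,
             ias_visited = length(unique(lab[lab %in% IA_CATEGORIES])),
             prop_inner = mean(lab %in% INNER_REGIONS),
             prop_eyes = mean(lab %in% EYE_REGIONS),
             prop_nose = mean(lab == "nose"),
             prop_mouth = mean(lab == "mouth"),
             prop_outer = mean(lab == "outer"),
             afd = sum(fx$duration) / n,
             first_afd = fx$duration[1],
             valid = TRUE, reason = "", stringsAsFactors = FALSE)
}

#' Marker table for a whole cohort
#'
#' Applies [compute_markers()] per trial of a cohort fixation table.
#' Trials present in `trials` but without any detected fixation get a
#' `valid = FALSE` row, so no trial silently disappears.
#'
#' @param fixations Cohort fixation table from [detect_fixations_cohort()].
#' @param trials Trial table (keys `participant`, `condition`, `block`,
#'   `trial`, `item_type`); when supplied, fixation-less trials are filled
#'   in as invalid rows.
#' @param layout A [face_layout()].
#' @param onset Stimulus onset, ms.
#' @return Data frame: trial keys plus the marker fields.
#' @export
compute_marker_table <- function(fixations, trials = NULL,
                                 layout = face_layout(), onset = 0) {
  check_cols(fixations, c("participant", "block", "trial", "onset",
                          "duration", "cx", "cy"), "fixations")
  key <- paste(fixations$participant, fixations$block, fixations$trial,
               sep = "\r")
  idx <- split(seq_len(nrow(fixations)), key)
  lab_all <- assign_region(fixations$cx, fixations$cy, layout)
  ng <- length(idx)
  first <- integer(ng)
  num <- integer(ng); ias <- integer(ng)
  p_in <- p_ey <- p_no <- p_mo <- p_ou <- afd <- fafd <- rep(NA_real_, ng)
  has_fix <- logical(ng)
  for (k in seq_len(ng)) {
    r <- idx[[k]]
    r <- r[order(fixations$onset[r])]
    first[k] <- r[1]
    r <- r[fixations$onset[r] >= onset]
    n <- length(r)
    num[k] <- n
    if (n == 0L) next
    has_fix[k] <- TRUE
    lab <- lab_all[r]
    ias[k] <- length(unique(lab[lab %in% IA_CATEGORIES]))
    p_ey[k] <- mean(lab == "left_eye" | lab == "right_eye")
    p_no[k] <- mean(lab == "nose")
    p_mo[k] <- mean(lab == "mouth")
    p_in[k] <- p_ey[k] + p_no[k] + p_mo[k]
    p_ou[k] <- mean(lab == "outer")
    afd[k] <- sum(fixations$duration[r]) / n
    fafd[k] <- fixations$duration[r[1]]
  }
  out <- data.frame(participant = fixations$participant[first],
                    condition = fixations$condition[first],
                    block = fixations$block[first],
                    trial = fixations$trial[first],
                    item_type = fixations$item_type[first],
                    num_fixations = num, ias_visited = ias,
                    prop_inner = p_in, prop_eyes = p_ey, prop_nose = p_no,
                    prop_mouth = p_mo, prop_outer = p_ou, afd = afd,
                    first_afd = fafd, valid = has_fix,
                    reason = ifelse(has_fix, "", "no_fixations"),
                    stringsAsFactors = FALSE)
  if (!is.null(trials)) {
    check_cols(trials, c("participant", "condition", "block", "trial",
                         "item_type"), "trials")
    tkey <- paste(trials$participant, trials$block, trials$trial, sep = "\r")
    missing <- !(tkey %in% names(idx))
    if (any(missing)) {
      fill <- do.call(rbind, lapply(which(missing), function(i) {
        cbind(trials[i, c("participant", "condition", "block", "trial",
                          "item_type")],
              compute_markers(data.frame(onset = numeric(0),
                                         duration = numeric(0),
                                         cx = numeric(0), cy = numeric(0)),
                              layout, onset))
      }))
      out <- rbind(out, fill)
    }
  }
  out <- out[order(out$participant, out$block, out$trial), ]
  rownames(out) <- NULL
  out
}

#' Apply the trial-exclusion rules
#'
#' Removes, with one logged reason per removed trial: buffer trials,
#' incorrectly answered probe / irrelevant / target trials (a "yes" to a
#' face that should have been denied, or vice versa), and trials without
#' usable fixations.
#'
#' @param trials Trial table with `answer`/`correct` columns (from
#'   [generate_cohort()] or equivalent).
#' @param markers Marker table from [compute_marker_table()], keyed
#'   consistently with `trials`.
#' @return List with `retained` (marker table rows that survive) and
#'   `exclusions` (trial keys plus `reason`:
#'   `buffer`, `incorrect_probe`, `incorrect_irrelevant`,
#'   `incorrect_target`, `no_fixations`). `retained` plus `exclusions`
#'   partition the input marker rows.
#' @export
filter_trials <- function(trials, markers) {
  check_cols(trials, c("participant", "block", "trial", "item_type",
                       "correct"), "trials")
  check_cols(markers, c("participant", "block", "trial", "item_type",
                        "valid"), "markers")
  tkey <- paste(trials$participant, trials$block, trials$trial, sep = "\r")
  mkey <- paste(markers$participant, markers$block, markers$trial, sep = "\r")
  if (anyDuplicated(tkey) || anyDuplicated(mkey))
    stop_bad_arg("trials", "duplicate trial keys")
  pos <- match(mkey, tkey)
  if (anyNA(pos))
    stop_bad_arg("markers", "contains trials absent from the trial table")
  correct <- trials$correct[pos]
  itype <- markers$item_type
  reason <- rep(NA_character_, nrow(markers))
  reason[itype == "buffer"] <- "buffer"
  wrong <- is.na(reason) & !correct
  reason[wrong] <- paste0("incorrect_", itype[wrong])
  reason[is.na(reason) & !markers$valid] <- "no_fixations"
  keep <- is.na(reason)
  excl <- cbind(markers[!keep, c("participant", "condition", "block",
                                 "trial", "item_type")],
                reason = reason[!keep])
  rownames(excl) <- NULL
  retained <- markers[keep, , drop = FALSE]
  rownames(retained) <- NULL
  list(retained = retained, exclusions = excl)
}
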