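#' Segment a hypnogram into bouts
#'
#' A bout is a maximal run of consecutive epochs scored as the same state.
#' Consecutive bouts therefore always have distinct states, onsets abut
#' (`onset[k+1] == onset[k] + n_epochs[k]`), and bout lengths sum to the
#' hypnogram length. The final, possibly truncated bout is included as-is.
#'
#' @param h A [hypnogram].
#' @return A data frame with columns `subject_id`, `treatment`, `state`,
#'   `onset_epoch` (0-based), `n_epochs`, `duration_s`.
#' @export
segment_bouts <- function(h) {
  validate_hypnogram(h)
  r <- rle(h$states)
  n <- r$lengths
  onset <- cumsum(c(0L, n[-length(n)]))
  data.frame(
    subject_id = h$subject_id,
    treatment = h$treatment,
    state = r$values,
    onset_epoch = as.integer(onset),
    n_epochs = as.integer(n),
    duration_s = n * h$epoch_seconds,
    stringsAsFactors = FALSE
  )
}

#' Reclassify REMS bouts by duration
#'
#' REMS bouts lasting at most `cutoff_epochs` epochs (default 4, i.e. 16 s
#' at 4-s epochs) become `REMS_S` (short); longer REMS bouts become
#' `REMS_L`. All other bouts and the bout order are unchanged. The total
#' number of REMS epochs is conserved across the split.
#'
#' @param bouts Bout data frame from [segment_bouts()] (possibly row-bound
#'   over a study); must not already contain `REMS_S`/`REMS_L`.
#' @param cutoff_epochs Maximum length, in epochs, of a short REMS bout.
#' @return The bout data frame with REMS relabelled.
#' @export
reclassify_rems <- function(bouts, cutoff_epochs = 4L) {
  stopifnot(is.data.frame(bouts), cutoff_epochs >= 1L)
  if (any(bouts$state %in% c("REMS_S", "REMS_L"))) {
    stop("bouts already contain reclassified REMS_S/REMS_L labels")
  }
  is_rems <- bouts$state == "REMS"
  bouts$state[is_rems] <- ifelse(bouts$n_epochs[is_rems] <= cutoff_epochs,
                                 "REMS_S", "REMS_L")
  bouts
}

#' Assign bouts to time bins by onset
#'
#' The observation window is split into `n_bins` bins of `bin_epochs` epochs
#' each (defaults: three 1-h bins of 900 four-second epochs). A bout belongs
#' to the bin containing its onset: `floor(onset_epoch / bin_epochs)`
#' (0-based). Bouts whose onset falls at or beyond `n_bins * bin_epochs` are
#' outside the window and get bin `NA`. A bout spanning a bin boundary is
#' counted once, in its onset bin, and its full duration contributes there.
#'
#' @param bouts Bout data frame.
#' @param bin_epochs Bin width in epochs.
#' @param n_bins Number of bins in the observation window.
#' @return The bout data frame with an integer `bin` column (0-based; `NA`
#'   marks bouts outside the window).
#' @export
bin_bouts <- function(bouts, bin_epochs = 900L, n_bins = 3L) {
  stopifnot(is.data.frame(bouts), bin_epochs >= 1L, n_bins >= 1L)
  b <- as.integer(floor(bouts$onset_epoch / bin_epochs))
  b[b >= n_bins] <- NA_integer_
  bouts$bin <- b
  bouts
}

#' Parameters of the NREM sleep latency rule
#'
#' The latency rule looks for the first consecutive NREM sleep (S1, S2, IS)
#' episode lasting at least 3 min (45 four-second epochs of NREM content by
#' default) that is not interrupted by more than 14 consecutive non-NREM
#' epochs, nor by a cumulated total of more than 240 s (60 epochs) not
#' scored as NREM.
#'
#' @param min_episode_epochs Minimum qualifying NREM content, in epochs.
#' @param max_consecutive_interrupt_epochs Longest tolerated single
#'   interruption, in epochs; a longer run fails the episode.
#' @param max_cumulative_interrupt_epochs Total interruption budget, in
#'   epochs; exceeding it fails the episode.
#' @param episode_length_counts_interruptions If `TRUE`, tolerated
#'   interruption epochs count toward the 3-min episode length (wall-time
#'   reading); default `FALSE` counts NREM content only, since the
#'   interruption budget alone exceeds 3 min and a wall-time reading would
#'   let an episode qualify while mostly awake.
#' @return An object of class `latency_params`.
#' @export
latency_params <- function(min_episode_epochs = 45L,
                           max_consecutive_interrupt_epochs = 14L,
                           max_cumulative_interrupt_epochs = 60L,
                           episode_length_counts_interruptions = FALSE) {
  stopifnot(min_episode_epochs >= 1L,
            max_consecutive_interrupt_epochs >= 1L,
            max_cumulative_interrupt_epochs >= 1L)
  structure(list(
    min_episode_epochs = as.integer(min_episode_epochs),
    max_consecutive_interrupt_epochs = as.integer(max_consecutive_interrupt_epochs),
    max_cumulative_interrupt_epochs = as.integer(max_cumulative_interrupt_epochs),
    episode_length_counts_interruptions = isTRUE(episode_length_counts_interruptions)
  ), class = "latency_params")
}

#' NREM sleep latency
#'
#' Time elapsed between drug administration and the onset of the first
#' qualifying NREM sleep episode under the interruption-tolerance rule of
#' [latency_params()]. Scanning starts at `h$treatment_epoch`. A candidate
#' episode begins at the first NREM-state epoch; within an episode, NREM
#' epochs and interruption (non-NREM) epochs are accumulated. The episode
#' fails the moment a non-NREM run exceeds the consecutive limit or the
#' cumulative interruption budget is exceeded; scanning then resumes after
#' the non-NREM run that caused the failure. The episode qualifies the
#' moment its accumulated length reaches the minimum; the latency is then
#' `(episode start epoch - treatment_epoch) * epoch_seconds`.
#'
#' @param h A [hypnogram] (raw or reclassified states; REMS_S/REMS_L are
#'   non-NREM like REMS).
#' @param params A [latency_params] object.
#' @return Latency in seconds, or `NA_real_` if no episode qualifies before
#'   the end of the recording.
#' @export
nrem_latency <- function(h, params = latency_params()) {
  validate_hypnogram(h)
  stopifnot(inherits(params, "latency_params"))
  is_nrem <- h$states %in% NREMS_STATES
  n <- length(is_nrem)
  i <- h$treatment_epoch + 1L  # 1-based scan position
  while (i <= n) {
    # find the start of the next candidate episode
    while (i <= n && !is_nrem[i]) i <- i + 1L
    if (i > n) return(NA_real_)
    start <- i
    nrem_count <- 0L
    cum_int <- 0L
    run_int <- 0L
    failed <- FALSE
    while (i <= n) {
      if (is_nrem[i]) {
        nrem_count <- nrem_count + 1L
        run_int <- 0L
        len <- if (params$episode_length_counts_interruptions) {
          nrem_count + cum_int
        } else nrem_count
        if (len >= params$min_episode_epochs) {
          return((start - 1L - h$treatment_epoch) * h$epoch_seconds)
        }
      } else {
        run_int <- run_int + 1L
        cum_int <- cum_int + 1L
        if (run_int > params$max_consecutive_interrupt_epochs ||
            cum_int > params$max_cumulative_interrupt_epochs) {
          # skip past the non-NREM run that caused the failure
          while (i <= n && !is_nrem[i]) i <- i + 1L
          failed <- TRUE
          break
        }
      }
      i <- i + 1L
    }
    if (!failed) return(NA_real_)  # recording ended inside an episode
  }
  NA_real_
}

#' Segment, reclassify, and bin every hypnogram of a study
#'
#' Convenience wrapper running [segment_bouts()], [reclassify_rems()], and
#' [bin_bouts()] over a list of hypnograms and row-binding the results.
#'
#' @param hypnograms List of [hypnogram] objects.
#' @param rems_cutoff_epochs Passed to [reclassify_rems()]; `NULL` skips
#'   reclassification.
#' @param bin_epochs,n_bins Passed to [bin_bouts()].
#' @return A study-level bout data frame.
#' @export
study_bouts <- function(hypnograms, rems_cutoff_epochs = 4L,
                        bin_epochs = 900L, n_bins = 3L) {
  if (inherits(hypnograms, "hypnogram")) hypnograms <- list(hypnograms)
  parts <- lapply(hypnograms, segment_bouts)
  bouts <- do.call(rbind, parts)
  if (!is.null(rems_cutoff_epochs)) {
    bouts <- reclassify_rems(bouts, rems_cutoff_epochs)
  }
  bin_bouts(bouts, bin_epochs = bin_epochs, n_bins = n_bins)
}
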