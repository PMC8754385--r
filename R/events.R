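#' Simulate an aversive-conditioning task event schedule
#'
#' Emulates the acquisition phase of a cued aversive-conditioning paradigm:
#' 16 aversive-cue (CS+) presentations of 6 s each, of which 8 co-terminate
#' with an electrical shock (US, modeled as a 3-s event starting at cue
#' offset, with no delay) and 8 are unreinforced. Trials are separated by an
#' inter-stimulus interval drawn uniformly from 8-12 s. Reinforced positions
#' are randomized across the 16 trials. Habituation trials are not generated.
#'
#' @param seed Optional integer seed.
#' @param n_cues Number of CS+ presentations.
#' @param n_reinforced Number of cues followed by the US.
#' @param cue_duration,us_duration Durations in seconds.
#' @param isi_range Length-2 numeric, uniform jitter range for the
#'   inter-stimulus interval in seconds.
#' @param start Onset of the first cue, seconds.
#'
#' @return An event tibble with columns `onset`, `duration` (seconds) and
#'   `trial_type` (one of `"CSplus_US"`, `"CSplus_noUS"`, `"US"`), onsets
#'   strictly increasing.
#' @examples
#' ev <- simulate_task_events(seed = 1)
#' dplyr::count(ev, trial_type)
#' @export
simulate_task_events <- function(seed = NULL, n_cues = 16L,
                                 n_reinforced = 8L,
                                 cue_duration = 6, us_duration = 3,
                                 isi_range = c(8, 12), start = 10) {
  if (n_reinforced > n_cues) abort("More reinforced cues than cues.")
  with_seed_or_current(seed, {
    reinforced <- sort(sample.int(n_cues, n_reinforced))
    isi <- runif(n_cues, isi_range[1], isi_range[2])
    onset <- numeric(0); duration <- numeric(0); type <- character(0)
    t <- start
    for (k in seq_len(n_cues)) {
      rein <- k %in% reinforced
      onset <- c(onset, t)
      duration <- c(duration, cue_duration)
      type <- c(type, if (rein) "CSplus_US" else "CSplus_noUS")
      t <- t + cue_duration
      if (rein) {
        onset <- c(onset, t)       # US starts at cue offset, no delay
        duration <- c(duration, us_duration)
        type <- c(type, "US")
        t <- t + us_duration
      }
      t <- t + isi[k]
    }
    tibble(onset = onset, duration = duration,
           trial_type = factor(type,
                               levels = c("CSplus_US", "CSplus_noUS", "US")))
  })
}

#' Validate an event table
#'
#' @param events Event tibble with columns `onset`, `duration`, `trial_type`.
#' @return The events, invisibly.
#' @export
validate_events <- function(events) {
  need <- c("onset", "duration", "trial_type")
  if (!all(need %in% names(events))) {
    abort("Events need columns onset, duration, trial_type.")
  }
  if (is.unsorted(events$onset, strictly = TRUE)) {
    abort("Event onsets must be strictly increasing.")
  }
  if (any(events$duration <= 0)) abort("Event durations must be positive.")
  invisible(events)
}

#' Read / write BIDS-style event tables
#'
#' Tab-separated with columns `onset`, `duration`, `trial_type`.
#'
#' @param path File path.
#' @param events Event tibble.
#' @return `read_events()` returns the validated event tibble.
#' @export
read_events <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_events(x)
  x
}

#' @rdname read_events
#' @export
write_events <- function(events, path) {
  readr::write_tsv(events, path, progress = FALSE)
  invisible(path)
}

#' Total scan duration implied by an event table
#'
#' Last event offset plus a washout for the hemodynamic tail.
#'
#' @param events Event tibble.
#' @param washout Seconds appended after the final event offset.
#' @return Duration in seconds.
#' @export
events_duration <- function(events, washout = 16) {
  max(events$onset + events$duration) + washout
}
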