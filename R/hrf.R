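#' Canonical double-gamma hemodynamic response function
#'
#' The standard canonical HRF: a gamma density peaking near 6 s minus a
#' later gamma undershoot (peak delay 16 s) scaled by 1/6, sampled on
#' `[0, 32]` s and normalized so the positive lobe sums to 1. Both gammas
#' use unit dispersion (shape = delay, rate = 1).
#'
#' @param dt Sampling interval in seconds, `0 < dt <= 32`.
#' @return Numeric vector of kernel samples at `seq(0, 32, by = dt)`, with a
#'   `times` attribute.
#' @examples
#' h <- canonical_hrf(0.1)
#' attr(h, "times")[which.max(h)]   # ~5 s
#' @export
canonical_hrf <- function(dt) {
  if (length(dt) != 1L || !is.finite(dt) || dt <= 0 || dt > 32) {
    abort("`dt` must be a single value in (0, 32].")
  }
  t <- seq(0, 32, by = dt)
  h <- dgamma(t, shape = 6, rate = 1) - dgamma(t, shape = 16, rate = 1) / 6
  h <- h / sum(h[h > 0])
  attr(h, "times") <- t
  h
}

#' Condition weight series for weighted connectivity
#'
#' Builds the per-volume weight vector for a task condition: a unit-height
#' boxcar over each event's `[onset, onset + duration)` on a fine time grid,
#' convolved with the canonical HRF, sampled at volume acquisition times,
#' with negative convolution lobes rectified to zero (weighted correlation
#' requires nonnegative weights).
#'
#' `condition` may name several trial types: their boxcars are merged into
#' one series (e.g. `c("CSplus_US", "US")` for a shock trial modeled from
#' cue onset through shock offset).
#'
#' @param events Event tibble (`onset`, `duration`, `trial_type`).
#' @param condition Character vector of trial types to include.
#' @param n_vols Number of volumes.
#' @param tr Repetition time, seconds.
#' @param oversample Microtime resolution as a fraction of `tr`.
#' @return A tibble of class `condition_weights` with columns `volume`,
#'   `time`, `weight`; the condition label is kept as an attribute.
#' @export
condition_weight_series <- function(events, condition, n_vols, tr,
                                    oversample = 16L) {
  validate_events(events)
  sel <- as.character(events$trial_type) %in% condition
  if (!any(sel)) {
    abort(paste0("No events with trial_type in {",
                 paste(condition, collapse = ", "), "}."))
  }
  ev <- events[sel, ]
  dt <- tr / oversample
  grid_len <- ceiling(n_vols * tr / dt) + 1L
  grid <- (seq_len(grid_len) - 1L) * dt
  box <- rep(0, grid_len)
  for (i in seq_len(nrow(ev))) {
    on <- ev$onset[i]; off <- ev$onset[i] + ev$duration[i]
    box[grid >= on & grid < off] <- 1
  }
  h <- canonical_hrf(dt)
  conv <- convolve_causal(box, as.numeric(h))
  vol_times <- (seq_len(n_vols) - 1L) * tr
  w <- conv[pmin(round(vol_times / dt) + 1L, grid_len)]
  w <- pmax(w, 0)
  structure(
    tibble(volume = seq_len(n_vols), time = vol_times, weight = w),
    condition = paste(condition, collapse = "+"),
    class = c("condition_weights", class(tibble())))
}

# causal discrete convolution truncated to the input length
convolve_causal <- function(x, k) {
  n <- length(x)
  out <- stats::convolve(x, rev(k), type = "open")[seq_len(n)]
  out
}

# accept a condition_weights tibble or bare numeric vector
as_weight_vector <- function(w, n_vols = NULL) {
  v <- if (inherits(w, "condition_weights") || is.data.frame(w)) {
    w[["weight"]]
  } else {
    as.numeric(w)
  }
  if (anyNA(v) || any(v < 0)) abort("Weights must be nonnegative and finite.")
  if (all(v == 0)) abort("Weights must not be all zero.")
  if (!is.null(n_vols) && length(v) != n_vols) {
    abort("Weight length must equal the volume count.")
  }
  v
}
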