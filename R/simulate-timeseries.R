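#' Simulate ROI time series with condition-dependent heritable connectivity
#'
#' Generates per-subject volumes-by-nodes BOLD-like time series in which
#' designated node pairs share a latent signal whose loading follows the
#' task: during shock trials (merged aversive-cue + shock weight series)
#' the pair correlation is raised by `condition_edge_boost`, so the
#' condition contrast of weighted FC is positive on those edges and
#' centered on zero elsewhere. The per-subject boost magnitude varies
#' around its mean with an ACE-structured factor (`pair_share`), making the
#' planted contrast heritable at the cohort level. The boost enters as a
#' correlation modulation of a latent factor loading, not a mean shift, so
#' regressing out task mean effects leaves the connectivity signal intact.
#' Six-parameter motion traces (translations mm, rotations rad) are emitted
#' per subject, optionally with injected translation spikes for testing
#' motion screening.
#'
#' @param cohort Cohort tibble.
#' @param events Event tibble (see [simulate_task_events()]).
#' @param n_nodes Number of nodes.
#' @param tr Repetition time, seconds (> 0).
#' @param condition_edge_boost Nonnegative latent-factor variance added on
#'   boosted edges at full condition weight.
#' @param pair_share [ace_params()] governing twin sharing of the boost
#'   magnitude.
#' @param boost_edges Two-column matrix of node pairs to boost (upper
#'   triangle); defaults to edge (1, 2).
#' @param spike_subjects Character vector of subject ids receiving one
#'   translation spike.
#' @param spike_mm Spike amplitude in mm.
#' @param seed Optional integer seed.
#' @return List with `ts` (named list of volumes-by-nodes matrices),
#'   `motion` (named list of volumes-by-6 matrices), `boost` (tibble
#'   `subject_id`, `boost`), `n_vols`, `tr`.
#' @export
simulate_roi_timeseries <- function(cohort, events, n_nodes, tr = 2.4,
                                    condition_edge_boost = 0,
                                    pair_share = ace_params(0.6, 0),
                                    boost_edges = cbind(1L, 2L),
                                    spike_subjects = character(0),
                                    spike_mm = 3, seed = NULL) {
  validate_cohort(cohort)
  validate_events(events)
  if (tr <= 0) abort("`tr` must be positive.")
  if (condition_edge_boost < 0) abort("Boost must be nonnegative.")
  be <- as.matrix(boost_edges)
  if (length(be) && (any(be < 1 | be > n_nodes) || any(be[, 1] >= be[, 2]))) {
    abort("boost_edges must be upper-triangle pairs within range.")
  }
  n_vols <- ceiling(events_duration(events) / tr)
  w <- condition_weight_series(events, c("CSplus_US", "US"), n_vols, tr)$weight
  wn <- w / max(w)

  with_seed_or_current(seed, {
    # ACE-structured modulation of the per-subject boost magnitude
    bfac <- pheno_matrix(
      simulate_ace_phenotypes(cohort, pair_share, n_elements = 1L))[, 1]
    boost_s <- condition_edge_boost * pmax(1 + 0.5 * bfac, 0)

    ts <- vector("list", nrow(cohort)); motion <- vector("list", nrow(cohort))
    names(ts) <- names(motion) <- cohort$subject_id
    for (i in seq_len(nrow(cohort))) {
      x <- matrix(rnorm(n_vols * n_nodes), n_vols, n_nodes)
      if (nrow(be) && boost_s[i] > 0) {
        lam <- sqrt(boost_s[i] * wn)
        for (k in seq_len(nrow(be))) {
          f <- rnorm(n_vols)
          x[, be[k, 1]] <- x[, be[k, 1]] + lam * f
          x[, be[k, 2]] <- x[, be[k, 2]] + lam * f
        }
      }
      colnames(x) <- sprintf("n%03d", seq_len(n_nodes))
      ts[[i]] <- x
      m <- cbind(
        apply(matrix(rnorm(n_vols * 3, sd = 0.02), n_vols), 2, cumsum),
        apply(matrix(rnorm(n_vols * 3, sd = 2e-4), n_vols), 2, cumsum))
      if (cohort$subject_id[i] %in% spike_subjects) {
        v <- sample.int(n_vols - 1L, 1L) + 1L
        m[v, 1] <- m[v, 1] + spike_mm
      }
      colnames(m) <- c("trans_x", "trans_y", "trans_z",
                       "rot_x", "rot_y", "rot_z")
      motion[[i]] <- m
    }
    list(ts = ts, motion = motion,
         boost = tibble(subject_id = cohort$subject_id, boost = boost_s),
         n_vols = n_vols, tr = tr)
  })
}
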