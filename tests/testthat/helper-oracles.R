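# Independent oracles and fixture builders shared across test files.

# Brute-force largest supra-threshold component, written without igraph:
# boolean reachability by repeated matrix multiplication, then edge counts
# per component, with the package's documented tie-breaks (edges, then
# nodes, then smallest minimum node id).
brute_largest_component <- function(h2m, tau) {
  n <- nrow(h2m)
  adj <- (h2m > tau) & upper.tri(h2m)
  adj <- adj | t(adj)
  reach <- adj | diag(TRUE, n)
  for (k in seq_len(n)) reach <- (reach %*% reach) > 0
  nodes_with_edges <- which(rowSums(adj) > 0)
  if (!length(nodes_with_edges)) {
    return(list(nodes = integer(0), size_edges = 0L, size_nodes = 0L))
  }
  seen <- rep(FALSE, n)
  comps <- list()
  for (v in nodes_with_edges) {
    if (seen[v]) next
    members <- which(reach[v, ] & rowSums(adj) > 0)
    seen[members] <- TRUE
    comps[[length(comps) + 1L]] <- members
  }
  stats <- lapply(comps, function(m) {
    sub <- adj[m, m, drop = FALSE]
    list(nodes = m, size_edges = sum(sub) / 2, size_nodes = length(m))
  })
  ord <- order(-vapply(stats, `[[`, numeric(1), "size_edges"),
               -vapply(stats, `[[`, numeric(1), "size_nodes"),
               vapply(stats, function(s) min(s$nodes), numeric(1)))
  stats[[ord[1]]]
}

# Recruitment roster reproducing the published exclusion arithmetic:
# 153 nominal pairs, one subject never scanned (305 recruited), 8 full
# high-motion pairs, 4 amplitude outliers in distinct pairs (co-twins
# follow), 17 full pairs plus the widowed twin with missing data.
make_recruitment_roster <- function(seed = 404) {
  cohort <- simulate_cohort(76, 77, seed = seed)       # 153 pairs, 306 subjects
  pairs <- cohort_pairs(cohort)
  dropped <- pairs$twin2[153]                          # never recruited
  roster <- cohort[cohort$subject_id != dropped, ]     # 305 recruited

  motion_pairs <- pairs$pair_id[1:8]
  outlier_subjects <- pairs$twin1[9:12]
  missing_pairs <- pairs$pair_id[13:29]

  qc <- withr::with_seed(seed + 1, tibble::tibble(
    subject_id = roster$subject_id,
    high_motion = roster$pair_id %in% motion_pairs,
    bold_mean = stats::rnorm(nrow(roster)),
    missing = roster$pair_id %in% missing_pairs
  ))
  qc$bold_mean[qc$subject_id %in% outlier_subjects] <- 50
  list(roster = roster, qc = qc,
       truth = list(motion = 16L, outlier = 8L, missing = 35L, final = 246L))
}

# small convenience cohort used in many structural tests
toy_cohort <- function(n_mz = 4, n_dz = 4, seed = 7) {
  simulate_cohort(n_mz, n_dz, seed = seed)
}
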