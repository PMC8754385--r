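#' Condition-weighted ROI-to-ROI functional connectivity
#'
#' Weighted Pearson correlation between every pair of node time series,
#' with weighted means: `r_ij = sum(w (x_i - xbar_w)(x_j - xbar_w)) /
#' sqrt(sum(w (x_i - xbar_w)^2) sum(w (x_j - xbar_w)^2))`, Fisher-z
#' transformed (`atanh`) with `|r|` clipped at `1 - 1e-7` to keep the
#' output finite. A node with zero weighted variance gets a zero row and
#' column with a warning.
#'
#' @param ts Volumes-by-nodes numeric matrix.
#' @param w A [condition_weight_series()] tibble or nonnegative numeric
#'   vector of per-volume weights; at least 3 volumes must carry positive
#'   weight.
#' @return Symmetric node-by-node Fisher-z matrix with zero diagonal.
#' @export
weighted_fc <- function(ts, w) {
  y <- as.matrix(ts)
  wv <- as_weight_vector(w, nrow(y))
  if (sum(wv > 0) < 3L) abort("Need at least 3 positively weighted volumes.")
  cw <- cov.wt(y, wt = wv / sum(wv), cor = FALSE, method = "ML")
  v <- diag(cw$cov)
  bad <- v <= 0 | !is.finite(v)
  r <- matrix(0, ncol(y), ncol(y))
  if (any(bad)) {
    warn(paste0("Node(s) with zero weighted variance set to 0: ",
                paste(which(bad), collapse = ", ")))
  }
  good <- which(!bad)
  if (length(good) >= 2L) {
    cg <- cw$cov[good, good, drop = FALSE]
    r[good, good] <- cg / sqrt(tcrossprod(diag(cg)))
  }
  cap <- 1 - 1e-7
  z <- atanh(pmin(pmax(r, -cap), cap))
  diag(z) <- 0
  dimnames(z) <- list(colnames(y), colnames(y))
  (z + t(z)) / 2
}

#' Condition contrast of two Fisher-z matrices
#'
#' @param z_a,z_b Same-shape symmetric matrices.
#' @return Element-wise `z_a - z_b` with zero diagonal.
#' @export
condition_contrast <- function(z_a, z_b) {
  if (!all(dim(z_a) == dim(z_b))) abort("Matrix shapes differ.")
  out <- z_a - z_b
  diag(out) <- 0
  out
}

#' Network-level summary of an edgewise matrix
#'
#' Summarises node-by-node edge values into network-by-network cells: for
#' distinct networks A and B the sum of all A-B edge values divided by
#' `|A| + |B|`; for A = B the sum of within-network edge values (each
#' unordered pair once) divided by `|A|`.
#'
#' @param m Symmetric node-by-node matrix.
#' @param labels Character/factor vector of network labels, one per node,
#'   or a node-metadata tibble with columns `node_id`, `network`.
#' @return Symmetric network-by-network matrix (dimnames = network names).
#' @export
network_summary <- function(m, labels) {
  if (is.data.frame(labels)) labels <- labels$network
  labels <- as.character(labels)
  if (length(labels) != nrow(m)) abort("One label per node required.")
  if (anyNA(labels)) abort("Every node must be labeled.")
  nets <- sort(unique(labels))
  ind <- vapply(nets, function(g) as.numeric(labels == g),
                numeric(length(labels)))
  sums <- t(ind) %*% m %*% ind          # diagonal double-counts i<j pairs
  sizes <- colSums(ind)
  denom <- outer(sizes, sizes, `+`)
  out <- sums / denom
  diag(out) <- diag(sums) / 2 / sizes
  dimnames(out) <- list(nets, nets)
  out
}

#' Tidy a network summary matrix
#'
#' @param m Network-by-network matrix from [network_summary()].
#' @return Long tibble `network_a`, `network_b`, `value` (upper triangle
#'   plus diagonal).
#' @export
tidy_network_summary <- function(m) {
  nets <- rownames(m)
  idx <- which(upper.tri(m, diag = TRUE), arr.ind = TRUE)
  tibble(network_a = nets[idx[, 1]], network_b = nets[idx[, 2]],
         value = m[idx])
}

#' Subject-level nociceptive FC contrast from time series
#'
#' Convenience wrapper running the full first-level chain for one subject:
#' confound regression (task mean effects, 12 motion terms, scrub
#' regressors), band-pass filtering, condition-weighted FC for two
#' conditions, and their contrast.
#'
#' @param ts Volumes-by-nodes matrix.
#' @param events Event tibble.
#' @param tr Repetition time (s).
#' @param condition_a,condition_b Character vectors of trial types for the
#'   two conditions (A minus B).
#' @param motion Optional volumes-by-6 motion matrix.
#' @param scrub_vols Optional integer vector of volumes to scrub.
#' @param band Length-2 numeric pass band in Hz.
#' @return Symmetric Fisher-z contrast matrix.
#' @export
fc_contrast_pipeline <- function(ts, events, tr,
                                 condition_a = c("CSplus_US", "US"),
                                 condition_b = "CSplus_noUS",
                                 motion = NULL, scrub_vols = NULL,
                                 band = c(0.008, 0.09)) {
  y <- as.matrix(ts)
  n_vols <- nrow(y)
  w_a <- condition_weight_series(events, condition_a, n_vols, tr)
  w_b <- condition_weight_series(events, condition_b, n_vols, tr)
  conf <- cbind(task_a = w_a$weight, task_b = w_b$weight)
  if (!is.null(motion)) conf <- cbind(conf, motion_confounds(motion))
  sc <- scrub_regressors(scrub_vols, n_vols)
  if (!is.null(sc)) conf <- cbind(conf, sc)
  resid <- regress_confounds(y, conf)
  filt <- bandpass_filter(resid, tr, band[1], band[2])
  condition_contrast(weighted_fc(filt, w_a), weighted_fc(filt, w_b))
}
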