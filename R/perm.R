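#' Permute twin identity (zygosity shuffle)
#'
#' Randomly reassigns the MZ/DZ labels across pairs while preserving the MZ
#' and DZ pair counts and leaving pair memberships untouched. This breaks
#' the differential genetic sharing that identifies the additive component
#' while keeping within-pair dependence, making it the exchangeability-
#' respecting null for tests of A > 0.
#'
#' @param cohort Cohort tibble with at least 2 pairs.
#' @param seed Optional integer seed.
#' @return A cohort tibble with permuted zygosity labels.
#' @export
permute_zygosity <- function(cohort, seed = NULL) {
  validate_cohort(cohort)
  pairs <- cohort_pairs(cohort)
  if (nrow(pairs) < 2L) abort("Need at least 2 pairs to permute.")
  with_seed_or_current(seed, {
    perm <- sample.int(nrow(pairs))
    new_zyg <- pairs$zygosity[perm]
    out <- cohort
    out$zygosity <- new_zyg[match(cohort$pair_id, pairs$pair_id)]
    out
  })
}

# permute a pair-level dizygosity indicator in place (fast path used inside
# permutation loops; RNG state managed by the caller)
permute_is_dz <- function(is_dz) is_dz[sample.int(length(is_dz))]

#' Element-wise FWE-corrected permutation p-values
#'
#' Max-statistic permutation correction for the per-element test of
#' additive-genetic variance: the observed one-sided slope statistic of
#' every element is compared against the permutation distribution of the
#' maximum statistic over all elements under zygosity shuffling, giving
#' `p_e = (1 + #{perm max >= stat_e}) / (n_perm + 1)`.
#'
#' @param pheno Phenotype tibble or matrix (see [lrsd_ace()]).
#' @param cohort Cohort tibble.
#' @param n_perm Number of permutations (>= 100 recommended).
#' @param seed Optional integer seed.
#' @return Tibble with columns `element`, `stat_A`, `p_fwe`.
#' @export
elementwise_fwe <- function(pheno, cohort, n_perm = 1000, seed = NULL) {
  validate_cohort(cohort)
  y <- if (is.matrix(pheno)) pheno else pheno_matrix(pheno)
  y <- y[cohort$subject_id, , drop = FALSE]
  sq <- pair_sq_diffs(y, cohort)
  degenerate <- sq$var_p <= 0
  if (any(degenerate)) {
    warn(paste0("Excluding degenerate element(s): ",
                paste(colnames(y)[degenerate], collapse = ", ")))
  }
  d <- sq$d[, !degenerate, drop = FALSE]
  obs <- pmax(lrsd_t(d, sq$is_dz)$t, 0)
  max_null <- with_seed_or_current(seed, {
    vapply(seq_len(n_perm), function(b) {
      max(pmax(lrsd_t(d, permute_is_dz(sq$is_dz))$t, 0))
    }, numeric(1))
  })
  p <- vapply(obs, function(s) (1 + sum(max_null >= s)) / (n_perm + 1),
              numeric(1))
  tibble(element = colnames(d), stat_A = unname(obs), p_fwe = unname(p))
}

# coerce an adjacency specification (igraph or 2-column edge index matrix)
# into an igraph over n named element vertices
as_element_graph <- function(adjacency, elements) {
  if (inherits(adjacency, "igraph")) {
    g <- adjacency
    if (igraph::vcount(g) != length(elements)) {
      abort("Adjacency must cover all elements.")
    }
    igraph::V(g)$name <- elements
    return(g)
  }
  el <- as.matrix(adjacency)
  if (length(el) && (ncol(el) != 2L || any(el < 1 | el > length(elements)))) {
    abort("Adjacency edge list must be a 2-column index matrix over elements.")
  }
  g <- igraph::make_empty_graph(n = length(elements), directed = FALSE)
  igraph::V(g)$name <- elements
  if (length(el)) g <- igraph::add_edges(g, t(el))
  g
}

# components of the subgraph induced by a logical supra-threshold mask;
# returns a list of integer vectors of element indices, largest first
supra_clusters <- function(g, supra) {
  ids <- which(supra)
  if (!length(ids)) return(list())
  sub <- igraph::induced_subgraph(g, ids)
  comp <- igraph::components(sub)
  cl <- split(ids[seq_along(comp$membership)], comp$membership)
  cl[order(-lengths(cl), vapply(cl, min, numeric(1)))]
}

#' Cluster-extent FWE inference on a heritability map
#'
#' Thresholds the per-element parametric p-values for A > 0 at the cluster-
#' forming level, groups supra-threshold elements into connected clusters
#' under a user-supplied adjacency, and assigns each observed cluster a
#' family-wise-error p-value from the permutation null distribution of the
#' maximum cluster extent (element count) under zygosity shuffling.
#'
#' @param pheno Phenotype tibble or matrix.
#' @param cohort Cohort tibble.
#' @param adjacency An igraph over the elements or a 2-column edge index
#'   matrix; isolated elements form singleton clusters.
#' @param forming_p Cluster-forming threshold on the parametric p (strict
#'   `<`).
#' @param n_perm Number of permutations.
#' @param seed Optional integer seed.
#' @return Tibble with one row per observed cluster: `cluster`, `elements`
#'   (list column of element names), `extent`, `fwe_p`; zero rows when no
#'   element survives the forming threshold.
#' @export
cluster_fwe <- function(pheno, cohort, adjacency, forming_p = 0.05,
                        n_perm = 1000, seed = NULL) {
  validate_cohort(cohort)
  y <- if (is.matrix(pheno)) pheno else pheno_matrix(pheno)
  y <- y[cohort$subject_id, , drop = FALSE]
  g <- as_element_graph(adjacency, colnames(y))
  sq <- pair_sq_diffs(y, cohort)
  obs_p <- boundary_p(lrsd_t(sq$d, sq$is_dz)$t)
  clusters <- supra_clusters(g, obs_p < forming_p)
  null_max <- with_seed_or_current(seed, {
    vapply(seq_len(n_perm), function(b) {
      pb <- boundary_p(lrsd_t(sq$d, permute_is_dz(sq$is_dz))$t)
      cl <- supra_clusters(g, pb < forming_p)
      if (length(cl)) max(lengths(cl)) else 0L
    }, numeric(1))
  })
  if (!length(clusters)) {
    return(tibble(cluster = integer(0), elements = list(),
                  extent = integer(0), fwe_p = numeric(0)))
  }
  tibble(
    cluster = seq_along(clusters),
    elements = lapply(clusters, function(i) colnames(y)[i]),
    extent = lengths(clusters),
    fwe_p = vapply(lengths(clusters), function(ext)
      (1 + sum(null_max >= ext)) / (n_perm + 1), numeric(1))
  )
}

#' Power curve for detecting additive-genetic variance in a twin design
#'
#' Monte-Carlo power of the one-sided squared-pair-differences test for
#' A > 0 at significance level `alpha`, over a grid of true additive-
#' genetic fractions (with C = 0, E = 1 - A and unit phenotype variance).
#' Reports the smallest A reaching 80% power by linear interpolation
#' between grid points.
#'
#' @param n_mz,n_dz Numbers of MZ and DZ pairs.
#' @param a_grid Increasing grid of additive-genetic fractions in `[0, 1)`.
#' @param alpha Significance level.
#' @param n_rep Replicates per grid point (>= 500 recommended).
#' @param seed Optional integer seed.
#' @param power_target Power level to locate on the curve.
#' @return A tibble of class `twin_power_curve` with columns `a`, `power`;
#'   attributes `a80` (interpolated crossing, NA if never reached),
#'   `alpha`, `n_rep`, `n_mz`, `n_dz`.
#' @examples
#' pw <- twin_power_curve(56, 67, a_grid = c(0.3, 0.6, 0.9),
#'                        n_rep = 200, seed = 1)
#' attr(pw, "a80")
#' @export
twin_power_curve <- function(n_mz, n_dz, a_grid = seq(0.1, 0.9, by = 0.05),
                             alpha = 0.05, n_rep = 2000, seed = NULL,
                             power_target = 0.80) {
  if (!length(a_grid)) abort("Empty grid.")
  if (any(a_grid < 0 | a_grid >= 1)) abort("Grid values must lie in [0, 1).")
  if (is.unsorted(a_grid, strictly = TRUE)) abort("Grid must be increasing.")
  cohort <- simulate_cohort(n_mz, n_dz, seed = 1L)  # structure only
  power <- with_seed_or_current(seed, {
    vapply(a_grid, function(a) {
      ph <- simulate_ace_phenotypes(
        cohort, ace_params(A = a, C = 0), n_elements = n_rep)
      sq <- pair_sq_diffs(pheno_matrix(ph), cohort)
      p <- boundary_p(lrsd_t(sq$d, sq$is_dz)$t)
      mean(p <= alpha)
    }, numeric(1))
  })
  a80 <- NA_real_
  hit <- which(power >= power_target)
  if (length(hit)) {
    i <- hit[1]
    a80 <- if (i == 1L) a_grid[1] else {
      a_grid[i - 1] + (power_target - power[i - 1]) *
        (a_grid[i] - a_grid[i - 1]) / (power[i] - power[i - 1])
    }
  }
  out <- tibble(a = a_grid, power = power)
  class(out) <- c("twin_power_curve", class(out))
  attr(out, "a80") <- a80
  attr(out, "alpha") <- alpha
  attr(out, "n_rep") <- n_rep
  attr(out, "n_mz") <- n_mz
  attr(out, "n_dz") <- n_dz
  attr(out, "power_target") <- power_target
  out
}

#' @method glance twin_power_curve
#' @export
glance.twin_power_curve <- function(x, ...) {
  tibble(a80 = attr(x, "a80"), alpha = attr(x, "alpha"),
         n_rep = attr(x, "n_rep"),
         n_mz = attr(x, "n_mz"), n_dz = attr(x, "n_dz"))
}

#' @method autoplot twin_power_curve
#' @export
autoplot.twin_power_curve <- function(object, ...) {
  tgt <- attr(object, "power_target")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$a, y = .data$power)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = tgt, linetype = "dashed") +
    ggplot2::labs(
      x = "additive-genetic variance fraction (A)",
      y = sprintf("power at alpha = %.2f", attr(object, "alpha")),
      title = sprintf("Twin-design power, %d MZ + %d DZ pairs",
                      attr(object, "n_mz"), attr(object, "n_dz"))) +
    ggplot2::ylim(0, 1)
  a80 <- attr(object, "a80")
  if (is.finite(a80)) {
    p <- p + ggplot2::geom_vline(xintercept = a80, linetype = "dotted")
  }
  p
}
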