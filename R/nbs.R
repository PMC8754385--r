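#' Edgewise heritability of a functional-connectivity stack
#'
#' Vectorizes the upper triangle of every subject's FC matrix, fits the
#' squared-pair-differences ACE model to each edge, and reshapes the
#' constrained heritability estimates into a symmetric node-by-node matrix
#' with zero diagonal. Degenerate edges (zero variance across subjects)
#' get h2 = 0 with a warning.
#'
#' @param fc An [fc_stack()] with one matrix per cohort subject.
#' @param cohort Cohort tibble.
#' @return A symmetric matrix of class `h2_matrix` with entries in `[0, 1]`;
#'   node metadata from the stack is attached as an attribute.
#' @export
edgewise_h2 <- function(fc, cohort) {
  validate_cohort(cohort)
  stopifnot(inherits(fc, "fc_stack"))
  missing_ids <- setdiff(cohort$subject_id, names(fc$mats))
  if (length(missing_ids)) {
    abort(paste0("FC stack missing subject(s): ",
                 paste(head(missing_ids, 3), collapse = ", ")))
  }
  y <- fc_edge_matrix(fc)[cohort$subject_id, , drop = FALSE]
  sq <- pair_sq_diffs(y, cohort)
  est <- ace_from_moments(colMeans(sq$d[!sq$is_dz, , drop = FALSE]),
                          colMeans(sq$d[sq$is_dz, , drop = FALSE]),
                          sq$var_p)
  h2 <- est$h2
  if (anyNA(h2)) {
    warn(sprintf("%d degenerate edge(s) set to h2 = 0.", sum(is.na(h2))))
    h2[is.na(h2)] <- 0
  }
  m <- edge_vector_to_matrix(h2, fc$n_nodes)
  structure(m, node_meta = fc$node_meta, class = c("h2_matrix", "matrix"))
}

# fast h2 vector for permutation loops (degenerate edges -> 0)
h2_vector <- function(d, is_dz, var_p) {
  est <- ace_from_moments(colMeans(d[!is_dz, , drop = FALSE]),
                          colMeans(d[is_dz, , drop = FALSE]), var_p)
  h2 <- est$h2
  h2[is.na(h2)] <- 0
  h2
}

# largest-component edge count for an h2 edge vector thresholded at tau
# (strict >), over the n-node edge layout `edges` (from upper_tri_edges)
max_component_edges <- function(h2, edges, tau) {
  keep <- h2 > tau
  if (!any(keep)) return(0L)
  el <- cbind(edges$node_a[keep], edges$node_b[keep])
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  memb <- igraph::components(g)$membership
  max(tabulate(memb[el[, 1]]))
}

#' Largest supra-threshold connected component
#'
#' Binarizes the heritability matrix at `h2 > tau` (strict) and returns the
#' connected component with the most edges; ties are broken by node count,
#' then by the smallest minimum node id, so the output is deterministic.
#'
#' @param h2m An `h2_matrix` (or any symmetric nonnegative matrix).
#' @param tau Threshold in `[0, 1]`.
#' @return Object of class `component_result`: `nodes` (sorted integer
#'   ids), `edges` (tibble `node_a`, `node_b`, `h2`), `size_edges`,
#'   `size_nodes`, `threshold`, `p_perm` (NA until tested).
#' @export
largest_component <- function(h2m, tau) {
  if (tau < 0 || tau > 1) abort("`tau` must lie in [0, 1].")
  n <- nrow(h2m)
  edges <- upper_tri_edges(n)
  h2 <- h2m[upper.tri(h2m)]
  keep <- h2 > tau
  empty <- structure(
    list(nodes = integer(0),
         edges = tibble(node_a = integer(0), node_b = integer(0),
                        h2 = numeric(0)),
         size_edges = 0L, size_nodes = 0L, threshold = tau,
         p_perm = NA_real_),
    class = "component_result")
  if (!any(keep)) return(empty)
  el <- cbind(edges$node_a[keep], edges$node_b[keep])
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  memb <- igraph::components(g)$membership
  edge_comp <- memb[el[, 1]]
  n_edges <- tabulate(edge_comp)
  n_nodes <- tabulate(memb)[seq_along(n_edges)]
  min_node <- vapply(seq_along(n_edges), function(k)
    min(which(memb == k)), numeric(1))
  best <- order(-n_edges, -n_nodes, min_node)[1]
  sel <- edge_comp == best
  structure(
    list(nodes = sort(which(memb == best)),
         edges = tibble(node_a = el[sel, 1], node_b = el[sel, 2],
                        h2 = h2[keep][sel]),
         size_edges = sum(sel), size_nodes = sum(memb == best),
         threshold = tau, p_perm = NA_real_),
    class = "component_result")
}

#' @export
print.component_result <- function(x, ...) {
  cat(sprintf("<component_result> %d edges over %d nodes at h2 > %.3f",
              x$size_edges, x$size_nodes, x$threshold))
  if (is.finite(x$p_perm)) cat(sprintf(", p_perm = %.4g", x$p_perm))
  cat("\n")
  invisible(x)
}

#' @method tidy component_result
#' @export
tidy.component_result <- function(x, ...) x$edges

#' @method glance component_result
#' @export
glance.component_result <- function(x, ...) {
  tibble(size_edges = x$size_edges, size_nodes = x$size_nodes,
         threshold = x$threshold, p_perm = x$p_perm)
}

#' Network-based-statistics test for a heritable component
#'
#' Tests whether the largest connected component of the edgewise
#' heritability matrix thresholded at `tau` is larger than expected under
#' the null of no differential genetic sharing: the heritability matrix is
#' recomputed for `n_perm` zygosity shuffles and the observed component's
#' edge count is compared with the permutation distribution of the maximum
#' component edge count, giving
#' `p = (1 + #{perm size >= observed}) / (n_perm + 1)`.
#'
#' @param fc An [fc_stack()].
#' @param cohort Cohort tibble.
#' @param tau Binarization threshold on h2.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Optional integer seed.
#' @return A `component_result` with `p_perm` filled in and the null edge-
#'   count distribution attached as attribute `null_sizes`.
#' @export
nbs_h2_test <- function(fc, cohort, tau, n_perm = 1000, seed = NULL) {
  validate_cohort(cohort)
  y <- fc_edge_matrix(fc)[cohort$subject_id, , drop = FALSE]
  edges <- upper_tri_edges(fc$n_nodes)
  sq <- pair_sq_diffs(y, cohort)
  obs_h2 <- h2_vector(sq$d, sq$is_dz, sq$var_p)
  obs <- largest_component(edge_vector_to_matrix(obs_h2, fc$n_nodes), tau)
  null_sizes <- with_seed_or_current(seed, {
    vapply(seq_len(n_perm), function(b) {
      max_component_edges(
        h2_vector(sq$d, permute_is_dz(sq$is_dz), sq$var_p), edges, tau)
    }, integer(1))
  })
  obs$p_perm <- (1 + sum(null_sizes >= obs$size_edges)) / (n_perm + 1)
  attr(obs, "null_sizes") <- null_sizes
  attr(obs, "n_perm") <- n_perm
  obs
}

#' Component size and significance over a threshold grid
#'
#' Runs the network-based-statistics test over an ascending grid of h2
#' thresholds, re-using one shared permutation stream: each permuted
#' heritability matrix is computed once and re-thresholded at every `tau`,
#' so the sweep is internally consistent and costs one permutation pass.
#'
#' @param fc An [fc_stack()].
#' @param cohort Cohort tibble.
#' @param taus Ascending numeric vector of thresholds.
#' @param n_perm Number of permutations.
#' @param seed Optional integer seed.
#' @return Tibble of class `nbs_sweep` with columns `tau`, `size_edges`,
#'   `size_nodes`, `p_perm`.
#' @export
threshold_sweep <- function(fc, cohort, taus = c(seq(0.25, 0.32, by = 0.01),
                                                 0.328),
                            n_perm = 1000, seed = NULL) {
  if (is.unsorted(taus, strictly = TRUE)) abort("`taus` must be ascending.")
  validate_cohort(cohort)
  y <- fc_edge_matrix(fc)[cohort$subject_id, , drop = FALSE]
  edges <- upper_tri_edges(fc$n_nodes)
  sq <- pair_sq_diffs(y, cohort)
  obs_h2 <- h2_vector(sq$d, sq$is_dz, sq$var_p)
  obs_m <- edge_vector_to_matrix(obs_h2, fc$n_nodes)
  obs <- lapply(taus, function(tau) largest_component(obs_m, tau))
  null_sizes <- with_seed_or_current(seed, {
    vapply(seq_len(n_perm), function(b) {
      h2b <- h2_vector(sq$d, permute_is_dz(sq$is_dz), sq$var_p)
      vapply(taus, function(tau) max_component_edges(h2b, edges, tau),
             integer(1))
    }, integer(length(taus)))
  })
  null_sizes <- matrix(null_sizes, nrow = n_perm, ncol = length(taus),
                       byrow = TRUE)
  out <- tibble(
    tau = taus,
    size_edges = vapply(obs, `[[`, integer(1), "size_edges"),
    size_nodes = vapply(obs, `[[`, integer(1), "size_nodes"))
  out$p_perm <- vapply(seq_along(taus), function(j)
    (1 + sum(null_sizes[, j] >= out$size_edges[j])) / (n_perm + 1),
    numeric(1))
  class(out) <- c("nbs_sweep", class(out))
  attr(out, "n_perm") <- n_perm
  out
}

#' @method autoplot nbs_sweep
#' @export
autoplot.nbs_sweep <- function(object, alpha = 0.05, ...) {
  df <- as_tibble(object)
  df$significant <- df$p_perm < alpha
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tau, y = .data$size_edges)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(color = .data$significant)) +
    ggplot2::labs(x = "h2 threshold", y = "largest component (edges)",
                  color = sprintf("p < %.2f", alpha))
}

#' Within- and between-network edge counts of a component
#'
#' @param comp A `component_result`.
#' @param labels Network labels (vector, one per node, or node-metadata
#'   tibble with a `network` column).
#' @return Symmetric network-by-network integer count matrix whose total
#'   (upper triangle + diagonal) equals the component's edge count.
#' @export
component_network_edge_counts <- function(comp, labels) {
  if (is.data.frame(labels)) labels <- labels$network
  labels <- as.character(labels)
  nets <- sort(unique(labels))
  out <- matrix(0L, length(nets), length(nets), dimnames = list(nets, nets))
  if (!comp$size_edges) return(out)
  la <- labels[comp$edges$node_a]
  lb <- labels[comp$edges$node_b]
  if (anyNA(la) || anyNA(lb)) abort("Every component node must be labeled.")
  for (k in seq_along(la)) {
    i <- match(la[k], nets); j <- match(lb[k], nets)
    out[i, j] <- out[i, j] + 1L
    if (i != j) out[j, i] <- out[j, i] + 1L
  }
  out
}

#' Overlap of a component's nodes with a reference node set
#'
#' @param comp A `component_result`.
#' @param node_set Integer vector of node ids (e.g., nodes inside an
#'   a-priori pain-signature mask).
#' @return Named integer vector `c(inside, outside)`, summing to the
#'   component's node count.
#' @export
node_overlap <- function(comp, node_set) {
  inside <- sum(comp$nodes %in% node_set)
  c(inside = inside, outside = comp$size_nodes - inside)
}

#' Heatmap of an edgewise heritability matrix
#'
#' @param object An `h2_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot h2_matrix
#' @export
autoplot.h2_matrix <- function(object, ...) {
  n <- nrow(object)
  df <- tidyr::expand_grid(node_a = seq_len(n), node_b = seq_len(n))
  df$h2 <- as.vector(t(unclass(object)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$node_b, y = .data$node_a,
                                   fill = .data$h2)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "node", y = "node", fill = "h2")
}

#' Write a component as an edge list plus JSON summary
#'
#' @param comp A `component_result`.
#' @param edge_path Path for the tab-separated edge list
#'   (`node_a`, `node_b`, `h2`).
#' @param json_path Optional path for a JSON summary (sizes, threshold,
#'   permutation p).
#' @return `edge_path`, invisibly.
#' @export
write_component <- function(comp, edge_path, json_path = NULL) {
  readr::write_tsv(comp$edges, edge_path, progress = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(size_edges = comp$size_edges, size_nodes = comp$size_nodes,
           threshold = comp$threshold, p_perm = comp$p_perm,
           nodes = comp$nodes),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(edge_path)
}
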