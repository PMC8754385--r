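#' Per-subject functional-connectivity matrix stack
#'
#' Container for one symmetric node-by-node matrix per subject on the
#' Fisher-z scale (or any edgewise phenotype laid out as a matrix), with
#' optional node metadata (network labels, coordinates).
#'
#' @param mats Named list of symmetric numeric matrices (names are subject
#'   ids), all of the same dimension, zero diagonal, finite entries.
#' @param node_meta Optional tibble with columns `node_id`, `network` and
#'   optionally `x`, `y`, `z` (MNI mm).
#' @return An object of class `fc_stack`.
#' @export
fc_stack <- function(mats, node_meta = NULL) {
  if (!length(mats) || is.null(names(mats)) || any(names(mats) == "")) {
    abort("`mats` must be a non-empty named list of matrices.")
  }
  n <- unique(vapply(mats, nrow, integer(1)))
  if (length(n) != 1L || any(vapply(mats, ncol, integer(1)) != n)) {
    abort("All matrices must be square with a common node count.")
  }
  for (m in mats) {
    if (!all(is.finite(m))) abort("FC matrices must be finite.")
    if (max(abs(m - t(m))) > 1e-8) abort("FC matrices must be symmetric.")
  }
  if (!is.null(node_meta) && nrow(node_meta) != n) {
    abort("node_meta must have one row per node.")
  }
  structure(list(mats = mats, node_meta = node_meta, n_nodes = n),
            class = "fc_stack")
}

#' @export
print.fc_stack <- function(x, ...) {
  cat(sprintf("<fc_stack> %d subjects x %d nodes (%d edges)\n",
              length(x$mats), x$n_nodes, x$n_nodes * (x$n_nodes - 1) / 2))
  invisible(x)
}

#' @export
length.fc_stack <- function(x) length(x$mats)

# upper-triangle edge index for an n-node graph, column-major to match
# upper.tri() vectorization
upper_tri_edges <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  tibble(node_a = idx[, "row"], node_b = idx[, "col"],
         edge = sprintf("%d-%d", idx[, "row"], idx[, "col"]))
}

# stack -> subjects x edges matrix of upper-triangle values
fc_edge_matrix <- function(stack) {
  stopifnot(inherits(stack, "fc_stack"))
  n <- stack$n_nodes
  ut <- upper.tri(matrix(0, n, n))
  y <- t(vapply(stack$mats, function(m) m[ut],
                numeric(n * (n - 1) / 2)))
  colnames(y) <- upper_tri_edges(n)$edge
  y
}

# edge-values vector -> symmetric matrix with zero diagonal
edge_vector_to_matrix <- function(v, n) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- v
  m + t(m)
}

#' Long tidy view of an FC stack
#'
#' @param x An `fc_stack`.
#' @param ... Unused.
#' @return Tibble with columns `subject_id`, `node_a`, `node_b`, `value`.
#' @method tidy fc_stack
#' @export
tidy.fc_stack <- function(x, ...) {
  edges <- upper_tri_edges(x$n_nodes)
  y <- fc_edge_matrix(x)
  tidyr::expand_grid(subject_id = rownames(y), edges[, c("node_a", "node_b")]) %>%
    mutate(value = as.vector(t(y)))
}

#' Simulate edgewise ACE-structured FC phenotypes
#'
#' Generates one symmetric FC matrix per subject by drawing every upper-
#' triangle edge from the twin ACE model: edges in `planted_edges` use
#' `planted_params`, all other edges use `background_params`. This is the
#' direct edge-level route for testing heritability mapping without the
#' time-series pipeline.
#'
#' @param cohort Cohort tibble.
#' @param n_nodes Number of nodes.
#' @param planted_edges Two-column matrix/data frame of node index pairs
#'   (upper triangle, `node_a < node_b`), or `NULL` for none.
#' @param planted_params,background_params [ace_params()] for planted and
#'   background edges.
#' @param node_meta Optional node metadata tibble.
#' @param seed Optional integer seed.
#' @return An [fc_stack()] with one matrix per subject.
#' @export
simulate_fc_phenotypes <- function(cohort, n_nodes, planted_edges = NULL,
                                   planted_params = ace_params(0.6, 0),
                                   background_params = ace_params(0, 0),
                                   node_meta = NULL, seed = NULL) {
  validate_cohort(cohort)
  edges <- upper_tri_edges(n_nodes)
  n_edges <- nrow(edges)
  planted_idx <- integer(0)
  if (!is.null(planted_edges) && NROW(planted_edges) > 0) {
    pe <- as.matrix(planted_edges)[, 1:2, drop = FALSE]
    if (any(pe < 1 | pe > n_nodes)) abort("Planted edge index out of range.")
    if (any(pe[, 1] >= pe[, 2])) {
      abort("Planted edges must be upper-triangle pairs (node_a < node_b).")
    }
    key <- sprintf("%d-%d", pe[, 1], pe[, 2])
    planted_idx <- match(key, edges$edge)
    if (anyNA(planted_idx)) abort("Planted edge index out of range.")
  }
  pm <- as_ace_matrix(background_params)[rep(1L, n_edges), , drop = FALSE]
  if (length(planted_idx)) {
    pm[planted_idx, ] <- as_ace_matrix(planted_params)[
      rep(1L, length(planted_idx)), ]
  }
  pheno <- simulate_ace_phenotypes(cohort, as.data.frame(pm), seed = seed)
  y <- pheno_matrix(pheno)
  mats <- lapply(seq_len(nrow(y)), function(i)
    edge_vector_to_matrix(y[i, ], n_nodes))
  names(mats) <- rownames(y)
  out <- fc_stack(mats, node_meta)
  out$planted_edges <- edges$edge[planted_idx]
  out
}

#' Read / write an FC matrix stack
#'
#' One tab-separated file per subject (square matrix with node-id header),
#' in a directory; file names are `<subject_id>.tsv`.
#'
#' @param dir Directory path.
#' @param stack An `fc_stack`.
#' @param node_meta Optional node metadata to attach on read.
#' @return `read_fc_stack()` returns an `fc_stack`.
#' @export
write_fc_stack <- function(stack, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (id in names(stack$mats)) {
    write_matrix_tsv(stack$mats[[id]], file.path(dir, paste0(id, ".tsv")))
  }
  invisible(dir)
}

#' @rdname write_fc_stack
#' @export
read_fc_stack <- function(dir, node_meta = NULL) {
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  if (!length(files)) abort("No .tsv matrix files found.")
  mats <- lapply(files, read_matrix_tsv)
  names(mats) <- sub("\\.tsv$", "", basename(files))
  fc_stack(mats, node_meta)
}
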