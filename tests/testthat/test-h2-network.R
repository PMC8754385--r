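test_that("largest_component matches hand-built and brute-force answers", {
  m <- matrix(0, 5, 5)
  m[1, 2] <- m[2, 3] <- m[4, 5] <- 0.9
  m <- m + t(m)
  comp <- largest_component(m, 0.5)
  expect_equal(comp$nodes, 1:3)
  expect_equal(comp$size_edges, 2L)
  expect_equal(comp$size_nodes, 3L)

  empty <- largest_component(m, 0.95)
  expect_equal(empty$size_edges, 0L)
  expect_equal(empty$size_nodes, 0L)

  # random 6-node instances against the independent reachability oracle
  withr::with_seed(42, {
    for (i in 1:100) {
      r <- matrix(runif(36), 6); r <- (r + t(r)) / 2; diag(r) <- 0
      tau <- runif(1, 0.2, 0.8)
      got <- largest_component(r, tau)
      want <- brute_largest_component(r, tau)
      expect_equal(got$size_edges, as.integer(want$size_edges))
      expect_equal(got$size_nodes, as.integer(want$size_nodes))
      expect_equal(got$nodes, want$nodes, ignore_attr = TRUE)
    }
  })

  # monotone shrinkage under threshold increase
  sizes <- vapply(seq(0, 0.9, by = 0.1), function(tau)
    largest_component(m, tau)$size_edges, integer(1))
  expect_true(all(diff(sizes) <= 0))
  expect_error(largest_component(m, 1.5), "\\[0, 1\\]")
})

test_that("edgewise heritability separates planted from background edges", {
  co <- simulate_cohort(200, 200, seed = 51)
  fc <- simulate_fc_phenotypes(co, n_nodes = 15,
                               planted_edges = cbind(1:5, 2:6),
                               planted_params = ace_params(0.6, 0),
                               seed = 52)
  h2 <- edgewise_h2(fc, co)
  expect_s3_class(h2, "h2_matrix")
  expect_true(isSymmetric(unclass(h2)))
  expect_true(all(h2 >= 0 & h2 <= 1))
  expect_true(all(diag(h2) == 0))

  ut <- upper_tri_edges(15)
  planted <- ut$edge %in% fc$planted_edges
  vals <- h2[upper.tri(h2)]
  expect_gt(mean(vals[planted]), mean(vals[!planted]) + 0.2)

  # pure-noise stack concentrates near zero
  noise <- simulate_fc_phenotypes(co, n_nodes = 10, seed = 53)
  h2n <- edgewise_h2(noise, co)
  expect_lt(median(h2n[upper.tri(h2n)]), 0.15)
})

test_that("edgewise heritability commutes with node relabeling", {
  co <- simulate_cohort(20, 20, seed = 61)
  fc <- simulate_fc_phenotypes(co, n_nodes = 8,
                               planted_edges = cbind(1L, 2L),
                               planted_params = ace_params(0.7, 0),
                               seed = 62)
  perm <- c(3, 1, 4, 2, 8, 6, 5, 7)
  fc_perm <- fc_stack(lapply(fc$mats, function(m) m[perm, perm]))
  h2 <- edgewise_h2(fc, co)
  h2p <- edgewise_h2(fc_perm, co)
  expect_equal(unclass(h2p), unclass(h2)[perm, perm], ignore_attr = TRUE)
})

test_that("the NBS permutation p hits its floor for an overwhelming signal", {
  co <- simulate_cohort(80, 80, seed = 71)
  fc <- simulate_fc_phenotypes(co, n_nodes = 12,
                               planted_edges = cbind(1:8, 2:9),
                               planted_params = ace_params(0.9, 0),
                               seed = 72)
  res <- nbs_h2_test(fc, co, tau = 0.4, n_perm = 99, seed = 73)
  expect_equal(res$p_perm, 1 / 100)
  expect_gte(res$size_edges, 6)
  expect_true(all(res$edges$h2 > 0.4))
})

test_that("threshold sweeps share one permutation stream deterministically", {
  co <- simulate_cohort(40, 40, seed = 81)
  fc <- simulate_fc_phenotypes(co, n_nodes = 10,
                               planted_edges = cbind(1:4, 2:5),
                               planted_params = ace_params(0.8, 0),
                               seed = 82)
  taus <- seq(0.1, 0.5, by = 0.1)
  sw1 <- threshold_sweep(fc, co, taus, n_perm = 60, seed = 83)
  sw2 <- threshold_sweep(fc, co, taus, n_perm = 60, seed = 83)
  expect_equal(as_tibble(sw1), as_tibble(sw2))
  expect_true(all(diff(sw1$size_edges) <= 0))
  expect_s3_class(autoplot(sw1), "ggplot")
  expect_s3_class(autoplot(edgewise_h2(fc, co)), "ggplot")
  expect_error(threshold_sweep(fc, co, rev(taus)), "ascending")

  # single-threshold sweep row agrees with the direct test
  one <- threshold_sweep(fc, co, 0.3, n_perm = 60, seed = 99)
  direct <- nbs_h2_test(fc, co, tau = 0.3, n_perm = 60, seed = 99)
  expect_equal(one$size_edges, direct$size_edges)
  expect_equal(one$p_perm, direct$p_perm)
})

test_that("component summaries count edges and nodes correctly", {
  m <- matrix(0, 6, 6)
  m[1, 2] <- m[3, 4] <- 0.9     # edges between networks X and Y
  m[1, 3] <- 0.9                # within X
  m <- m + t(m)
  labels <- c("X", "Y", "X", "Y", "Z", "Z")
  comp <- largest_component(m, 0.5)
  counts <- component_network_edge_counts(comp, labels)
  expect_equal(counts["X", "Y"], 2L)
  expect_equal(counts["X", "X"], 1L)
  expect_equal(sum(counts[upper.tri(counts, diag = TRUE)]), comp$size_edges)

  empty <- largest_component(m, 0.99)
  expect_true(all(component_network_edge_counts(empty, labels) == 0))

  expect_equal(node_overlap(comp, 1:6),
               c(inside = comp$size_nodes, outside = 0L))
  expect_equal(node_overlap(comp, integer(0)),
               c(inside = 0L, outside = comp$size_nodes))
  expect_equal(node_overlap(list(nodes = 1:3, size_nodes = 3L), c(2, 3, 4)),
               c(inside = 2L, outside = 1L))
})

test_that("result objects round-trip through tidy/glance/io", {
  co <- simulate_cohort(20, 20, seed = 91)
  fc <- simulate_fc_phenotypes(co, n_nodes = 6,
                               planted_edges = cbind(1L, 2L),
                               planted_params = ace_params(0.9, 0),
                               seed = 92)
  res <- nbs_h2_test(fc, co, tau = 0.3, n_perm = 49, seed = 93)
  expect_equal(nrow(tidy(res)), res$size_edges)
  expect_equal(glance(res)$p_perm, res$p_perm)

  ep <- withr::local_tempfile(fileext = ".tsv")
  jp <- withr::local_tempfile(fileext = ".json")
  write_component(res, ep, jp)
  back <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(back$size_edges, res$size_edges)

  dir <- withr::local_tempdir()
  write_fc_stack(fc, dir)
  fc2 <- read_fc_stack(dir)
  expect_equal(fc2$mats[[co$subject_id[1]]],
               fc$mats[[co$subject_id[1]]], ignore_attr = TRUE,
               tolerance = 1e-12)
})
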