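test_that("simulate_cohort builds valid pair structures at any size", {
  big <- simulate_cohort(56, 67, seed = 3)
  expect_equal(nrow(big), 246)
  expect_equal(dplyr::n_distinct(big$pair_id), 123)
  expect_equal(unname(zygosity_counts(big)), c(56L, 67L))
  expect_silent(validate_cohort(big))

  one <- simulate_cohort(1, 0, seed = 1)
  expect_equal(nrow(one), 2)
  expect_equal(unique(as.character(one$zygosity)), "MZ")
  expect_equal(one$pair_id[1], one$pair_id[2])

  dz <- simulate_cohort(0, 3, seed = 1)
  expect_equal(nrow(dz), 6)
  expect_equal(unname(zygosity_counts(dz)), c(0L, 3L))

  expect_error(simulate_cohort(-1, 5), "non-negative")
  expect_error(simulate_cohort(0, 0), "at least one")
  expect_identical(simulate_cohort(5, 5, seed = 42),
                   simulate_cohort(5, 5, seed = 42))
})

test_that("ACE phenotypes reproduce the closed-form twin correlations", {
  co <- simulate_cohort(2000, 2000, seed = 11)
  ph <- simulate_ace_phenotypes(co, ace_params(0.5, 0.2), seed = 12)
  r <- twin_correlations(ph, co)
  expect_equal(r$r_mz, 0.7, tolerance = 0.03 / 0.7)
  expect_equal(r$r_dz, 0.45, tolerance = 0.03 / 0.45)
  expect_equal(var(pheno_matrix(ph)[, 1]), 1, tolerance = 0.05)

  null <- simulate_ace_phenotypes(co, ace_params(0, 0), seed = 13)
  rn <- twin_correlations(null, co)
  expect_lt(abs(rn$r_mz), 0.05)
  expect_lt(abs(rn$r_dz), 0.05)
})

test_that("a pure-A model makes MZ co-twins near-identical", {
  co <- simulate_cohort(50, 50, seed = 5)
  ph <- simulate_ace_phenotypes(co, ace_params(1 - 1e-6, 0, 1e-6), seed = 6)
  pairs <- cohort_pairs(co)
  y <- pheno_matrix(ph)[, 1]
  mz <- pairs$zygosity == "MZ"
  expect_lt(max(abs(y[pairs$twin1[mz]] - y[pairs$twin2[mz]])), 1e-2)
})

test_that("phenotype generation is deterministic and validates parameters", {
  co <- toy_cohort()
  expect_identical(simulate_ace_phenotypes(co, ace_params(0.3, 0.1), seed = 9),
                   simulate_ace_phenotypes(co, ace_params(0.3, 0.1), seed = 9))
  expect_error(ace_params(1.2, 0), "\\[0, 1\\]")
  expect_error(ace_params(0.5, 0.5, 0.5), "A \\+ C \\+ E")
  expect_error(ace_params(0.6, 0.4, 0), "E must")
})

test_that("task event schedules match the conditioning paradigm", {
  ev <- simulate_task_events(seed = 21)
  counts <- table(ev$trial_type)
  expect_equal(unname(counts["CSplus_US"]), 8)
  expect_equal(unname(counts["CSplus_noUS"]), 8)
  expect_equal(unname(counts["US"]), 8)

  cues <- ev[ev$trial_type != "US", ]
  expect_true(all(cues$duration == 6))
  expect_true(all(ev$duration[ev$trial_type == "US"] == 3))

  # the US starts exactly at the offset of its reinforced cue
  us <- ev[ev$trial_type == "US", ]
  rein <- ev[ev$trial_type == "CSplus_US", ]
  expect_equal(us$onset, rein$onset + rein$duration)

  # inter-trial gaps (offset of the trial's last event to next cue onset)
  trial_end <- vapply(seq_len(nrow(cues)), function(i) {
    off <- cues$onset[i] + cues$duration[i]
    if (as.character(cues$trial_type[i]) == "CSplus_US") off + 3 else off
  }, numeric(1))
  gaps <- cues$onset[-1] - trial_end[-nrow(cues)]
  expect_true(all(gaps >= 8 & gaps <= 12))
  expect_lte(max(ev$onset + ev$duration), 587)
  expect_true(!is.unsorted(ev$onset, strictly = TRUE))

  expect_identical(simulate_task_events(seed = 1), simulate_task_events(seed = 1))
  expect_false(identical(simulate_task_events(seed = 1),
                         simulate_task_events(seed = 2)))
})

test_that("edge-level FC simulation plants heritability where asked", {
  co <- simulate_cohort(150, 150, seed = 31)
  planted <- cbind(1:20, 2:21)
  fc <- simulate_fc_phenotypes(co, n_nodes = 25, planted_edges = planted,
                               planted_params = ace_params(0.6, 0),
                               background_params = ace_params(0, 0),
                               seed = 32)
  expect_s3_class(fc, "fc_stack")
  expect_equal(fc$n_nodes, 25)
  expect_equal(length(fc), 600)

  h2 <- edgewise_h2(fc, co)
  pe <- upper_tri_edges(25)$edge %in% fc$planted_edges
  h2v <- h2[upper.tri(h2)]
  expect_gt(mean(h2v[pe]), mean(h2v[!pe]) + 0.2)

  none <- simulate_fc_phenotypes(co, n_nodes = 5, planted_edges = NULL,
                                 seed = 33)
  expect_equal(length(none$planted_edges), 0)
  expect_error(simulate_fc_phenotypes(co, 5, planted_edges = cbind(1, 9)),
               "out of range")
  expect_error(simulate_fc_phenotypes(co, 5, planted_edges = cbind(3, 2)),
               "upper-triangle")
})

test_that("FC matrices have the configured node dimension", {
  co <- toy_cohort(2, 2)
  fc <- simulate_fc_phenotypes(co, n_nodes = 400, seed = 1)
  expect_equal(dim(fc$mats[[1]]), c(400, 400))
  expect_true(isSymmetric(fc$mats[[1]]))
  expect_true(all(diag(fc$mats[[1]]) == 0))
})

test_that("ROI time series carry a condition-dependent connectivity boost", {
  co <- simulate_cohort(25, 25, seed = 41)
  ev <- simulate_task_events(seed = 42)
  boosted <- simulate_roi_timeseries(co, ev, n_nodes = 8, tr = 2.4,
                                     condition_edge_boost = 1.5,
                                     boost_edges = cbind(1L, 2L), seed = 43)
  flat <- simulate_roi_timeseries(co, ev, n_nodes = 8, tr = 2.4,
                                  condition_edge_boost = 0, seed = 43)
  contrast12 <- function(sim) {
    n_vols <- sim$n_vols
    w_a <- condition_weight_series(ev, c("CSplus_US", "US"), n_vols, sim$tr)
    w_b <- condition_weight_series(ev, "CSplus_noUS", n_vols, sim$tr)
    vapply(sim$ts, function(x) {
      condition_contrast(weighted_fc(x, w_a), weighted_fc(x, w_b))[1, 2]
    }, numeric(1))
  }
  z_boost <- contrast12(boosted)
  z_flat <- contrast12(flat)
  expect_gt(mean(z_boost), 0.05)
  expect_lt(abs(mean(z_flat)), 3 * sd(z_flat) / sqrt(length(z_flat)) + 0.02)

  expect_error(simulate_roi_timeseries(co, ev, 8, tr = 0), "positive")
})

test_that("injected motion spikes exceed the screening threshold", {
  co <- toy_cohort(2, 2)
  ev <- simulate_task_events(seed = 1)
  spiky <- simulate_roi_timeseries(co, ev, n_nodes = 3, tr = 2.4,
                                   spike_subjects = co$subject_id[1],
                                   spike_mm = 3, seed = 2)
  fd <- framewise_displacement(spiky$motion[[co$subject_id[1]]])
  expect_gt(max(fd), 0.5)
})
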