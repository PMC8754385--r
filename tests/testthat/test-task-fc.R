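test_that("canonical HRF has the standard double-gamma shape", {
  h <- canonical_hrf(0.1)
  t <- attr(h, "times")
  expect_equal(t[which.max(h)], 5, tolerance = 0.5 / 5)
  expect_equal(h[1], 0)                       # gamma density is 0 at t = 0
  expect_equal(sum(h[h > 0]), 1)
  expect_lt(min(h), 0)                        # undershoot present
  expect_equal(length(canonical_hrf(2.4)), floor(32 / 2.4) + 1)
  expect_error(canonical_hrf(0), "\\(0, 32\\]")
})

test_that("condition weights track their events and decay afterwards", {
  ev <- simulate_task_events(seed = 5)
  tr <- 2.4
  n_vols <- ceiling(events_duration(ev) / tr)
  w_us <- condition_weight_series(ev, c("CSplus_US", "US"), n_vols, tr)
  w_no <- condition_weight_series(ev, "CSplus_noUS", n_vols, tr)
  expect_equal(nrow(w_us), n_vols)
  expect_true(all(w_us$weight >= 0))
  expect_gt(max(w_us$weight), 0)

  # weights decay toward zero once the last event is 32 s past
  last_off <- max(ev$onset + ev$duration)
  tail_w <- w_us$weight[w_us$time > last_off + 32]
  if (length(tail_w)) expect_lt(max(tail_w), 1e-6 * max(w_us$weight))

  # disjoint conditions dominate disjoint volumes: the peak frame of each
  # reinforced trial belongs to the US series, not the unreinforced one
  rein_onsets <- ev$onset[ev$trial_type == "CSplus_US"]
  peak_vols <- round((rein_onsets + 6) / tr) + 1
  expect_true(all(w_us$weight[peak_vols] > w_no$weight[peak_vols]))

  expect_error(condition_weight_series(ev, "nope", n_vols, tr),
               "No events")
})

test_that("confound regression residualizes exactly", {
  set.seed(31)
  y <- matrix(rnorm(200 * 5), 200, 5)
  x <- cbind(rnorm(200), rnorm(200), rnorm(200))

  r <- regress_confounds(y, x)
  expect_lt(max(abs(crossprod(cbind(1, x), r))) / max(abs(y)), 1e-8)

  centered <- regress_confounds(y, NULL)
  expect_equal(centered, sweep(y, 2, colMeans(y)), tolerance = 1e-12)

  sc <- scrub_regressors(17, 200)
  r2 <- regress_confounds(y, cbind(x, sc))
  expect_equal(max(abs(r2[17, ])), 0, tolerance = 1e-10)

  expect_warning(regress_confounds(y, cbind(x, x[, 1])), "collinear")
  expect_error(regress_confounds(y, matrix(0, 100, 3)), "one row per volume")
})

test_that("ideal band-pass keeps the band and kills everything else", {
  n <- 250; tr <- 1
  t <- seq_len(n) - 1
  rms <- function(x) sqrt(mean(x^2))
  inband <- sin(2 * pi * 0.04 * t)
  slow <- sin(2 * pi * 0.004 * t)
  fast <- sin(2 * pi * 0.15 * t)
  y <- cbind(inband, slow, fast, dc = rep(2, n))

  f <- bandpass_filter(y, tr = tr, low = 0.008, high = 0.09)
  expect_gt(rms(f[, 1]) / rms(inband), 0.9)
  expect_lt(rms(f[, 2]) / rms(slow), 0.1)
  expect_lt(rms(f[, 3]) / rms(fast), 0.1)
  expect_lt(abs(mean(f[, 4])), 1e-10)

  expect_equal(bandpass_filter(f, tr, 0.008, 0.09), f, tolerance = 1e-10)
  expect_error(bandpass_filter(y, tr, 0.05, 0.6), "Nyquist")
  expect_error(bandpass_filter(y, tr, 0.09, 0.008), "low < high")
})

test_that("weighted correlation reduces, restricts and clips correctly", {
  set.seed(51)
  y <- matrix(rnorm(120 * 6), 120, 6)

  z_const <- weighted_fc(y, rep(2.5, 120))
  plain <- atanh(pmin(pmax(cor(y), -(1 - 1e-7)), 1 - 1e-7))
  diag(plain) <- 0
  expect_equal(z_const, plain, tolerance = 1e-10, ignore_attr = TRUE)

  w_block <- c(rep(0, 40), rep(1, 50), rep(0, 30))
  z_block <- weighted_fc(y, w_block)
  block_only <- atanh(cor(y[41:90, ])); diag(block_only) <- 0
  expect_equal(z_block, block_only, tolerance = 1e-8, ignore_attr = TRUE)

  y2 <- cbind(y[, 1], y[, 1], y[, 3])     # perfectly correlated pair
  z_dup <- weighted_fc(y2, rep(1, 120))
  expect_true(all(is.finite(z_dup)))
  expect_equal(z_dup[1, 2], atanh(1 - 1e-7))

  # affine invariance per node, positive rescaling invariance of weights
  y3 <- y; y3[, 2] <- 5 * y3[, 2] - 7
  w <- runif(120)
  expect_equal(weighted_fc(y3, w), weighted_fc(y, w), tolerance = 1e-9)
  expect_equal(weighted_fc(y, 3.7 * w), weighted_fc(y, w), tolerance = 1e-12)

  expect_warning(z0 <- weighted_fc(cbind(y[, 1:2], 0), rep(1, 120)),
                 "zero weighted variance")
  expect_true(all(z0[3, ] == 0) && all(z0[, 3] == 0))
  expect_error(weighted_fc(y, c(1, 1, rep(0, 118))), "at least 3")
})

test_that("condition contrasts are antisymmetric with zero diagonal", {
  set.seed(61)
  a <- matrix(rnorm(25), 5); a <- a + t(a); diag(a) <- 0
  b <- matrix(rnorm(25), 5); b <- b + t(b); diag(b) <- 0
  expect_equal(condition_contrast(a, a), matrix(0, 5, 5))
  expect_equal(condition_contrast(a, b), -condition_contrast(b, a))
  expect_error(condition_contrast(a, b[1:4, 1:4]), "shapes differ")
})

test_that("network summary matches hand-enumerated cases", {
  m <- matrix(0, 4, 4)
  m[1, 3] <- m[1, 4] <- m[2, 3] <- m[2, 4] <- 1
  m <- m + t(m)
  labels <- c("A", "A", "B", "B")
  s <- network_summary(m, labels)
  expect_equal(s["A", "B"], 1)              # 4 edges / (2 + 2)
  expect_equal(s["A", "A"], 0)

  m2 <- matrix(0, 4, 4); m2[1, 2] <- 0.8; m2 <- m2 + t(m2)
  s2 <- network_summary(m2, labels)
  expect_equal(s2["A", "A"], 0.4)           # single within edge / |A|
  expect_equal(s2["B", "B"], 0)
  expect_true(isSymmetric(s2))

  expect_equal(network_summary(matrix(0, 4, 4), labels),
               matrix(0, 2, 2, dimnames = list(c("A", "B"), c("A", "B"))))
  expect_error(network_summary(m, c("A", "A", NA, "B")), "labeled")
})

test_that("the first-level contrast pipeline is deterministic", {
  co <- toy_cohort(2, 2)
  ev <- simulate_task_events(seed = 71)
  sim <- simulate_roi_timeseries(co, ev, n_nodes = 6, tr = 2.4,
                                 condition_edge_boost = 1,
                                 boost_edges = cbind(1L, 2L), seed = 72)
  id <- co$subject_id[1]
  z1 <- fc_contrast_pipeline(sim$ts[[id]], ev, 2.4, motion = sim$motion[[id]])
  z2 <- fc_contrast_pipeline(sim$ts[[id]], ev, 2.4, motion = sim$motion[[id]])
  expect_identical(z1, z2)
  expect_true(isSymmetric(z1))
  expect_true(all(diag(z1) == 0))
})
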