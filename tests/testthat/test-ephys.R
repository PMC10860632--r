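# Evoked rates, thresholds, adaptation ratio, clustering, ratio test, RF area.

test_that("firing_rate counts in half-open windows", {
  rec <- make_recording(seq(0, 599.999, by = 1),
                        data.frame(kind = "spontaneous",
                                   filament_index = NA_integer_, onset = 0,
                                   duration = 600, trial = 1))
  expect_equal(firing_rate(rec, c(0, 600)), 1)
  expect_equal(firing_rate(rec, c(200, 200.5)), 2)   # spike at 200 included
  expect_equal(firing_rate(rec, c(599.5, 600)), 0)
  # duration-weighted mean of sub-rates equals the whole-window rate
  r1 <- firing_rate(rec, c(0, 100)); r2 <- firing_rate(rec, c(100, 600))
  expect_equal((100 * r1 + 500 * r2) / 600, firing_rate(rec, c(0, 600)))
  expect_error(firing_rate(rec, c(5, 5)), "empty window")
})

test_that("evoked_response averages first-second counts over trials", {
  ep <- vf_epochs(rep(4L, 3), c(10, 30, 50))
  spikes <- c(10 + seq(0, 0.99, length.out = 10),
              30 + seq(0, 0.99, length.out = 20),
              50 + seq(0, 0.99, length.out = 30))
  rec <- make_recording(spikes, ep)
  expect_equal(evoked_response(rec, "vf", 4), 20)
  silent <- make_recording(numeric(0), ep)
  expect_equal(evoked_response(silent, "vf", 4), 0)
  expect_error(evoked_response(silent, "vf", 9), "no epochs")
  expect_warning(
    evoked_response(make_recording(numeric(0), ep[1:2, ]), "vf", 4),
    "expected 3 trials")
})

test_that("vf_threshold applies the inclusive 10 Hz rule", {
  # three trials per filament; per-trial spike counts given explicitly
  build <- function(counts_per_filament) {
    onsets <- c(); fils <- c(); trials <- c(); spikes <- c()
    t0 <- 0
    for (f in seq_along(counts_per_filament)) {
      for (tr in 1:3) {
        n <- counts_per_filament[[f]][tr]
        if (n > 0) spikes <- c(spikes, t0 + seq(0, 0.99, length.out = n))
        onsets <- c(onsets, t0); fils <- c(fils, f); trials <- c(trials, tr)
        t0 <- t0 + 20
      }
    }
    make_recording(spikes, vf_epochs(fils, onsets, trials = trials))
  }
  rates <- function(...) lapply(list(...), function(r) rep(r, 3))
  expect_identical(vf_threshold(build(rates(2, 4, 6, 12, 20))), 4L)
  # mean 9.67 Hz just misses; exactly 10 Hz qualifies (inclusive rule)
  expect_identical(vf_threshold(build(list(c(10, 10, 9), c(10, 10, 10)))), 2L)
  expect_identical(vf_threshold(build(rates(2, 4, 6))), NA_integer_)
  expect_error(vf_threshold(make_recording(1, data.frame(
    kind = "spontaneous", filament_index = NA_integer_, onset = 0,
    duration = 10, trial = 1))), "no vf epochs")
})

test_that("adaptive_ratio pools counts across threshold trials", {
  ep <- vf_epochs(rep(4L, 3), c(0, 20, 40))
  # 8 spikes in first halves, none in second halves -> R = 0
  r0 <- make_recording(c(seq(0.0, 0.4, length.out = 4),
                         seq(20.0, 20.4, length.out = 4)), ep)
  expect_equal(adaptive_ratio(r0, 4), 0)
  # 5 and 5 -> R = 1
  r1 <- make_recording(c(seq(0.0, 0.45, length.out = 5),
                         seq(0.5, 0.95, length.out = 5)), ep)
  expect_equal(adaptive_ratio(r1, 4), 1)
  # a spike exactly at onset + 0.5 belongs to the second half-window
  rhalf <- make_recording(c(0.1, 0.5), ep)
  expect_equal(adaptive_ratio(rhalf, 4), 1)
  # zero denominator -> NA with warning
  rna <- make_recording(c(0.7, 20.8), ep)
  expect_warning(rr <- adaptive_ratio(rna, 4), "excluded")
  expect_true(is.na(rr))
  short <- make_recording(c(0.1), vf_epochs(4L, 0, duration = 0.8))
  expect_error(adaptive_ratio(short, 4), "shorter than 1 s")
})

test_that("kmeans_boundary is the exact 1-D 2-means optimum", {
  km <- kmeans_boundary(c(0, 0, 1, 1))
  expect_equal(km$boundary, 0.5)
  expect_identical(km$labels, c("adapting", "adapting", "nonadapting",
                                "nonadapting"))
  set.seed(7)
  x <- c(rnorm(50, 0.10, 0.05), rnorm(25, 0.80, 0.10))
  km2 <- kmeans_boundary(x)
  or <- oracle_best_split(x)
  expect_equal(km2$split_sse, or$sse)
  expect_equal(km2$boundary, or$boundary)
  # translation equivariance
  km3 <- kmeans_boundary(x + 2)
  expect_equal(km3$boundary, km2$boundary + 2)
  expect_error(kmeans_boundary(c(0.5, 0.5, 0.5)), "identical")
  expect_error(kmeans_boundary(0.2), "2 finite")
})

test_that("ratio_binomial_test reproduces the reported cohort p-values", {
  expect_equal(round(ratio_binomial_test(8, 30, 1 / 3), 2), 0.56)
  expect_equal(round(ratio_binomial_test(5, 28, 1 / 3), 2), 0.11)
  # modal outcome -> p = 1 (k = 10 is the mode of Binomial(30, 1/3))
  expect_equal(ratio_binomial_test(10, 30, 1 / 3), 1)
  expect_error(ratio_binomial_test(5, 4))
})

test_that("receptive_field_area is the absolute shoelace area", {
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(receptive_field_area(sq), 1)
  expect_equal(receptive_field_area(sq[4:1, ]), 1)   # orientation-free
  set.seed(11)
  ang <- sort(runif(7, 0, 2 * pi))
  poly <- cbind(cos(ang), sin(ang)) * runif(7, 0.8, 1.2)
  expect_lt(abs(receptive_field_area(poly) - oracle_polygon_area_mc(poly)) /
              receptive_field_area(poly), 0.01)
  bow <- cbind(c(0, 1, 1, 0), c(0, 1, 0, 1))
  expect_error(receptive_field_area(bow), "self-intersecting")
  expect_error(receptive_field_area(sq[1:2, ]), ">= 3 vertices")
})

test_that("classify_cohort labels with kmeans or a fixed boundary", {
  # spontaneous firing off: small-count noise is exercised in the
  # acceptance recovery test, this checks the labeling plumbing
  recs <- c(
    lapply(1:6, function(s) gen_spike_recording(
      spike_sim_spec("adapting", decay_tau = 0.1, spontaneous_rate = 0,
                     seed = s))),
    lapply(7:9, function(s) gen_spike_recording(
      spike_sim_spec("nonadapting", spontaneous_rate = 0, seed = s))))
  suppressWarnings(
    expect_warning(cl <- classify_cohort(recs), "strongest filament"))
  truth <- vapply(recs, attr, "", "true_class")
  expect_identical(unname(cl$cells$label), unname(truth))
  expect_identical(sum(cl$counts), 9L)
  # fixed boundary, inclusive on the upper side: R = 0.33 -> nonadapting
  ep <- vf_epochs(rep(1L, 3), c(0, 20, 40))
  # pooled counts 100 and 33 -> R = 0.33
  mk <- function(n1, n2) make_recording(
    c(seq(0, 0.49, length.out = n1), seq(0.5, 0.99, length.out = n2)), ep)
  cl2 <- classify_cohort(list(mk(100, 33), mk(100, 80)), boundary = 0.33)
  expect_identical(cl2$cells$label, c("nonadapting", "nonadapting"))
  cl3 <- classify_cohort(list(mk(100, 32), mk(100, 80)), boundary = 0.33)
  expect_identical(cl3$cells$label[1], "adapting")
  expect_error(classify_cohort(list()), "empty cohort")
})
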