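# Generators: determinism, ground-truth nesting, rate-function fidelity.

test_that("engulfment phantom ground truth is exact and nested", {
  spec0 <- engulfment_phantom_spec(engulfed_fraction = 0, blur_sigma = 0,
                                   noise_sd = 0, seed = 4)
  ph0 <- gen_engulfment_phantom(spec0)
  expect_identical(ph0$truth$true_engulfed_um3, 0)

  spec1 <- engulfment_phantom_spec(engulfed_fraction = 1, blur_sigma = 0,
                                   noise_sd = 0, seed = 4)
  ph1 <- gen_engulfment_phantom(spec1)
  meas <- quantify_engulfment(ph1$volume,
                              thresholds = c(microglia = 100, lysosome = 100,
                                             fiber = 100))
  expect_identical(meas$engulfed_um3, ph1$truth$true_engulfed_um3)
  expect_identical(meas$lysosome_um3, ph1$truth$true_lysosome_um3)
  expect_identical(meas$microglia_um3, ph1$truth$true_microglia_um3)

  for (s in c(2, 5, 9)) {
    tr <- gen_engulfment_phantom(engulfment_phantom_spec(seed = s))$truth
    expect_lte(tr$true_engulfed_um3, tr$true_lysosome_um3)
    expect_lte(tr$true_lysosome_um3, tr$true_microglia_um3)
    expect_gte(tr$true_engulfed_um3, 0)
  }
})

test_that("phantom generation is deterministic in spec + seed", {
  a <- gen_engulfment_phantom(engulfment_phantom_spec(seed = 7))
  b <- gen_engulfment_phantom(engulfment_phantom_spec(seed = 7))
  c <- gen_engulfment_phantom(engulfment_phantom_spec(seed = 8))
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$volume$data, c$volume$data))
})

test_that("phantom spec validation rejects bad values", {
  expect_error(engulfment_phantom_spec(engulfed_fraction = 1.2))
  expect_error(engulfment_phantom_spec(voxel_size = c(0, 0.2, 0.2)))
  expect_error(engulfment_phantom_spec(n_microglia = -1))
  # grid physically too small for a cell
  expect_error(
    gen_engulfment_phantom(engulfment_phantom_spec(
      grid_shape = c(4, 8, 8), voxel_size = c(0.5, 0.2, 0.2))),
    "placement error")
})

test_that("puncta phantom: exact count and additive volume", {
  expect_identical(gen_puncta_phantom(n_puncta = 0, seed = 1)$truth$true_count,
                   0L)
  pp <- gen_puncta_phantom(n_puncta = 25, seed = 2)
  expect_identical(pp$truth$true_count, 25L)
  expect_equal(pp$truth$true_total_um3,
               sum(pp$truth$per_object_voxels) * prod(pp$volume$voxel_size))
  meas <- quantify_puncta(pp$volume, threshold = 100)
  expect_identical(meas$count, 25L)
  expect_equal(meas$total_um3, pp$truth$true_total_um3)
})

test_that("spike simulator matches its rate function", {
  # no drive at all -> silence
  quiet <- gen_spike_recording(spike_sim_spec("nonadapting", peak_rate = 0,
                                              spontaneous_rate = 0, seed = 3),
                               subthreshold_rate = 0)
  expect_length(quiet$spike_times, 0)

  # trial-averaged counts in each half-window vs analytic integrals, 3 SE
  tau <- 0.15; n_tr <- 200
  rec <- gen_spike_recording(spike_sim_spec("adapting", peak_rate = 40,
                                            decay_tau = tau,
                                            spontaneous_rate = 0,
                                            n_trials = n_tr, seed = 12))
  ep <- rec$epochs[rec$epochs$kind == "vf" & rec$epochs$filament_index == 4, ]
  n1 <- sum(sapply(ep$onset, function(t0)
    sum(rec$spike_times >= t0 & rec$spike_times < t0 + 0.5)))
  n2 <- sum(sapply(ep$onset, function(t0)
    sum(rec$spike_times >= t0 + 0.5 & rec$spike_times < t0 + 1)))
  mu1 <- 40 * tau * (1 - exp(-0.5 / tau)) * n_tr
  mu2 <- 40 * tau * (exp(-0.5 / tau) - exp(-1 / tau)) * n_tr
  expect_lt(abs(n1 - mu1), 3 * sqrt(mu1))
  expect_lt(abs(n2 - mu2), 3 * sqrt(mu2))
  # closed-form expected R
  expect_lt(abs(adaptive_ratio(rec, 4) - oracle_expected_R(tau)),
            3 * sqrt(mu2) / mu1)
})

test_that("cohort generator is seeded and centred", {
  co <- gen_cohort(cohort_spec(n_per_group = 200, group_means = c(0, 0),
                               seed = 6))
  se <- sqrt(2 / 200)
  expect_lt(abs(mean_difference(co$a, co$b)), 3 * se)
  expect_identical(gen_cohort(cohort_spec(seed = 5)),
                   gen_cohort(cohort_spec(seed = 5)))
  expect_error(cohort_spec(n_per_group = 1))
  expect_error(cohort_spec(group_sds = c(1, 0)))
})
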