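test_that("identical config and seed give bit-identical movies", {
  s1 <- small_sim(seed = 9)
  s2 <- small_sim(seed = 9)
  expect_identical(s1$movie$frames, s2$movie$frames)
  expect_identical(s1$truth, s2$truth)
  s3 <- small_sim(seed = 10)
  expect_false(identical(s1$movie$frames, s3$movie$frames))
})

test_that("a silent zero-noise plate is the static zone baseline", {
  quiet <- well_spec(network_rate = 0, out_rate_per_pixel = 0)
  sim <- small_sim(wells = list(B02 = quiet), noise_sd = 0)
  fr <- sim$movie$frames
  # every frame identical, and values are exactly the three zone levels
  expect_true(all(apply(fr, c(2, 3), function(v) length(unique(v))) == 1))
  expect_setequal(unique(as.vector(fr)), c(200, 900, 3000))
})

test_that("network event counts follow the configured Poisson rate", {
  sim <- small_sim(wells = list(B02 = well_spec(network_rate = 6)),
                   duration = 600, seed = 5)
  n <- length(sim$truth$B02$network_times)
  expect_gte(n, qpois(0.005, 60))
  expect_lte(n, qpois(0.995, 60))
})

test_that("full participation without jitter or noise makes growth pixels identical", {
  spec <- well_spec(participation_prob = 1, jitter_sd = 0,
                    in_amplitude_cv = 0, out_rate_per_pixel = 0)
  sim <- small_sim(wells = list(B02 = spec), noise_sd = 0, seed = 3)
  mask <- build_zone_mask(sim$movie)
  pt <- extract_pixel_traces(sim$movie, mask, "B02")
  expect_true(all(apply(pt$traces, 1, function(v) length(unique(v)) == 1)))
  r <- pairwise_correlation(pt)
  expect_equal(unname(r$r[upper.tri(r$r)]), rep(1, sum(upper.tri(r$r))),
               tolerance = 1e-12)
})

test_that("injected transients peak at the drawn amplitude up to discretization", {
  spec <- well_spec(network_rate = 1, participation_prob = 1, jitter_sd = 0,
                    in_amplitude_cv = 0, out_rate_per_pixel = 0)
  sim <- small_sim(wells = list(B02 = spec), duration = 300, noise_sd = 0,
                   seed = 8)
  mask <- build_zone_mask(sim$movie)
  pt <- extract_pixel_traces(sim$movie, mask, "B02")
  ss <- detect_spikes(pt$traces[, 1], 100, frame_rate = 8)
  truth <- sim$truth$B02
  expect_equal(nrow(ss), length(truth$network_times))
  # peak of the discretized kernel is within one frame of the maximum, where
  # the kernel can lose a few percent of its unit height
  expect_true(all(abs(ss$prominence - 300) / 300 < 0.12))
  expect_true(all(abs(ss$peak_time - truth$network_times) < 0.5))
})

test_that("ground truth conserves every injected event", {
  sim <- small_sim(seed = 12, duration = 120)
  tr <- sim$truth$B02
  expect_equal(tr$n_events_injected,
               sum(tr$participation) + sum(lengths(tr$out_times)))
  expect_true(all(unlist(tr$out_times) >= 0 &
                    unlist(tr$out_times) <= 120))
  expect_true(all(tr$network_times >= 0 & tr$network_times <= 120))
})

test_that("per-pixel participation matches participation_prob in expectation", {
  spec <- well_spec(network_rate = 12, participation_prob = 0.7,
                    out_rate_per_pixel = 0)
  sim <- small_sim(wells = list(B02 = spec), duration = 600, seed = 4)
  part <- sim$truth$B02$participation
  n <- length(part)
  phat <- mean(part)
  se <- sqrt(0.7 * 0.3 / n)
  expect_lt(abs(phat - 0.7), 4 * se)
})

test_that("drug addition scales rate and amplitude after the addition time", {
  spec <- well_spec(network_rate = 12, drug_time = 300,
                    drug_frequency_scale = 0.25, drug_amplitude_scale = 0.5,
                    jitter_sd = 0, out_rate_per_pixel = 0)
  sim <- small_sim(wells = list(B02 = spec), duration = 600, seed = 6)
  tt <- sim$truth$B02$network_times
  n_pre <- sum(tt < 300); n_post <- sum(tt >= 300)
  # 60 expected before, 15 after
  expect_gt(n_pre, qpois(0.005, 60) - 1)
  expect_lt(n_post, qpois(0.995, 15) + 1)
  amps <- sim$truth$B02$in_amplitudes
  pre_mean <- mean(amps[tt < 300, ][amps[tt < 300, ] > 0])
  post_mean <- mean(amps[tt >= 300, ][amps[tt >= 300, ] > 0])
  expect_equal(post_mean / pre_mean, 0.5, tolerance = 0.15)
})

test_that("Hill scaling follows its closed form", {
  expect_equal(hill_scale(0.31, top = 1, bottom = 0, ic50 = 0.31, slope = 1),
               0.5)
  expect_equal(hill_scale(0, top = 1, bottom = 0, ic50 = 0.31, slope = 1), 1)
  doses <- 10^seq(log10(0.31) - 2, log10(0.31) + 2, length.out = 9)
  base <- well_spec(network_rate = 6,
                    hill_params = list(top = 1, bottom = 0, ic50 = 0.31,
                                       slope = 1))
  specs <- simulate_dose_series(base, doses)
  got <- vapply(specs, function(s) s$network_rate, numeric(1))
  want <- 6 * (0 + (1 - 0) / (1 + (doses / 0.31)^1))
  expect_equal(got, want, tolerance = 1e-12)
  expect_equal(vapply(specs, function(s) s$dose, numeric(1)), doses)
})

test_that("invalid simulation parameters name the offending field", {
  expect_error(well_spec(participation_prob = 1.2), "participation_prob")
  expect_error(well_spec(network_rate = -1), "network_rate")
  expect_error(well_spec(kernel_rise_tau = 0), "kernel")
  expect_error(sim_config(wells = list(B02 = well_spec()), duration = 0.1,
                          frame_rate = 8), "duration")
  expect_error(sim_config(wells = list(B02 = well_spec()),
                          zone_brightness = c(5, 2, 9)), "zone_brightness")
  expect_error(sim_config(wells = list(ZZ9 = well_spec())), "well ids")
  expect_error(well_spec(hill_params = list(top = 1, bottom = 0, ic50 = -1,
                                            slope = 1)), "ic50")
  ok <- well_spec(hill_params = list(top = 1, bottom = 0, ic50 = 1, slope = 1))
  expect_error(simulate_dose_series(ok, c(-1, 1)), "doses")
})

test_that("the transient kernel has unit peak and the configured support", {
  t <- seq(0, 10, by = 0.001)
  k <- transient_kernel(t)
  expect_equal(max(k), 1, tolerance = 1e-6)
  expect_equal(k[1], 0)
  expect_true(all(transient_kernel(c(-1, -0.01)) == 0))
  # analytic peak time
  tpk <- 0.1 * 0.6 / 0.5 * log(6)
  expect_equal(t[which.max(k)], tpk, tolerance = 0.002)
})
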