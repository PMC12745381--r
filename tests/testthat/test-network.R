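test_that("empty-well thresholds separate background from real spikes", {
  wells <- list(C03 = well_spec(out_rate_per_pixel = 0, jitter_sd = 0))
  sim <- small_sim(wells = wells, duration = 120, seed = 31)
  mask <- build_zone_mask(sim$movie)
  thr <- global_threshold(sim$movie, mask)
  expect_true(thr$threshold > 0)
  # no empty well produces a detection at the derived threshold
  for (w in sim$movie$layout$empty_wells[1:10]) {
    tr <- extract_well_trace(sim$movie, mask, w)
    expect_equal(nrow(detect_spikes(tr, thr$threshold)), 0)
  }
  # all true network spikes (prominence ~300 >> threshold) retained
  tr <- extract_well_trace(sim$movie, mask, "C03")
  ss <- detect_spikes(tr, thr$threshold)
  expect_equal(nrow(ss), length(sim$truth$C03$network_times))
})

test_that("zero-noise empty wells give a positive floor threshold", {
  quiet <- well_spec(network_rate = 0, out_rate_per_pixel = 0)
  sim <- small_sim(wells = list(B02 = quiet), noise_sd = 0, duration = 10)
  mask <- build_zone_mask(sim$movie)
  thr <- global_threshold(sim$movie, mask)
  expect_true(thr$threshold > 0)
  expect_true(all(thr$empty_max_prominences == 0))
})

test_that("a layout without empty wells demands an explicit threshold", {
  sim <- small_sim(duration = 10, seed = 3)
  sim$movie$layout$empty_wells <- character(0)
  mask <- build_zone_mask(sim$movie)
  expect_error(global_threshold(sim$movie, mask), "empty wells")
})

test_that("frequency and amplitude arithmetic", {
  mk <- function(n, dur, proms = rep(1, n)) {
    spike_set(data.frame(peak_index = seq_len(n), peak_time = seq_len(n),
                         peak_value = proms, prominence = proms,
                         amplitude = proms, fwhm = rep(1, n),
                         left_half_time = seq_len(n) - 0.5,
                         right_half_time = seq_len(n) + 0.5,
                         label = rep("unlabeled", n)),
              threshold = 0.5, frame_rate = 1, duration = dur)
  }
  expect_equal(spike_frequency(mk(0, 300)), 0)
  expect_equal(spike_frequency(mk(26, 300)), 5.2)
  # 16 and 17 events in 5 min bracket a control-like 3.3/min
  expect_equal(spike_frequency(mk(16, 300)), 3.2)
  expect_equal(spike_frequency(mk(17, 300)), 3.4)
  expect_equal(mean_spike_amplitude(mk(1, 300, 322)), 322)
  expect_equal(mean_spike_amplitude(mk(2, 300, c(1, 3))), 2)
  na <- mean_spike_amplitude(mk(0, 300))
  expect_true(is.na(na))
  expect_equal(attr(na, "flag"), "no_events")
  # frequency is additive over disjoint windows
  expect_equal(spike_frequency(mk(10, 300)) + spike_frequency(mk(16, 300)),
               26 / 600 * 60 * 2)
})

test_that("acute drug response recovers the simulated frequency scaling", {
  spec <- well_spec(network_rate = 8, drug_time = 300,
                    drug_frequency_scale = 0.5, out_rate_per_pixel = 0)
  sim <- small_sim(wells = list(B02 = spec), duration = 600, seed = 17)
  mask <- build_zone_mask(sim$movie)
  wt <- extract_well_trace(sim$movie, mask, "B02")
  thr <- global_threshold(sim$movie, mask)$threshold
  dr <- drug_response(wt, 300, thr)
  # post/pre ratio 0.5 within Poisson error of ~40 and ~20 events
  expect_lt(abs(dr$frequency_ratio - 0.5), 0.25)
  expect_error(drug_response(wt, 600, thr), "addition_time")
  expect_error(drug_response(wt, 0, thr), "addition_time")
  short <- drug_response(wt, 550, thr)
  expect_true("short_post_window" %in% short$flags)
})

test_that("no-effect traces yield mostly non-significant paired tests", {
  # synthetic well traces with identical statistics before and after a mock
  # addition time; 20 replicate plates of 6 wells
  set.seed(99)
  n_sig <- 0
  reps <- 20
  for (r in seq_len(reps)) {
    traces <- lapply(1:6, function(i) {
      x <- rnorm(2400, 0, 1)
      ev <- runif(rpois(1, 20), 0, 600)
      for (t0 in ev) {
        idx <- floor(t0 * 4):min(2400, floor(t0 * 4) + 8)
        idx <- idx[idx >= 1]
        x[idx] <- x[idx] + 30 * exp(-(idx - t0 * 4) / 3)
      }
      lfca_trace(x, frame_rate = 4, source = paste0("W", i))
    })
    names(traces) <- paste0("W", 1:6)
    res <- drug_response_tests(traces, 300, threshold = 10)
    if (isTRUE(res$tests$frequency$p < 0.05)) n_sig <- n_sig + 1
  }
  expect_gte((reps - n_sig) / reps, 0.9)
})

test_that("noiseless Hill data recover the IC50 almost exactly", {
  doses <- 10^seq(log10(0.31) - 2, log10(0.31) + 2, length.out = 8)
  resp <- 0 + (6 - 0) / (1 + (doses / 0.31)^1)
  fit <- fit_dose_response(doses, resp)
  expect_lt(abs(fit$ic50 - 0.31) / 0.31, 1e-6)
  expect_equal(fit$top, 6, tolerance = 1e-5)
  expect_equal(fit$bottom, 0, tolerance = 1e-4)
  expect_equal(fit$hill_slope, 1, tolerance = 1e-5)
  expect_false(fit$poor_fit)
})

test_that("flat or inadequate dose-response data are flagged, not accepted", {
  doses <- c(0.01, 0.1, 1, 10)
  fit <- fit_dose_response(doses, rep(5, 4) + c(1e-9, -1e-9, 1e-9, -1e-9))
  expect_true(fit$poor_fit)
  expect_error(fit_dose_response(c(1, 2, 3), c(5, 4, 3)), "4 distinct")
  expect_error(fit_dose_response(c(-1, 1, 2, 3), c(5, 4, 3, 2)), ">= 0")
})

test_that("network windows pad, merge, and cover participating events", {
  ss <- spike_set(data.frame(peak_index = c(85, 100), peak_time = c(10.5, 12.4),
                             peak_value = 1, prominence = 1, amplitude = 1,
                             fwhm = c(1.2, 0.8),
                             left_half_time = c(10.0, 12.0),
                             right_half_time = c(11.2, 12.8),
                             label = "unlabeled"),
                  threshold = 0.4, frame_rate = 8, duration = 60)
  w <- network_windows(ss, pad = 0.125)
  expect_equal(unname(w[1, ]), c(9.875, 11.325))
  expect_equal(unname(w[2, ]), c(11.875, 12.925))
  # abutting/overlapping windows merge
  w2 <- network_windows(ss, pad = 0.4)
  expect_equal(nrow(w2), 1)
  expect_equal(unname(w2[1, ]), c(9.6, 13.2))

  # simulated well: nearly all ground-truth participating events fall inside
  sim <- small_sim(wells = list(B02 = well_spec(out_rate_per_pixel = 0)),
                   duration = 300, seed = 23)
  mask <- build_zone_mask(sim$movie)
  wt <- extract_well_trace(sim$movie, mask, "B02")
  thr <- global_threshold(sim$movie, mask)$threshold
  win <- network_windows(detect_spikes(wt, thr))
  # each injected event peaks tpk after its onset (difference-of-exponentials)
  tpk <- 0.1 * 0.6 / 0.5 * log(6)
  apex <- unlist(sim$truth$B02$in_times) + tpk
  frac <- mean(vapply(apex, function(t)
    any(t >= win[, "start"] & t <= win[, "end"]), logical(1)))
  expect_gte(frac, 0.95)
})
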