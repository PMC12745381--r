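# Hand-built pixel_traces object: traces is frames x pixels.
mk_pt <- function(traces, frame_rate = 8, normalization = "minmax") {
  structure(list(traces = traces,
                 coords = cbind(row = seq_len(ncol(traces)),
                                col = rep(1L, ncol(traces))),
                 frame_rate = frame_rate, normalization = normalization,
                 flags = rep(NA_character_, ncol(traces)), well = "T01"),
            class = "pixel_traces")
}

# one normalized transient of given prominence at a given frame
pulse_trace <- function(n, at, height) {
  x <- numeric(n)
  x[(at - 2):(at + 4)] <- height * c(0.2, 0.6, 1, 0.7, 0.45, 0.25, 0.1)
  x
}

test_that("active pixels rank above silent ones and the shoulder finds them", {
  set.seed(41)
  n <- 240; n_active <- 180
  traces <- matrix(pmin(pmax(stats::rnorm(500 * n, 0.03, 0.02), 0), 1), 500, n)
  for (j in seq_len(n_active)) {
    for (at in sample(10:490, 5))
      traces[(at - 2):(at + 2), j] <-
        pmin(1, traces[(at - 2):(at + 2), j] + runif(1, 0.5, 0.9) *
               c(0.3, 0.7, 1, 0.6, 0.3))
  }
  rk <- rank_active_pixels(mk_pt(traces), 0.4, N = n_active)
  expect_setequal(rk$pixel[rk$selected], seq_len(n_active))
  expect_true(all(rk$rank[seq_len(n_active)] <= n_active))
  expect_lt(abs(attr(rk, "shoulder") - n_active), 25)
  expect_false(attr(rk, "degenerate"))
})

test_that("silent wells give a degenerate ranking", {
  traces <- matrix(0, 100, 20)
  traces[5, ] <- 0.05  # tiny common blip below threshold
  rk <- rank_active_pixels(mk_pt(traces), 0.4, N = 10)
  expect_true(attr(rk, "degenerate"))
  expect_true(all(rk$score == 0))
  expect_equal(sum(rk$selected), 10)
})

test_that("per-pixel detection needs normalized traces and converts FWHM to seconds", {
  raw <- mk_pt(matrix(stats::runif(200, 0, 5), 100, 2),
               normalization = "none")
  expect_error(detect_pixel_spikes(raw), "normalized")

  # Gaussian pulse, sigma = 0.5 s at 8 fps: FWHM = 2 sqrt(2 ln 2) sigma
  fr <- 8
  t <- seq(0, 30, by = 1 / fr)
  g <- exp(-(t - 15)^2 / (2 * 0.5^2))
  tab <- detect_pixel_spikes(mk_pt(matrix(g, ncol = 1)), 0.4)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$prominence, 1, tolerance = 1e-6)
  expect_lt(abs(tab$fwhm - 2 * sqrt(2 * log(2)) * 0.5), 1 / fr)

  # noise below 0.1 produces nothing at the 0.4 threshold
  set.seed(5)
  noise <- matrix(pmin(pmax(stats::rnorm(2000, 0.2, 0.02), 0), 1), 500, 4)
  expect_equal(nrow(detect_pixel_spikes(mk_pt(noise), 0.4)), 0)
})

test_that("IN/OUT classification follows the window rule", {
  x1 <- pulse_trace(400, 84, 0.9)    # peak at frame 84 -> 10.375 s
  x2 <- pulse_trace(400, 161, 0.8)   # peak at frame 161 -> 20 s
  tab <- detect_pixel_spikes(mk_pt(cbind(x1, x2)), 0.4)
  win <- structure(cbind(start = 10.0, end = 11.2),
                   frame_rate = 8, duration = 50,
                   class = c("network_windows", "matrix", "array"))
  lab <- classify_in_out(tab, win)
  expect_equal(lab$label[lab$peak_time < 15], "IN")
  expect_equal(lab$label[lab$peak_time > 15], "OUT")
  # partition: every spike is labeled exactly once
  expect_equal(sum(lab$label == "IN") + sum(lab$label == "OUT"), nrow(lab))
})

test_that("threshold sweep fractions start at 1 and fall monotonically", {
  set.seed(55)
  traces <- sapply(1:12, function(j) {
    x <- pmin(pmax(stats::rnorm(800, 0.05, 0.015), 0), 1)
    for (at in sample(20:780, 6))
      x[(at - 2):(at + 4)] <- pmin(1, x[(at - 2):(at + 4)] +
                                     runif(1, 0.3, 0.95) *
                                     c(0.2, 0.6, 1, 0.7, 0.45, 0.25, 0.1))
    x
  })
  win <- structure(cbind(start = c(10, 50), end = c(15, 55)),
                   frame_rate = 8, duration = 100,
                   class = c("network_windows", "matrix", "array"))
  sw <- threshold_sweep(mk_pt(traces), win)
  for (cl in c("IN", "OUT", "all")) {
    f <- sw$fraction[sw$class == cl]
    expect_equal(f[1], 1)
    expect_true(all(diff(f) <= 0))
    expect_true(all(f >= 0 & f <= 1))
  }
  # single pulse of prominence 0.5: retained up to 0.5, gone above
  one <- mk_pt(matrix(pulse_trace(200, 100, 0.5), ncol = 1))
  sw1 <- threshold_sweep(one, win)
  a <- sw1[sw1$class == "all", ]
  expect_true(all(a$fraction[a$threshold <= 0.5] == 1))
  expect_true(all(a$fraction[a$threshold > 0.5] == 0))

  # silent input is flagged
  sw0 <- threshold_sweep(mk_pt(matrix(0, 100, 2)), win)
  expect_equal(attr(sw0, "flag"), "no_spikes_at_floor")
  expect_true(all(is.na(sw0$fraction)))
})

test_that("local-field summaries do the documented arithmetic", {
  # 4 pixels, each exactly 3 spikes in 300 s -> 0.6 spikes/min
  traces <- sapply(1:4, function(j) {
    x <- numeric(2400)
    for (at in c(300, 1100, 1900) + 10 * j)
      x[(at - 2):(at + 4)] <- c(0.2, 0.6, 1, 0.7, 0.45, 0.25, 0.1)
    x
  })
  tab <- detect_pixel_spikes(mk_pt(traces), 0.4)
  win <- structure(cbind(start = 36, end = 42), frame_rate = 8,
                   duration = 300,
                   class = c("network_windows", "matrix", "array"))
  tab <- classify_in_out(tab, win)
  s <- summarize_local_fields(tab)
  expect_equal(s$mean_pixel_frequency, 0.6)
  expect_equal(s$n_spikes, 12)

  # class means: IN {0.8}, OUT {0.4}
  x <- pulse_trace(400, 84, 0.8) + pulse_trace(400, 240, 0.4)
  tab2 <- detect_pixel_spikes(mk_pt(matrix(x, ncol = 1)), 0.2)
  win2 <- structure(cbind(start = 10, end = 11.2), frame_rate = 8,
                    duration = 50,
                    class = c("network_windows", "matrix", "array"))
  tab2 <- classify_in_out(tab2, win2)
  s2 <- summarize_local_fields(tab2)
  expect_equal(s2$in_amplitude, 0.8, tolerance = 1e-12)
  expect_equal(s2$out_amplitude, 0.4, tolerance = 1e-12)
  # overall mean equals the count-weighted mean of the class means (exact)
  expect_equal(s2$mean_amplitude,
               (s2$n_in * s2$in_amplitude + s2$n_out * s2$out_amplitude) /
                 (s2$n_in + s2$n_out))
})

test_that("simulated wells partition spikes and favor IN amplitudes", {
  sim <- small_sim(seed = 61, duration = 120)
  mask <- build_zone_mask(sim$movie)
  wt <- extract_well_trace(sim$movie, mask, "B02")
  thr <- global_threshold(sim$movie, mask)$threshold
  win <- network_windows(detect_spikes(wt, thr))
  pt <- extract_pixel_traces(sim$movie, mask, "B02", "minmax")
  tab <- classify_in_out(detect_pixel_spikes(pt, 0.4), win)
  s <- summarize_local_fields(tab)
  expect_equal(s$n_in + s$n_out, s$n_spikes)
  # network transients are configured larger than local ones
  expect_gt(s$in_amplitude, s$out_amplitude)
})
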