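# Independent brute-force oracles, kept deliberately naive (plain scans and
# direct summation) so they share no code with the package implementation.

# Enumerate local maxima (leftmost plateau sample) and compute prominence,
# bases and half-prominence crossings by scanning outwards sample by sample.
oracle_spikes <- function(x, threshold, frame_rate) {
  n <- length(x)
  peaks <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[i]) j <- j + 1L
      if (j < n && x[j + 1L] < x[i]) peaks <- c(peaks, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  rows <- lapply(peaks, function(p) {
    v <- x[p]
    lmin <- v; lpos <- p
    k <- p - 1L
    while (k >= 1L && x[k] <= v) {
      if (x[k] < lmin) { lmin <- x[k]; lpos <- k }
      k <- k - 1L
    }
    rmin <- v; rpos <- p
    k <- p + 1L
    while (k <= n && x[k] <= v) {
      if (x[k] < rmin) { rmin <- x[k]; rpos <- k }
      k <- k + 1L
    }
    prom <- v - max(lmin, rmin)
    if (prom < threshold || prom <= 0) return(NULL)
    h <- v - prom / 2
    li <- lpos
    k <- p
    while (k > lpos && x[k - 1L] >= h) k <- k - 1L
    if (k > lpos) {
      li <- (k - 1L) + (h - x[k - 1L]) / (x[k] - x[k - 1L])
    }
    ri <- rpos
    k <- p
    while (k < rpos && x[k + 1L] >= h) k <- k + 1L
    if (k < rpos) {
      ri <- (k + 1L) - (h - x[k + 1L]) / (x[k] - x[k + 1L])
    }
    data.frame(peak_index = p, peak_value = v, prominence = prom,
               fwhm = (ri - li) / frame_rate)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(peak_index = integer(0), peak_value = numeric(0),
                      prominence = numeric(0), fwhm = numeric(0))
  out
}

# Random test traces: smooth oscillation + transients + noise, assorted
# lengths; occasionally includes exact plateaus and flat stretches.
random_trace <- function(len, plateaus = FALSE) {
  t <- seq_len(len)
  x <- 2 * sin(t / stats::runif(1, 3, 20)) + stats::rnorm(len, sd = 0.5)
  k <- sample(0:3, 1)
  for (i in seq_len(k)) {
    p <- sample(len, 1)
    w <- sample(2:6, 1)
    idx <- pmax(1, pmin(len, (p - w):(p + w)))
    x[idx] <- x[idx] + stats::runif(1, 1, 6) * exp(-abs(idx - p) / w)
  }
  if (plateaus) {
    x <- round(x, 1)  # quantization creates exact ties and plateaus
  }
  x
}

# Direct-summation Jensen-Shannon divergence (base 2).
oracle_jsd <- function(p, q) {
  m <- (p + q) / 2
  s <- 0
  for (i in seq_along(p)) {
    if (p[i] > 0) s <- s + 0.5 * p[i] * log2(p[i] / m[i])
    if (q[i] > 0) s <- s + 0.5 * q[i] * log2(q[i] / m[i])
  }
  s
}

# Small simulated plate shared by several tests: one active well on a 96-well
# grid with small tiles so unit tests stay fast.
small_sim <- function(wells = list(B02 = well_spec()), duration = 60,
                      tile = c(8, 8), seed = 42, frame_rate = 8,
                      noise_sd = 20, ...) {
  cfg <- sim_config(wells = wells, plate_format = 96, tile_shape = tile,
                    frame_rate = frame_rate, duration = duration,
                    noise_sd = noise_sd, rng_seed = seed, ...)
  simulate_plate(cfg)
}
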