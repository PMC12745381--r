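#' Well simulation parameters
#'
#' Phenomenological model of one cocultured well: synchronized network calcium
#' spikes in which each growth pixel participates with some probability, plus
#' independent local ("OUT") spikes per pixel, both rendered with a
#' GCaMP6f-like difference-of-exponentials transient and lognormal amplitudes.
#'
#' Defaults describe a control coculture of induced glutamatergic neurons on
#' primary astrocytes in 96-well format: network spikes at 3.3/min with 90%
#' pixel participation and independent local spikes at 2.6/min per pixel, so
#' the expected per-pixel spike rate is about 5.6/min.
#'
#' @param network_rate network spikes per minute.
#' @param participation_prob probability that a growth pixel participates in a
#'   given network spike.
#' @param in_amplitude_mean,in_amplitude_cv lognormal amplitude (a.u. counts)
#'   of network-spike transients per participating pixel.
#' @param out_rate_per_pixel local (OUT) spikes per minute per pixel,
#'   homogeneous Poisson, independent across pixels.
#' @param out_amplitude_mean,out_amplitude_cv lognormal amplitude of OUT
#'   transients.
#' @param kernel_rise_tau,kernel_decay_tau transient kernel time constants, s.
#' @param jitter_sd Gaussian jitter (s) of each pixel's participation relative
#'   to the network event time.
#' @param drug_time time (s) of acute compound addition, or `NA` for none.
#' @param drug_frequency_scale,drug_amplitude_scale multiplicative scales
#'   applied to `network_rate` and `in_amplitude_mean` from `drug_time` on.
#' @param dose compound concentration for dose-response wells, or `NA`.
#' @param hill_params list `(top, bottom, ic50, slope)`; when set together
#'   with `dose`, the network rate is scaled by
#'   `bottom + (top - bottom) / (1 + (dose / ic50)^slope)`.
#' @return object of class `well_spec` (a validated list).
#' @export
well_spec <- function(network_rate = 3.3,
                      participation_prob = 0.9,
                      in_amplitude_mean = 300, in_amplitude_cv = 0.2,
                      out_rate_per_pixel = 2.6,
                      out_amplitude_mean = 250, out_amplitude_cv = 0.25,
                      kernel_rise_tau = 0.1, kernel_decay_tau = 0.6,
                      jitter_sd = 0.05,
                      drug_time = NA_real_,
                      drug_frequency_scale = 1, drug_amplitude_scale = 1,
                      dose = NA_real_, hill_params = NULL) {
  spec <- list(network_rate = network_rate,
               participation_prob = participation_prob,
               in_amplitude_mean = in_amplitude_mean,
               in_amplitude_cv = in_amplitude_cv,
               out_rate_per_pixel = out_rate_per_pixel,
               out_amplitude_mean = out_amplitude_mean,
               out_amplitude_cv = out_amplitude_cv,
               kernel_rise_tau = kernel_rise_tau,
               kernel_decay_tau = kernel_decay_tau,
               jitter_sd = jitter_sd,
               drug_time = drug_time,
               drug_frequency_scale = drug_frequency_scale,
               drug_amplitude_scale = drug_amplitude_scale,
               dose = dose, hill_params = hill_params)
  validate_well_spec(spec)
  class(spec) <- "well_spec"
  spec
}

validate_well_spec <- function(spec) {
  chk <- function(cond, field, msg)
    if (!cond) stop(sprintf("well_spec: field '%s' %s", field, msg),
                    call. = FALSE)
  chk(spec$network_rate >= 0, "network_rate", "must be >= 0")
  chk(spec$participation_prob >= 0 && spec$participation_prob <= 1,
      "participation_prob", "must lie in [0, 1]")
  chk(spec$out_rate_per_pixel >= 0, "out_rate_per_pixel", "must be >= 0")
  chk(spec$in_amplitude_mean > 0, "in_amplitude_mean", "must be > 0")
  chk(spec$out_amplitude_mean > 0, "out_amplitude_mean", "must be > 0")
  chk(spec$in_amplitude_cv >= 0, "in_amplitude_cv", "must be >= 0")
  chk(spec$out_amplitude_cv >= 0, "out_amplitude_cv", "must be >= 0")
  chk(spec$kernel_rise_tau > 0, "kernel_rise_tau", "must be > 0")
  chk(spec$kernel_decay_tau > spec$kernel_rise_tau, "kernel_decay_tau",
      "must exceed kernel_rise_tau")
  chk(spec$jitter_sd >= 0, "jitter_sd", "must be >= 0")
  chk(spec$drug_frequency_scale >= 0, "drug_frequency_scale", "must be >= 0")
  chk(spec$drug_amplitude_scale >= 0, "drug_amplitude_scale", "must be >= 0")
  if (!is.null(spec$hill_params)) {
    hp <- spec$hill_params
    if (!all(c("top", "bottom", "ic50", "slope") %in% names(hp)))
      stop("well_spec: hill_params needs top, bottom, ic50, slope",
           call. = FALSE)
    chk(hp$ic50 > 0, "hill_params$ic50", "must be > 0")
  }
  invisible(spec)
}

#' Plate simulation configuration
#'
#' @param wells named list mapping well ids to [well_spec()] objects. Wells
#'   not listed are simulated dry (zone baseline plus noise only), as the
#'   empty edge wells used for background thresholds.
#' @param plate_format,tile_shape,pixel_pitch_um,empty_wells,
#'   compound_addition_time passed to [plate_layout()]; `empty_wells`
#'   defaults to all wells without a spec.
#' @param frame_rate frames per second (8 for pixel-resolution acquisition,
#'   5 for standard well-level recordings).
#' @param duration recording length, seconds.
#' @param zone_brightness baseline counts for the outside, border and growth
#'   zones of each tile (strictly increasing).
#' @param noise_sd additive Gaussian noise, counts.
#' @param rng_seed integer seed; one RNG stream per well is derived from it so
#'   any single well can be re-simulated independently.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(wells,
                       plate_format = 96,
                       tile_shape = NULL,
                       frame_rate = 8,
                       duration = 300,
                       zone_brightness = c(outside = 200, border = 900,
                                           growth = 3000),
                       noise_sd = 40,
                       pixel_pitch_um = 284,
                       empty_wells = NULL,
                       compound_addition_time = NA_real_,
                       rng_seed = 1L) {
  if (!is.list(wells) || is.null(names(wells)) || any(names(wells) == ""))
    stop("sim_config: 'wells' must be a named list of well_spec objects")
  lapply(wells, function(w) {
    if (!inherits(w, "well_spec")) stop("sim_config: wells must be well_spec")
  })
  if (frame_rate <= 0) stop("sim_config: field 'frame_rate' must be > 0")
  if (duration * frame_rate < 2)
    stop("sim_config: field 'duration' too short: need >= 2 frames")
  if (noise_sd < 0) stop("sim_config: field 'noise_sd' must be >= 0")
  zb <- zone_brightness
  if (length(zb) != 3L || !(zb[1] < zb[2] && zb[2] <= zb[3]))
    stop("sim_config: field 'zone_brightness' must be ordered ",
         "outside < border <= growth")
  layout <- plate_layout(plate_format = plate_format, tile_shape = tile_shape,
                         empty_wells = character(0),
                         pixel_pitch_um = pixel_pitch_um,
                         compound_addition_time = compound_addition_time)
  ids <- well_ids(layout$n_rows, layout$n_cols)
  bad <- setdiff(names(wells), ids)
  if (length(bad))
    stop("sim_config: field 'wells' has unknown well ids: ",
         paste(bad, collapse = ", "))
  if (is.null(empty_wells)) empty_wells <- setdiff(ids, names(wells))
  layout$empty_wells <- empty_wells
  structure(list(layout = layout, wells = wells,
                 frame_rate = frame_rate, duration = duration,
                 zone_brightness = stats::setNames(as.numeric(zb),
                                                   c("outside", "border",
                                                     "growth")),
                 noise_sd = noise_sd,
                 rng_seed = as.integer(rng_seed)),
            class = "sim_config")
}

#' GCaMP6f-like calcium transient kernel
#'
#' Difference of exponentials `exp(-t/decay) - exp(-t/rise)` for `t >= 0`,
#' normalized to unit peak, so a transient of drawn amplitude `A` adds `A`
#' counts at its peak. Defaults (rise 0.1 s, decay 0.6 s) give a fast-rising,
#' sub-second transient spanning several frames at 8 frames/s.
#'
#' @param t time since event onset, seconds (vectorized; negative times give 0).
#' @param rise_tau,decay_tau time constants, s; `decay_tau > rise_tau > 0`.
#' @return kernel values in `[0, 1]`.
#' @export
transient_kernel <- function(t, rise_tau = 0.1, decay_tau = 0.6) {
  stopifnot(rise_tau > 0, decay_tau > rise_tau)
  tpk <- rise_tau * decay_tau / (decay_tau - rise_tau) * log(decay_tau / rise_tau)
  kmax <- exp(-tpk / decay_tau) - exp(-tpk / rise_tau)
  out <- numeric(length(t))
  pos <- t >= 0
  out[pos] <- (exp(-t[pos] / decay_tau) - exp(-t[pos] / rise_tau)) / kmax
  out
}

#' Hill dose scaling
#'
#' Four-parameter logistic scale applied to the network spike rate:
#' `bottom + (top - bottom) / (1 + (dose / ic50)^slope)`. A dose of 0 returns
#' `top`; a dose equal to `ic50` returns the midpoint.
#'
#' @param dose concentration(s), >= 0.
#' @param top,bottom asymptotic scales.
#' @param ic50 half-maximal concentration, > 0.
#' @param slope Hill slope.
#' @return numeric scale(s).
#' @export
hill_scale <- function(dose, top = 1, bottom = 0, ic50, slope = 1) {
  if (ic50 <= 0) stop("hill_scale(): ic50 must be > 0")
  if (any(dose < 0)) stop("hill_scale(): doses must be >= 0")
  bottom + (top - bottom) / (1 + (dose / ic50)^slope)
}

#' Expand a base well into a dose series
#'
#' Returns one [well_spec()] per dose with the network rate Hill-scaled by the
#' base spec's `hill_params`, emulating wells pre-incubated with increasing
#' compound concentrations.
#'
#' @param base a [well_spec()] with non-NULL `hill_params`.
#' @param doses numeric vector of concentrations, >= 0.
#' @return list of `well_spec`, one per dose, with `dose` recorded.
#' @export
simulate_dose_series <- function(base, doses) {
  stopifnot(inherits(base, "well_spec"))
  if (is.null(base$hill_params))
    stop("simulate_dose_series(): base spec has no hill_params")
  hp <- base$hill_params
  if (hp$ic50 <= 0) stop("simulate_dose_series(): ic50 must be > 0")
  if (any(doses < 0)) stop("simulate_dose_series(): doses must be >= 0")
  lapply(doses, function(d) {
    s <- unclass(base)
    s$network_rate <- base$network_rate *
      hill_scale(d, hp$top, hp$bottom, hp$ic50, hp$slope)
    s$dose <- d
    s$hill_params <- NULL
    do.call(well_spec, s)
  })
}

# Zone labels of one tile: outermost 1-px ring = outside, next ring = border,
# interior = growth. Returns integer matrix (1 outside, 2 border, 3 growth).
tile_zone_template <- function(ty, tx) {
  z <- matrix(3L, ty, tx)
  ring <- function(m, k, val) {
    m[k, ] <- val; m[ty - k + 1L, ] <- val
    m[, k] <- val; m[, tx - k + 1L] <- val
    m
  }
  z <- ring(z, 2L, 2L)   # border ring
  z <- ring(z, 1L, 1L)   # outside ring
  z
}

# Derived, reproducible per-well seed (kept below 2^31).
well_seed <- function(rng_seed, well_index) {
  as.integer((as.double(rng_seed) * 7919 + well_index * 104729) %% 2147483647)
}

#' Simulate a plate movie with known ground truth
#'
#' Renders the full camera frame stack for a plate: per-well tiles with a
#' three-zone brightness baseline (outside < border < growth), synchronized
#' network transients with per-pixel Bernoulli participation and Gaussian
#' timing jitter, independent per-pixel local (OUT) transients, additive
#' Gaussian noise, and optional acute drug scaling of rate and amplitude from
#' the addition time onward. Overlapping transients add linearly. Frames are
#' quantized to integer counts in `[0, 65535]`, like the 16-bit detector of a
#' kinetic plate reader, which also makes TIFF round-trips exact.
#'
#' @param config a [sim_config()].
#' @return list with elements
#'   \describe{
#'     \item{movie}{an `lfca_movie` (frames, frame_rate, layout, ...)}
#'     \item{truth}{per-well ground truth: network event times, the
#'       events x pixels participation matrix and amplitudes, OUT spike times
#'       and amplitudes per pixel, growth-pixel coordinates, applied scales.}
#'   }
#' @export
simulate_plate <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  layout <- config$layout
  fr <- config$frame_rate
  n_frames <- round(config$duration * fr)
  ty <- layout$tile_shape[1]; tx <- layout$tile_shape[2]
  Y <- layout$n_rows * ty; X <- layout$n_cols * tx
  zone <- tile_zone_template(ty, tx)
  base_tile <- matrix(config$zone_brightness[c("outside", "border",
                                               "growth")][zone], ty, tx)
  frame_times <- (seq_len(n_frames) - 1) / fr

  movie <- array(0, dim = c(n_frames, Y, X))
  ids <- well_ids(layout$n_rows, layout$n_cols)
  truth <- list()

  for (wi in seq_along(ids)) {
    id <- ids[wi]
    b <- tile_bounds(layout, id)
    ys <- (b$y0 + 1L):b$y1; xs <- (b$x0 + 1L):b$x1
    set.seed(well_seed(config$rng_seed, wi))
    # baseline + noise for the whole tile
    tile <- array(rep(base_tile, each = n_frames),
                  dim = c(n_frames, ty, tx))
    if (config$noise_sd > 0)
      tile <- tile + stats::rnorm(length(tile), 0, config$noise_sd)

    spec <- config$wells[[id]]
    if (!is.null(spec)) {
      gp <- which(zone == 3L, arr.ind = TRUE)  # growth pixels (row, col)
      npx <- nrow(gp)
      tw <- simulate_well_events(spec, config$duration, npx)
      # render transients into per-pixel traces
      for (px in seq_len(npx)) {
        tr <- tile[, gp[px, 1], gp[px, 2]]
        ev_t <- c(tw$in_times[[px]], tw$out_times[[px]])
        ev_a <- c(tw$in_amps[[px]], tw$out_amps[[px]])
        if (length(ev_t))
          tr <- add_transients(tr, ev_t, ev_a, fr, frame_times,
                               spec$kernel_rise_tau, spec$kernel_decay_tau)
        tile[, gp[px, 1], gp[px, 2]] <- tr
      }
      truth[[id]] <- list(
        network_times = tw$network_times,
        participation = tw$participation,
        in_amplitudes = tw$in_amplitudes,
        in_times = tw$in_times,
        out_times = tw$out_times,
        out_amplitudes = tw$out_amps,
        growth_pixels = gp,
        frequency_scale = tw$frequency_scale,
        amplitude_scale = tw$amplitude_scale,
        n_events_injected = tw$n_events_injected
      )
    }
    # quantize per tile to 16-bit detector counts (avoids whole-array copies)
    tile <- round(tile)
    tile[tile < 0] <- 0
    tile[tile > 65535] <- 65535
    movie[, ys, xs] <- tile
  }

  m <- lfca_movie(movie, frame_rate = fr, layout = layout, binning = 1L,
                  start_time = 0)
  list(movie = m, truth = truth)
}

# Draw all event times/amplitudes for one well. Returns per-pixel IN times
# (jittered) and amplitudes, plus the network-level truth.
simulate_well_events <- function(spec, duration, npx) {
  freq_scale <- 1
  if (!is.null(spec$hill_params) && !is.na(spec$dose))
    freq_scale <- hill_scale(spec$dose, spec$hill_params$top,
                             spec$hill_params$bottom, spec$hill_params$ic50,
                             spec$hill_params$slope)
  rate_s <- spec$network_rate * freq_scale / 60

  if (!is.na(spec$drug_time)) {
    t1 <- spec$drug_time
    n1 <- stats::rpois(1, rate_s * t1)
    n2 <- stats::rpois(1, rate_s * spec$drug_frequency_scale * (duration - t1))
    net <- sort(c(stats::runif(n1, 0, t1), stats::runif(n2, t1, duration)))
  } else {
    n <- stats::rpois(1, rate_s * duration)
    net <- sort(stats::runif(n, 0, duration))
  }
  nev <- length(net)

  part <- matrix(stats::runif(nev * npx) < spec$participation_prob, nev, npx)
  amp_mean <- rep(spec$in_amplitude_mean, nev)
  if (!is.na(spec$drug_time))
    amp_mean[net >= spec$drug_time] <- amp_mean[net >= spec$drug_time] *
      spec$drug_amplitude_scale
  amps <- matrix(0, nev, npx)
  if (nev)
    amps[] <- rlnorm_mean_cv(nev * npx, rep(amp_mean, npx),
                             spec$in_amplitude_cv)
  amps[!part] <- 0
  jit <- matrix(stats::rnorm(nev * npx, 0, spec$jitter_sd), nev, npx)

  in_times <- vector("list", npx); in_amps <- vector("list", npx)
  for (px in seq_len(npx)) {
    sel <- part[, px]
    in_times[[px]] <- pmin(pmax(net[sel] + jit[sel, px], 0), duration)
    in_amps[[px]] <- amps[sel, px]
  }

  out_rate_s <- spec$out_rate_per_pixel / 60
  out_times <- vector("list", npx); out_amps <- vector("list", npx)
  for (px in seq_len(npx)) {
    k <- stats::rpois(1, out_rate_s * duration)
    out_times[[px]] <- sort(stats::runif(k, 0, duration))
    out_amps[[px]] <- rlnorm_mean_cv(k, spec$out_amplitude_mean,
                                     spec$out_amplitude_cv)
  }

  list(network_times = net, participation = part, in_amplitudes = amps,
       in_times = in_times, in_amps = in_amps,
       out_times = out_times, out_amps = out_amps,
       frequency_scale = freq_scale * spec$drug_frequency_scale,
       amplitude_scale = spec$drug_amplitude_scale,
       n_events_injected = sum(part) + sum(lengths(out_times)))
}

# Lognormal draws with the requested arithmetic mean and CV (cv = 0 degrades
# to the constant mean).
rlnorm_mean_cv <- function(n, mean, cv) {
  if (n == 0) return(numeric(0))
  if (cv == 0) return(rep_len(mean, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

# Add unit-peak kernels scaled by 'amps' at times 'ev_t' into a trace.
add_transients <- function(tr, ev_t, amps, fr, frame_times, rise, decay) {
  n <- length(tr)
  support <- 12 * decay
  for (e in seq_along(ev_t)) {
    t0 <- ev_t[e]
    i0 <- max(1L, floor(t0 * fr) + 1L)
    i1 <- min(n, ceiling((t0 + support) * fr) + 1L)
    if (i0 > n || i1 < 1L || i1 < i0) next
    idx <- i0:i1
    tr[idx] <- tr[idx] + amps[e] *
      transient_kernel(frame_times[idx] - t0, rise, decay)
  }
  tr
}
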