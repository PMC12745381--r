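#' Global detection threshold from empty wells
#'
#' Plate-wide prominence threshold for network-spike detection, derived from
#' the background signal of the dry wells at the plate edge: for every empty
#' well the maximal peak prominence of its well-average trace is measured, and
#' the threshold is the mean plus three standard deviations of those maxima
#' (with a single empty well, just its maximum). A zero-noise plate yields a
#' small positive floor so that any real transient still passes.
#'
#' @param movie an [lfca_movie()].
#' @param mask a [build_zone_mask()] result.
#' @param layout optional [plate_layout()] naming the empty wells; defaults to
#'   the movie's layout.
#' @return list with `threshold`, `empty_max_prominences` (named per empty
#'   well), `mean`, `sd`.
#' @export
global_threshold <- function(movie, mask, layout = NULL) {
  if (is.null(layout)) layout <- movie$layout
  if (!length(layout$empty_wells))
    stop("global_threshold(): layout names no empty wells; pass an explicit ",
         "detection threshold instead")
  maxp <- vapply(layout$empty_wells, function(w) {
    tr <- extract_well_trace(movie, mask, w)
    ss <- detect_spikes(tr, threshold = 0)
    if (nrow(ss)) max(ss$prominence) else 0
  }, numeric(1))
  m <- mean(maxp)
  s <- if (length(maxp) > 1L) stats::sd(maxp) else 0
  thr <- m + 3 * s
  if (thr <= 0) thr <- .Machine$double.eps
  list(threshold = thr, empty_max_prominences = maxp, mean = m, sd = s)
}

#' Network spike frequency
#'
#' Spike count divided by the analyzed duration, in spikes per minute.
#'
#' @param spikeset a [spike_set()].
#' @return spikes/min.
#' @export
spike_frequency <- function(spikeset) {
  dur <- attr(spikeset, "duration_analyzed")
  if (is.null(dur) || dur <= 0)
    stop("spike_frequency(): duration_analyzed must be > 0")
  nrow(spikeset) / dur * 60
}

#' Mean network spike amplitude
#'
#' Arithmetic mean of event prominences. An empty spike set returns `NA` with
#' attribute `flag = "no_events"` rather than an error, so that silent wells
#' propagate visibly through summaries.
#'
#' @param spikeset a [spike_set()].
#' @return mean prominence (a.u.), or flagged `NA`.
#' @export
mean_spike_amplitude <- function(spikeset) {
  if (!nrow(spikeset))
    return(structure(NA_real_, flag = "no_events"))
  mean(spikeset$prominence)
}

#' Acute drug response of one well
#'
#' Splits a well trace at the compound-addition time and computes spike
#' frequency and mean amplitude separately for the baseline window
#' `[0, addition_time)` and the post-addition window. A guard interval after
#' the addition (default 10 s) is excluded to skip the dispense artifact.
#' Pair the per-well ratios across wells with
#' [compare_two_groups()]`(paired = TRUE)` for the within-well treatment
#' versus baseline test.
#'
#' @param trace an [lfca_trace()] (well-average signal).
#' @param addition_time compound addition time, s; must lie inside the trace.
#' @param threshold prominence detection threshold.
#' @param guard seconds after `addition_time` excluded from the post window.
#' @return list with `baseline` and `post` (each `frequency`, `amplitude`,
#'   `n_spikes`, `duration`), the frequency and amplitude ratios post/baseline,
#'   and `flags` (e.g. `"short_post_window"` when the post window is under
#'   60 s).
#' @export
drug_response <- function(trace, addition_time, threshold, guard = 10) {
  fr <- attr(trace, "frame_rate")
  x <- as.numeric(trace)
  total <- length(x) / fr
  if (!(addition_time > 0 && addition_time < total))
    stop("drug_response(): addition_time must lie inside the trace")
  i_add <- floor(addition_time * fr)
  i_post <- min(length(x), floor((addition_time + guard) * fr) + 1L)
  seg <- function(idx) detect_spikes(x[idx], threshold, frame_rate = fr)
  base_ss <- seg(1:i_add)
  post_ss <- seg(i_post:length(x))
  flags <- character(0)
  if (attr(post_ss, "duration_analyzed") < 60)
    flags <- c(flags, "short_post_window")
  metrics <- function(ss) list(frequency = spike_frequency(ss),
                               amplitude = as.numeric(mean_spike_amplitude(ss)),
                               n_spikes = nrow(ss),
                               duration = attr(ss, "duration_analyzed"))
  b <- metrics(base_ss); p <- metrics(post_ss)
  list(baseline = b, post = p,
       frequency_ratio = if (b$frequency > 0) p$frequency / b$frequency else
         NA_real_,
       amplitude_ratio = if (isTRUE(b$amplitude > 0)) p$amplitude / b$amplitude
         else NA_real_,
       flags = flags)
}

#' Paired drug-response tests across wells
#'
#' Applies [drug_response()] to each well trace and tests post versus baseline
#' frequency and amplitude with paired t-tests (within-well comparison).
#'
#' @param traces named list of [lfca_trace()] well traces.
#' @inheritParams drug_response
#' @return list with `per_well` (data frame) and `tests` (paired t results for
#'   frequency and amplitude).
#' @export
drug_response_tests <- function(traces, addition_time, threshold, guard = 10) {
  res <- lapply(traces, drug_response, addition_time = addition_time,
                threshold = threshold, guard = guard)
  per_well <- data.frame(
    well = names(res),
    baseline_frequency = vapply(res, function(r) r$baseline$frequency, 0),
    post_frequency = vapply(res, function(r) r$post$frequency, 0),
    baseline_amplitude = vapply(res, function(r) r$baseline$amplitude, 0),
    post_amplitude = vapply(res, function(r) r$post$amplitude, 0),
    row.names = NULL
  )
  paired_t <- function(a, b) {
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < 2) return(list(t = NA_real_, df = NA_real_, p = NA_real_))
    ht <- stats::t.test(b[ok], a[ok], paired = TRUE)
    list(t = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value)
  }
  list(per_well = per_well,
       tests = list(
         frequency = paired_t(per_well$baseline_frequency,
                              per_well$post_frequency),
         amplitude = paired_t(per_well$baseline_amplitude,
                              per_well$post_amplitude)))
}

#' Four-parameter logistic dose-response fit
#'
#' Least-squares fit of `response = bottom + (top - bottom) /
#' (1 + 10^(slope * (log10(dose) - log10(ic50))))` in log-dose, the standard
#' 4PL model for inhibition curves, via Levenberg-Marquardt
#' ([minpack.lm::nlsLM()]). Start values come from the data: `top`/`bottom`
#' from the mean response at the extreme doses, `ic50` from linear
#' interpolation of the half response, slope 1. Zero doses are allowed in the
#' data and handled by fitting on the Hill form in concentration space.
#'
#' @param doses concentrations (>= 0), at least 4 distinct values.
#' @param responses numeric responses, same length.
#' @return object of class `dose_response_fit`: list with `top`, `bottom`,
#'   `ic50`, `hill_slope`, `residual_sse`, `fitted` (per input dose),
#'   `poor_fit` flag and `diagnostics`. Flat or non-monotone data are fitted
#'   but flagged rather than silently accepted.
#' @export
fit_dose_response <- function(doses, responses) {
  stopifnot(length(doses) == length(responses))
  if (any(doses < 0)) stop("fit_dose_response(): doses must be >= 0")
  if (length(unique(doses)) < 4L)
    stop("fit_dose_response(): need >= 4 distinct doses")
  df <- data.frame(dose = doses, resp = responses)
  agg <- stats::aggregate(resp ~ dose, df, mean)
  agg <- agg[order(agg$dose), ]
  top0 <- agg$resp[1]; bot0 <- agg$resp[nrow(agg)]
  if (top0 < bot0) { tmp <- top0; top0 <- bot0; bot0 <- tmp }
  half <- (top0 + bot0) / 2
  below <- which(agg$resp <= half & agg$dose > 0)
  ic0 <- if (length(below)) agg$dose[min(below)] else
    stats::median(agg$dose[agg$dose > 0])
  if (!is.finite(ic0) || ic0 <= 0) ic0 <- max(doses[doses > 0], 1)

  fit <- try(minpack.lm::nlsLM(
    resp ~ bottom + (top - bottom) / (1 + (dose / exp(lic50))^slope),
    data = df,
    start = list(top = top0, bottom = bot0, lic50 = log(ic0), slope = 1),
    control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    # degenerate (e.g. flat) data: report the constant model, flagged
    m <- mean(responses)
    return(structure(list(top = m, bottom = m, ic50 = ic0,
                          hill_slope = NA_real_,
                          residual_sse = sum((responses - m)^2),
                          fitted = rep(m, length(responses)),
                          poor_fit = TRUE,
                          diagnostics = list(
                            optimizer_error = attr(fit, "condition")$message,
                            response_sd = stats::sd(responses))),
                     class = "dose_response_fit"))
  }
  cf <- stats::coef(fit)
  fitted_vals <- stats::fitted(fit)
  sse <- sum(stats::residuals(fit)^2)
  span <- abs(cf[["top"]] - cf[["bottom"]])
  sd_resp <- stats::sd(responses)
  rho <- suppressWarnings(
    stats::cor(agg$dose, agg$resp, method = "spearman"))
  poor <- !is.finite(span) || span < 0.1 * max(sd_resp, 1e-12) ||
    !is.finite(rho) || abs(rho) < 0.5
  structure(list(top = cf[["top"]], bottom = cf[["bottom"]],
                 ic50 = exp(cf[["lic50"]]), hill_slope = cf[["slope"]],
                 residual_sse = sse, fitted = fitted_vals,
                 poor_fit = poor,
                 diagnostics = list(spearman_dose_response = rho,
                                    response_span = span,
                                    response_sd = sd_resp)),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf(
    "dose_response_fit: IC50 = %.4g, slope = %.3g, top = %.4g, bottom = %.4g%s\n",
    x$ic50, x$hill_slope, x$top, x$bottom,
    if (x$poor_fit) "  [POOR FIT]" else ""))
  invisible(x)
}

#' Network-spike participation windows
#'
#' One time interval per network spike of the well-average trace, spanning the
#' half-prominence crossings padded on both sides (default: one frame), inside
#' which per-pixel spikes count as participating (IN). Overlapping or abutting
#' intervals are merged.
#'
#' @param spikeset a [spike_set()] from a well-average trace.
#' @param pad padding added to each side, seconds; default one frame period.
#' @return object of class `network_windows`: matrix with columns `start`,
#'   `end` (s), merged and sorted, plus the frame rate as attribute.
#' @export
network_windows <- function(spikeset, pad = NULL) {
  fr <- attr(spikeset, "frame_rate")
  if (is.null(pad)) pad <- 1 / fr
  if (!nrow(spikeset)) {
    w <- matrix(numeric(0), ncol = 2,
                dimnames = list(NULL, c("start", "end")))
    return(structure(w, frame_rate = fr,
                     duration = attr(spikeset, "duration_analyzed"),
                     class = c("network_windows", class(w))))
  }
  start <- spikeset$left_half_time - pad
  end <- spikeset$right_half_time + pad
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  outs <- numeric(0); oute <- numeric(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      outs <- c(outs, ms); oute <- c(oute, me)
      ms <- start[i]; me <- end[i]
    }
  }
  outs <- c(outs, ms); oute <- c(oute, me)
  w <- cbind(start = outs, end = oute)
  structure(w, frame_rate = fr,
            duration = attr(spikeset, "duration_analyzed"),
            class = c("network_windows", class(w)))
}
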