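#' Prominence-based spike detection
#'
#' Detects calcium spikes in a fluorescence trace as local maxima whose
#' topographic prominence reaches a threshold. Prominence is the height of a
#' peak above the highest contour line that encloses no higher peak: for each
#' peak the trace is scanned outwards on both sides until a strictly higher
#' sample (or the trace end) is reached, the minimum of each flank is taken,
#' and the prominence is the peak value minus the larger of the two flank
#' minima. The spike amplitude reported throughout the package is this
#' prominence, not the absolute peak height, so detection is invariant to
#' baseline offsets.
#'
#' The full width at half maximum (FWHM) of each spike is measured at half the
#' prominence below the peak, with linear interpolation between samples, and
#' clamped to the peak's prominence bases when a flank never drops that low.
#' Plateau maxima are resolved to the leftmost sample of the plateau.
#'
#' @param trace numeric vector of fluorescence intensity, or an
#'   [lfca_trace()] object carrying its own frame rate.
#' @param threshold minimum prominence for a peak to be kept, in the units of
#'   `trace`.
#' @param frame_rate frames per second, used to convert frame indices to
#'   seconds. Ignored (taken from the object) when `trace` is an `lfca_trace`.
#' @param min_separation minimum distance between retained peaks, in frames.
#'   When two peaks are closer, the less prominent one is dropped. Distinct
#'   strict local maxima are always at least 2 frames apart, so the default
#'   only affects plateau-derived doublets.
#' @return A `spike_set`: a data frame with one row per spike and columns
#'   `peak_index` (1-based frame), `peak_time` (s, frame 1 is time 0),
#'   `peak_value`, `prominence`, `amplitude` (== prominence), `fwhm` (s),
#'   `left_half_time`, `right_half_time` (s), `label` (all `"unlabeled"`),
#'   plus attributes `detection_threshold`, `frame_rate` and
#'   `duration_analyzed` (s).
#' @examples
#' x <- c(0, 0, 1, 2, 1, 0, 0, 3, 0, 0)
#' detect_spikes(x, threshold = 0.5, frame_rate = 5)
#' @export
detect_spikes <- function(trace, threshold, frame_rate = NULL,
                          min_separation = 2L) {
  if (inherits(trace, "lfca_trace")) {
    frame_rate <- attr(trace, "frame_rate")
    x <- as.numeric(trace)
  } else {
    x <- as.numeric(trace)
  }
  if (is.null(frame_rate) || !is.finite(frame_rate) || frame_rate <= 0)
    stop("detect_spikes(): a positive 'frame_rate' is required")
  if (length(x) < 3L)
    stop("detect_spikes(): trace must have at least 3 samples")
  if (anyNA(x)) stop("detect_spikes(): trace contains NA values")
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold >= 0)

  pk <- local_maxima(x)
  res <- peak_prominences(x, pk)
  keep <- res$prominence >= threshold & res$prominence > 0
  pk <- pk[keep]
  prom <- res$prominence[keep]
  lb <- res$left_base[keep]
  rb <- res$right_base[keep]

  if (length(pk) > 1L && min_separation > 1L) {
    ord <- order(prom, decreasing = TRUE)
    kept <- logical(length(pk))
    taken <- integer(0)
    for (j in ord) {
      if (!length(taken) || all(abs(pk[j] - pk[taken]) >= min_separation)) {
        kept[j] <- TRUE
        taken <- c(taken, j)
      }
    }
    pk <- pk[kept]; prom <- prom[kept]; lb <- lb[kept]; rb <- rb[kept]
  }

  o <- order(pk)
  pk <- pk[o]; prom <- prom[o]; lb <- lb[o]; rb <- rb[o]

  w <- half_prominence_widths(x, pk, prom, lb, rb)
  events <- data.frame(
    peak_index = pk,
    peak_time = (pk - 1) / frame_rate,
    peak_value = x[pk],
    prominence = prom,
    amplitude = prom,
    fwhm = (w$right - w$left) / frame_rate,
    left_half_time = (w$left - 1) / frame_rate,
    right_half_time = (w$right - 1) / frame_rate,
    label = rep("unlabeled", length(pk)),
    stringsAsFactors = FALSE
  )
  spike_set(events, threshold = threshold, frame_rate = frame_rate,
            duration = length(x) / frame_rate)
}

#' @rdname detect_spikes
#' @param events data frame of spike events (see [detect_spikes()]).
#' @param duration duration of the analyzed trace, seconds.
#' @export
spike_set <- function(events, threshold, frame_rate, duration) {
  structure(events,
            detection_threshold = threshold,
            frame_rate = frame_rate,
            duration_analyzed = duration,
            class = c("spike_set", "data.frame"))
}

#' @export
print.spike_set <- function(x, ...) {
  cat(sprintf("spike_set: %d events in %.1f s (threshold %.4g)\n",
              nrow(x), attr(x, "duration_analyzed"),
              attr(x, "detection_threshold")))
  if (nrow(x)) print.data.frame(x, ...)
  invisible(x)
}

# Indices of strict local maxima; plateaus resolved to the leftmost sample.
local_maxima <- function(x) {
  r <- rle(x)
  n_runs <- length(r$values)
  if (n_runs < 3L) return(integer(0))
  starts <- cumsum(c(1L, r$lengths[-n_runs]))
  inner <- 2:(n_runs - 1L)
  is_peak <- r$values[inner] > r$values[inner - 1L] &
    r$values[inner] > r$values[inner + 1L]
  starts[inner][is_peak]
}

# Topographic prominence of each peak, scipy-style: scan each flank until a
# strictly higher sample or the signal edge; the base is the flank minimum.
peak_prominences <- function(x, peaks) {
  n <- length(x)
  np <- length(peaks)
  prom <- numeric(np); lbase <- integer(np); rbase <- integer(np)
  for (j in seq_len(np)) {
    p <- peaks[j]; v <- x[p]
    # left flank
    if (p == 1L) {
      lmin <- v; lpos <- p
    } else {
      left <- x[1:(p - 1L)]
      higher <- which(left > v)
      lo <- if (length(higher)) max(higher) + 1L else 1L
      seg <- x[lo:p]
      lpos <- lo + which.min(seg) - 1L
      lmin <- x[lpos]
    }
    # right flank
    if (p == n) {
      rmin <- v; rpos <- p
    } else {
      right <- x[(p + 1L):n]
      higher <- which(right > v)
      hi <- if (length(higher)) p + min(higher) - 1L else n
      seg <- x[p:hi]
      rpos <- p + which.min(seg) - 1L
      rmin <- x[rpos]
    }
    prom[j] <- v - max(lmin, rmin)
    lbase[j] <- lpos
    rbase[j] <- rpos
  }
  list(prominence = prom, left_base = lbase, right_base = rbase)
}

# Interpolated crossings at half prominence below each peak, searched within
# the peak's prominence bases. Returned positions are fractional 1-based
# frame indices.
half_prominence_widths <- function(x, peaks, prom, lbase, rbase) {
  np <- length(peaks)
  left <- numeric(np); right <- numeric(np)
  for (j in seq_len(np)) {
    p <- peaks[j]
    h <- x[p] - 0.5 * prom[j]
    # left crossing
    lo <- lbase[j]
    li <- lo
    if (p > lo) {
      below <- which(x[lo:(p - 1L)] < h)
      if (length(below)) {
        k <- lo + max(below) - 1L
        li <- k + (h - x[k]) / (x[k + 1L] - x[k])
      }
    }
    # right crossing
    hi <- rbase[j]
    ri <- hi
    if (hi > p) {
      below <- which(x[(p + 1L):hi] < h)
      if (length(below)) {
        k <- p + min(below)
        ri <- k - (h - x[k]) / (x[k - 1L] - x[k])
      }
    }
    left[j] <- li
    right[j] <- ri
  }
  list(left = left, right = right)
}
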