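#' Rank pixels by spiking activity
#'
#' Treats each growth pixel as a virtual electrode and ranks pixels by the
#' mean maximal fluorescence across their detected spikes (pixels without
#' spikes score 0), the same logic as focusing multi-electrode-array analysis
#' on "active" electrodes. The rank-score curve typically drops off at the
#' number of pixels that actually cover spiking neurons; that shoulder is
#' estimated as the rank with maximal perpendicular distance to the chord of
#' the curve.
#'
#' @param pixel_traces an [extract_pixel_traces()] result (min-max
#'   normalized).
#' @param base_threshold prominence threshold used for the per-pixel spike
#'   detection behind the score (default 0.4).
#' @param N number of top pixels to select: 400 for 96-well and 130 for
#'   384-well optical plates (the approximate growth-area coverage).
#' @return object of class `pixel_ranking`: data frame with one row per pixel
#'   (`pixel`, `row`, `col`, `score`, `n_spikes`, `rank`, `selected`), plus
#'   attributes `shoulder` (estimated active-pixel count), `N` and
#'   `degenerate` (TRUE when every pixel is silent).
#' @export
rank_active_pixels <- function(pixel_traces, base_threshold = 0.4, N = 400) {
  stopifnot(inherits(pixel_traces, "pixel_traces"))
  tr <- pixel_traces$traces
  fr <- pixel_traces$frame_rate
  npx <- ncol(tr)
  score <- numeric(npx)
  nsp <- integer(npx)
  for (j in seq_len(npx)) {
    ss <- detect_spikes(tr[, j], base_threshold, frame_rate = fr)
    nsp[j] <- nrow(ss)
    score[j] <- if (nrow(ss)) mean(ss$peak_value) else 0
  }
  ord <- order(score, seq_len(npx), decreasing = c(TRUE, FALSE),
               method = "radix")
  rank <- integer(npx); rank[ord] <- seq_len(npx)
  n_sel <- min(N, npx)
  selected <- rank <= n_sel
  degenerate <- all(score == 0)

  s_sorted <- score[ord]
  shoulder <- if (degenerate || npx < 3L) NA_integer_ else {
    r <- seq_len(npx)
    # distance of each point of the rank-score curve to its end-to-end chord
    dx <- npx - 1; dy <- s_sorted[npx] - s_sorted[1]
    d <- abs(dy * (r - 1) - dx * (s_sorted - s_sorted[1]))
    which.max(d)
  }
  structure(data.frame(pixel = seq_len(npx),
                       row = pixel_traces$coords[, 1],
                       col = pixel_traces$coords[, 2],
                       score = score, n_spikes = nsp, rank = rank,
                       selected = selected),
            shoulder = shoulder, N = N, degenerate = degenerate,
            flag = if (npx < N) "fewer_pixels_than_N" else NULL,
            class = c("pixel_ranking", "data.frame"))
}

#' Default top-N pixels per plate format
#' @param plate_format 96 or 384.
#' @return 400 for 96-well plates, 130 for 384-well.
#' @export
default_top_n <- function(plate_format) {
  if (plate_format == 96) 400L
  else if (plate_format == 384) 130L
  else stop("default_top_n(): plate_format must be 96 or 384")
}

#' Per-pixel spike detection
#'
#' Runs [detect_spikes()] on every (min-max normalized) pixel trace of a well
#' with the local-field prominence threshold (0.4 unless stated otherwise) and
#' collects all events into one table; FWHM and times are in seconds.
#'
#' @param pixel_traces an [extract_pixel_traces()] result with
#'   `normalization = "minmax"`.
#' @param prominence_threshold detection threshold on the normalized scale.
#' @param pixels optional integer vector restricting detection to a subset of
#'   pixels (e.g. the top-N from [rank_active_pixels()]).
#' @return object of class `pixel_spike_table`: data frame with columns
#'   `well`, `pixel`, `row`, `col`, the [detect_spikes()] event fields and
#'   `label` (`"unlabeled"` until [classify_in_out()]); attributes
#'   `frame_rate`, `duration`, `n_pixels`, `threshold`.
#' @export
detect_pixel_spikes <- function(pixel_traces, prominence_threshold = 0.4,
                                pixels = NULL) {
  stopifnot(inherits(pixel_traces, "pixel_traces"))
  tr <- pixel_traces$traces
  if (pixel_traces$normalization != "minmax" ||
      min(tr) < 0 || max(tr) > 1)
    stop("detect_pixel_spikes(): pixel traces must be min-max normalized ",
         "to [0, 1]")
  fr <- pixel_traces$frame_rate
  if (is.null(pixels)) pixels <- seq_len(ncol(tr))
  rows <- lapply(pixels, function(j) {
    ss <- detect_spikes(tr[, j], prominence_threshold, frame_rate = fr)
    if (!nrow(ss)) return(NULL)
    ev <- as.data.frame(ss)
    rownames(ev) <- NULL
    data.frame(well = pixel_traces$well, pixel = j,
               row = unname(pixel_traces$coords[j, 1]),
               col = unname(pixel_traces$coords[j, 2]), ev)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(well = character(0), pixel = integer(0),
                      row = integer(0), col = integer(0),
                      empty_spike_events())
  structure(out, frame_rate = fr,
            duration = nrow(tr) / fr,
            n_pixels = length(pixels),
            threshold = prominence_threshold,
            class = c("pixel_spike_table", "data.frame"))
}

empty_spike_events <- function() {
  data.frame(peak_index = integer(0), peak_time = numeric(0),
             peak_value = numeric(0), prominence = numeric(0),
             amplitude = numeric(0), fwhm = numeric(0),
             left_half_time = numeric(0), right_half_time = numeric(0),
             label = character(0))
}

#' Classify pixel spikes as IN or OUT of network spikes
#'
#' A pixel spike is labeled `IN` when its peak time falls inside any merged
#' network-spike window (closed intervals), and `OUT` otherwise. IN spikes
#' represent local activity participating in a synchronized network spike; OUT
#' spikes are isolated local events invisible in the well-average signal.
#'
#' @param table a [detect_pixel_spikes()] result.
#' @param windows a [network_windows()] result from the same well's average
#'   trace.
#' @return the table with `label` filled in.
#' @export
classify_in_out <- function(table, windows) {
  stopifnot(inherits(table, "pixel_spike_table"),
            inherits(windows, "network_windows"))
  table$label <- ifelse(in_any_window(table$peak_time, windows), "IN", "OUT")
  table
}

# Vectorized closed-interval membership.
in_any_window <- function(times, windows) {
  if (!nrow(windows)) return(rep(FALSE, length(times)))
  out <- rep(FALSE, length(times))
  for (i in seq_len(nrow(windows)))
    out <- out | (times >= windows[i, "start"] & times <= windows[i, "end"])
  out
}

#' Threshold sweep of spike retention
#'
#' Re-detects pixel spikes at prominence thresholds from the sweep floor (0.1,
#' just above noise) to 1.0 in steps of 0.01 and reports, per threshold and
#' per class (IN, OUT, all), the fraction of spikes retained relative to the
#' floor threshold. Because prominence does not depend on the detection
#' threshold, detection is run once at the floor and higher thresholds filter
#' by prominence, which makes the fractions monotone non-increasing by
#' construction.
#'
#' @param pixel_traces min-max normalized [extract_pixel_traces()] result.
#' @param windows [network_windows()] of the same well.
#' @param thresholds sweep grid (default `seq(0.1, 1, by = 0.01)`).
#' @param pixels optional pixel subset (e.g. top-N).
#' @return object of class `threshold_sweep`: data frame `(threshold, class,
#'   n, fraction)`; attribute `flag = "no_spikes_at_floor"` (with `NA`
#'   fractions) when nothing is detected at the floor threshold.
#' @export
threshold_sweep <- function(pixel_traces, windows,
                            thresholds = seq(0.10, 1.00, by = 0.01),
                            pixels = NULL) {
  floor_thr <- min(thresholds)
  tab <- detect_pixel_spikes(pixel_traces, floor_thr, pixels = pixels)
  tab <- classify_in_out(tab, windows)
  classes <- list(IN = tab$prominence[tab$label == "IN"],
                  OUT = tab$prominence[tab$label == "OUT"],
                  all = tab$prominence)
  n0 <- vapply(classes, length, 0L)
  rows <- do.call(rbind, lapply(names(classes), function(cl) {
    proms <- classes[[cl]]
    n <- vapply(thresholds, function(th) sum(proms >= th), 0L)
    data.frame(threshold = thresholds, class = cl, n = n,
               fraction = if (n0[[cl]] > 0) n / n0[[cl]] else NA_real_)
  }))
  structure(rows,
            floor = floor_thr,
            flag = if (n0[["all"]] == 0) "no_spikes_at_floor" else NULL,
            class = c("threshold_sweep", "data.frame"))
}

#' Per-well local-field summary
#'
#' Summarizes a labeled pixel spike table per well: the mean over (selected)
#' pixels of the per-pixel spike frequency, and the mean amplitude and FWHM
#' over spikes, overall and per class (IN / OUT). Selected pixels without any
#' spike contribute zero frequency.
#'
#' @param table a labeled [classify_in_out()] table.
#' @param selection integer vector of pixel indices included in the summary
#'   (e.g. the top-N active pixels), or `NULL` for all pixels present.
#' @param duration analyzed duration in seconds; defaults to the table's.
#' @param n_pixels number of pixels behind the frequency average; defaults to
#'   `length(selection)` or the table's pixel count.
#' @return data frame with one row per well: `n_spikes`, `n_in`, `n_out`,
#'   `mean_pixel_frequency` (spikes/min), `mean_amplitude`, `mean_fwhm`, and
#'   the per-class `in_`/`out_` amplitude and FWHM means.
#' @export
summarize_local_fields <- function(table, selection = NULL, duration = NULL,
                                   n_pixels = NULL) {
  stopifnot(inherits(table, "pixel_spike_table"))
  if (is.null(duration)) duration <- attr(table, "duration")
  if (!is.null(selection)) {
    table <- table[table$pixel %in% selection, , drop = FALSE]
    if (is.null(n_pixels)) n_pixels <- length(selection)
  } else if (is.null(n_pixels)) {
    n_pixels <- attr(table, "n_pixels")
  }
  wells <- unique(table$well)
  if (!length(wells)) wells <- character(0)
  rows <- lapply(wells, function(w) {
    d <- table[table$well == w, , drop = FALSE]
    m <- function(v) if (length(v)) mean(v) else NA_real_
    data.frame(
      well = w,
      n_spikes = nrow(d),
      n_in = sum(d$label == "IN"),
      n_out = sum(d$label == "OUT"),
      mean_pixel_frequency = nrow(d) / n_pixels / duration * 60,
      mean_amplitude = m(d$amplitude),
      mean_fwhm = m(d$fwhm),
      in_amplitude = m(d$amplitude[d$label == "IN"]),
      out_amplitude = m(d$amplitude[d$label == "OUT"]),
      in_fwhm = m(d$fwhm[d$label == "IN"]),
      out_fwhm = m(d$fwhm[d$label == "OUT"])
    )
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(well = character(0))
  rownames(out) <- NULL
  out
}
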