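#' Pairwise pixel correlation
#'
#' Pearson correlation of all pixel-trace pairs of a well, optionally
#' restricted to a subset of frames (a phase mask from [phase_masks()]), which
#' yields the phase-restricted variants: correlation over frames inside
#' network-spike windows (IN phases) versus outside them (OUT phases). Pixels
#' with zero variance over the analyzed frames are excluded from the matrix
#' and listed.
#'
#' @param pixel_traces an [extract_pixel_traces()] result.
#' @param phase_mask optional logical vector over frames (TRUE = analyze); at
#'   least 10 frames must remain.
#' @param pixels optional pixel subset (e.g. top-N active pixels).
#' @param phase label stored with the result: `"full"`, `"in_phases"` or
#'   `"out_phases"`.
#' @return object of class `synchrony_result`: list with `r` (correlation
#'   matrix, unit diagonal), `coords` (pixels x 2), `mean_r` (mean
#'   off-diagonal), `excluded` (zero-variance pixel indices), `phase`,
#'   `n_frames`, and the layout pixel pitch when available.
#' @export
pairwise_correlation <- function(pixel_traces, phase_mask = NULL,
                                 pixels = NULL, phase = "full") {
  stopifnot(inherits(pixel_traces, "pixel_traces"))
  tr <- pixel_traces$traces
  coords <- pixel_traces$coords
  if (!is.null(pixels)) {
    tr <- tr[, pixels, drop = FALSE]
    coords <- coords[pixels, , drop = FALSE]
  }
  if (ncol(tr) < 2L)
    stop("pairwise_correlation(): need >= 2 pixels")
  if (!is.null(phase_mask)) {
    stopifnot(length(phase_mask) == nrow(tr))
    if (sum(phase_mask) < 10L)
      stop("pairwise_correlation(): phase mask keeps fewer than 10 frames")
    tr <- tr[phase_mask, , drop = FALSE]
  }
  v <- apply(tr, 2, stats::var)
  excluded <- which(v == 0)
  keep <- which(v > 0)
  if (length(keep) < 2L)
    stop("pairwise_correlation(): fewer than 2 pixels with variance in the ",
         "analyzed frames")
  r <- stats::cor(tr[, keep, drop = FALSE])
  r[r > 1] <- 1; r[r < -1] <- -1
  diag(r) <- 1
  structure(list(r = r, coords = coords[keep, , drop = FALSE],
                 pixel_index = keep,
                 mean_r = mean(r[upper.tri(r)]),
                 excluded = excluded, phase = phase,
                 n_frames = nrow(tr),
                 pixel_pitch_um = attr(pixel_traces, "pixel_pitch_um")),
            class = "synchrony_result")
}

#' @export
print.synchrony_result <- function(x, ...) {
  cat(sprintf("synchrony_result (%s): %d pixels, %d frames, mean r = %.4f\n",
              x$phase, nrow(x$r), x$n_frames, x$mean_r))
  invisible(x)
}

#' Correlation versus inter-pixel distance
#'
#' Pairs the correlation coefficients with the physical Euclidean distance
#' between pixel centers (pixel pitch times index difference) and bins them
#' into equal-width distance bins with mean and 95% confidence interval per
#' bin, visualizing how synchronization decays across the well surface.
#'
#' @param result a [pairwise_correlation()] result.
#' @param pixel_pitch_um physical pixel pitch, micrometers.
#' @param n_bins number of equal-width distance bins (default 10).
#' @return data frame `(bin_center_um, mean_r, ci_lo, ci_hi, n_pairs)`.
#' @export
correlation_vs_distance <- function(result, pixel_pitch_um = 284,
                                    n_bins = 10) {
  stopifnot(inherits(result, "synchrony_result"))
  co <- result$coords
  if (is.null(co) || !nrow(co))
    stop("correlation_vs_distance(): no pixel coordinates present")
  d <- as.matrix(stats::dist(co)) * pixel_pitch_um
  ut <- upper.tri(d)
  dd <- d[ut]; rr <- result$r[ut]
  if (length(unique(dd)) == 1L) {
    bins <- factor(rep(1, length(dd)))
    centers <- unique(dd)
  } else {
    breaks <- seq(min(dd), max(dd), length.out = n_bins + 1)
    bins <- cut(dd, breaks, include.lowest = TRUE)
    centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  }
  out <- do.call(rbind, lapply(seq_along(levels(bins)), function(i) {
    sel <- as.integer(bins) == i
    n <- sum(sel)
    if (!n) return(data.frame(bin_center_um = centers[i], mean_r = NA_real_,
                              ci_lo = NA_real_, ci_hi = NA_real_,
                              n_pairs = 0L))
    m <- mean(rr[sel])
    se <- if (n > 1) stats::sd(rr[sel]) / sqrt(n) else 0
    q <- if (n > 1) stats::qt(0.975, n - 1) else 0
    data.frame(bin_center_um = centers[i], mean_r = m,
               ci_lo = m - q * se, ci_hi = m + q * se, n_pairs = n)
  }))
  rownames(out) <- NULL
  out
}

#' Frame masks for IN and OUT recording phases
#'
#' Converts network-spike windows into complementary boolean frame masks: a
#' frame belongs to the IN phase when its midpoint time lies inside a (closed)
#' window, and to the OUT phase otherwise, so the two masks partition the
#' recording exactly.
#'
#' @param windows a [network_windows()] result.
#' @param n_frames number of frames in the recording.
#' @param frame_rate frames per second.
#' @return list with logical vectors `in_mask` and `out_mask` of length
#'   `n_frames`.
#' @export
phase_masks <- function(windows, n_frames, frame_rate) {
  mid <- (seq_len(n_frames) - 0.5) / frame_rate
  in_mask <- in_any_window(mid, windows)
  list(in_mask = in_mask, out_mask = !in_mask)
}

#' Display ordering for clustered correlation heatmaps
#'
#' Hierarchical ordering of the pixels by average-linkage clustering on the
#' `1 - r` distance, so that strongly correlated pixel communities appear as
#' contiguous blocks in a heatmap. Ties are broken deterministically by pixel
#' index (hclust on a fixed input is deterministic).
#'
#' @param r correlation matrix (symmetric, unit diagonal).
#' @return integer permutation of the pixel indices.
#' @export
cluster_order <- function(r) {
  stopifnot(is.matrix(r), nrow(r) == ncol(r))
  if (nrow(r) == 1L) return(1L)
  hc <- stats::hclust(stats::as.dist(1 - r), method = "average")
  hc$order
}
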