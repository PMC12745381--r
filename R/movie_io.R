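#' Plate movie container
#'
#' A grayscale frame stack from a kinetic plate reader together with its
#' acquisition metadata.
#'
#' @param frames numeric 3-D array `(time, y, x)` of non-negative intensities
#'   (a.u. counts).
#' @param frame_rate frames per second (> 0).
#' @param layout a [plate_layout()] describing the well grid on the image.
#' @param binning camera binning factor (metadata only).
#' @param start_time acquisition start, seconds.
#' @return object of class `lfca_movie`.
#' @export
lfca_movie <- function(frames, frame_rate, layout, binning = 1L,
                       start_time = 0) {
  if (length(dim(frames)) != 3L)
    stop("lfca_movie: frames must be a 3-D (time, y, x) array")
  if (dim(frames)[1] < 2L)
    stop("lfca_movie: time axis too short (need >= 2 frames)")
  if (!is.numeric(frame_rate) || frame_rate <= 0)
    stop("lfca_movie: frame_rate must be > 0")
  if (min(frames) < 0)
    stop("lfca_movie: negative intensities")
  stopifnot(inherits(layout, "plate_layout"))
  exp_dim <- c(layout$n_rows * layout$tile_shape[1],
               layout$n_cols * layout$tile_shape[2])
  if (!all(dim(frames)[2:3] == exp_dim))
    stop(sprintf(
      "lfca_movie: frame size %d x %d does not match layout (%d x %d)",
      dim(frames)[2], dim(frames)[3], exp_dim[1], exp_dim[2]))
  structure(list(frames = frames, frame_rate = frame_rate, layout = layout,
                 binning = as.integer(binning), start_time = start_time),
            class = "lfca_movie")
}

#' @export
print.lfca_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "lfca_movie: %d frames of %d x %d px at %g fps (%.1f s), binning %d\n",
    d[1], d[2], d[3], x$frame_rate, d[1] / x$frame_rate, x$binning))
  invisible(x)
}

#' Write / read a plate movie as multi-page TIFF
#'
#' Frames are stored as 16-bit grayscale TIFF pages (values must be integer
#' counts in `[0, 65535]`, as produced by [simulate_plate()] and by 16-bit
#' plate-reader detectors), so a write/load round trip is exact. Acquisition
#' metadata (frame rate, binning, start time) is written to a YAML sidecar
#' `<path>.yaml`; `load_movie()` reads it when present, otherwise the frame
#' rate must come from the caller.
#'
#' @param movie an [lfca_movie()].
#' @param path output TIFF path.
#' @return `write_movie()` returns `path` invisibly.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "lfca_movie"))
  fr <- movie$frames
  if (max(fr) > 65535 || any(fr != round(fr)))
    stop("write_movie(): frames must be integer counts in [0, 65535]")
  pages <- lapply(seq_len(dim(fr)[1]), function(i) fr[i, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "LZW")
  yaml::write_yaml(list(frame_rate = movie$frame_rate,
                        binning = movie$binning,
                        start_time = movie$start_time),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_movie
#' @param layout a [plate_layout()] matching the movie geometry.
#' @param frame_rate frames per second; overrides the sidecar when given,
#'   required when no sidecar exists.
#' @return `load_movie()` returns an `lfca_movie` with intensities as numeric
#'   counts.
#' @export
load_movie <- function(path, layout, frame_rate = NULL) {
  stopifnot(inherits(layout, "plate_layout"))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) < 2L)
    stop("load_movie(): time axis too short (need >= 2 frames)")
  meta <- list()
  sidecar <- paste0(path, ".yaml")
  if (file.exists(sidecar)) meta <- yaml::read_yaml(sidecar)
  if (is.null(frame_rate)) frame_rate <- meta$frame_rate
  if (is.null(frame_rate))
    stop("load_movie(): frame_rate missing; no metadata sidecar found and ",
         "none supplied")
  d <- dim(pages[[1]])
  frames <- array(0, dim = c(length(pages), d[1], d[2]))
  for (i in seq_along(pages)) frames[i, , ] <- round(pages[[i]] * 65535)
  lfca_movie(frames, frame_rate = frame_rate, layout = layout,
             binning = if (is.null(meta$binning)) 1L else meta$binning,
             start_time = if (is.null(meta$start_time)) 0 else
               meta$start_time)
}

#' Zone masks from pixel brightness
#'
#' For each well tile, the temporal mean brightness of every pixel is
#' clustered into three classes (1-D k-means with deterministic centers
#' initialized at the minimum, median and maximum brightness) and the classes
#' are mapped, by ascending center, to the `outside`, `border` and `growth`
#' zones of the well. Only growth pixels carry cells; the growth area of dry
#' wells is visible through plate autofluorescence, which is what makes the
#' same procedure work for the empty edge wells used for background
#' thresholds.
#'
#' @param movie an [lfca_movie()] spanning at least 10 frames.
#' @param layout optional [plate_layout()]; defaults to the movie's.
#' @return object of class `zone_mask`: list with `labels` (integer matrix of
#'   the full image, 1 = outside, 2 = border, 3 = growth),
#'   `growth_pixel_count` (named per well) and the layout.
#' @export
build_zone_mask <- function(movie, layout = NULL) {
  stopifnot(inherits(movie, "lfca_movie"))
  if (is.null(layout)) layout <- movie$layout
  if (dim(movie$frames)[1] < 10L)
    stop("build_zone_mask(): movie must span >= 10 frames")
  mean_img <- colMeans(movie$frames, dims = 1)
  ids <- well_ids(layout$n_rows, layout$n_cols)
  labels <- matrix(NA_integer_, nrow(mean_img), ncol(mean_img))
  counts <- stats::setNames(integer(length(ids)), ids)
  for (id in ids) {
    b <- tile_bounds(layout, id)
    ys <- (b$y0 + 1L):b$y1; xs <- (b$x0 + 1L):b$x1
    tilev <- mean_img[ys, xs]
    v <- as.vector(tilev)
    if (length(unique(v)) < 3L)
      stop(sprintf(paste0(
        "build_zone_mask(): degenerate mask in well %s: fewer than 3 ",
        "distinct brightness values"), id))
    km <- stats::kmeans(v, centers = gap_init_centers(v, 3L),
                        iter.max = 100L)
    ord <- order(km$centers)  # ascending: outside < border < growth
    zmap <- integer(3); zmap[ord] <- 1:3
    lab <- matrix(zmap[km$cluster], length(ys), length(xs))
    labels[ys, xs] <- lab
    counts[id] <- sum(lab == 3L)
  }
  structure(list(labels = labels, growth_pixel_count = counts,
                 layout = layout),
            class = "zone_mask")
}

#' @export
print.zone_mask <- function(x, ...) {
  cat(sprintf("zone_mask: %d wells, growth pixels per well %d-%d (median %g)\n",
              length(x$growth_pixel_count), min(x$growth_pixel_count),
              max(x$growth_pixel_count),
              stats::median(x$growth_pixel_count)))
  invisible(x)
}

#' Export a zone mask as a CSV of (well, row, col, zone)
#' @param mask a [build_zone_mask()] result.
#' @param path output CSV path.
#' @return `path`, invisibly. Coordinates are 0-based pixel indices on the
#'   full image; zones are `outside`, `border`, `growth`.
#' @export
write_zone_mask_csv <- function(mask, path) {
  layout <- mask$layout
  ids <- well_ids(layout$n_rows, layout$n_cols)
  rows <- lapply(ids, function(id) {
    b <- tile_bounds(layout, id)
    ys <- (b$y0 + 1L):b$y1; xs <- (b$x0 + 1L):b$x1
    lab <- mask$labels[ys, xs]
    idx <- which(!is.na(lab), arr.ind = TRUE)
    data.frame(well = id,
               row = b$y0 + idx[, 1] - 1L,
               col = b$x0 + idx[, 2] - 1L,
               zone = c("outside", "border", "growth")[lab[idx]])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

# Deterministic 1-D k-means initialization: split the sorted values at the
# k - 1 largest gaps (leftmost on ties) and take group means as centers.
# Brightness zones are near-plateaus, so the gap split lands each center on
# its plateau and the subsequent Lloyd iterations converge to the zone means;
# no random restarts, so masks are reproducible.
gap_init_centers <- function(v, k) {
  s <- sort(v)
  gaps <- diff(s)
  cut_at <- sort(order(gaps, decreasing = TRUE)[seq_len(k - 1L)])
  bounds <- c(0L, cut_at, length(s))
  centers <- vapply(seq_len(k), function(i)
    mean(s[(bounds[i] + 1L):bounds[i + 1L]]), numeric(1))
  matrix(centers)
}

#' @rdname write_zone_mask_csv
#' @details `write_zone_mask_png()` writes the labels as a grayscale image
#'   (outside dark, growth bright) for visual inspection.
#' @export
write_zone_mask_png <- function(mask, path) {
  png::writePNG(mask$labels / 3, path)
  invisible(path)
}

#' Apply a spatial-uniformity gain map
#'
#' Divides every frame by a per-pixel gain map (e.g. a flat-field or
#' spatial-uniformity calibration supplied with the instrument). The map is
#' user-provided; no correction is inferred from the data.
#'
#' @param movie an [lfca_movie()].
#' @param gain_map positive numeric matrix matching the frame size.
#' @return the corrected `lfca_movie`.
#' @export
apply_gain_map <- function(movie, gain_map) {
  stopifnot(inherits(movie, "lfca_movie"))
  if (!is.matrix(gain_map) || !all(dim(gain_map) == dim(movie$frames)[2:3]))
    stop("apply_gain_map(): gain map must match the frame size")
  if (any(gain_map <= 0))
    stop("apply_gain_map(): gain map must be strictly positive")
  movie$frames <- sweep(movie$frames, 2:3, gain_map, "/")
  movie
}

# Growth-pixel coordinates (full-image, 1-based) of one well.
growth_pixels <- function(mask, well) {
  b <- tile_bounds(mask$layout, well)
  ys <- (b$y0 + 1L):b$y1; xs <- (b$x0 + 1L):b$x1
  idx <- which(mask$labels[ys, xs] == 3L, arr.ind = TRUE)
  if (!nrow(idx)) return(idx)
  cbind(row = b$y0 + idx[, 1], col = b$x0 + idx[, 2])
}

#' Fluorescence trace
#'
#' A numeric intensity-versus-time vector with its frame rate, normalization
#' state and source (well id or pixel coordinate) attached.
#'
#' @param values numeric vector of intensities.
#' @param frame_rate frames per second.
#' @param normalization `"none"`, `"minmax"` or `"dFF0"`.
#' @param source well id or pixel coordinate label.
#' @param flag optional flag, e.g. `"zero_range"` for a constant pixel under
#'   min-max normalization.
#' @return object of class `lfca_trace` (a numeric vector with attributes).
#' @export
lfca_trace <- function(values, frame_rate, normalization = "none",
                       source = NA_character_, flag = NULL) {
  structure(as.numeric(values), frame_rate = frame_rate,
            normalization = normalization, source = source, flag = flag,
            class = "lfca_trace")
}

#' Well-average trace
#'
#' Mean intensity over the growth pixels of a well, per frame: the standard
#' plate-reader well signal in which synchronized network spikes are visible
#' and isolated local spikes average out.
#'
#' @param movie an [lfca_movie()].
#' @param mask a [build_zone_mask()] result.
#' @param well well id.
#' @return an [lfca_trace()] (normalization `"none"`).
#' @export
extract_well_trace <- function(movie, mask, well) {
  gp <- growth_pixels(mask, well)
  if (!nrow(gp))
    stop(sprintf("extract_well_trace(): well %s has no growth pixels", well))
  tr <- pixel_trace_matrix(movie, gp)
  lfca_trace(rowMeans(tr), movie$frame_rate, source = well)
}

#' Per-pixel traces of a well
#'
#' One trace per growth pixel. Under `normalization = "minmax"` each trace is
#' rescaled to `[0, 1]` over its own range, the bounded scale on which the
#' pixel-level prominence thresholds (0.4 detection, 0.1 sweep floor) are
#' defined; a zero-range pixel yields an all-zero trace flagged
#' `"zero_range"` rather than an error.
#'
#' @inheritParams extract_well_trace
#' @param normalization `"none"` or `"minmax"`.
#' @return object of class `pixel_traces`: list with `traces` (frames x pixels
#'   numeric matrix), `coords` (pixels x 2 matrix of 1-based full-image row,
#'   col), `frame_rate`, `normalization`, `flags` (character per pixel or NA)
#'   and `well`.
#' @export
extract_pixel_traces <- function(movie, mask, well, normalization = "none") {
  gp <- growth_pixels(mask, well)
  if (!nrow(gp))
    stop(sprintf("extract_pixel_traces(): well %s has no growth pixels",
                 well))
  normalization <- match.arg(normalization, c("none", "minmax"))
  tr <- pixel_trace_matrix(movie, gp)
  flags <- rep(NA_character_, ncol(tr))
  if (normalization == "minmax") {
    rng <- apply(tr, 2, range)
    span <- rng[2, ] - rng[1, ]
    zero <- span == 0
    span[zero] <- 1
    tr <- sweep(sweep(tr, 2, rng[1, ]), 2, span, "/")
    tr[, zero] <- 0
    flags[zero] <- "zero_range"
  }
  structure(list(traces = tr, coords = gp, frame_rate = movie$frame_rate,
                 normalization = normalization, flags = flags, well = well),
            class = "pixel_traces")
}

# frames x pixels matrix for given full-image (row, col) coordinates.
pixel_trace_matrix <- function(movie, coords) {
  n_frames <- dim(movie$frames)[1]
  out <- matrix(0, n_frames, nrow(coords))
  for (j in seq_len(nrow(coords)))
    out[, j] <- movie$frames[, coords[j, 1], coords[j, 2]]
  out
}

#' @export
print.pixel_traces <- function(x, ...) {
  cat(sprintf("pixel_traces: well %s, %d pixels x %d frames (%s)\n",
              x$well, ncol(x$traces), nrow(x$traces), x$normalization))
  invisible(x)
}
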