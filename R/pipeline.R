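#' Pipeline run configuration
#'
#' Validated bundle of the analysis constants used along the full pipeline:
#' the network threshold policy (`"auto"` = derive from empty wells, or an
#' explicit prominence), the local-field detection prominence (0.4 on the
#' normalized scale), the threshold-sweep floor (0.1) and step (0.01), the
#' top-N active-pixel policy, and the compound-addition time if any.
#'
#' @param network_threshold `"auto"` or a positive prominence in trace units.
#' @param pixel_prominence local-field detection threshold, in `(0, 1]`.
#' @param sweep_floor,sweep_step threshold-sweep grid on the normalized scale;
#'   `sweep_floor < 1`.
#' @param top_n `"auto"` (400 for 96-well, 130 for 384-well) or an integer.
#' @param addition_time compound-addition time (s) or `NA`.
#' @param seed integer seed recorded in the run metadata.
#' @return object of class `run_config`.
#' @export
run_config <- function(network_threshold = "auto",
                       pixel_prominence = 0.4,
                       sweep_floor = 0.1, sweep_step = 0.01,
                       top_n = "auto",
                       addition_time = NA_real_,
                       seed = 1L) {
  if (!(identical(network_threshold, "auto") ||
        (is.numeric(network_threshold) && network_threshold > 0)))
    stop("run_config: network_threshold must be \"auto\" or a positive number")
  if (!(pixel_prominence > 0 && pixel_prominence <= 1))
    stop("run_config: pixel_prominence must lie in (0, 1]")
  if (!(sweep_floor > 0 && sweep_floor < 1))
    stop("run_config: sweep_floor must lie in (0, 1)")
  if (!(sweep_step > 0 && sweep_step <= 1 - sweep_floor))
    stop("run_config: invalid sweep_step")
  if (!(identical(top_n, "auto") || (is.numeric(top_n) && top_n >= 1)))
    stop("run_config: top_n must be \"auto\" or a positive integer")
  structure(list(network_threshold = network_threshold,
                 pixel_prominence = pixel_prominence,
                 sweep_floor = sweep_floor, sweep_step = sweep_step,
                 top_n = top_n, addition_time = addition_time,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with any subset of the [run_config()] fields.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop("read_run_config(): configuration file not found: ", path)
  y <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop("read_run_config(): unknown fields: ", paste(unknown, collapse = ", "))
  do.call(run_config, y)
}

#' Run the full analysis pipeline on a plate movie
#'
#' Executes all stages in order on one movie: zone-mask construction,
#' well-level network-spike analysis (frequency, amplitude, FWHM; drug
#' response when an addition time is configured), pixel-level local-field
#' analysis on the top-N active pixels (spike table, IN/OUT classification,
#' threshold sweep), phase-restricted synchrony, and report rendering.
#'
#' @param movie an [lfca_movie()] (use [load_movie()] for files).
#' @param config a [run_config()].
#' @param out_dir output directory for the report files.
#' @param wells wells to analyze; default: all wells not listed as empty.
#' @return list with all stage results (`mask`, `threshold`, `well_summary`,
#'   `local_field_summary`, `sweeps`, `synchrony`, `files`), invisibly.
#' @export
run_pipeline <- function(movie, config = run_config(), out_dir, wells = NULL) {
  stopifnot(inherits(movie, "lfca_movie"), inherits(config, "run_config"))
  layout <- movie$layout
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  mask <- stage("zone_mask", build_zone_mask(movie))
  if (is.null(wells)) {
    ids <- well_ids(layout$n_rows, layout$n_cols)
    wells <- setdiff(ids, layout$empty_wells)
  }
  thr <- if (identical(config$network_threshold, "auto"))
    stage("global_threshold", global_threshold(movie, mask, layout)$threshold)
  else config$network_threshold

  top_n <- if (identical(config$top_n, "auto"))
    default_top_n(layout$plate_format) else as.integer(config$top_n)
  sweep_grid <- seq(config$sweep_floor, 1, by = config$sweep_step)

  well_rows <- list(); lf_rows <- list(); sweeps <- list(); sync <- list()
  for (w in wells) {
    wt <- stage("well_trace", extract_well_trace(movie, mask, w))
    ss <- stage("network_spikes", detect_spikes(wt, thr))
    row <- data.frame(well = w, n_spikes = nrow(ss),
                      freq_per_min = spike_frequency(ss),
                      mean_amplitude = as.numeric(mean_spike_amplitude(ss)),
                      mean_fwhm = if (nrow(ss)) mean(ss$fwhm) else NA_real_)
    if (!is.na(config$addition_time)) {
      dr <- stage("drug_response",
                  drug_response(wt, config$addition_time, thr))
      row$baseline_freq <- dr$baseline$frequency
      row$post_freq <- dr$post$frequency
      row$frequency_ratio <- dr$frequency_ratio
      row$amplitude_ratio <- dr$amplitude_ratio
    }
    well_rows[[w]] <- row

    pt <- stage("pixel_traces",
                extract_pixel_traces(movie, mask, w, "minmax"))
    rk <- stage("pixel_ranking",
                rank_active_pixels(pt, config$pixel_prominence, top_n))
    sel <- rk$pixel[rk$selected]
    tab <- stage("pixel_spikes",
                 detect_pixel_spikes(pt, config$pixel_prominence,
                                     pixels = sel))
    win <- network_windows(ss)
    tab <- classify_in_out(tab, win)
    lf_rows[[w]] <- summarize_local_fields(tab, selection = sel)
    sweeps[[w]] <- stage("threshold_sweep",
                         threshold_sweep(pt, win, thresholds = sweep_grid,
                                         pixels = sel))
    masks <- phase_masks(win, nrow(pt$traces), pt$frame_rate)
    sync[[w]] <- stage("synchrony", list(
      full = pairwise_correlation(pt, pixels = sel, phase = "full"),
      in_phases = try_or_null(
        pairwise_correlation(pt, masks$in_mask, pixels = sel,
                             phase = "in_phases")),
      out_phases = try_or_null(
        pairwise_correlation(pt, masks$out_mask, pixels = sel,
                             phase = "out_phases"))))
  }
  well_summary <- do.call(rbind, well_rows)
  local_field_summary <- do.call(rbind, lf_rows)
  rownames(well_summary) <- rownames(local_field_summary) <- NULL

  first <- wells[1]
  dcurve <- try_or_null(correlation_vs_distance(
    sync[[first]]$full, pixel_pitch_um = layout$pixel_pitch_um))
  files <- stage("report", render_report(
    list(well_summary = well_summary,
         local_field_summary = local_field_summary,
         sweep = sweeps[[first]],
         distance_curve = dcurve),
    out_dir,
    metadata = list(seed = config$seed, network_threshold = thr,
                    pixel_prominence = config$pixel_prominence,
                    sweep_floor = config$sweep_floor,
                    sweep_step = config$sweep_step, top_n = top_n,
                    wells = wells)))
  invisible(list(mask = mask, threshold = thr, well_summary = well_summary,
                 local_field_summary = local_field_summary, sweeps = sweeps,
                 synchrony = sync, files = files))
}

try_or_null <- function(expr) {
  tryCatch(expr, error = function(e) NULL)
}
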