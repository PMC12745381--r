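#' Two-group comparison with fold difference
#'
#' Student t-test between two groups of a metric table, unpaired for
#' across-well comparisons or paired (matched by well id) for within-well
#' comparisons such as drug treatment versus baseline. The fold difference is
#' `mean(group B) / mean(group A)`, with group A the reference (control).
#'
#' @param table data frame with columns `well`, `group`, `value` (optionally
#'   `metric`).
#' @param metric metric name to filter on when a `metric` column is present.
#' @param groups character vector of two group labels, reference first.
#' @param paired match observations by `well` and use a paired t-test.
#' @param var_equal use the pooled-variance t-test (default TRUE, the
#'   classical Student test).
#' @return list with `t`, `df`, `p`, per-group `mean` and `sd`, `n`, and
#'   `fold_difference` (mean B / mean A).
#' @export
compare_two_groups <- function(table, metric = NULL, groups, paired = FALSE,
                               var_equal = TRUE) {
  stopifnot(length(groups) == 2L)
  if (!is.null(metric) && "metric" %in% names(table))
    table <- table[table$metric == metric, , drop = FALSE]
  a <- table[table$group == groups[1], , drop = FALSE]
  b <- table[table$group == groups[2], , drop = FALSE]
  if (nrow(a) < 2L || nrow(b) < 2L)
    stop("compare_two_groups(): need >= 2 values per group")
  if (paired) {
    common <- intersect(a$well, b$well)
    if (length(common) < 2L)
      stop("compare_two_groups(): paired comparison needs >= 2 matched wells")
    va <- a$value[match(common, a$well)]
    vb <- b$value[match(common, b$well)]
    ht <- stats::t.test(vb, va, paired = TRUE)
  } else {
    va <- a$value; vb <- b$value
    ht <- stats::t.test(vb, va, var.equal = var_equal)
  }
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value,
       mean = stats::setNames(c(mean(va), mean(vb)), groups),
       sd = stats::setNames(c(stats::sd(va), stats::sd(vb)), groups),
       n = stats::setNames(c(length(va), length(vb)), groups),
       fold_difference = mean(vb) / mean(va),
       paired = paired)
}

#' Two-way ANOVA with Tukey post-hoc comparisons
#'
#' Fits `value ~ factorA * factorB` and reports type-II sums of squares for
#' the main effects and interaction (via [car::Anova()]; on balanced designs
#' type I and II coincide), plus Tukey HSD pairwise comparisons. For families
#' of separate t-tests use [stats::p.adjust()]`(method = "bonferroni")` on the
#' collected p-values.
#'
#' @param table data frame with the metric values and both factor columns.
#' @param metric optional metric name to filter on (column `metric`).
#' @param factorA,factorB names of the two factor columns.
#' @param value name of the value column (default `"value"`).
#' @return list with `anova` (data frame: term, sum_sq, df, F, p), `tukey`
#'   (the [stats::TukeyHSD()] result) and the fitted `lm` model.
#' @export
two_way_anova <- function(table, metric = NULL, factorA, factorB,
                          value = "value") {
  if (!is.null(metric) && "metric" %in% names(table))
    table <- table[table$metric == metric, , drop = FALSE]
  d <- data.frame(value = table[[value]],
                  A = factor(table[[factorA]]),
                  B = factor(table[[factorB]]))
  if (nlevels(d$A) < 2L || nlevels(d$B) < 2L)
    stop("two_way_anova(): each factor needs >= 2 levels")
  cells <- table(d$A, d$B)
  if (any(cells == 0)) {
    bad <- which(cells == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("two_way_anova(): empty design cell %s x %s",
                 levels(d$A)[bad[1]], levels(d$B)[bad[2]]))
  }
  if (any(cells < 2))
    stop("two_way_anova(): need >= 2 replicates per design cell")
  fit <- stats::lm(value ~ A * B, data = d)
  a2 <- car::Anova(fit, type = "II")
  terms <- rownames(a2)
  terms <- sub("^A:B$", paste(factorA, factorB, sep = ":"), terms)
  terms <- sub("^A$", factorA, terms)
  terms <- sub("^B$", factorB, terms)
  tab <- data.frame(term = terms,
                    sum_sq = a2[["Sum Sq"]],
                    df = a2[["Df"]],
                    F = a2[["F value"]],
                    p = a2[["Pr(>F)"]],
                    row.names = NULL)
  aovfit <- stats::aov(value ~ A * B, data = d)
  list(anova = tab, tukey = stats::TukeyHSD(aovfit), model = fit)
}

#' Write analysis reports
#'
#' Writes the standard artifact set of a pipeline run into a directory:
#' summary tables as CSV, figures (normalized pixel heatmap, threshold-sweep
#' curves, correlation-versus-distance curves, box plots with overlaid
#' points), and a run-metadata JSON (package version, seed, thresholds).
#' Components that are `NULL` are reported as explicit "no data" placeholders
#' rather than dropped silently. CSV output is deterministic for identical
#' inputs.
#'
#' @param results named list; recognized elements: `well_summary`,
#'   `local_field_summary` (data frames), `sweep` (a [threshold_sweep()]),
#'   `distance_curve` (a [correlation_vs_distance()] data frame),
#'   `pixel_traces` (an [extract_pixel_traces()] result, for the heatmap),
#'   `metrics` (long data frame `well, group, metric, value` for box plots).
#' @param outputs_dir target directory (created if needed).
#' @param metadata named list merged into the run-metadata JSON (seeds,
#'   thresholds, input paths).
#' @return character vector of the files written, invisibly.
#' @export
render_report <- function(results, outputs_dir, metadata = list()) {
  ok <- dir.create(outputs_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outputs_dir))
    stop("render_report(): cannot create output directory ", outputs_dir)
  written <- character(0)
  put_csv <- function(df, name) {
    f <- file.path(outputs_dir, name)
    if (is.null(df)) {
      writeLines("no data", f)
    } else {
      utils::write.csv(df, f, row.names = FALSE)
    }
    written <<- c(written, f)
  }
  put_csv(results$well_summary, "well_summary.csv")
  put_csv(results$local_field_summary, "local_field_summary.csv")
  put_csv(results$sweep, "threshold_sweep.csv")
  put_csv(results$distance_curve, "correlation_vs_distance.csv")

  put_png <- function(plot_fun, name, width = 900, height = 600) {
    f <- file.path(outputs_dir, name)
    grDevices::png(f, width = width, height = height)
    on.exit(grDevices::dev.off(), add = TRUE)
    plot_fun()
    written <<- c(written, f)
  }
  if (!is.null(results$pixel_traces)) {
    pt <- results$pixel_traces
    put_png(function() {
      m <- t(pt$traces)  # pixels x time
      graphics::image(x = seq_len(ncol(m)) / pt$frame_rate,
                      y = seq_len(nrow(m)), z = t(m),
                      col = grDevices::hcl.colors(64, "inferno"),
                      xlab = "time (s)", ylab = "pixel",
                      main = sprintf("well %s: normalized pixel activity",
                                     pt$well))
    }, "pixel_heatmap.png")
  }
  if (!is.null(results$sweep)) {
    sw <- results$sweep
    put_png(function() {
      p <- ggplot2::ggplot(sw, ggplot2::aes(
        x = .data$threshold, y = .data$fraction, colour = .data$class)) +
        ggplot2::geom_line() +
        ggplot2::labs(x = "prominence threshold",
                      y = "fraction of spikes retained")
      print(p)
    }, "threshold_sweep.png")
  }
  if (!is.null(results$distance_curve)) {
    dc <- results$distance_curve
    put_png(function() {
      p <- ggplot2::ggplot(dc, ggplot2::aes(
        x = .data$bin_center_um, y = .data$mean_r)) +
        ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lo,
                                          ymax = .data$ci_hi), alpha = 0.3) +
        ggplot2::geom_line() +
        ggplot2::labs(x = "inter-pixel distance (um)", y = "mean Pearson r")
      print(p)
    }, "correlation_vs_distance.png")
  }
  if (!is.null(results$metrics)) {
    mt <- results$metrics
    put_png(function() {
      p <- ggplot2::ggplot(mt, ggplot2::aes(
        x = .data$group, y = .data$value)) +
        ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey85") +
        ggplot2::geom_jitter(width = 0.15, size = 1) +
        ggplot2::facet_wrap(~metric, scales = "free_y") +
        ggplot2::labs(x = NULL, y = NULL)
      print(p)
    }, "metrics_boxplots.png")
  }

  meta <- c(list(package = "lfca",
                 version = as.character(utils::packageVersion("lfca")),
                 r_version = paste(R.version$major, R.version$minor,
                                   sep = "."),
                 timestamp = NULL),
            metadata)
  meta$timestamp <- NULL  # keep metadata deterministic for identical runs
  f <- file.path(outputs_dir, "run_metadata.json")
  jsonlite::write_json(meta, f, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  written <- c(written, f)
  invisible(written)
}
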