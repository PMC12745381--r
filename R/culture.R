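#' Survival percentage from nuclei counts
#'
#' Endpoint cell survival of one cell type:
#' `100 * density * well_area / seeded`, where `density` is the final nuclear
#' density of that type (nuclei/mm^2), `well_area` the culture surface of the
#' well (mm^2; 10.6276 mm^2 for a standard 384-well plate) and `seeded` the
#' number of cells originally plated.
#'
#' @param density final nuclei density, nuclei/mm^2 (>= 0).
#' @param well_area well culture area, mm^2 (> 0).
#' @param seeded number of seeded cells (> 0).
#' @return percentage (vectorized over inputs).
#' @export
survival_percent <- function(density, well_area, seeded) {
  if (any(density < 0)) stop("survival_percent(): density must be >= 0")
  if (any(well_area <= 0)) stop("survival_percent(): well_area must be > 0")
  if (any(seeded <= 0)) stop("survival_percent(): seeded must be > 0")
  100 * density * well_area / seeded
}

#' Neuron-to-astrocyte ratio
#'
#' @param neuron_density,astro_density nuclei/mm^2; `astro_density` must be
#'   positive.
#' @return dimensionless iN/pA ratio (vectorized). Note that the ratio of two
#'   group means differs from the mean of per-well ratios; compute the latter
#'   by applying this function per well before averaging.
#' @export
cell_type_ratio <- function(neuron_density, astro_density) {
  if (any(astro_density <= 0))
    stop("cell_type_ratio(): astro_density must be > 0")
  neuron_density / astro_density
}

#' Total survival rate
#'
#' Total endpoint cell number relative to total seeded cells:
#' `(neuron_density + astro_density) * well_area /
#' (seeded_neurons + seeded_astros)`.
#'
#' @param neuron_density,astro_density endpoint nuclei densities, nuclei/mm^2.
#' @param well_area culture area, mm^2.
#' @param seeded_neurons,seeded_astros seeded cell numbers (sum > 0).
#' @return fraction (1 = all seeded cells present at endpoint; values above 1
#'   indicate proliferation).
#' @export
total_survival_rate <- function(neuron_density, astro_density, well_area,
                                seeded_neurons, seeded_astros) {
  if (any(seeded_neurons + seeded_astros <= 0))
    stop("total_survival_rate(): total seeded cells must be > 0")
  if (any(well_area <= 0)) stop("total_survival_rate(): well_area must be > 0")
  (neuron_density + astro_density) * well_area /
    (seeded_neurons + seeded_astros)
}

#' Cells covered per pixel
#'
#' Number of cells of a given type under one camera pixel:
#' `density (/mm^2) * pixel_area (um^2) * 1e-6`. At the 96-well
#' pixel-resolution setting (about 400 growth pixels per well) the pixel area
#' is about 80,425 um^2 (~284 x 284 um).
#'
#' @param density nuclei/mm^2.
#' @param pixel_area_um2 area of one pixel, um^2 (> 0).
#' @param round_to_integer round the result to whole cells.
#' @return cells per pixel (vectorized).
#' @export
cells_per_pixel <- function(density, pixel_area_um2, round_to_integer = FALSE) {
  if (any(pixel_area_um2 <= 0))
    stop("cells_per_pixel(): pixel_area_um2 must be > 0")
  out <- density * pixel_area_um2 * 1e-6
  if (round_to_integer) round(out) else out
}

#' Per-well culture metrics from a nuclei-count table
#'
#' Applies the survival, ratio and total-survival arithmetic to a table of
#' per-well nuclei counts (one row per well).
#'
#' @param counts data frame with columns `well`, `group`, `neuron_density`,
#'   `astro_density`, `well_area`, `seeded_neurons`, `seeded_astros`.
#' @return the table with added columns `neuron_survival_pct`,
#'   `astro_survival_pct`, `in_pa_ratio`, `total_survival`.
#' @export
culture_metrics_table <- function(counts) {
  need <- c("well", "neuron_density", "astro_density", "well_area",
            "seeded_neurons", "seeded_astros")
  miss <- setdiff(need, names(counts))
  if (length(miss))
    stop("culture_metrics_table(): missing columns: ",
         paste(miss, collapse = ", "))
  counts$neuron_survival_pct <- survival_percent(
    counts$neuron_density, counts$well_area, counts$seeded_neurons)
  counts$astro_survival_pct <- survival_percent(
    counts$astro_density, counts$well_area, counts$seeded_astros)
  counts$in_pa_ratio <- cell_type_ratio(counts$neuron_density,
                                        counts$astro_density)
  counts$total_survival <- total_survival_rate(
    counts$neuron_density, counts$astro_density, counts$well_area,
    counts$seeded_neurons, counts$seeded_astros)
  counts
}

#' Jensen-Shannon marker specificity
#'
#' Scores how specifically a gene marks a target cluster: the gene's mean
#' expression across clusters is normalized to a probability distribution and
#' compared, by Jensen-Shannon divergence, with the distribution of a
#' hypothetical perfectly specific gene (all mass on the target cluster). The
#' base-2 logarithm bounds the divergence by 1, so the reported specificity
#' `1 - JSD` is 1 for a perfectly specific gene and 0 for a gene exclusive to
#' other clusters.
#'
#' @param profile numeric matrix of mean expression, genes x clusters
#'   (non-negative), with row and column names.
#' @param gene gene (row) name.
#' @param target_cluster cluster (column) name.
#' @return list with `jsd` (bits, in `[0, 1]`) and `specificity` (`1 - jsd`).
#' @export
marker_specificity_jsd <- function(profile, gene, target_cluster) {
  stopifnot(is.matrix(profile))
  if (ncol(profile) < 2L)
    stop("marker_specificity_jsd(): need >= 2 clusters")
  if (!gene %in% rownames(profile))
    stop("marker_specificity_jsd(): unknown gene: ", gene)
  if (!target_cluster %in% colnames(profile))
    stop("marker_specificity_jsd(): unknown cluster: ", target_cluster)
  p <- profile[gene, ]
  if (any(p < 0)) stop("marker_specificity_jsd(): negative expression")
  tot <- sum(p)
  if (tot <= 0)
    stop("marker_specificity_jsd(): gene has zero total expression")
  p <- p / tot
  q <- stats::setNames(numeric(ncol(profile)), colnames(profile))
  q[target_cluster] <- 1
  jsd <- js_divergence(p, q)
  list(jsd = jsd, specificity = 1 - jsd)
}

#' Jensen-Shannon divergence (base 2)
#'
#' `JSD(p, q) = (KL(p || m) + KL(q || m)) / 2` with `m = (p + q) / 2` and
#' base-2 logarithms, so the result lies in `[0, 1]`; zero-probability terms
#' contribute nothing (`0 log 0 = 0`).
#'
#' @param p,q probability vectors of equal length (each summing to 1).
#' @return divergence in bits.
#' @export
js_divergence <- function(p, q) {
  stopifnot(length(p) == length(q))
  if (any(p < 0) || any(q < 0)) stop("js_divergence(): negative probabilities")
  if (abs(sum(p) - 1) > 1e-8 || abs(sum(q) - 1) > 1e-8)
    stop("js_divergence(): inputs must sum to 1")
  m <- (p + q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log2(a[nz] / b[nz]))
  }
  (kl(p, m) + kl(q, m)) / 2
}
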