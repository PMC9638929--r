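#' Per-gene translation states from footprint and RNA-Seq counts
#'
#' Converts a per-gene count table into absolute per-cell quantities.
#' RNA counts are length-normalised to reads per kilobase (RPK) and the
#' RPK shares scaled to the total cellular mRNA copy number; footprint
#' count shares are scaled to the number of actively translating
#' ribosomes (`total_ribosomes * active_fraction`).  The average
#' ribosome density of a gene is its bound ribosomes divided by its
#' transcript copies.
#'
#' Genes with zero RNA count cannot be assigned a density; they are
#' excluded and reported in the `excluded_genes` attribute, together
#' with the fraction of footprint reads they carried
#' (`excluded_fp_fraction`).  Densities exceeding the physical packing
#' limit of one ribosome per 10 codons (`length_nt / 30`) are not
#' truncated; their prevalence is reported as the `over_cap_fraction`
#' attribute, a useful dataset-integrity metric.
#'
#' @param counts Data frame with columns `gene_id`, `length_nt`,
#'   `fp_count`, `rna_count` (see [read_counts()]).
#' @param params A [cell_params()] object.
#' @return Data frame with columns `gene_id`, `length_nt`, `rna_copies`,
#'   `ribosomes_bound`, `density`, with QC attributes as described.
#' @export
compute_states <- function(counts, params) {
  counts <- validate_counts(counts)
  if (!inherits(params, "cell_params"))
    pp_stop_invalid("params must be a cell_params object")
  keep <- counts$rna_count > 0
  excluded <- counts$gene_id[!keep]
  total_fp <- sum(counts$fp_count)
  excluded_fp_fraction <-
    if (total_fp > 0) sum(counts$fp_count[!keep]) / total_fp else 0
  cc <- counts[keep, , drop = FALSE]
  rpk <- cc$rna_count / (cc$length_nt / 1000)
  sum_rpk <- sum(rpk)
  sum_fp <- sum(cc$fp_count)
  if (sum_rpk <= 0)
    pp_stop_degenerate("all RNA counts are zero; cannot compute states")
  if (sum_fp <= 0)
    pp_stop_degenerate("all footprint counts are zero; cannot compute states")
  rna_copies <- rpk / sum_rpk * params$total_mrna
  ribosomes_bound <- cc$fp_count / sum_fp *
    params$total_ribosomes * params$active_fraction
  density <- ribosomes_bound / rna_copies
  out <- data.frame(gene_id = cc$gene_id, length_nt = cc$length_nt,
                    rna_copies = rna_copies,
                    ribosomes_bound = ribosomes_bound,
                    density = density,
                    stringsAsFactors = FALSE)
  attr(out, "excluded_genes") <- as.character(excluded)
  attr(out, "excluded_fp_fraction") <- excluded_fp_fraction
  attr(out, "over_cap_fraction") <- mean(density > cc$length_nt / 30)
  out
}

#' Assign per-gene ribosomes to polysome peaks
#'
#' A gene with average ribosome density `d` contributes its bound
#' ribosomes to the two peaks whose integer indices straddle `d`: with
#' `f = d - floor(d)`, a share `1 - f` of the ribosomes goes to peak
#' `floor(d)` and a share `f` to peak `ceiling(d)` (an integer density
#' puts everything on that one peak).  For example, a transcript at 10
#' RNA copies carrying 5.8 ribosomes on average (58 in total) places
#' 11.6 ribosomes on the 5-some peak and 46.4 on the 6-some peak.
#'
#' Densities below one assign part of the ribosome mass to "peak 0",
#' i.e. to transcript copies carrying no ribosome; that mass is recorded
#' (it balances the ribosome books) but is invisible in a gradient and
#' contributes nothing to the rendered profile.  Mass that would land on
#' peaks above `n_max` is pooled into peak `n_max`, with the pooled
#' amount reported in the `pooled_mass` attribute.
#'
#' @param states Output of [compute_states()], or any data frame with
#'   columns `ribosomes_bound` and `density`.
#' @param n_max Highest modelled peak index (default 20).
#' @return Named numeric vector of unnormalised ribosome masses for peak
#'   indices `"0"` to `"n_max"`, with attribute `pooled_mass`.
#' @export
assign_to_peaks <- function(states, n_max = 20) {
  d <- states$density
  R <- states$ribosomes_bound
  if (is.null(d) || is.null(R))
    pp_stop_invalid("states must have columns density and ribosomes_bound")
  if (any(!is.finite(d)) || any(d < 0))
    pp_stop_invalid("densities must be finite and non-negative")
  if (n_max < 1) pp_stop_invalid("n_max must be at least 1")
  lo <- floor(d)
  f <- d - lo
  hi <- lo + 1
  m_lo <- R * (1 - f)
  m_hi <- R * f
  pooled <- sum(m_lo[lo > n_max]) + sum(m_hi[hi > n_max])
  tgt <- c(pmin(lo, n_max), pmin(hi, n_max))
  m <- c(m_lo, m_hi)
  masses <- stats::setNames(numeric(n_max + 1), as.character(0:n_max))
  agg <- rowsum(m, tgt)
  masses[rownames(agg)] <- agg[, 1]
  attr(masses, "pooled_mass") <- pooled
  masses
}

#' Complete a modelled profile with inactive ribosomes
#'
#' Ribo-Seq only sees translating ribosomes, so the free-subunit peaks
#' and part of the monosome peak of a real gradient are missing from the
#' n-some masses.  When `include_idle` is `TRUE`, the inactive ribosome
#' pool (`total_ribosomes * (1 - active_fraction)`) is added: a
#' `split_fraction` share is dissociated into subunits and contributes
#' to the 40S and 60S peaks in proportion to subunit mass, and the
#' remainder sediments as idle 80S monosomes.  The completed masses are
#' then normalised to a peak-volume vector summing to 1.  When
#' `include_idle` is `FALSE` (appropriate when the inactive proportion
#' is unknown, e.g. under stress conditions), only the n-some masses are
#' normalised and the subunit entries are zero.
#'
#' @param nsome_masses Output of [assign_to_peaks()].
#' @param params A [cell_params()] object.
#' @param include_idle Whether to add the inactive-ribosome peaks.
#' @return Named peak-volume vector over `"40S"`, `"60S"`, `"1"` ...
#'   `"n_max"`, summing to 1.
#' @export
add_inactive <- function(nsome_masses, params, include_idle = TRUE) {
  if (!inherits(params, "cell_params"))
    pp_stop_invalid("params must be a cell_params object")
  labels <- names(nsome_masses)
  if (is.null(labels))
    pp_stop_invalid("nsome_masses must be named by peak index")
  ns <- nsome_masses[labels != "0"]
  v <- c("40S" = 0, "60S" = 0)
  v[names(ns)] <- as.numeric(ns)
  if (include_idle) {
    inactive <- params$total_ribosomes * (1 - params$active_fraction)
    v["40S"] <- v["40S"] +
      inactive * params$split_fraction * params$small_subunit_fraction
    v["60S"] <- v["60S"] +
      inactive * params$split_fraction * (1 - params$small_subunit_fraction)
    if (!"1" %in% names(v))
      pp_stop_invalid("nsome_masses must include the monosome peak (index 1)")
    v["1"] <- v["1"] + inactive * (1 - params$split_fraction)
  }
  tot <- sum(v)
  if (tot <= 0)
    pp_stop_degenerate("no ribosome mass to normalise; profile is degenerate")
  v / tot
}

#' Render a peak-volume vector as a continuous profile trace
#'
#' Places one Gaussian per peak at the position predicted by the
#' location model, with standard deviation `width_factor` times the
#' local inter-peak spacing, scaled by the peak volume, and samples the
#' sum on a regular grid spanning all peaks plus four standard
#' deviations on each side.  The rendered curve integrates to the total
#' rendered volume (1 for a full normalised vector).
#'
#' @param volumes Named peak-volume vector.
#' @param location_model A [fit_location_model()] result (or any
#'   `peak_location_model`).
#' @param width_factor Peak width as a fraction of local spacing
#'   (default 0.25).
#' @param n_grid Number of grid samples (default 1000).
#' @param small_subunit_fraction Mass fraction used for the fractional
#'   subunit indices (default yeast, 0.35).
#' @return A [profile_trace()] with the generating [profile_model()]
#'   attached as attribute `model`.
#' @export
render_modelled_profile <- function(volumes, location_model,
                                    width_factor = 0.25, n_grid = 1000,
                                    small_subunit_fraction = 0.35) {
  labels <- names(volumes)
  if (is.null(labels)) pp_stop_invalid("volumes must be named by peak label")
  keep <- volumes > 0
  if (!any(keep)) pp_stop_degenerate("all peak volumes are zero")
  v <- volumes[keep]
  idx <- peak_index_value(names(v), small_subunit_fraction)
  mu <- predict_positions(location_model, idx)
  ord <- order(mu)
  v <- v[ord]; mu <- mu[ord]
  sigma <- width_factor * local_spacing(mu)
  grid <- seq(min(mu - 4 * sigma), max(mu + 4 * sigma),
              length.out = max(n_grid, 20))
  y <- numeric(length(grid))
  for (i in seq_along(mu)) y <- y + v[i] * stats::dnorm(grid, mu[i], sigma[i])
  tr <- profile_trace(grid, y)
  attr(tr, "model") <- profile_model(
    data.frame(label = names(v), mu = mu, sigma = sigma, s = as.numeric(v)))
  tr
}

#' Model a polysome profile from a count table
#'
#' Convenience wrapper running the full modelling chain
#' [compute_states()] -> [assign_to_peaks()] -> [add_inactive()].
#'
#' @inheritParams compute_states
#' @inheritParams assign_to_peaks
#' @inheritParams add_inactive
#' @return Normalised peak-volume vector with QC attributes
#'   `excluded_genes`, `excluded_fp_fraction`, `over_cap_fraction` and
#'   `pooled_mass` carried over from the stages.
#' @examples
#' counts <- data.frame(gene_id = c("a", "b"), length_nt = c(900, 1500),
#'                      fp_count = c(300, 700), rna_count = c(40, 60))
#' model_polysome(counts, cell_params("yeast"))
#' @export
model_polysome <- function(counts, params, include_idle = TRUE, n_max = 20) {
  states <- compute_states(counts, params)
  masses <- assign_to_peaks(states, n_max = n_max)
  vol <- add_inactive(masses, params, include_idle = include_idle)
  attr(vol, "excluded_genes") <- attr(states, "excluded_genes")
  attr(vol, "excluded_fp_fraction") <- attr(states, "excluded_fp_fraction")
  attr(vol, "over_cap_fraction") <- attr(states, "over_cap_fraction")
  attr(vol, "pooled_mass") <- attr(masses, "pooled_mass")
  vol
}
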