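#' Specification for synthetic polysome fixtures
#'
#' Collects every knob of the synthetic-data generator in one validated
#' object, so that a fixture is fully reproducible from (spec, seed)
#' alone.  Defaults emulate a fast-growing yeast culture: per-gene
#' ribosome densities are log-normal with median 2 ribosomes/transcript
#' and log-sd 0.6 (profile mass peaking around the tri-some), transcript
#' lengths log-normal around 1.5 kb, and expression levels log-normal
#' with log-sd 1.  Densities are capped at the physical packing limit of
#' one ribosome per 10 codons (`length_nt / 30`).
#'
#' @param seed Integer RNG seed.
#' @param n_genes Number of genes.
#' @param density_meanlog,density_sdlog Log-normal parameters of the
#'   per-gene ribosome density (ribosomes per transcript copy).
#' @param expression_meanlog,expression_sdlog Log-normal parameters of
#'   relative transcript copy numbers.
#' @param length_meanlog,length_sdlog Log-normal parameters of CDS
#'   length in nucleotides.
#' @param depth_fp,depth_rna Total simulated footprint / RNA-Seq reads.
#' @param trace_noise_sd Trace noise standard deviation as a fraction of
#'   the maximum signal.
#' @param loc_a,loc_b Parameters of the generating peak-location model
#'   `position = loc_a * ln(index) + loc_b`.
#' @param width_factor Peak sigma as a fraction of local peak spacing.
#' @param debris_A,debris_k,baseline_m,baseline_c Background components
#'   of generated traces.
#' @param n_points Samples per generated trace.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_genes = 500L,
                         density_meanlog = log(2), density_sdlog = 0.6,
                         expression_meanlog = 0, expression_sdlog = 1,
                         length_meanlog = log(1500), length_sdlog = 0.45,
                         depth_fp = 1e6, depth_rna = 1e6,
                         trace_noise_sd = 0.01,
                         loc_a = 20, loc_b = 30, width_factor = 0.25,
                         debris_A = 2, debris_k = 0.5,
                         baseline_m = 5e-4, baseline_c = 0.05,
                         n_points = 600L) {
  spec <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
               density_meanlog = density_meanlog, density_sdlog = density_sdlog,
               expression_meanlog = expression_meanlog,
               expression_sdlog = expression_sdlog,
               length_meanlog = length_meanlog, length_sdlog = length_sdlog,
               depth_fp = depth_fp, depth_rna = depth_rna,
               trace_noise_sd = trace_noise_sd,
               loc_a = loc_a, loc_b = loc_b, width_factor = width_factor,
               debris_A = debris_A, debris_k = debris_k,
               baseline_m = baseline_m, baseline_c = baseline_c,
               n_points = as.integer(n_points))
  if (spec$n_genes < 1) pp_stop_invalid("n_genes must be positive")
  if (spec$depth_fp <= 0 || spec$depth_rna <= 0)
    pp_stop_invalid("sequencing depths must be positive")
  if (spec$density_sdlog < 0 || spec$trace_noise_sd < 0 ||
      spec$width_factor <= 0 || spec$loc_a <= 0)
    pp_stop_invalid("negative or zero fixture parameter where positive required")
  structure(spec, class = "fixture_spec")
}

# Draw the per-gene ground truth (lengths, copies, densities, bound
# ribosomes) implied by a fixture spec. Assumes the RNG seed has been set
# by the caller.
draw_truth <- function(spec, volumes = NULL) {
  n <- spec$n_genes
  len <- pmax(150, round(stats::rlnorm(n, spec$length_meanlog,
                                       spec$length_sdlog)))
  copies <- stats::rlnorm(n, spec$expression_meanlog, spec$expression_sdlog)
  if (is.null(volumes)) {
    density <- stats::rlnorm(n, spec$density_meanlog, spec$density_sdlog)
    density <- pmin(density, len / 30)  # physical packing cap
  } else {
    # Prescribed n-some volumes: genes get integer densities and their
    # copy numbers are rescaled so each peak's ribosome mass is exactly
    # proportional to its prescribed volume.
    labels <- names(volumes)
    if (is.null(labels) || any(labels %in% c("40S", "60S")))
      pp_stop_invalid("prescribed volumes must cover integer n-some peaks only")
    pk <- as.integer(labels)
    gene_pk <- pk[sample.int(length(pk), n, replace = TRUE,
                             prob = volumes / sum(volumes))]
    density <- as.numeric(gene_pk)
    for (p in unique(gene_pk)) {
      sel <- gene_pk == p
      mass <- sum(copies[sel] * p)
      copies[sel] <- copies[sel] * (volumes[as.character(p)] / mass)
    }
    copies <- copies / sum(copies)
  }
  data.frame(gene_id = sprintf("g%04d", seq_len(n)), length_nt = len,
             rna_copies = copies, density = density,
             ribosomes_bound = copies * density,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic count table with known ground truth
#'
#' Draws per-gene transcript copies and ribosome densities from the
#' spec's distributions (or pins them to a prescribed peak-volume
#' vector), then simulates sequencing: expected footprint reads are
#' proportional to bound ribosomes (`copies * density`) and expected
#' RNA-Seq reads to `copies * length_nt / 1000` (so that RPK recovers
#' relative copy numbers).  Realised counts are multinomial at the
#' spec's depths, so the totals are exact.
#'
#' @param spec A [fixture_spec()].
#' @param volumes Optional named vector of prescribed n-some volumes
#'   (integer peak labels); genes then receive integer densities whose
#'   pooled ribosome mass reproduces this vector exactly in expectation.
#' @return List with elements `counts` (a count table suitable for
#'   [compute_states()]) and `truth` (per-gene data frame with columns
#'   `gene_id`, `length_nt`, `rna_copies`, `density`,
#'   `ribosomes_bound`, on an arbitrary scale).
#' @export
make_count_table <- function(spec, volumes = NULL) {
  if (!inherits(spec, "fixture_spec")) pp_stop_invalid("spec must be a fixture_spec")
  set.seed(spec$seed)
  truth <- draw_truth(spec, volumes)
  p_fp <- truth$ribosomes_bound
  p_rna <- truth$rna_copies * truth$length_nt / 1000
  counts <- data.frame(
    gene_id = truth$gene_id,
    length_nt = truth$length_nt,
    fp_count = as.numeric(stats::rmultinom(1, spec$depth_fp, p_fp)),
    rna_count = as.numeric(stats::rmultinom(1, spec$depth_rna, p_rna)),
    stringsAsFactors = FALSE)
  list(counts = counts, truth = truth)
}

#' Cell parameters consistent with a fixture's ground truth
#'
#' [compute_states()] recovers absolute copy numbers and densities only
#' when the assumed cellular totals match the generating truth.  This
#' helper builds a [cell_params()] whose totals are exactly the truth's
#' total copies and total bound ribosomes (scaled by the chosen active
#' fraction), so parameter-recovery comparisons are meaningful.
#'
#' @param truth The `truth` element of [make_count_table()].
#' @param active_fraction,split_fraction,small_subunit_fraction Passed
#'   through to [cell_params()].
#' @return A [cell_params()] object.
#' @export
fixture_params <- function(truth, active_fraction = 0.85,
                           split_fraction = 0.3,
                           small_subunit_fraction = 0.35) {
  cell_params("yeast",
              total_mrna = sum(truth$rna_copies),
              total_ribosomes = sum(truth$ribosomes_bound) / active_fraction,
              active_fraction = active_fraction,
              split_fraction = split_fraction,
              small_subunit_fraction = small_subunit_fraction)
}

#' Generate a synthetic gradient trace with known generating model
#'
#' Renders the given peak-volume vector as scaled Gaussians at the
#' positions of the spec's logarithmic location model (sigma =
#' `width_factor` times local spacing), adds the spec's debris
#' exponential and linear baseline, samples on a regular grid from
#' position 0, and adds Gaussian noise scaled to the maximum signal.
#'
#' @param spec A [fixture_spec()].
#' @param volumes Named peak-volume vector to render.
#' @return List with elements `trace` (a [profile_trace()]), `model`
#'   (the generating [profile_model()]) and `location_model`.
#' @export
make_trace <- function(spec, volumes) {
  if (!inherits(spec, "fixture_spec")) pp_stop_invalid("spec must be a fixture_spec")
  set.seed(spec$seed)
  labels <- names(volumes)
  if (is.null(labels)) pp_stop_invalid("volumes must be named by peak label")
  keep <- volumes > 0
  v <- volumes[keep]
  loc <- new_peak_location_model(spec$loc_a, spec$loc_b,
                                 peak_index_value(labels[keep]))
  mu <- predict_positions(loc, peak_index_value(names(v)))
  ord <- order(mu)
  v <- v[ord]; mu <- mu[ord]
  sigma <- spec$width_factor * local_spacing(mu)
  model <- profile_model(
    data.frame(label = names(v), mu = mu, sigma = sigma, s = as.numeric(v)),
    background = list(A = spec$debris_A, k = spec$debris_k,
                      m = spec$baseline_m, c = spec$baseline_c))
  grid <- seq(0, max(mu + 4 * sigma), length.out = spec$n_points)
  y <- evaluate_model(model, grid)
  if (spec$trace_noise_sd > 0)
    y <- y + stats::rnorm(length(y), 0, spec$trace_noise_sd * max(y))
  list(trace = profile_trace(grid, y), model = model, location_model = loc)
}

#' Generate a synthetic known-good collection of volume vectors
#'
#' Emulates a reference collection of sound datasets by perturbing a
#' base peak-volume vector with small multiplicative log-normal noise
#' and renormalising.  The result is suitable input for [fit_null()].
#'
#' @param spec A [fixture_spec()] (its seed and density distribution are
#'   used; the default base vector is the modelled profile implied by
#'   the spec's density distribution under yeast parameters).
#' @param n_datasets Number of vectors to generate (>= 3).
#' @param base_volumes Optional base peak-volume vector; default derived
#'   from the spec.
#' @param perturb_sd Log-scale standard deviation of the multiplicative
#'   perturbation (default 0.05).
#' @return List of `n_datasets` named peak-volume vectors.
#' @export
make_known_good_collection <- function(spec, n_datasets = 31,
                                       base_volumes = NULL,
                                       perturb_sd = 0.05) {
  if (!inherits(spec, "fixture_spec")) pp_stop_invalid("spec must be a fixture_spec")
  if (n_datasets < 3) pp_stop_insufficient("n_datasets must be at least 3")
  set.seed(spec$seed)
  if (is.null(base_volumes)) {
    truth <- draw_truth(spec)
    masses <- assign_to_peaks(truth)
    base_volumes <- add_inactive(masses, cell_params("yeast"))
  }
  lapply(seq_len(n_datasets), function(i) {
    v <- base_volumes * exp(stats::rnorm(length(base_volumes), 0, perturb_sd))
    v / sum(v)
  })
}
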