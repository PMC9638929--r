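#' Cell-type parameters for polysome modelling
#'
#' Organism-level constants needed to convert relative sequencing counts
#' into absolute per-cell quantities and to complete the non-translating
#' part of a modelled profile:
#'
#' * `total_mrna` — mRNA copies per cell (yeast 60 000, HEK293 300 000).
#' * `total_ribosomes` — ribosomes per cell (yeast 200 000, HEK293
#'   2 000 000).
#' * `active_fraction` — fraction of ribosomes engaged in translation
#'   (0.85 for fast-growing yeast).
#' * `split_fraction` — fraction of the inactive ribosomes dissociated
#'   into free 40S/60S subunits (0.3 in yeast; mammalian cells show
#'   relatively larger subunit peaks, so the HEK293 preset ships with
#'   0.6, which should be treated as tunable).
#' * `small_subunit_fraction` — mass fraction of the small subunit
#'   (0.35 yeast, 0.37 mammal), used for the fractional subunit peak
#'   indices.
#'
#' The HEK293 preset inherits the yeast active fraction; both fractions
#' in that preset are starting points to be adjusted against an
#' experimental profile.
#'
#' @param preset `"yeast"` or `"hek293"`.
#' @param ... Named overrides for any of the fields above.
#' @return A `cell_params` list.
#' @examples
#' cell_params("yeast")
#' cell_params("yeast", active_fraction = 0.7)
#' @export
cell_params <- function(preset = c("yeast", "hek293"), ...) {
  preset <- match.arg(preset)
  p <- switch(preset,
    yeast = list(total_mrna = 60000, total_ribosomes = 200000,
                 active_fraction = 0.85, split_fraction = 0.3,
                 small_subunit_fraction = 0.35),
    hek293 = list(total_mrna = 300000, total_ribosomes = 2e6,
                  active_fraction = 0.85, split_fraction = 0.6,
                  small_subunit_fraction = 0.37))
  over <- list(...)
  if (length(over) > 0) {
    bad <- setdiff(names(over), names(p))
    if (length(bad) > 0 || is.null(names(over)) || any(names(over) == ""))
      pp_stop_invalid(sprintf("unknown cell parameter(s): %s",
                              paste(bad, collapse = ", ")))
    p[names(over)] <- over
  }
  for (f in c("active_fraction", "split_fraction", "small_subunit_fraction"))
    if (p[[f]] < 0 || p[[f]] > 1)
      pp_stop_invalid(sprintf("%s must be in [0, 1]", f))
  if (p$total_mrna <= 0 || p$total_ribosomes <= 0)
    pp_stop_invalid("total_mrna and total_ribosomes must be positive")
  p$preset <- preset
  structure(p, class = "cell_params")
}

#' @export
print.cell_params <- function(x, ...) {
  cat(sprintf(paste0(
    "<cell_params> preset '%s': %g mRNAs, %g ribosomes, ",
    "active %.2f, split %.2f, small-subunit mass %.2f\n"),
    x$preset, x$total_mrna, x$total_ribosomes,
    x$active_fraction, x$split_fraction, x$small_subunit_fraction))
  invisible(x)
}
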