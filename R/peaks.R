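#' Fractional peak indices for ribosomal subunits
#'
#' Peaks in a polysome profile are indexed by the number of ribosomes in
#' the sedimenting particle: 1 for the monosome (80S), 2, 3, ... for the
#' n-somes.  The free subunit peaks are given fractional indices in
#' proportion to their mass relative to a complete ribosome: the small
#' (40S) subunit carries 0.35 of the ribosome mass in yeast and 0.37 in
#' mammals, and the large (60S) subunit the complement.
#'
#' @param species `"yeast"` or `"mammal"`.
#' @return Named numeric vector with elements `40S` and `60S`.
#' @examples
#' subunit_indices("yeast")   # 0.35, 0.65
#' subunit_indices("mammal")  # 0.37, 0.63
#' @export
subunit_indices <- function(species = c("yeast", "mammal")) {
  species <- match.arg(species)
  small <- if (species == "yeast") 0.35 else 0.37
  c("40S" = small, "60S" = 1 - small)
}

# Map peak labels ("40S", "60S", "1", "2", ...) to numeric n-some indices.
peak_index_value <- function(labels, small_subunit_fraction = 0.35) {
  idx <- suppressWarnings(as.numeric(labels))
  idx[labels == "40S"] <- small_subunit_fraction
  idx[labels == "60S"] <- 1 - small_subunit_fraction
  if (any(is.na(idx)))
    pp_stop_invalid(sprintf("unrecognised peak label(s): %s",
                            paste(labels[is.na(idx)], collapse = ", ")))
  idx
}

# Canonical ordering of peak labels: 40S, 60S, then integer n-somes.
order_peak_labels <- function(labels) {
  idx <- peak_index_value(labels)
  labels[order(idx)]
}

#' Detect peaks in a profile trace by monotonic runs
#'
#' A candidate peak is a sample where a run of at least `min_run`
#' consecutive points with strictly increasing absorbance is immediately
#' followed by a run of at least `min_run` points with strictly decreasing
#' absorbance.  Run lengths are counted in points, with the apex point
#' shared by both runs; ties (equal consecutive readings) break a run.
#' The one exception is a flat plateau at the apex itself, which is
#' tolerated (noise-free signals sampled symmetrically around a maximum
#' produce one): the peak is then placed at the plateau midpoint.
#'
#' @param trace A [profile_trace()].
#' @param min_run Minimum run length in points on each flank (default 4).
#' @param min_position Optional cutoff: peaks at positions below this are
#'   discarded.  Used to exclude the debris region at the top of the
#'   gradient before peak indexing.
#' @return Numeric vector of peak positions in increasing order (may be
#'   empty).
#' @examples
#' x <- seq(0, 10, length.out = 100)
#' detect_peaks(profile_trace(x, dnorm(x, 5, 1)))
#' @export
detect_peaks <- function(trace, min_run = 4, min_position = -Inf) {
  if (!is_profile_trace(trace)) trace <- profile_trace(trace$position, trace$absorbance)
  if (min_run < 2) pp_stop_invalid("min_run must be at least 2")
  y <- trace$absorbance
  if (length(y) < 2 * min_run)
    pp_stop_invalid("trace shorter than 2 * min_run samples")
  s <- sign(diff(y))
  r <- rle(s)
  ends <- cumsum(r$lengths)
  need <- min_run - 1L   # a run of k points spans k - 1 differences
  apex <- integer(0)
  nr <- length(r$values)
  for (j in seq_len(max(nr - 1L, 0L))) {
    if (r$values[j] != 1 || r$lengths[j] < need) next
    if (r$values[j + 1] == -1 && r$lengths[j + 1] >= need) {
      apex <- c(apex, ends[j] + 1L)
    } else if (r$values[j + 1] == 0 && j + 2L <= nr &&
               r$values[j + 2] == -1 && r$lengths[j + 2] >= need) {
      # apex plateau: place the peak at the plateau midpoint
      apex <- c(apex, (ends[j] + 1L + ends[j + 1] + 1L) %/% 2L)
    }
  }
  pos <- trace$position[apex]
  pos[pos >= min_position]
}

new_peak_location_model <- function(a, b, index_domain, rms = NA_real_) {
  structure(list(a = a, b = b, index_domain = index_domain, rms = rms),
            class = "peak_location_model")
}

#' Fit the logarithmic peak-location model
#'
#' Sedimentation compresses successive n-some peaks: observed peak
#' positions are well described by `position = a * ln(index) + b`, where
#' `index` is the n-some number (with fractional indices for the free
#' subunits, see [subunit_indices()]).  The fit is ordinary least squares
#' on `ln(index)`.
#'
#' @param peak_positions Numeric vector of peak positions, strictly
#'   increasing.
#' @param peak_indices Numeric vector of peak indices (> 0), strictly
#'   increasing, same length.
#' @return A `peak_location_model` with elements `a`, `b`, `index_domain`
#'   and `rms` (root-mean-square fit residual).
#' @examples
#' m <- fit_location_model(10 + 20 * log(1:8), 1:8)
#' m$a; m$b
#' @export
fit_location_model <- function(peak_positions, peak_indices) {
  peak_positions <- as.numeric(peak_positions)
  peak_indices <- as.numeric(peak_indices)
  if (length(peak_positions) != length(peak_indices))
    pp_stop_invalid("positions and indices must have the same length")
  if (length(peak_positions) < 3)
    pp_stop_insufficient("at least 3 (position, index) pairs are required")
  if (any(peak_indices <= 0))
    pp_stop_domain("peak indices must be positive")
  if (any(diff(peak_indices) <= 0))
    pp_stop_invalid("peak indices must be strictly increasing")
  if (any(diff(peak_positions) <= 0))
    pp_stop_invalid("peak positions must be strictly increasing")
  fit <- stats::lsfit(log(peak_indices), peak_positions)
  a <- unname(fit$coefficients[2])
  b <- unname(fit$coefficients[1])
  rms <- sqrt(mean(fit$residuals^2))
  new_peak_location_model(a, b, peak_indices, rms)
}

#' @export
print.peak_location_model <- function(x, ...) {
  cat(sprintf(
    "<peak_location_model> position = %.4g * ln(index) + %.4g (rms %.3g, %d peaks)\n",
    x$a, x$b, x$rms, length(x$index_domain)))
  invisible(x)
}

#' Predict peak positions from a location model
#'
#' Evaluates `a * ln(index) + b`, including extrapolation beyond the
#' fitted index range (this is how positions for the compressed
#' high-polysome region are obtained from the few visually separable
#' peaks).
#'
#' @param model A `peak_location_model`.
#' @param indices Numeric peak indices, all > 0.
#' @return Numeric vector of predicted positions.
#' @export
predict_positions <- function(model, indices) {
  if (!inherits(model, "peak_location_model"))
    pp_stop_invalid("model must be a peak_location_model")
  indices <- as.numeric(indices)
  if (any(!is.finite(indices)) || any(indices <= 0))
    pp_stop_domain("peak indices must be positive and finite")
  model$a * log(indices) + model$b
}
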