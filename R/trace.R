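#' Construct a polysome profile trace
#'
#' A profile trace holds one optical-density scan of a sucrose density
#' gradient: a strictly increasing gradient coordinate (arbitrary units,
#' e.g. sample index or mm along the scan) paired with OD254 absorbance
#' readings.
#'
#' @param position Numeric vector of gradient coordinates, strictly
#'   increasing, at least 20 samples.
#' @param absorbance Numeric vector of OD254 readings, same length as
#'   `position`, all finite.
#' @return A `profile_trace`: a data frame with columns `position` and
#'   `absorbance`.
#' @examples
#' x <- seq(0, 10, length.out = 50)
#' tr <- profile_trace(x, dnorm(x, 5, 1))
#' @export
profile_trace <- function(position, absorbance) {
  position <- as.numeric(position)
  absorbance <- as.numeric(absorbance)
  if (length(position) != length(absorbance))
    pp_stop_invalid("position and absorbance must have the same length")
  if (length(position) < 20)
    pp_stop_invalid("a profile trace needs at least 20 samples")
  if (any(!is.finite(position)) || any(!is.finite(absorbance)))
    pp_stop_invalid("positions and absorbances must be finite")
  bad <- which(diff(position) <= 0)
  if (length(bad) > 0)
    pp_stop_invalid(sprintf(
      "positions must be strictly increasing (first violation at row %d)",
      bad[1] + 1L))
  structure(data.frame(position = position, absorbance = absorbance),
            class = c("profile_trace", "data.frame"))
}

#' @export
print.profile_trace <- function(x, ...) {
  cat(sprintf("<profile_trace> %d samples, position %g..%g, max OD %.4g\n",
              nrow(x), x$position[1], x$position[nrow(x)],
              max(x$absorbance)))
  invisible(x)
}

is_profile_trace <- function(x) inherits(x, "profile_trace")
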