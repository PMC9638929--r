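# Shared fixture builders for the test suite. Everything is generated in
# code under fixed seeds; no file state.

# Brute-force local-maximum search (independent oracle for detect_peaks
# on noise-free signals): a strict local maximum of the sampled signal.
brute_force_maxima <- function(x, y) {
  ix <- which(diff(sign(diff(y))) == -2) + 1L
  x[ix]
}

# A noise-free multi-Gaussian trace following the logarithmic location
# rule position = a*ln(n) + b, with amplitude per peak.
log_spaced_trace <- function(n_peaks = 5, a = 20, b = 10, sigma = 0.8,
                             amplitude = 0.5, n_points = 400,
                             noise_sd = 0, seed = 42) {
  set.seed(seed)
  mus <- a * log(seq_len(n_peaks)) + b
  x <- seq(b - 5, max(mus) + 5, length.out = n_points)
  y <- numeric(n_points)
  for (m in mus) y <- y + amplitude * dnorm(x, m, sigma)
  if (noise_sd > 0) y <- y + rnorm(n_points, 0, noise_sd)
  list(trace = profile_trace(x, y), mus = mus, sigma = sigma,
       amplitude = amplitude)
}

# Random normalised peak-volume vector over 40S/60S/1..n.
random_volumes <- function(n_peaks = 12, subunits = TRUE) {
  labels <- c(if (subunits) c("40S", "60S"), as.character(seq_len(n_peaks)))
  v <- runif(length(labels))
  setNames(v / sum(v), labels)
}

# Base yeast-like volume vector shared across comparison tests.
base_volume_vector <- function() {
  spec <- fixture_spec(seed = 11)
  make_known_good_collection(spec, 3, perturb_sd = 0)[[1]]
}
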