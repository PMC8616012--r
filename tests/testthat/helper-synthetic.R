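# Shared fixture builders for synthetic traces and event matching.

# Build a trace_set with Gaussian pulses planted at known sample centers.
# `amplitude` is the peak of the *summed* scattering channels; the four
# analyzer channels split it according to `weights` (summing to 1), and the
# fluorescence channel carries `f_frac` of the total profile.
plant_pulses <- function(n, centers, amplitude, sigma = 5,
                         weights = c(0.1, 0.35, 0.15, 0.4),
                         f_frac = 0.2, noise_sd = 0, sampling_rate = 2e5) {
  ch <- matrix(0, n, 5L)
  amplitude <- rep_len(amplitude, length(centers))
  for (i in seq_along(centers)) {
    idx <- max(1, centers[i] - 6 * sigma):min(n, centers[i] + 6 * sigma)
    prof <- amplitude[i] * exp(-(idx - centers[i])^2 / (2 * sigma^2))
    for (k in 1:4) ch[idx, k] <- ch[idx, k] + weights[k] * prof
    ch[idx, 5] <- ch[idx, 5] + f_frac * prof
  }
  if (noise_sd > 0) ch <- ch + matrix(rnorm(length(ch), sd = noise_sd), n, 5L)
  trace_set(ch[, 1], ch[, 2], ch[, 3], ch[, 4], ch[, 5],
            sampling_rate = sampling_rate)
}

# Match detected event windows to planted centers; returns logical vectors
# (found per center, matched per event).
match_events <- function(events, centers, slack = 0) {
  found <- vapply(centers, function(c0)
    any(events$start - slack <= c0 & c0 < events$end + slack), logical(1))
  matched <- vapply(seq_len(nrow(events)), function(i)
    any(centers >= events$start[i] - slack & centers < events$end[i] + slack),
    logical(1))
  list(found = found, matched = matched)
}

# Random physical Stokes vector with DOP <= 1 and unit-scale intensity.
random_physical_stokes <- function() {
  dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
  p <- runif(1)
  I <- runif(1, 0.5, 2)
  stokes(c(I, I * p * dir))
}
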