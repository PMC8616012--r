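#' Bundle synchronized multichannel voltage traces
#'
#' Five equal-length voltage series sampled at a common fixed rate: the four
#' polarization-analyzer channels IL, I0, I90, I135 and the fluorescence
#' channel FL.
#'
#' @param IL,I0,I90,I135,FL numeric voltage series of equal length, no NaNs.
#' @param sampling_rate samples per second (> 0).
#' @param t0 start time, seconds.
#' @return object of class \code{trace_set}.
#' @export
trace_set <- function(IL, I0, I90, I135, FL, sampling_rate, t0 = 0) {
  ch <- list(IL = IL, I0 = I0, I90 = I90, I135 = I135, FL = FL)
  n <- unique(lengths(ch))
  if (length(n) != 1L) stop("all five channels must have equal length")
  if (any(vapply(ch, function(x) any(!is.finite(x)), logical(1))))
    stop("traces must be finite (encode gaps explicitly before this point)")
  stopifnot(sampling_rate > 0)
  structure(list(channels = lapply(ch, as.numeric),
                 sampling_rate = sampling_rate, t0 = t0, n = n),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat("Multichannel trace set: ", x$n, " samples x 5 channels @ ",
      format(x$sampling_rate), " Hz (", format(x$n / x$sampling_rate),
      " s)\n", sep = "")
  invisible(x)
}

#' Rolling-median baseline and robust noise estimate
#'
#' The baseline is a running median over \code{window} samples (odd; rounded
#' up if even), which sparse transit pulses do not perturb. The noise SD is
#' the median absolute deviation of the residual scaled to the
#' Gaussian-equivalent SD (factor 1.4826).
#'
#' @param trace numeric voltage series.
#' @param window window length in samples (>= 3, <= length of trace).
#' @return list with \code{baseline} (series) and \code{noise_sd} (scalar).
#' @export
estimate_baseline <- function(trace, window = 501L) {
  n <- length(trace)
  if (window < 3L) stop("baseline window must be >= 3 samples")
  if (window > n) stop("baseline window (", window,
                       ") longer than trace (", n, ")")
  k <- as.integer(window); if (k %% 2L == 0L) k <- k + 1L
  k <- min(k, if (n %% 2L == 0L) n - 1L else n)
  baseline <- as.numeric(stats::runmed(trace, k, endrule = "median"))
  list(baseline = baseline,
       noise_sd = stats::mad(trace - baseline, center = 0))
}

#' Detect particle transit pulses in a trace set
#'
#' Detection runs on the sum of the four scattering channels (a
#' polarization-independent proxy for total intensity I): samples exceeding
#' \code{baseline + k_threshold * noise_sd} for at least \code{min_width}
#' consecutive samples form candidate events, and events whose gap is
#' smaller than \code{min_separation} are merged. For each event, every
#' channel is integrated over the event window after subtracting its own
#' rolling-median baseline, giving volt-second integrals; the fluorescence
#' integral Fm is taken over the same window as the scattering pulse, which
#' is what makes the two measurements simultaneous. The per-event SNR is
#' \code{(peak - baseline) / noise_sd} of the summed scattering trace.
#'
#' @param traces a \code{\link{trace_set}}.
#' @param k_threshold detection threshold in units of the noise SD (> 0).
#' @param min_width minimum pulse width, samples.
#' @param min_separation events closer than this (samples) are merged.
#' @param baseline_window rolling-median window, samples.
#' @return data.frame of pulse events with columns \code{start},
#'   \code{end} (half-open sample interval \code{[start, end)}),
#'   \code{IL}, \code{I0}, \code{I90}, \code{I135}, \code{Fm}
#'   (baseline-subtracted integrals, volt seconds), \code{peak} (volts over
#'   baseline) and \code{snr}.
#' @export
detect_pulses <- function(traces, k_threshold = 5, min_width = 8L,
                          min_separation = 16L, baseline_window = 501L) {
  stopifnot(inherits(traces, "trace_set"), k_threshold > 0)
  if (traces$n == 0L) stop("empty trace")
  ch <- traces$channels
  total <- ch$IL + ch$I0 + ch$I90 + ch$I135
  bl <- estimate_baseline(total, baseline_window)
  above <- total > bl$baseline + k_threshold * bl$noise_sd
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_width
  ev <- cbind(start = starts[keep], end = ends[keep] + 1L)  # half-open
  if (nrow(ev) > 1L) {
    merged <- ev[1, , drop = FALSE]
    for (i in 2:nrow(ev)) {
      if (ev[i, "start"] - merged[nrow(merged), "end"] < min_separation) {
        merged[nrow(merged), "end"] <- ev[i, "end"]
      } else merged <- rbind(merged, ev[i, , drop = FALSE])
    }
    ev <- merged
  }
  if (nrow(ev) == 0L)
    return(data.frame(start = integer(), end = integer(), IL = numeric(),
                      I0 = numeric(), I90 = numeric(), I135 = numeric(),
                      Fm = numeric(), peak = numeric(), snr = numeric()))
  dt <- 1 / traces$sampling_rate
  per_ch_bl <- lapply(ch, function(x) estimate_baseline(x, baseline_window)$baseline)
  ints <- t(apply(ev, 1, function(e) {
    idx <- e[["start"]]:(e[["end"]] - 1L)
    vapply(names(ch), function(nm)
      sum(ch[[nm]][idx] - per_ch_bl[[nm]][idx]) * dt, numeric(1))
  }))
  peaks <- apply(ev, 1, function(e) {
    idx <- e[["start"]]:(e[["end"]] - 1L)
    max(total[idx] - bl$baseline[idx])
  })
  out <- data.frame(start = ev[, "start"], end = ev[, "end"],
                    IL = ints[, "IL"], I0 = ints[, "I0"],
                    I90 = ints[, "I90"], I135 = ints[, "I135"],
                    Fm = ints[, "FL"], peak = peaks,
                    snr = if (bl$noise_sd > 0) peaks / bl$noise_sd else Inf)
  attr(out, "noise_sd") <- bl$noise_sd
  attr(out, "dt") <- dt
  out
}

#' Per-particle features from detected pulses
#'
#' For each pulse, the four channel integrals are inverted through the
#' instrument matrix to the scattered Stokes vector, the normalized
#' components q, u, v and the degree of polarization are computed, and the
#' fluorescence feature is the ratio \code{F = Fm / I}. Because every
#' channel (including fluorescence) scales with the particle's position in
#' the focal volume by the same factor, q, u, v, DOP and F are all invariant
#' to that transit-position amplitude — the point of the ratio
#' normalization. Pulses whose recovered I falls at or below
#' \code{intensity_floor} are dropped and counted (attribute
#' \code{n_rejected}), not raised as errors, since near-zero I makes the
#' ratios blow up.
#'
#' @param pulses data.frame from \code{\link{detect_pulses}} (columns IL,
#'   I0, I90, I135, Fm; extra columns are carried through).
#' @param A instrument matrix used for inversion.
#' @param intensity_floor minimum recovered I (volt seconds). The default
#'   \code{5 * noise_sd * min_width * dt} — five noise SDs integrated over a
#'   minimal pulse — is computed from the attributes \code{detect_pulses}
#'   leaves on its result when available, else 0.
#' @param min_width used for the default floor.
#' @return data.frame with columns \code{I}, \code{q}, \code{u}, \code{v},
#'   \code{dop}, \code{F}, \code{physical}, \code{pulse} (row id of the
#'   source pulse) plus any \code{snr} column carried over; attribute
#'   \code{n_rejected} counts dropped records.
#' @export
features_from_pulses <- function(pulses, A, intensity_floor = NULL,
                                 min_width = 8L) {
  if (is.null(intensity_floor)) {
    ns <- attr(pulses, "noise_sd"); dt <- attr(pulses, "dt")
    intensity_floor <- if (!is.null(ns) && !is.null(dt))
      5 * ns * min_width * dt else 0
  }
  Ainv <- solve(as.matrix(A))
  n <- nrow(pulses)
  out <- data.frame(I = numeric(n), q = numeric(n), u = numeric(n),
                    v = numeric(n), dop = numeric(n), F = numeric(n),
                    physical = logical(n), pulse = seq_len(n))
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    s <- as.numeric(Ainv %*% c(pulses$IL[i], pulses$I0[i],
                               pulses$I90[i], pulses$I135[i]))
    if (!is.finite(s[1]) || s[1] <= intensity_floor) { keep[i] <- FALSE; next }
    pc <- polarization_components(s, id = i)
    out[i, 1:6] <- c(s[1], pc$q, pc$u, pc$v, pc$dop, pulses$Fm[i] / s[1])
    out$physical[i] <- pc$physical
  }
  if ("snr" %in% names(pulses)) out$snr <- pulses$snr
  res <- out[keep, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_rejected") <- sum(!keep)
  res
}

#' Write / read trace sets as columnar text
#'
#' Plain tab-separated text with a commented header carrying the sampling
#' rate and start time, columns \code{time, IL, I0, I90, I135, FL}.
#'
#' @param traces a \code{\link{trace_set}}.
#' @param path file path.
#' @return \code{write_traces} returns \code{path} invisibly;
#'   \code{read_traces} returns a \code{trace_set}.
#' @export
write_traces <- function(traces, path) {
  stopifnot(inherits(traces, "trace_set"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# polarcyte trace v1",
               paste0("# sampling_rate_hz\t", format(traces$sampling_rate, digits = 15)),
               paste0("# t0_s\t", format(traces$t0, digits = 15))), con)
  df <- data.frame(time = traces$t0 + (seq_len(traces$n) - 1) / traces$sampling_rate,
                   traces$channels)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  hdr <- readLines(path, n = 3L)
  rate <- as.numeric(sub(".*\t", "", hdr[grepl("sampling_rate_hz", hdr)]))
  t0 <- as.numeric(sub(".*\t", "", hdr[grepl("t0_s", hdr)]))
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  trace_set(df$IL, df$I0, df$I90, df$I135, df$FL,
            sampling_rate = rate, t0 = if (is.na(t0)) 0 else t0)
}
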