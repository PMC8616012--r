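#' Define a particle class for the instrument simulator
#'
#' Each class is a parametric family of single-particle scattering Mueller
#' matrices at the 120-degree backscattering geometry, plus a fluorescence
#' ratio distribution and a pulse-amplitude distribution. The Mueller family
#' is built from three physically guaranteed factors — a linear diattenuator
#' (strength \code{diattenuation}, axis \code{diatt_axis}), a linear
#' retarder (\code{retardance} degrees, axis \code{ret_axis}) and an
#' isotropic depolarizer (polarization-preservation factor \code{depol} in
#' [0, 1]) — each jittered per particle, so every generated matrix maps
#' physical Stokes vectors to physical Stokes vectors. These families are
#' synthetic stand-ins chosen to reproduce qualitative class structure, not
#' measured Mueller matrices of any real sample.
#'
#' The fluorescence ratio is the per-particle Fm/I: exactly 0 for
#' non-fluorescent classes, else lognormal with the given mean and SD.
#' Pulse amplitude (relative transit depth x size) is lognormal.
#'
#' @param name class label.
#' @param diattenuation,diatt_sd mean and per-particle SD of the
#'   diattenuation in [0, 1).
#' @param retardance,ret_sd mean and SD of the retardance, degrees.
#' @param depol,depol_sd mean and SD of the depolarization preservation
#'   factor (1 = none, 0 = fully depolarizing).
#' @param diatt_axis,ret_axis element axes, degrees.
#' @param f_ratio_mean,f_ratio_sd mean and SD of Fm/I (0 mean means
#'   non-fluorescent: ratios exactly 0).
#' @param amplitude_meanlog,amplitude_sdlog lognormal pulse-amplitude
#'   parameters.
#' @return object of class \code{particle_class}.
#' @export
particle_class <- function(name, diattenuation, retardance, depol,
                           diatt_axis = 0, ret_axis = 45,
                           diatt_sd = 0.05, ret_sd = 15, depol_sd = 0.08,
                           f_ratio_mean = 0, f_ratio_sd = 0,
                           amplitude_meanlog = 0, amplitude_sdlog = 0.3) {
  stopifnot(diattenuation >= 0, diattenuation < 1,
            depol >= 0, depol <= 1, f_ratio_mean >= 0)
  structure(list(name = name, diattenuation = diattenuation,
                 retardance = retardance, depol = depol,
                 diatt_axis = diatt_axis, ret_axis = ret_axis,
                 diatt_sd = diatt_sd, ret_sd = ret_sd, depol_sd = depol_sd,
                 f_ratio_mean = f_ratio_mean, f_ratio_sd = f_ratio_sd,
                 amplitude_meanlog = amplitude_meanlog,
                 amplitude_sdlog = amplitude_sdlog),
            class = "particle_class")
}

# Linear diattenuator, strength d, axis theta (deg); physical for d in [0,1].
.mueller_diattenuator <- function(d, theta = 0) {
  s <- sqrt(pmax(0, 1 - d^2))
  M0 <- matrix(c(1, d, 0, 0,
                 d, 1, 0, 0,
                 0, 0, s, 0,
                 0, 0, 0, s), 4, 4, byrow = TRUE)
  .mueller_rotator(-theta) %*% M0 %*% .mueller_rotator(theta)
}

# One per-particle Mueller draw from a class's jittered parametric family.
.draw_mueller <- function(cls) {
  d <- min(0.99, max(0, stats::rnorm(1, cls$diattenuation, cls$diatt_sd)))
  r <- stats::rnorm(1, cls$retardance, cls$ret_sd)
  p <- min(1, max(0, stats::rnorm(1, cls$depol, cls$depol_sd)))
  diag(c(1, p, p, p)) %*%
    unclass(mueller_waveplate(r, cls$ret_axis)) %*%
    .mueller_diattenuator(d, cls$diatt_axis)
}

#' Specify a simulated single-particle experiment
#'
#' Particles of the listed classes arrive as a Poisson process at
#' \code{arrival_rate} events per second over \code{duration} seconds and
#' transit the focal volume with a Gaussian intensity profile of width
#' \code{transit_time} ms. Illumination defaults to 45-degree linearly
#' polarized light. The seed is mandatory: every draw the simulator makes is
#' reproducible from it. The default sampling rate (200 kHz) puts 20 samples
#' across a 0.1 ms transit.
#'
#' @param classes list of \code{\link{particle_class}} objects.
#' @param proportions mixing proportions (summing to 1).
#' @param arrival_rate events per second, >= 0.
#' @param duration trace duration, seconds.
#' @param seed integer seed (mandatory).
#' @param incident_stokes incident Stokes vector (default \code{[1,0,1,0]}).
#' @param noise_sd additive Gaussian detector noise SD per channel, volts.
#' @param transit_time transit time, ms.
#' @param sampling_rate Hz.
#' @param instrument instrument matrix used to render channel voltages
#'   (default the theoretical analyzer matrix).
#' @return object of class \code{experiment_design}.
#' @export
experiment_design <- function(classes, proportions = NULL,
                              arrival_rate = 10, duration = 1, seed,
                              incident_stokes = c(1, 0, 1, 0),
                              noise_sd = 0.002, transit_time = 0.1,
                              sampling_rate = 2e5,
                              instrument = theoretical_instrument_matrix()) {
  if (missing(seed)) stop("a seed is mandatory for reproducible simulation")
  if (inherits(classes, "particle_class")) classes <- list(classes)
  if (is.null(proportions)) proportions <- rep(1 / length(classes), length(classes))
  if (abs(sum(proportions) - 1) > 1e-8) stop("proportions must sum to 1")
  stopifnot(length(proportions) == length(classes), arrival_rate >= 0,
            duration > 0, noise_sd >= 0, transit_time > 0, sampling_rate > 0)
  structure(list(classes = classes, proportions = proportions,
                 arrival_rate = arrival_rate, duration = duration,
                 seed = as.integer(seed),
                 incident_stokes = as.numeric(incident_stokes),
                 noise_sd = noise_sd, transit_time = transit_time,
                 sampling_rate = sampling_rate, instrument = instrument),
            class = "experiment_design")
}

#' Draw the particle population of an experiment
#'
#' Arrival times are a Poisson process; each particle gets a class label
#' (multinomial by the mixing proportions), a scattered Stokes vector
#' \code{Sout = M_particle \%*\% incident}, an Fm/I ratio and a transit
#' amplitude. Deterministic under the design seed.
#'
#' @param design an \code{\link{experiment_design}}.
#' @return data.frame with columns \code{time}, \code{label},
#'   \code{S_I, S_Q, S_U, S_V}, \code{f_ratio}, \code{amplitude}.
#' @export
sample_particles <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  set.seed(design$seed)
  n <- stats::rpois(1, design$arrival_rate * design$duration)
  times <- sort(stats::runif(n, 0, design$duration))
  ki <- sample.int(length(design$classes), n, replace = TRUE,
                   prob = design$proportions)
  out <- data.frame(time = times,
                    label = vapply(design$classes[ki], `[[`, "", "name"),
                    S_I = numeric(n), S_Q = numeric(n),
                    S_U = numeric(n), S_V = numeric(n),
                    f_ratio = numeric(n), amplitude = numeric(n))
  for (i in seq_len(n)) {
    cls <- design$classes[[ki[i]]]
    s <- as.numeric(.draw_mueller(cls) %*% design$incident_stokes)
    out[i, c("S_I", "S_Q", "S_U", "S_V")] <- s
    out$f_ratio[i] <- if (cls$f_ratio_mean > 0) {
      m <- cls$f_ratio_mean; v <- max(cls$f_ratio_sd, 1e-12)^2
      stats::rlnorm(1, log(m^2 / sqrt(m^2 + v)), sqrt(log(1 + v / m^2)))
    } else 0
    out$amplitude[i] <- stats::rlnorm(1, cls$amplitude_meanlog,
                                      cls$amplitude_sdlog)
  }
  out
}

#' Render a particle population into multichannel voltage traces
#'
#' Each particle contributes a Gaussian temporal profile (SD = transit
#' time / 4, truncated at 4 SD) scaled by its amplitude. The four analyzer
#' voltages follow the instrument forward model applied to the particle's
#' scattered Stokes vector; the fluorescence channel is the particle's Fm/I
#' ratio times its scattered-intensity profile. Overlapping transits add
#' linearly and are counted in the \code{n_overlap} attribute (the
#' occupancy > 1 analogue). Additive Gaussian noise per channel;
#' deterministic under the design seed.
#'
#' @param particles data.frame from \code{\link{sample_particles}}.
#' @param design the same \code{\link{experiment_design}}.
#' @return a \code{\link{trace_set}} with attributes \code{truth} (the
#'   particle table) and \code{n_overlap}.
#' @export
render_traces <- function(particles, design) {
  stopifnot(inherits(design, "experiment_design"))
  fs <- design$sampling_rate
  transit_s <- design$transit_time * 1e-3
  if (transit_s * fs < 4) stop("transit must span at least 4 samples")
  n <- max(2L, ceiling(design$duration * fs))
  sig <- transit_s / 4
  half <- ceiling(4 * sig * fs)
  ch <- matrix(0, n, 5L)
  A <- as.matrix(design$instrument)
  for (i in seq_len(nrow(particles))) {
    c0 <- round(particles$time[i] * fs)
    idx <- max(1L, c0 - half):min(n, c0 + half)
    if (!length(idx)) next
    prof <- particles$amplitude[i] *
      exp(-((idx - c0) / fs)^2 / (2 * sig^2))
    s <- as.numeric(particles[i, c("S_I", "S_Q", "S_U", "S_V")])
    v <- as.numeric(A %*% s)
    for (k in 1:4) ch[idx, k] <- ch[idx, k] + v[k] * prof
    ch[idx, 5] <- ch[idx, 5] + particles$f_ratio[i] * s[1] * prof
  }
  n_overlap <- if (nrow(particles) > 1)
    sum(diff(sort(particles$time)) < 2 * 4 * sig) else 0L
  if (n_overlap > 0)
    warning(n_overlap, " overlapping transit(s) rendered additively")
  set.seed(design$seed + 1L)
  if (design$noise_sd > 0)
    ch <- ch + matrix(stats::rnorm(length(ch), sd = design$noise_sd), n, 5L)
  out <- trace_set(ch[, 1], ch[, 2], ch[, 3], ch[, 4], ch[, 5],
                   sampling_rate = fs)
  attr(out, "truth") <- particles
  attr(out, "n_overlap") <- n_overlap
  out
}

# Synthetic benchmark class parameter tables. Values are constructed to
# reproduce qualitative class structure (which pairs overlap in
# polarization, ordering of fluorescence means), not any instrument's
# measured values.
.preset_classes <- function(preset) {
  switch(preset,
    "ps10-family" = list(
      particle_class("PS10",     0.15,  20, 0.95, f_ratio_mean = 0),
      particle_class("PS10-100", 0.30,  70, 0.70, f_ratio_mean = 0),
      particle_class("SiO2",     0.05, 120, 0.90, f_ratio_mean = 0),
      particle_class("PS10-F",   0.15,  20, 0.95,
                     f_ratio_mean = 0.60, f_ratio_sd = 0.15)),
    "algae4" = list(
      particle_class("P.T.", 0.45,  30, 0.85,
                     f_ratio_mean = 0.10, f_ratio_sd = 0.04),
      particle_class("D.S.", 0.10, 130, 0.55,
                     f_ratio_mean = 0.30, f_ratio_sd = 0.10),
      particle_class("P.G.", 0.25,  70, 0.75,
                     f_ratio_mean = 0.90, f_ratio_sd = 0.35),
      particle_class("M.A.", 0.27,  74, 0.73,
                     f_ratio_mean = 0.45, f_ratio_sd = 0.12)),
    "submicron" = list(
      particle_class("PS0.5",    0.10,  15, 0.97, f_ratio_mean = 0,
                     amplitude_meanlog = log(0.05)),
      particle_class("S-805",    0.25,  50, 0.88,
                     f_ratio_mean = 0.30, f_ratio_sd = 0.08,
                     amplitude_meanlog = log(0.08)),
      particle_class("S-WH7803", 0.40,  95, 0.78,
                     f_ratio_mean = 0.60, f_ratio_sd = 0.15,
                     amplitude_meanlog = log(0.08))),
    stop("unknown preset '", preset, "'; available: ps10-family, algae4, submicron")
  )
}

#' Generate a labeled benchmark feature table
#'
#' Produces a reproducible per-particle feature table (I, q, u, v, dop, F,
#' label) for one of three synthetic presets that mirror the structure of
#' typical mixed-suspension experiments:
#' \describe{
#'   \item{ps10-family}{three non-fluorescent microsphere classes plus a
#'     fluorescent twin of the smooth polystyrene class — identical
#'     polarization family, positive F;}
#'   \item{algae4}{four microalgae-like classes: two polarization-distinct,
#'     two polarization-overlapping but fluorescence-distinct, with class
#'     mean F ordered P.G. > M.A. > D.S. > P.T. and the largest spread for
#'     P.G.;}
#'   \item{submicron}{three small-particle classes at low pulse amplitude:
#'     a non-fluorescent microsphere and two fluorescent
#'     cyanobacteria-like classes.}
#' }
#' Each particle's Stokes vector is drawn from its class family, pushed
#' through the analyzer forward model with detector noise, inverted through
#' the instrument matrix, and reduced to features — the same path measured
#' data would take. Class parameter tables are attached as the
#' \code{design} attribute.
#'
#' @param preset one of \code{"ps10-family"}, \code{"algae4"},
#'   \code{"submicron"}.
#' @param seed integer seed.
#' @param n_per_class particles per class (default 500).
#' @param noise_sd detector noise SD on each simulated voltage.
#' @return data.frame of features with a \code{label} factor column.
#' @export
make_benchmark_suite <- function(preset, seed, n_per_class = 500,
                                 noise_sd = 0.01) {
  classes <- .preset_classes(preset)
  set.seed(seed)
  A <- theoretical_instrument_matrix()
  Ainv <- solve(as.matrix(A))
  incident <- c(1, 0, 1, 0)
  rows <- vector("list", length(classes) * n_per_class)
  r <- 0L
  for (cls in classes) {
    for (j in seq_len(n_per_class)) {
      amp <- stats::rlnorm(1, cls$amplitude_meanlog, cls$amplitude_sdlog)
      s <- amp * as.numeric(.draw_mueller(cls) %*% incident)
      fr <- if (cls$f_ratio_mean > 0) {
        m <- cls$f_ratio_mean; v <- max(cls$f_ratio_sd, 1e-12)^2
        stats::rlnorm(1, log(m^2 / sqrt(m^2 + v)), sqrt(log(1 + v / m^2)))
      } else 0
      v4 <- as.numeric(as.matrix(A) %*% s) + stats::rnorm(4, sd = noise_sd)
      fm <- fr * s[1] + stats::rnorm(1, sd = noise_sd)
      srec <- as.numeric(Ainv %*% v4)
      if (srec[1] <= 0) next
      pc <- polarization_components(srec)
      r <- r + 1L
      rows[[r]] <- data.frame(I = srec[1], q = pc$q, u = pc$u, v = pc$v,
                              dop = pc$dop, F = fm / srec[1],
                              label = cls$name)
    }
  }
  out <- do.call(rbind, rows[seq_len(r)])
  out$label <- factor(out$label, levels = vapply(classes, `[[`, "", "name"))
  rownames(out) <- NULL
  attr(out, "design") <- classes
  out
}
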