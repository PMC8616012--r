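#' Chlorophyll fluorescence yield
#'
#' The volumetric fluorescence emission rate of a chlorophyll-a-containing
#' cell is modeled as a five-factor product:
#' \deqn{F' = PAR \cdot [chla] \cdot \bar{a}^* \cdot Q_a^*(\lambda_{em})
#'   \cdot \phi_F}
#' with PAR the photosynthetically active radiation intensity in
#' umol/(m^2 s), \code{chla} the chlorophyll-a concentration in mg/m^3,
#' \code{a_star} the absorption coefficient per unit chlorophyll in
#' m^2/mg, \code{Qa_star} the dimensionless reabsorption factor and
#' \code{phi_F} the dimensionless emission quantum-efficiency factor.
#' The product carries units umol photons/(m^3 s); conversion to radiant
#' power is a separate, explicit step (\code{\link{photon_rate_to_nW}})
#' because the emission wavelength enters only there.
#'
#' @param PAR photosynthetically active radiation, umol/(m^2 s), >= 0.
#' @param chla chlorophyll-a concentration, mg/m^3, >= 0.
#' @param a_star absorption coefficient per chlorophyll, m^2/mg, >= 0.
#' @param Qa_star reabsorption factor in [0, 1].
#' @param phi_F quantum-efficiency factor in [0, 1].
#' @return fluorescence yield F', umol/(m^3 s).
#' @export
fluorescence_yield <- function(PAR, chla, a_star, Qa_star, phi_F) {
  vals <- c(PAR = PAR, chla = chla, a_star = a_star,
            Qa_star = Qa_star, phi_F = phi_F)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all fluorescence-yield factors must be finite and >= 0")
  if (Qa_star > 1 || phi_F > 1)
    stop("Qa_star and phi_F are dimensionless factors <= 1")
  PAR * chla * a_star * Qa_star * phi_F
}

#' Fraction of isotropic emission collected by a solid angle
#'
#' Fluorescence emitted evenly in all directions is collected in proportion
#' to the receiving solid angle: \code{solid_angle / (4 pi)}. The 0.014 sr
#' collection aperture of the 120-degree backscattering geometry collects
#' 0.11 percent of the total emission.
#'
#' @param solid_angle steradians, in (0, 4*pi].
#' @return dimensionless fraction in (0, 1].
#' @export
collection_fraction <- function(solid_angle) {
  if (!is.finite(solid_angle) || solid_angle <= 0 || solid_angle > 4 * pi)
    stop("solid angle must be in (0, 4*pi] steradians")
  solid_angle / (4 * pi)
}

#' Detector voltage from optical power
#'
#' @param power optical power at the detector, nW, >= 0.
#' @param sensitivity radiant sensitivity, V/nW (default 5, a typical
#'   high-gain photodetector module).
#' @param daq_gain additional acquisition-chain gain factor (default 1);
#'   real acquisition cards often apply an extra undocumented gain, so it is
#'   exposed rather than folded into the sensitivity.
#' @return volts.
#' @export
detector_voltage <- function(power, sensitivity = 5, daq_gain = 1) {
  if (!is.finite(power) || power < 0) stop("power must be >= 0 nW")
  stopifnot(sensitivity > 0, daq_gain > 0)
  power * sensitivity * daq_gain
}

#' Convert a photon emission rate to radiant power
#'
#' 1 umol of photons is 6.02214076e17 photons; each carries
#' \code{h c / lambda} joules. Used to move the fluorescence yield (photon
#' units) onto the detector's power scale (nW).
#'
#' @param umol_per_s photon rate, umol/s.
#' @param wavelength_nm emission wavelength, nm (default 685, the chlorophyll-a
#'   fluorescence peak).
#' @return power in nW.
#' @export
photon_rate_to_nW <- function(umol_per_s, wavelength_nm = 685) {
  stopifnot(umol_per_s >= 0, wavelength_nm > 0)
  h <- 6.62607015e-34; c0 <- 2.99792458e8
  photons <- umol_per_s * 6.02214076e17
  photons * h * c0 / (wavelength_nm * 1e-9) * 1e9
}

#' Expected particle occupancy of the scattering volume
#'
#' With particles distributed at concentration c (per mL) and a scattering
#' volume V (uL), the expected number in the volume is \code{c * V / 1000}.
#' Arrivals being Poisson, the probability of two or more particles being
#' probed at once is \code{1 - exp(-m) - m exp(-m)}. At 1e5 particles/mL
#' and 0.01 uL the expectation is exactly 1 — the concentration ceiling for
#' single-particle operation.
#'
#' @param concentration particles per mL, > 0.
#' @param volume scattering volume, uL, > 0.
#' @return list with \code{expected} (mean count) and \code{p_multi}
#'   (Poisson probability of >= 2 particles).
#' @export
occupancy <- function(concentration, volume) {
  if (!is.finite(concentration) || concentration <= 0 ||
      !is.finite(volume) || volume <= 0)
    stop("concentration and volume must be positive")
  m <- concentration * volume * 1e-3   # uL -> mL
  list(expected = m, p_multi = stats::ppois(1, m, lower.tail = FALSE))
}

#' Photodamage exposure check
#'
#' Energy deposited on a cell during one transit: \code{power x dwell x
#' interception}, compared to a photoinhibition threshold. The geometric
#' interception factor is the fraction of the focal-spot power actually
#' intercepted by the cell (cell cross-section over focal-spot area, capped
#' at 1); for cells smaller than the focal spot it is well below 1, which is
#' why a 300 mW beam dwelling 0.1 ms (30 uJ at full interception) can
#' deposit well under 1 uJ on a micron-scale cell.
#'
#' @param power illumination power, mW, >= 0.
#' @param dwell transit/dwell time, ms, >= 0.
#' @param damage_threshold photoinhibition energy threshold, uJ
#'   (default 816.43).
#' @param interception geometric interception factor in [0, 1].
#' @return list with \code{energy} (uJ) and \code{safe} (logical,
#'   energy < threshold).
#' @export
exposure_check <- function(power, dwell, damage_threshold = 816.43,
                           interception = 1) {
  stopifnot(power >= 0, dwell >= 0, damage_threshold >= 0,
            interception >= 0, interception <= 1)
  energy <- power * dwell * interception   # mW * ms = uJ
  list(energy = energy, safe = energy < damage_threshold)
}

#' Interception factor from cell and focal-spot size
#'
#' @param cell_diameter_um cell diameter, um.
#' @param spot_diameter_um focal-spot diameter, um (default 10).
#' @return area ratio capped at 1.
#' @export
interception_factor <- function(cell_diameter_um, spot_diameter_um = 10) {
  stopifnot(cell_diameter_um > 0, spot_diameter_um > 0)
  min(1, (cell_diameter_um / spot_diameter_um)^2)
}

#' Print the full fluorescence physics chain
#'
#' Convenience wrapper running yield -> photon-to-power conversion ->
#' solid-angle collection -> detector voltage, returning each stage.
#'
#' @param params list with PAR, chla, a_star, Qa_star, phi_F.
#' @param emitting_volume_m3 emitting (cell) volume, m^3.
#' @param solid_angle collection solid angle, sr.
#' @param sensitivity detector radiant sensitivity, V/nW.
#' @param daq_gain acquisition gain factor.
#' @param wavelength_nm emission wavelength for the photon-power conversion.
#' @return data.frame, one row per stage with value and unit.
#' @export
fluorescence_chain <- function(params, emitting_volume_m3,
                               solid_angle = 0.014, sensitivity = 5,
                               daq_gain = 1, wavelength_nm = 685) {
  yield <- do.call(fluorescence_yield, params)
  rate <- yield * emitting_volume_m3           # umol photons / s
  total_nW <- photon_rate_to_nW(rate, wavelength_nm)
  frac <- collection_fraction(solid_angle)
  volts <- detector_voltage(total_nW * frac, sensitivity, daq_gain)
  data.frame(stage = c("yield", "photon_rate", "total_power",
                       "collected_power", "voltage"),
             value = c(yield, rate, total_nW, total_nW * frac, volts),
             unit = c("umol/(m^3 s)", "umol/s", "nW", "nW", "V"))
}
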