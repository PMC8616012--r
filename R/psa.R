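#' Describe the four-channel division-of-amplitude analyzer
#'
#' The analyzer splits the collected beam into four parallel channels with a
#' tree of non-polarizing beam splitters (one 50:50 and two 30:70 cubes) and
#' analyzes each through its own polarization optics:
#' \describe{
#'   \item{L}{quarter-wave plate at 135 degrees, then polarizer at 90
#'     degrees — the left-handed circular channel;}
#'   \item{I0}{polarizer at 0 degrees — horizontal linear;}
#'   \item{I90}{polarizer at 90 degrees — vertical linear;}
#'   \item{I135}{polarizer at 45 degrees — 45-degree linear.}
#' }
#' Which splitter fraction feeds which channel is configurable; the default
#' routes the 50:50 cube first and a 30:70 cube on each arm, giving channel
#' throughputs (0.15, 0.35, 0.15, 0.35) — the most equal arrangement this
#' splitter set allows. The assignment only affects the conditioning of the
#' instrument matrix, since the matrix is calibrated before inversion.
#'
#' @param split_fractions length-4 positive fractions (each <= 1) reaching
#'   channels L, 0, 90, 135 respectively.
#' @param gains per-detector volts-per-intensity factors (default 1).
#' @param psa_prefactor intensity fraction reaching the whole analyzer
#'   (e.g. 0.5 if the fluorescence pick-off splitter is modeled explicitly
#'   rather than absorbed into calibration); default 1.
#' @return object of class \code{analyzer_layout}.
#' @export
analyzer_layout <- function(split_fractions = c(0.15, 0.35, 0.15, 0.35),
                            gains = rep(1, 4), psa_prefactor = 1) {
  if (length(split_fractions) != 4L)
    stop("the analyzer has exactly four channels")
  if (any(split_fractions <= 0) || any(split_fractions > 1))
    stop("split fractions must be in (0, 1]")
  stopifnot(length(gains) == 4L, all(gains > 0),
            psa_prefactor > 0, psa_prefactor <= 1)
  structure(list(split_fractions = as.numeric(split_fractions),
                 gains = as.numeric(gains),
                 psa_prefactor = psa_prefactor,
                 channels = c("IL", "I0", "I90", "I135")),
            class = "analyzer_layout")
}

#' @export
print.analyzer_layout <- function(x, ...) {
  cat("Division-of-amplitude analyzer layout\n")
  cat("  channels:       ", paste(x$channels, collapse = ", "), "\n")
  cat("  split fractions:", format(x$split_fractions), "\n")
  cat("  detector gains: ", format(x$gains), "\n")
  cat("  PSA pre-factor: ", format(x$psa_prefactor), "\n")
  invisible(x)
}

# First Mueller row of each channel's analyzing optics (unit throughput).
.channel_analyzer_rows <- function() {
  chL <- mueller_polarizer(90) %*% mueller_waveplate(90, 135)
  rbind(IL   = chL[1, ],
        I0   = mueller_polarizer(0)[1, ],
        I90  = mueller_polarizer(90)[1, ],
        I135 = mueller_polarizer(45)[1, ])
}

#' Theoretical instrument matrix of the analyzer
#'
#' Row k of the 4x4 instrument matrix A maps an incident Stokes vector to
#' the voltage of detector k: \code{row_k = gain_k * split_k * prefactor *
#' (first Mueller row of channel k's optics)}. With unit gains and equal
#' splits the rows are proportional to \code{[1,0,0,-1]} (left circular),
#' \code{[1,1,0,0]}, \code{[1,-1,0,0]} and \code{[1,0,1,0]}, each scaled by
#' the polarizer's 1/2.
#'
#' @param layout an \code{\link{analyzer_layout}}.
#' @return object of class \code{instrument_matrix}: the 4x4 matrix with a
#'   \code{condition} attribute (2-norm condition number).
#' @export
theoretical_instrument_matrix <- function(layout = analyzer_layout()) {
  stopifnot(inherits(layout, "analyzer_layout"))
  rows <- .channel_analyzer_rows()
  A <- diag(layout$gains * layout$split_fractions * layout$psa_prefactor) %*% rows
  dimnames(A) <- list(layout$channels, c("I", "Q", "U", "V"))
  instrument_matrix(A)
}

#' Wrap a 4x4 matrix as an instrument matrix
#'
#' @param A 4x4 numeric matrix mapping Stokes vectors to channel voltages.
#' @return object of class \code{instrument_matrix}.
#' @export
instrument_matrix <- function(A) {
  A <- as.matrix(A)
  if (!all(dim(A) == c(4L, 4L)) || !all(is.finite(A)))
    stop("an instrument matrix is a finite 4x4 matrix")
  sv <- svd(A)$d
  structure(A, class = c("instrument_matrix", "matrix"),
            condition = if (min(sv) > 0) max(sv) / min(sv) else Inf)
}

#' @export
print.instrument_matrix <- function(x, ...) {
  cat("Instrument matrix (Stokes -> channel voltages)\n")
  print(unclass(x)[, , drop = FALSE], digits = 5)
  cat("condition number:", format(attr(x, "condition"), digits = 5), "\n")
  invisible(x)
}

#' Simulate the four channel voltages for an incident Stokes vector
#'
#' Forward model: \code{A \%*\% S} plus independent zero-mean Gaussian noise
#' per channel. \code{noise_sd = 0} is exact.
#'
#' @param A an \code{instrument_matrix} (or 4x4 matrix).
#' @param S Stokes vector.
#' @param noise_sd per-channel Gaussian noise standard deviation, volts.
#' @return named length-4 numeric of voltages (IL, I0, I90, I135).
#' @export
simulate_channel_voltages <- function(A, S, noise_sd = 0) {
  stopifnot(noise_sd >= 0)
  v <- as.numeric(as.matrix(A) %*% as.numeric(S))
  if (noise_sd > 0) v <- v + stats::rnorm(4L, sd = noise_sd)
  names(v) <- c("IL", "I0", "I90", "I135")
  v
}
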