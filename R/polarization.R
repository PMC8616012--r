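#' Construct a Stokes vector
#'
#' A Stokes vector \code{[I, Q, U, V]} describes the intensity and
#' polarization state of a light beam: \code{I} is the total intensity
#' (detector-voltage-equivalent units), and \code{Q}, \code{U}, \code{V} are
#' the residual intensities of 0-degree linear, 45-degree linear and
#' right-handed circular polarization. The handedness convention is
#' \code{V > 0} for right-handed circular light.
#'
#' A vector is *physical* when \code{Q^2 + U^2 + V^2 <= I^2} (within
#' tolerance) and \code{I >= 0}. Vectors recovered by inverting noisy
#' detector voltages can fall outside the physical cone; they are retained
#' and flagged rather than clipped, so downstream statistics are not biased.
#'
#' @param I,Q,U,V numeric components; alternatively pass a length-4 numeric
#'   as \code{I}.
#' @param tol relative tolerance used by the physicality check.
#' @return an object of class \code{stokes} (a named length-4 numeric with a
#'   \code{physical} attribute).
#' @examples
#' stokes(1, 0, 1, 0)            # 45-degree linear polarization
#' stokes(c(2, 1, 1, 1))
#' @export
stokes <- function(I, Q = NULL, U = NULL, V = NULL, tol = 1e-9) {
  if (is.null(Q) && length(I) == 4L) {
    s <- as.numeric(I)
  } else {
    s <- c(I, Q, U, V)
  }
  if (length(s) != 4L || !all(is.finite(s)))
    stop("a Stokes vector needs 4 finite components")
  names(s) <- c("I", "Q", "U", "V")
  structure(s, class = "stokes", physical = is_physical_stokes(s, tol = tol))
}

#' Test Stokes-vector physicality
#'
#' @param s length-4 numeric (I, Q, U, V).
#' @param tol relative tolerance on the cone condition.
#' @return logical: \code{I >= 0} and \code{Q^2+U^2+V^2 <= I^2 (1 + tol)}.
#' @export
is_physical_stokes <- function(s, tol = 1e-9) {
  s <- as.numeric(s)
  s[1] >= 0 && (s[2]^2 + s[3]^2 + s[4]^2) <= s[1]^2 * (1 + tol) + tol
}

#' @export
print.stokes <- function(x, ...) {
  cat("Stokes vector [I, Q, U, V]:", format(as.numeric(x), digits = 6), "\n")
  cat("  physical:", isTRUE(attr(x, "physical")), "\n")
  invisible(x)
}

# 2-theta rotation of the Q-U subspace, angles in degrees.
.mueller_rotator <- function(theta_deg) {
  a <- 2 * theta_deg * pi / 180
  c2 <- cos(a); s2 <- sin(a)
  matrix(c(1, 0, 0, 0,
           0, c2, s2, 0,
           0, -s2, c2, 0,
           0, 0, 0, 1), 4, 4, byrow = TRUE)
}

.as_mueller <- function(M) {
  structure(M, class = c("mueller", "matrix"))
}

#' Mueller matrix of an ideal linear polarizer
#'
#' Transmission axis at \code{theta} degrees counter-clockwise from
#' horizontal. The matrix is idempotent and has \code{M[1,1] = 1/2}:
#' an ideal polarizer passes half of unpolarized light.
#'
#' @param theta transmission-axis angle, degrees.
#' @return 4x4 \code{mueller} matrix.
#' @examples
#' mueller_polarizer(0)
#' apply_element(mueller_polarizer(0), stokes(1, 0, 0, 0))
#' @export
mueller_polarizer <- function(theta) {
  stopifnot(is.finite(theta))
  a <- 2 * theta * pi / 180
  C <- cos(a); S <- sin(a)
  M <- 0.5 * matrix(c(1, C, S, 0,
                      C, C^2, C * S, 0,
                      S, C * S, S^2, 0,
                      0, 0, 0, 0), 4, 4, byrow = TRUE)
  .as_mueller(M)
}

#' Mueller matrix of an ideal linear retarder
#'
#' Fast axis at \code{theta} degrees from horizontal, retardance
#' \code{retardance} degrees: 180 gives a half-wave plate, 90 a quarter-wave
#' plate. The element is lossless (\code{M[1,1] = 1}; intensity and degree of
#' polarization are preserved). Sign convention: at \code{theta = 0} the
#' U-V block is \code{[[cos d, sin d], [-sin d, cos d]]}, so a quarter-wave
#' plate at 0 degrees maps 45-degree linear light \code{[1,0,1,0]} to
#' left-handed circular \code{[1,0,0,-1]} under the V>0 = right-handed
#' convention.
#'
#' @param retardance retardance in degrees.
#' @param theta fast-axis angle in degrees.
#' @return 4x4 \code{mueller} matrix.
#' @export
mueller_waveplate <- function(retardance, theta = 0) {
  stopifnot(is.finite(retardance), is.finite(theta))
  d <- retardance * pi / 180
  M0 <- matrix(c(1, 0, 0, 0,
                 0, 1, 0, 0,
                 0, 0, cos(d), sin(d),
                 0, 0, -sin(d), cos(d)), 4, 4, byrow = TRUE)
  .as_mueller(.mueller_rotator(-theta) %*% M0 %*% .mueller_rotator(theta))
}

#' Apply a Mueller matrix (or a chain) to a Stokes vector
#'
#' Computes \code{M \%*\% S}. For a chain of elements pass a list; the
#' first list element is encountered first by the light, i.e. the chain
#' \code{list(A, B)} computes \code{B \%*\% A \%*\% S} (last element
#' leftmost).
#'
#' @param M a 4x4 matrix or a list of 4x4 matrices (optical path order).
#' @param S a \code{stokes} vector or length-4 numeric.
#' @return a \code{stokes} vector (physicality re-evaluated).
#' @export
apply_element <- function(M, S) {
  s <- as.numeric(S)
  if (length(s) != 4L) stop("S must have 4 components")
  if (is.list(M)) {
    for (m in M) s <- as.numeric(m %*% s)
  } else {
    if (!all(dim(M) == c(4L, 4L))) stop("M must be 4x4")
    s <- as.numeric(M %*% s)
  }
  stokes(s)
}

#' Polarization components and degree of polarization
#'
#' The normalized components are \code{q = Q/I}, \code{u = U/I},
#' \code{v = V/I}, each in \code{[-1, 1]} for physical light, and the degree
#' of polarization is \code{DOP = sqrt(q^2 + u^2 + v^2)}. The features are
#' scale invariant: multiplying the Stokes vector by any k > 0 leaves them
#' unchanged. For Stokes vectors recovered from noisy voltages DOP can
#' exceed 1; the result then carries \code{physical = FALSE} rather than
#' being clipped.
#'
#' @param S a \code{stokes} vector or length-4 numeric with \code{I > 0}.
#' @param id optional record identifier used in the error message.
#' @return list with \code{q}, \code{u}, \code{v}, \code{dop},
#'   \code{physical}.
#' @examples
#' polarization_components(stokes(2, 1, 1, 1))
#' @export
polarization_components <- function(S, id = NULL) {
  s <- as.numeric(S)
  if (length(s) != 4L) stop("S must have 4 components")
  if (!is.finite(s[1]) || s[1] <= 0)
    stop("polarization components undefined: I = ", format(s[1]),
         if (!is.null(id)) paste0(" (record ", id, ")") else "")
  q <- s[2] / s[1]; u <- s[3] / s[1]; v <- s[4] / s[1]
  dop <- sqrt(q^2 + u^2 + v^2)
  list(q = q, u = u, v = v, dop = dop, physical = dop <= 1 + 1e-9)
}
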