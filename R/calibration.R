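#' Canonical calibration probe states
#'
#' The six standard polarimeter calibration states: horizontal, vertical,
#' +45 and -45 linear, right- and left-handed circular, all at unit
#' intensity. Any four of them span the Stokes space; using all six gives a
#' well-conditioned over-determined fit.
#'
#' @return 4x6 matrix, one probe Stokes vector per column.
#' @export
canonical_probes <- function() {
  P <- cbind(H = c(1, 1, 0, 0), V = c(1, -1, 0, 0),
             P45 = c(1, 0, 1, 0), M45 = c(1, 0, -1, 0),
             RCP = c(1, 0, 0, 1), LCP = c(1, 0, 0, -1))
  rownames(P) <- c("I", "Q", "U", "V")
  P
}

#' Bundle calibration probes and measured voltages
#'
#' @param probes 4xN matrix of known incident Stokes vectors (columns), or a
#'   list of Stokes vectors. N >= 4 and the matrix must have rank 4.
#' @param voltages 4xN matrix of measured channel voltages (columns), rows
#'   IL, I0, I90, I135, matched to the probes.
#' @return object of class \code{calibration_set}.
#' @export
calibration_set <- function(probes, voltages) {
  if (is.list(probes)) probes <- do.call(cbind, lapply(probes, as.numeric))
  probes <- as.matrix(probes); voltages <- as.matrix(voltages)
  if (nrow(probes) != 4L || nrow(voltages) != 4L)
    stop("probes and voltages must be 4-row matrices (one state per column)")
  if (ncol(probes) != ncol(voltages))
    stop("probes and voltages must pair one-to-one")
  if (ncol(probes) < 4L)
    stop("calibration needs at least 4 probe states, got ", ncol(probes))
  structure(list(probes = probes, voltages = voltages),
            class = "calibration_set")
}

#' Estimate the instrument matrix from calibration probes
#'
#' Solves the least-squares problem \code{min_A sum_i || A s_i - v_i ||^2}
#' over all probe pairs — the matrix normal equations give
#' \code{A = V S^T (S S^T)^{-1}}. With exactly four independent probes this
#' is the exact solve. The probe matrix must have rank 4; otherwise the
#' unobserved Stokes subspace is reported in the error.
#'
#' @param cal a \code{\link{calibration_set}}.
#' @return an \code{\link{instrument_matrix}} with attributes
#'   \code{residual} (Frobenius norm of the voltage misfit) and
#'   \code{probe_condition} (condition number of the probe matrix).
#' @export
calibrate_psa <- function(cal) {
  stopifnot(inherits(cal, "calibration_set"))
  S <- cal$probes; V <- cal$voltages
  sv <- svd(S)
  tol <- max(dim(S)) * max(sv$d) * .Machine$double.eps
  r <- sum(sv$d > tol)
  if (r < 4L) {
    null_dir <- round(sv$u[, (r + 1L):4L, drop = FALSE], 4)
    stop("probe set is rank-deficient (rank ", r, "); unobserved Stokes ",
         "direction(s): ", paste(apply(null_dir, 2, function(x)
           paste0("[", paste(format(x), collapse = ", "), "]")),
           collapse = "; "))
  }
  # A = V S^T (S S^T)^{-1}, via the SVD pseudo-inverse of S
  A <- V %*% sv$v %*% diag(1 / sv$d, r) %*% t(sv$u)
  res <- sqrt(sum((A %*% S - V)^2))
  out <- instrument_matrix(A)
  dimnames(out) <- list(c("IL", "I0", "I90", "I135"), c("I", "Q", "U", "V"))
  attr(out, "residual") <- res
  attr(out, "probe_condition") <- max(sv$d) / min(sv$d)
  out
}

#' Recover a Stokes vector from the four channel voltages
#'
#' Inverts the instrument relation: \code{S = A^{-1} v}. Noisy voltages can
#' invert to a point outside the physical cone (DOP > 1); the result is then
#' flagged non-physical, never clipped.
#'
#' @param A instrument matrix (4x4, invertible).
#' @param ipsa length-4 voltages (IL, I0, I90, I135).
#' @param max_condition refuse inversion if the condition number of A
#'   exceeds this cap.
#' @return a \code{\link{stokes}} vector.
#' @export
stokes_from_voltages <- function(A, ipsa, max_condition = 1e8) {
  A <- as.matrix(A)
  sv <- svd(A)$d
  k <- if (min(sv) > 0) max(sv) / min(sv) else Inf
  if (!is.finite(k) || k > max_condition)
    stop("instrument matrix is ill-conditioned (condition number ",
         format(k, digits = 4), " > ", format(max_condition), ")")
  stokes(as.numeric(solve(A, as.numeric(ipsa))))
}

#' Worst-case and RMS reconstruction error on held-out states
#'
#' Simulates channel voltages for each holdout Stokes state with the true
#' instrument matrix (optionally with Gaussian detector noise), reconstructs
#' with the fitted matrix, and reports the errors in the normalized
#' components q, u and v as percentages of full scale. Each component spans
#' \code{[-1, 1]}, so full scale is 2; errors relative to unit half-range
#' are also returned since the instrument literature does not fix the
#' denominator.
#'
#' @param A_true instrument matrix generating the voltages.
#' @param A_fit instrument matrix used for reconstruction.
#' @param holdout list of Stokes vectors (or a 4-column-per-state matrix).
#' @param noise_sd detector noise SD (volts) added to each simulated
#'   voltage; 0 for the noiseless bound.
#' @return list with \code{worst_percent} and \code{rms_percent} (named q,
#'   u, v; percent of the full-scale range 2), and
#'   \code{worst_percent_halfrange} (denominator 1).
#' @export
calibration_error_report <- function(A_true, A_fit, holdout,
                                     noise_sd = 0) {
  if (is.matrix(holdout)) holdout <- asplit(holdout, 2)
  if (length(holdout) == 0L) stop("holdout set is empty")
  err <- vapply(holdout, function(s) {
    v <- simulate_channel_voltages(A_true, s, noise_sd = noise_sd)
    truth <- polarization_components(s)
    rec <- polarization_components(stokes_from_voltages(A_fit, v))
    c(q = rec$q - truth$q, u = rec$u - truth$u, v = rec$v - truth$v)
  }, numeric(3))
  list(worst_percent = 100 * apply(abs(err), 1, max) / 2,
       rms_percent = 100 * sqrt(rowMeans(err^2)) / 2,
       worst_percent_halfrange = 100 * apply(abs(err), 1, max))
}
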