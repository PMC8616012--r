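#' Serialize an instrument matrix as plain text
#'
#' A 4x4 whitespace-separated block with a commented metadata header
#' (condition number, creation note).
#'
#' @param A an \code{\link{instrument_matrix}}.
#' @param path file path.
#' @param note free-text note stored in the header.
#' @return \code{path}, invisibly; \code{read_instrument_matrix} returns
#'   the matrix.
#' @export
write_instrument_matrix <- function(A, path, note = "") {
  stopifnot(inherits(A, "instrument_matrix"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# polarcyte instrument matrix v1",
               paste0("# condition\t",
                      format(attr(A, "condition"), digits = 15)),
               paste0("# note\t", note)), con)
  utils::write.table(unclass(A), con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_instrument_matrix
#' @export
read_instrument_matrix <- function(path) {
  M <- as.matrix(utils::read.table(path, comment.char = "#"))
  dimnames(M) <- list(c("IL", "I0", "I90", "I135"), c("I", "Q", "U", "V"))
  instrument_matrix(M)
}

#' Write / read per-particle feature tables as CSV
#'
#' @param features feature data.frame (I, q, u, v, dop, F, label, ...).
#' @param path file path.
#' @return \code{path} invisibly; \code{read_features} returns the table
#'   with \code{label} as a factor when present.
#' @export
write_features <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path)
  if ("label" %in% names(df)) df$label <- factor(df$label)
  df
}

#' Write / read calibration sets as columnar text
#'
#' One row per probe: label, the four Stokes components, the four measured
#' voltages.
#'
#' @param cal a \code{\link{calibration_set}}.
#' @param path file path.
#' @return \code{path} invisibly; the reader returns a
#'   \code{calibration_set}.
#' @export
write_calibration_set <- function(cal, path) {
  stopifnot(inherits(cal, "calibration_set"))
  labs <- colnames(cal$probes)
  if (is.null(labs)) labs <- paste0("probe", seq_len(ncol(cal$probes)))
  df <- data.frame(label = labs, t(cal$probes), t(cal$voltages))
  names(df) <- c("label", "S_I", "S_Q", "S_U", "S_V",
                 "IL", "I0", "I90", "I135")
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_calibration_set
#' @export
read_calibration_set <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  probes <- t(as.matrix(df[, c("S_I", "S_Q", "S_U", "S_V")]))
  volts <- t(as.matrix(df[, c("IL", "I0", "I90", "I135")]))
  colnames(probes) <- df$label
  calibration_set(probes, volts)
}
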