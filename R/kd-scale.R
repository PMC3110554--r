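#' Kyte-Doolittle hydropathy scale
#'
#' Named numeric vector mapping each of the 20 canonical one-letter residue
#' codes to its Kyte-Doolittle hydropathy value (dimensionless KD units).
#' Isoleucine carries the maximum (4.5), arginine the minimum (-4.5).
#'
#' @format Named numeric vector of length 20.
#' @export
kyte_doolittle <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

#' Kyte-Doolittle hydropathy of a residue
#'
#' @param residue Character vector of upper-case one-letter residue codes.
#' @param position Optional integer vector of 1-based positions, used only to
#'   enrich the error message when a non-canonical code is met.
#' @return Numeric vector of KD hydropathy values.
#' @examples
#' kd_value("I")  # 4.5
#' kd_value("R")  # -4.5
#' @export
kd_value <- function(residue, position = NULL) {
  v <- kyte_doolittle[residue]
  bad <- which(is.na(v))
  if (length(bad) > 0L) {
    where <- if (!is.null(position)) {
      sprintf(" at position %s", paste(position[bad], collapse = ", "))
    } else ""
    stop(sprintf(
      "non-canonical residue code '%s'%s: no Kyte-Doolittle value is defined",
      paste(unique(residue[bad]), collapse = "', '"), where
    ), call. = FALSE)
  }
  unname(v)
}

# Split a sequence string into a residue vector, validating canonicity.
seq_residues <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  r <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  bad <- which(!(r %in% names(kyte_doolittle)))
  if (length(bad) > 0L) {
    stop(sprintf(
      "non-canonical residue code '%s' at position %s: no Kyte-Doolittle value is defined",
      r[bad[1]], bad[1]
    ), call. = FALSE)
  }
  r
}
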