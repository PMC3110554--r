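#' Per-residue structural annotation of a membrane protein
#'
#' Every residue carries one structural state (helical or not) and one
#' membrane state (in membrane or not). Maximal runs of the two boolean
#' tracks define the alpha-helices and the transmembrane segments (TMS);
#' kink positions, detected externally, are optional.
#'
#' @param helical Logical vector, one element per residue.
#' @param in_membrane Logical vector of the same length.
#' @param kinks Optional integer vector of 1-based kink positions; every kink
#'   must lie inside a helix.
#' @param sequence_id Identifier.
#' @return Object of class `membrane_annotation`: list with `sequence_id`,
#'   `length`, `helical`, `in_membrane`, `kinks`, and derived data frames
#'   `helices` and `tms` (columns `start`, `end`).
#' @export
membrane_annotation <- function(helical, in_membrane, kinks = integer(),
                                sequence_id = "seq") {
  stopifnot(is.logical(helical), is.logical(in_membrane))
  if (length(helical) != length(in_membrane)) {
    stop("helical and in_membrane tracks differ in length", call. = FALSE)
  }
  if (anyNA(helical) || anyNA(in_membrane)) {
    stop("annotation tracks must not contain NA", call. = FALSE)
  }
  kinks <- as.integer(sort(unique(kinks)))
  if (length(kinks) && (any(kinks < 1L) || any(kinks > length(helical)))) {
    stop("kink positions outside the sequence", call. = FALSE)
  }
  if (length(kinks) && !all(helical[kinks])) {
    bad <- kinks[!helical[kinks]]
    stop(sprintf("kink position(s) %s do not lie inside a helix",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  structure(
    list(sequence_id = sequence_id, length = length(helical),
         helical = helical, in_membrane = in_membrane, kinks = kinks,
         helices = runs_of(helical), tms = runs_of(in_membrane)),
    class = "membrane_annotation"
  )
}

# Maximal runs of TRUE in a logical vector -> data.frame(start, end).
runs_of <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = as.integer(starts[keep]), end = as.integer(ends[keep]))
}

#' @export
print.membrane_annotation <- function(x, ...) {
  cat(sprintf("<membrane_annotation> %s: %d residues, %d helix(es), %d TMS, %d kink(s)\n",
              x$sequence_id, x$length, nrow(x$helices), nrow(x$tms),
              length(x$kinks)))
  invisible(x)
}
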