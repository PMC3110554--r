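#' Window radii of a pulse group
#'
#' Group G1 (radii n = 2..6) targets small structural events (single helix
#' turns, kinks); group G2 (n = 12..16) targets whole transmembrane helices.
#' Intermediate radii are deliberately not offered.
#'
#' @param group `"G1"` or `"G2"`.
#' @return Integer vector of five window radii.
#' @export
group_radii <- function(group = c("G1", "G2")) {
  group <- match.arg(group)
  if (group == "G1") 2:6 else 12:16
}

# Sine taper over one flank of the window: w(k) = sin(k*pi/(n+1)), k = 1..n.
# Strictly positive on 1..n, symmetric about the flank midpoint, and zero at
# the (cancelling) central residue, so a window of radius n involves 2n+1
# residues.
sinus_weights <- function(n) {
  sin(seq_len(n) * pi / (n + 1L))
}

#' Hydrophobicity-variation score at one position
#'
#' The score at position `i` for window radius `n` is the sine-weighted sum of
#' KD hydropathies of the `n` residues following `i` minus the identically
#' weighted sum over the `n` residues preceding `i`:
#' \deqn{score(i) = \sum_{k=1}^{n} \sin\!\left(\frac{k\pi}{n+1}\right)
#'   \left[ KD(AA(i+k)) - KD(AA(i-k)) \right]}
#' A positive score marks a local rise of hydrophobicity at scale `n`. The
#' score is undefined (an error here) where the `2n+1`-residue window does not
#' fit inside the sequence; no padding or extrapolation is performed.
#'
#' @param seq Residue string (one-letter codes) or character vector of single
#'   residues.
#' @param i 1-based position; must satisfy `n + 1 <= i <= L - n`.
#' @param n Window radius (positive integer).
#' @return Numeric scalar.
#' @examples
#' variation_score("RRRRIIII", 4, 2)  # strictly positive: entering an I block
#' @export
variation_score <- function(seq, i, n) {
  r <- if (length(seq) > 1L) seq else seq_residues(seq)
  L <- length(r)
  stopifnot(length(i) == 1L, length(n) == 1L, n >= 1L)
  if (i < n + 1L || i > L - n) {
    stop(sprintf(
      "position %d is outside the defined range [%d, %d] for window radius %d",
      i, n + 1L, L - n, n
    ), call. = FALSE)
  }
  kd <- kd_value(r, seq_along(r))
  w <- sinus_weights(n)
  k <- seq_len(n)
  sum(w * (kd[i + k] - kd[i - k]))
}

#' Hydrophobicity-variation score matrix for one group
#'
#' Computes, for every window radius of the group, the variation score at
#' every position where the window fits. Positions outside a radius's defined
#' range `[n+1, L-n]` are `NA` (explicitly undefined, never zero-filled).
#'
#' @param seq Residue string.
#' @param group `"G1"` or `"G2"`.
#' @param sequence_id Identifier carried through to results.
#' @return An object of class `hpp_scores`: a list with elements
#'   `sequence_id`, `group`, `radii`, `residues` and `scores`
#'   (a 5 x L numeric matrix, rows named `n<radius>`).
#' @export
score_matrix <- function(seq, group = c("G1", "G2"), sequence_id = "seq") {
  group <- match.arg(group)
  radii <- group_radii(group)
  r <- seq_residues(seq)
  L <- length(r)
  if (L < 2L * min(radii) + 1L) {
    stop(sprintf(
      "sequence '%s' too short for group %s: length %d, need at least %d (2*%d + 1)",
      sequence_id, group, L, 2L * min(radii) + 1L, min(radii)
    ), call. = FALSE)
  }
  kd <- kd_value(r, seq_along(r))
  scores <- matrix(NA_real_, nrow = length(radii), ncol = L,
                   dimnames = list(paste0("n", radii), NULL))
  for (j in seq_along(radii)) {
    n <- radii[j]
    if (L < 2L * n + 1L) next
    pos <- (n + 1L):(L - n)
    w <- sinus_weights(n)
    acc <- numeric(length(pos))
    for (k in seq_len(n)) {
      acc <- acc + w[k] * (kd[pos + k] - kd[pos - k])
    }
    scores[j, pos] <- acc
  }
  structure(
    list(sequence_id = sequence_id, group = group, radii = radii,
         residues = r, scores = scores),
    class = "hpp_scores"
  )
}

#' @export
print.hpp_scores <- function(x, ...) {
  cat(sprintf("<hpp_scores> %s, group %s, radii %s, length %d\n",
              x$sequence_id, x$group, paste(x$radii, collapse = ","),
              ncol(x$scores)))
  invisible(x)
}

#' Defined range of a score track
#'
#' @param x An `hpp_scores` object.
#' @param n Window radius (must belong to the object's group).
#' @return Integer vector `c(first, last)` of the defined range, or `NULL`
#'   when the track is empty at this radius.
#' @export
defined_range <- function(x, n) {
  stopifnot(inherits(x, "hpp_scores"), n %in% x$radii)
  L <- ncol(x$scores)
  if (L < 2L * n + 1L) return(NULL)
  c(n + 1L, L - n)
}
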