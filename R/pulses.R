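#' Sign-consensus track over the five radii of a group
#'
#' A two-state finite-state automaton sweeps the common defined range of the
#' five score tracks (positions `max(radii)+1 .. L-max(radii)`). At each
#' position, if at least 4 of the 5 radius scores are strictly positive the
#' state becomes POSITIVE; if at least 4 are strictly negative it becomes
#' NEGATIVE; otherwise (3-2 splits, or ties involving exact zeros) the
#' automaton holds its current state. The initial state is NEGATIVE, so no
#' pulse can fire before the first decisive positive consensus. Exact zeros
#' count as neither positive nor negative.
#'
#' @param matrix An `hpp_scores` object with all five radius tracks.
#' @return An object of class `hpp_consensus`: list with `sequence_id`,
#'   `group`, `start`, `end` (sequence coordinates of the common range) and
#'   `states` (character vector `"POSITIVE"`/`"NEGATIVE"` over that range).
#' @export
sign_consensus <- function(matrix) {
  if (!inherits(matrix, "hpp_scores")) {
    stop("sign_consensus() expects an 'hpp_scores' object", call. = FALSE)
  }
  radii <- matrix$radii
  if (nrow(matrix$scores) != 5L || !all(paste0("n", radii) %in% rownames(matrix$scores))) {
    stop("score matrix is missing radius tracks; all five are required", call. = FALSE)
  }
  L <- ncol(matrix$scores)
  nmax <- max(radii)
  if (L < 2L * nmax + 1L) {
    stop(sprintf(
      "no common defined range for group %s: length %d, need at least %d",
      matrix$group, L, 2L * nmax + 1L
    ), call. = FALSE)
  }
  rng <- (nmax + 1L):(L - nmax)
  s <- matrix$scores[, rng, drop = FALSE]
  npos <- colSums(s > 0)
  nneg <- colSums(s < 0)
  # decisive positions flip the state; indecisive ones hold it
  decision <- ifelse(npos >= 4L, "POSITIVE", ifelse(nneg >= 4L, "NEGATIVE", NA))
  states <- character(length(rng))
  cur <- "NEGATIVE"
  for (t in seq_along(rng)) {
    if (!is.na(decision[t])) cur <- decision[t]
    states[t] <- cur
  }
  structure(
    list(sequence_id = matrix$sequence_id, group = matrix$group,
         start = rng[1], end = rng[length(rng)], states = states),
    class = "hpp_consensus"
  )
}

#' Call hydrophobic pulses from a consensus track
#'
#' A hydrophobic pulse is the first position of each maximal run of POSITIVE
#' consensus states. Positions are reported in 1-based sequence coordinates.
#'
#' @param consensus An `hpp_consensus` object.
#' @return An object of class `hpp_pulses`: list with `sequence_id`, `group`,
#'   `pulses` (strictly increasing integer vector, possibly empty) and the
#'   `consensus` it was derived from.
#' @export
call_pulses <- function(consensus) {
  if (!inherits(consensus, "hpp_consensus")) {
    stop("call_pulses() expects an 'hpp_consensus' object", call. = FALSE)
  }
  st <- consensus$states
  is_p <- st == "POSITIVE"
  run_start <- is_p & !c(FALSE, is_p[-length(is_p)])
  pulses <- consensus$start + which(run_start) - 1L
  structure(
    list(sequence_id = consensus$sequence_id, group = consensus$group,
         pulses = as.integer(pulses), consensus = consensus),
    class = "hpp_pulses"
  )
}

#' Detect hydrophobic pulses in a sequence
#'
#' Full chain: score_matrix -> sign_consensus -> call_pulses. Deterministic
#' for a fixed sequence and group.
#'
#' @param seq Residue string.
#' @param group `"G1"` (small structural events) or `"G2"` (whole
#'   transmembrane helices).
#' @param sequence_id Identifier carried through to results.
#' @return An `hpp_pulses` object; `$pulses` holds 1-based pulse positions.
#' @examples
#' fx <- make_block_sequence(list(c("R", 12), c("I", 20), c("R", 12)))
#' detect_hpulses(fx, "G2")$pulses
#' @export
detect_hpulses <- function(seq, group = c("G1", "G2"), sequence_id = "seq") {
  group <- match.arg(group)
  m <- score_matrix(seq, group, sequence_id = sequence_id)
  p <- call_pulses(sign_consensus(m))
  p$scores <- m
  p
}

#' @export
print.hpp_pulses <- function(x, ...) {
  cat(sprintf("<hpp_pulses> %s, group %s: %d pulse(s)%s\n",
              x$sequence_id, x$group, length(x$pulses),
              if (length(x$pulses)) paste0(" at ", paste(x$pulses, collapse = ", ")) else ""))
  invisible(x)
}
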