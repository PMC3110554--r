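#' Specification of a synthetic membrane-protein fixture
#'
#' Defaults describe a clean 4-helix bundle: 21-residue transmembrane
#' segments (the length of a straight helix perpendicular to the membrane
#' plane), 15-residue polar loops, helices extending 2 residues beyond each
#' TMS into the loops, strongly separated hydrophobic/polar alphabets, no
#' boundary jitter.
#'
#' @param n_tmh Number of transmembrane helices.
#' @param tms_length TMS length in residues (default 21).
#' @param loop_length Loop length in residues (default 15).
#' @param helix_flank Residues of helix extending past each TMS end
#'   (default 2), so TMH extremities A/D differ from TMS bounds B/C.
#' @param hydrophobic,polar Disjoint residue alphabets; the hydrophobic
#'   alphabet must have the higher mean KD value.
#' @param interfacial Insert one 8-residue interfacial helix (annotated
#'   helical, moderately hydrophobic composition) at the centre of each
#'   interior loop.
#' @param jitter Maximum absolute offset applied to each TMS boundary.
#' @param seed Integer RNG seed; identical seeds give identical fixtures.
#' @return List of class `fixture_spec`.
#' @export
tm_fixture_spec <- function(n_tmh = 4, tms_length = 21, loop_length = 15,
                            helix_flank = 2,
                            hydrophobic = c("I", "L", "V", "F"),
                            polar = c("R", "K", "D", "Q", "S"),
                            interfacial = FALSE, jitter = 0, seed = 1) {
  if (n_tmh < 1 || tms_length < 1 || loop_length < 1) {
    stop("n_tmh, tms_length and loop_length must be positive", call. = FALSE)
  }
  if (mean(kyte_doolittle[hydrophobic]) <= mean(kyte_doolittle[polar])) {
    stop("hydrophobic alphabet must have higher mean KD than the polar one",
         call. = FALSE)
  }
  structure(list(n_tmh = as.integer(n_tmh), tms_length = as.integer(tms_length),
                 loop_length = as.integer(loop_length),
                 helix_flank = as.integer(helix_flank),
                 hydrophobic = hydrophobic, polar = polar,
                 interfacial = isTRUE(interfacial),
                 jitter = as.integer(jitter), seed = as.integer(seed)),
            class = "fixture_spec")
}

# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Concatenate residue blocks into a sequence
#'
#' @param blocks List of `c(residue, length)` pairs (length coercible to
#'   integer), e.g. `list(c("R", 12), c("I", 20), c("R", 12))`.
#' @return Residue string.
#' @export
make_block_sequence <- function(blocks) {
  if (length(blocks) == 0L) stop("empty block list", call. = FALSE)
  parts <- vapply(blocks, function(b) {
    res <- as.character(b[[1]])
    len <- as.integer(b[[2]])
    if (!res %in% names(kyte_doolittle)) {
      stop(sprintf("non-canonical residue '%s' in block", res), call. = FALSE)
    }
    if (is.na(len) || len < 1L) stop("block length must be positive", call. = FALSE)
    strrep(res, len)
  }, character(1))
  paste(parts, collapse = "")
}

#' Generate a synthetic membrane protein with ground truth
#'
#' Renders alternating polar loops and hydrophobic TMS blocks
#' (`loop (tms loop) x n_tmh`), with residues drawn uniformly from the
#' spec's alphabets under a locally seeded RNG. The annotation marks each
#' TMS block in-membrane and helical, with the helix extended `helix_flank`
#' residues into the flanking loops; optional interfacial helices are
#' annotated helical only. The truth table records every planted event.
#'
#' @param spec A [tm_fixture_spec()] (or arguments passed through `...`).
#' @param ... Convenience overrides forwarded to [tm_fixture_spec()] when
#'   `spec` is missing.
#' @return List with `sequence`, `annotation` (a `membrane_annotation`),
#'   `truth` (data frame: kind, position; kinds `tms_begin`, `tms_end`,
#'   `helix_begin`, `helix_end`) and `spec`.
#' @export
make_tm_protein <- function(spec = tm_fixture_spec(...), ...) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_local_seed(spec$seed, {
    # jittered TMS bounds inside the nominal alternating layout
    bounds <- list()
    pos <- 0L
    for (i in seq_len(spec$n_tmh)) {
      b <- pos + spec$loop_length + 1L
      c_ <- b + spec$tms_length - 1L
      if (spec$jitter > 0L) {
        b <- b + sample(-spec$jitter:spec$jitter, 1L)
        c_ <- c_ + sample(-spec$jitter:spec$jitter, 1L)
      }
      bounds[[i]] <- c(b, c_)
      pos <- pos + spec$loop_length + spec$tms_length
    }
    L <- pos + spec$loop_length
    in_mem <- rep(FALSE, L)
    for (bc in bounds) in_mem[bc[1]:bc[2]] <- TRUE
    helical <- rep(FALSE, L)
    truth <- data.frame(kind = character(), position = integer())
    for (bc in bounds) {
      a <- max(1L, bc[1] - spec$helix_flank)
      d <- min(L, bc[2] + spec$helix_flank)
      helical[a:d] <- TRUE
      truth <- rbind(truth, data.frame(
        kind = c("tms_begin", "tms_end", "helix_begin", "helix_end"),
        position = c(bc[1], bc[2], a, d)))
    }
    seq_res <- ifelse(in_mem,
                      sample(spec$hydrophobic, L, replace = TRUE),
                      sample(spec$polar, L, replace = TRUE))
    if (spec$interfacial && spec$n_tmh >= 2L && spec$loop_length >= 12L) {
      ifl_alpha <- c("A", "L", "W", "S")  # amphipathic-ish composition
      for (i in seq_len(spec$n_tmh - 1L)) {
        gap_lo <- bounds[[i]][2] + spec$helix_flank + 2L
        gap_hi <- bounds[[i + 1L]][1] - spec$helix_flank - 2L
        mid <- (gap_lo + gap_hi) %/% 2L
        s <- mid - 4L; e <- mid + 3L
        if (s > gap_lo && e < gap_hi) {
          helical[s:e] <- TRUE
          seq_res[s:e] <- sample(ifl_alpha, 8L, replace = TRUE)
          truth <- rbind(truth, data.frame(
            kind = c("helix_begin", "helix_end"), position = c(s, e)))
        }
      }
    }
    list(sequence = paste(seq_res, collapse = ""),
         annotation = membrane_annotation(helical, in_mem,
                                          sequence_id = sprintf("synthetic_tm%d_seed%d",
                                                                spec$n_tmh, spec$seed)),
         truth = truth[order(truth$position), , drop = FALSE],
         spec = spec)
  })
}
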