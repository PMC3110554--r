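#' Landmark frames of transmembrane helices
#'
#' For each transmembrane segment (TMS) `[B;C]` of the annotation, the
#' transmembrane helix (TMH) `[A;D]` is the smallest interval covering all
#' helices that intersect the TMS; a TMH may thus contain more than one
#' alpha-helix. A TMS intersected by no helix is flagged `helix_less` and is
#' excluded from pair analyses.
#'
#' @param annotation A `membrane_annotation` with at least one TMS.
#' @return Data frame with columns `tms` (index), `A`, `B`, `C`, `D`,
#'   `helix_less`, ordered by `B`.
#' @export
derive_landmarks <- function(annotation) {
  stopifnot(inherits(annotation, "membrane_annotation"))
  tms <- annotation$tms
  if (nrow(tms) == 0L) {
    stop("annotation contains no transmembrane segment", call. = FALSE)
  }
  hel <- annotation$helices
  out <- data.frame(tms = seq_len(nrow(tms)),
                    A = NA_integer_, B = tms$start, C = tms$end,
                    D = NA_integer_, helix_less = FALSE)
  for (i in seq_len(nrow(tms))) {
    hit <- hel$start <= tms$end[i] & hel$end >= tms$start[i]
    if (!any(hit)) {
      out$helix_less[i] <- TRUE
    } else {
      out$A[i] <- min(hel$start[hit])
      out$D[i] <- max(hel$end[hit])
    }
  }
  out[order(out$B), , drop = FALSE]
}

#' Successive TMH pairs passing the analysis criteria
#'
#' Pairs consecutive landmark frames (first TMH `A..D`, next TMH `E..H` with
#' TMS `F..G`). A pair is included when the lengths of `[C;D]` and `[E;F]`
#' are strictly positive and the length of `[D;E]` (the inter-helix span) is
#' smaller than `max_loop`. Interval length is `end - start`. Each included
#' pair carries its analysis span from the midpoint of `[B;C]` to the
#' midpoint of `[F;G]` (midpoint = floor of the interval mean). Helix-less
#' frames never pair.
#'
#' @param frames Output of [derive_landmarks()].
#' @param max_loop Maximum `[D;E]` length in residues (default 40).
#' @return Data frame with columns `A`..`H`, `span_start`, `span_end`,
#'   `included`, `fail_reason`.
#' @export
successive_pairs <- function(frames, max_loop = 40) {
  fr <- frames[!frames$helix_less, , drop = FALSE]
  if (nrow(fr) < 2L) {
    return(data.frame(A = integer(), B = integer(), C = integer(),
                      D = integer(), E = integer(), F = integer(),
                      G = integer(), H = integer(),
                      span_start = integer(), span_end = integer(),
                      included = logical(), fail_reason = character()))
  }
  idx <- seq_len(nrow(fr) - 1L)
  out <- data.frame(
    A = fr$A[idx], B = fr$B[idx], C = fr$C[idx], D = fr$D[idx],
    E = fr$A[idx + 1L], F = fr$B[idx + 1L], G = fr$C[idx + 1L],
    H = fr$D[idx + 1L]
  )
  out$span_start <- (out$B + out$C) %/% 2L
  out$span_end <- (out$F + out$G) %/% 2L
  reason <- character(nrow(out))
  reason[out$D - out$C <= 0L] <- "len[C;D] not strictly positive"
  reason[out$F - out$E <= 0L] <- "len[E;F] not strictly positive"
  reason[out$E - out$D >= max_loop] <- sprintf("len[D;E] >= %d", max_loop)
  reason[out$E <= out$D] <- "frames overlap (D >= E)"
  out$included <- reason == ""
  out$fail_reason <- reason
  out
}

#' Localize G2 pulses within successive-TMH frames
#'
#' Classifies each G2 pulse falling in a pair's analysis span into one of the
#' loci `TMS`, `[C;D]`, `[D;E]`, `[E;F]`. Loci are mutually exclusive:
#' interval membership uses `[C;D)`, `[D;E)`, `[E;F]`, so position `E`
#' belongs to `[E;F]`; positions inside `[B;C]` or `[F;G]` are `TMS`. When a
#' pair holds more than one pulse strictly between C and F, the one closest
#' to `E` is selected (ties break toward the earlier position) and the
#' surplus is counted as discarded. The summary reports, per interval, the
#' residue fraction and the (selected-)pulse fraction of everything between
#' C and F.
#'
#' @param pairs Output of [successive_pairs()]; only included rows are used.
#' @param g2 An `hpp_pulses` object (group G2) or an integer pulse vector.
#' @return List with `per_pulse` (pair, pulse, locus, selected),
#'   `per_pair` (locus of the selected pulse, or `"none"`/`"TMS"`), and
#'   `summary` (interval, residues, residue_pct, pulses, pulse_pct), plus
#'   counts `n_discarded`, `n_tms`, `n_none`.
#' @export
localize_g2 <- function(pairs, g2) {
  pulses <- pulse_positions(g2)
  pr <- pairs[pairs$included, , drop = FALSE]
  per_pulse <- data.frame(pair = integer(), pulse = integer(),
                          locus = character(), selected = logical())
  per_pair <- data.frame(pair = integer(), locus = character(),
                         pulse = integer())
  res_cnt <- c("[C;D]" = 0L, "[D;E]" = 0L, "[E;F]" = 0L)
  pulse_cnt <- c("[C;D]" = 0L, "[D;E]" = 0L, "[E;F]" = 0L)
  n_discarded <- 0L; n_tms <- 0L; n_none <- 0L
  for (i in seq_len(nrow(pr))) {
    p <- pr[i, ]
    res_cnt["[C;D]"] <- res_cnt["[C;D]"] + (p$D - p$C)
    res_cnt["[D;E]"] <- res_cnt["[D;E]"] + (p$E - p$D)
    res_cnt["[E;F]"] <- res_cnt["[E;F]"] + (p$F - p$E + 1L)
    span <- pulses[pulses >= p$span_start & pulses <= p$span_end]
    if (length(span) == 0L) {
      n_none <- n_none + 1L
      per_pair <- rbind(per_pair, data.frame(pair = i, locus = "none",
                                             pulse = NA_integer_))
      next
    }
    locus <- vapply(span, function(x) {
      if ((x >= p$B && x <= p$C) || (x >= p$F && x <= p$G)) "TMS"
      else if (x >= p$C && x < p$D) "[C;D]"
      else if (x >= p$D && x < p$E) "[D;E]"
      else if (x >= p$E && x <= p$F) "[E;F]"
      else "none"
    }, character(1))
    in_cf <- locus %in% c("[C;D]", "[D;E]", "[E;F]")
    selected <- rep(FALSE, length(span))
    if (any(in_cf)) {
      cand <- which(in_cf)
      d <- abs(span[cand] - p$E)
      pick <- cand[order(d, span[cand])][1]
      selected[pick] <- TRUE
      n_discarded <- n_discarded + (sum(in_cf) - 1L)
      pulse_cnt[locus[pick]] <- pulse_cnt[locus[pick]] + 1L
      per_pair <- rbind(per_pair, data.frame(pair = i, locus = locus[pick],
                                             pulse = span[pick]))
    } else if (any(locus == "TMS")) {
      n_tms <- n_tms + 1L
      k <- which(locus == "TMS")[1]
      per_pair <- rbind(per_pair, data.frame(pair = i, locus = "TMS",
                                             pulse = span[k]))
    } else {
      n_none <- n_none + 1L
      per_pair <- rbind(per_pair, data.frame(pair = i, locus = "none",
                                             pulse = NA_integer_))
    }
    per_pulse <- rbind(per_pulse, data.frame(pair = i, pulse = span,
                                             locus = locus,
                                             selected = selected))
  }
  tot_res <- sum(res_cnt); tot_pulse <- sum(pulse_cnt)
  summary <- data.frame(
    interval = names(res_cnt),
    residues = as.integer(res_cnt),
    residue_pct = if (tot_res > 0) 100 * res_cnt / tot_res else rep(NA_real_, 3),
    pulses = as.integer(pulse_cnt),
    pulse_pct = if (tot_pulse > 0) 100 * pulse_cnt / tot_pulse else rep(NA_real_, 3),
    row.names = NULL
  )
  list(per_pulse = per_pulse, per_pair = per_pair, summary = summary,
       n_discarded = n_discarded, n_tms = n_tms, n_none = n_none)
}

#' Segment a sequence into transmembrane units (TMUs)
#'
#' A TMU is the interval between two consecutive G2 pulses (or a pulse and a
#' region end): the analysis region is cut at every pulse, each pulse opening
#' a new unit. Helices are assigned to the TMU containing their start. TMUs
#' tile the region without gaps or overlaps.
#'
#' @param g2 An `hpp_pulses` object (group G2) or an integer pulse vector.
#' @param annotation Optional `membrane_annotation` used to assign helices.
#' @param region Integer `c(start, end)`; defaults to the annotation's span,
#'   or to `range(pulses)` padded when no annotation is given.
#' @return Data frame with columns `start`, `end`, `n_helices`, and a list
#'   column `helices` of helix indices (rows of `annotation$helices`).
#' @export
segment_tmus <- function(g2, annotation = NULL, region = NULL) {
  pulses <- pulse_positions(g2)
  if (is.null(region)) {
    if (!is.null(annotation)) region <- c(1L, annotation$length)
    else if (length(pulses)) region <- c(1L, max(pulses) + 1L)
    else stop("no annotation, pulses or region to delimit TMUs", call. = FALSE)
  }
  p <- sort(pulses[pulses > region[1] & pulses <= region[2]])
  starts <- c(region[1], p)
  ends <- c(p - 1L, region[2])
  tmu <- data.frame(start = as.integer(starts), end = as.integer(ends))
  members <- vector("list", nrow(tmu))
  if (!is.null(annotation)) {
    hel <- annotation$helices
    for (i in seq_len(nrow(tmu))) {
      members[[i]] <- which(hel$start >= tmu$start[i] & hel$start <= tmu$end[i])
    }
  }
  tmu$n_helices <- vapply(members, length, integer(1))
  tmu$helices <- I(members)
  tmu
}

#' Pulses between consecutive TMHs versus interleaved helices
#'
#' For each included successive-TMH pair, counts the G2 pulses in `[D;E)` and
#' the helices lying strictly inside `(D;E)`, and cross-tabulates pulse count
#' (0, 1, 2, >2) against helix presence (none, one, more than one).
#'
#' @param pairs Output of [successive_pairs()].
#' @param g2 An `hpp_pulses` object or integer pulse vector.
#' @param annotation A `membrane_annotation`.
#' @return Integer matrix, rows `0`,`1`,`2`,`>2`, columns `no_helix`,
#'   `one_helix`, `multi_helix`.
#' @export
count_pulses_between_tmhs <- function(pairs, g2, annotation) {
  pulses <- pulse_positions(g2)
  pr <- pairs[pairs$included, , drop = FALSE]
  tab <- matrix(0L, nrow = 4L, ncol = 3L,
                dimnames = list(c("0", "1", "2", ">2"),
                                c("no_helix", "one_helix", "multi_helix")))
  hel <- annotation$helices
  for (i in seq_len(nrow(pr))) {
    p <- pr[i, ]
    np <- sum(pulses >= p$D & pulses < p$E)
    nh <- sum(hel$start > p$D & hel$end < p$E)
    ri <- if (np > 2L) 4L else np + 1L
    ci <- if (nh == 0L) 1L else if (nh == 1L) 2L else 3L
    tab[ri, ci] <- tab[ri, ci] + 1L
  }
  tab
}

#' Association between pulses and helicity, by membrane context
#'
#' Splits residues into a TM context (within `flank` residues of any TMS) and
#' a non-TM context, tabulates pulse positions and residues by helical state
#' in each context, and tests whether the pulse distribution over
#' helical/non-helical residues differs from the residue distribution
#' (chi-square goodness of fit of pulse counts against residue-proportional
#' expectations, one per context).
#'
#' @param pulses An `hpp_pulses` object or integer pulse vector.
#' @param annotation A `membrane_annotation`.
#' @param flank TM-context half-width in residues (default 40).
#' @return List with `counts` (data frame: context, helical, pulses,
#'   pulse_pct, residues, residue_pct) and `p_values` (named numeric,
#'   `TM` and `non_TM`; `NA` where undefined).
#' @export
context_association <- function(pulses, annotation, flank = 40) {
  pulses <- pulse_positions(pulses)
  L <- annotation$length
  tm_ctx <- rep(FALSE, L)
  for (i in seq_len(nrow(annotation$tms))) {
    lo <- max(1L, annotation$tms$start[i] - flank)
    hi <- min(L, annotation$tms$end[i] + flank)
    tm_ctx[lo:hi] <- TRUE
  }
  hel <- annotation$helical
  res <- data.frame()
  pvals <- c(TM = NA_real_, non_TM = NA_real_)
  for (ctx in c(TRUE, FALSE)) {
    name <- if (ctx) "TM" else "non_TM"
    in_ctx <- tm_ctx == ctx
    n_res <- c(sum(in_ctx & hel), sum(in_ctx & !hel))
    pl <- pulses[in_ctx[pulses]]
    n_pul <- c(sum(hel[pl]), sum(!hel[pl]))
    res <- rbind(res, data.frame(
      context = name, helical = c(TRUE, FALSE),
      pulses = n_pul,
      pulse_pct = if (sum(n_pul) > 0) 100 * n_pul / sum(n_pul) else NA_real_,
      residues = n_res,
      residue_pct = if (sum(n_res) > 0) 100 * n_res / sum(n_res) else NA_real_
    ))
    if (sum(n_pul) > 0 && all(n_res > 0)) {
      pvals[name] <- suppressWarnings(
        stats::chisq.test(n_pul, p = n_res / sum(n_res))$p.value
      )
    }
  }
  list(counts = res, p_values = pvals)
}

#' Classic Kyte-Doolittle sliding-window hydropathy
#'
#' Centered mean of KD hydropathies over a window (default 19 residues);
#' a region "has a peak" when any in-window average exceeds the threshold
#' (default 1.6), the classic criterion for calling a TMS.
#'
#' @param seq Residue string.
#' @param window Odd window width in residues.
#' @param threshold Peak-calling threshold in KD units.
#' @return Object of class `hpp_kd`: list with `average` (numeric, length L,
#'   `NA` where the window does not fit), `window`, `threshold`.
#' @export
kd_classic <- function(seq, window = 19, threshold = 1.6) {
  r <- seq_residues(seq)
  if (length(r) < window) {
    stop(sprintf("sequence length %d is shorter than the %d-residue window",
                 length(r), window), call. = FALSE)
  }
  if (window %% 2L == 0L) stop("window must be odd", call. = FALSE)
  kd <- kd_value(r, seq_along(r))
  avg <- as.numeric(stats::filter(kd, rep(1 / window, window), sides = 2))
  structure(list(average = avg, window = window, threshold = threshold),
            class = "hpp_kd")
}

#' Does a region contain a KD hydrophobic peak?
#'
#' @param kd An `hpp_kd` object.
#' @param start,end 1-based region bounds (inclusive).
#' @return Logical: any defined in-region average above the threshold.
#' @export
kd_has_peak <- function(kd, start, end) {
  stopifnot(inherits(kd, "hpp_kd"))
  any(kd$average[start:end] > kd$threshold, na.rm = TRUE)
}

#' G2 rescue of TMS missed by the classic KD criterion
#'
#' For every TMS lacking a KD hydrophobic peak, reports whether a G2 pulse
#' lies between the end of the preceding TMS (exclusive; sequence start for
#' the first TMS) and this TMS's end (inclusive) — i.e. whether the missed
#' segment is still correctly preceded by a pulse.
#'
#' @param annotation A `membrane_annotation`.
#' @param kd_result An `hpp_kd` object for the same sequence.
#' @param g2 An `hpp_pulses` object or integer pulse vector.
#' @return Data frame with columns `tms`, `B`, `C`, `peaked`, `rescued`
#'   (`NA` for peaked TMS).
#' @export
undetected_tms_rescue <- function(annotation, kd_result, g2) {
  pulses <- pulse_positions(g2)
  tms <- annotation$tms
  out <- data.frame(tms = seq_len(nrow(tms)), B = tms$start, C = tms$end,
                    peaked = NA, rescued = NA)
  for (i in seq_len(nrow(tms))) {
    out$peaked[i] <- kd_has_peak(kd_result, tms$start[i], tms$end[i])
    if (!out$peaked[i]) {
      prev_end <- if (i > 1L) tms$end[i - 1L] else 0L
      out$rescued[i] <- any(pulses > prev_end & pulses <= tms$end[i])
    }
  }
  out
}

# Accept either an hpp_pulses object or a bare integer vector of positions.
pulse_positions <- function(x) {
  if (inherits(x, "hpp_pulses")) return(x$pulses)
  as.integer(sort(x))
}
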