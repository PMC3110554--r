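#' Helix extremities in or near the membrane
#'
#' Returns extremity positions of helices whose distance to the closest TMS
#' does not exceed `flank` residues (a helix is "in or near the membrane").
#'
#' @param annotation A `membrane_annotation`.
#' @param kind `"begin"`, `"end"` or `"both"`.
#' @param flank Maximum helix-to-TMS distance in residues (default 40).
#' @return Sorted integer vector of extremity positions.
#' @export
membrane_helix_extremities <- function(annotation, kind = c("begin", "end", "both"),
                                       flank = 40) {
  kind <- match.arg(kind)
  hel <- annotation$helices
  tms <- annotation$tms
  if (nrow(tms) == 0L) return(integer())
  keep <- vapply(seq_len(nrow(hel)), function(i) {
    d <- pmax(tms$start - hel$end[i], hel$start[i] - tms$end, 0L)
    min(d) <= flank
  }, logical(1))
  h <- hel[keep, , drop = FALSE]
  out <- switch(kind, begin = h$start, end = h$end, both = c(h$start, h$end))
  sort(as.integer(out))
}

#' Assign the closest pulse to each extremity
#'
#' Greedy globally-nearest one-to-one matching: the (extremity, pulse) pair
#' with the smallest absolute signed distance (pulse - extremity) is taken
#' first, both items are retired, and the process repeats. Ties on |distance|
#' prefer the upstream pulse (negative distance), then the earlier pulse,
#' then the earlier extremity, so the result does not depend on input order.
#' Every extremity receives a pulse when pulses are at least as numerous.
#'
#' @param extremities Integer vector of 1-based positions.
#' @param pulses An `hpp_pulses` object or integer pulse vector.
#' @return List with `assignments` (data frame: extremity, pulse, distance,
#'   ordered by extremity; `pulse`/`distance` are `NA` when pulses ran out)
#'   and `histogram` (table of signed distances).
#' @export
assign_closest_pulses <- function(extremities, pulses) {
  ext <- sort(unique(as.integer(extremities)))
  pul <- sort(unique(pulse_positions(pulses)))
  asg <- data.frame(extremity = ext, pulse = NA_integer_,
                    distance = NA_integer_)
  if (length(pul) > 0L && length(ext) > 0L) {
    free_e <- rep(TRUE, length(ext))
    free_p <- rep(TRUE, length(pul))
    d <- outer(ext, pul, function(e, p) p - e)
    repeat {
      if (!any(free_e) || !any(free_p)) break
      dd <- abs(d)
      dd[!free_e, ] <- Inf
      dd[, !free_p] <- Inf
      m <- min(dd)
      if (!is.finite(m)) break
      cand <- which(dd == m, arr.ind = TRUE)
      # ties: upstream pulse first, then earlier pulse, then earlier extremity
      sgn <- d[cand]
      ord <- order(sgn >= 0, pul[cand[, 2]], ext[cand[, 1]])
      pick <- cand[ord[1], , drop = FALSE]
      ei <- pick[1, 1]; pi <- pick[1, 2]
      asg$pulse[ei] <- pul[pi]
      asg$distance[ei] <- d[ei, pi]
      free_e[ei] <- FALSE
      free_p[pi] <- FALSE
    }
  }
  hist <- table(asg$distance[!is.na(asg$distance)])
  list(assignments = asg, histogram = hist)
}

#' Match pulses to structural events within a tolerance
#'
#' Compares each pulse to five event kinds — helix begin/end, TMS begin/end,
#' kink — and classifies it as matched to the nearest event within the
#' tolerance, or unmatched. Equal-distance ties rank helix extremities over
#' TMS extremities over kinks (begin before end within a kind).
#'
#' @param g1 An `hpp_pulses` object or integer pulse vector.
#' @param annotation A `membrane_annotation` (kinks optional).
#' @param tolerance Maximum |pulse - event| in residues (default 3).
#' @return List with `per_pulse` (pulse, kind, event, distance; kind
#'   `"unmatched"` where no event is within tolerance), `matched_fraction`,
#'   and `kind_fractions` (percent of matched pulses per event family:
#'   helix extremity, TMS extremity, kink).
#' @export
match_events <- function(g1, annotation, tolerance = 3) {
  pulses <- pulse_positions(g1)
  ev <- rbind(
    data.frame(kind = "helix_begin", position = annotation$helices$start),
    data.frame(kind = "helix_end",   position = annotation$helices$end),
    data.frame(kind = "tms_begin",   position = annotation$tms$start),
    data.frame(kind = "tms_end",     position = annotation$tms$end),
    if (length(annotation$kinks))
      data.frame(kind = "kink", position = annotation$kinks)
  )
  rank <- c(helix_begin = 1L, helix_end = 2L, tms_begin = 3L,
            tms_end = 4L, kink = 5L)
  per <- data.frame(pulse = pulses, kind = "unmatched",
                    event = NA_integer_, distance = NA_integer_)
  for (i in seq_along(pulses)) {
    d <- ev$position - pulses[i]
    ok <- which(abs(d) <= tolerance)
    if (length(ok) == 0L) next
    ord <- ok[order(abs(d[ok]), rank[ev$kind[ok]], ev$position[ok])]
    per$kind[i] <- ev$kind[ord[1]]
    per$event[i] <- ev$position[ord[1]]
    per$distance[i] <- d[ord[1]]
  }
  matched <- per$kind != "unmatched"
  fam <- c(helix_begin = "helix", helix_end = "helix",
           tms_begin = "tms", tms_end = "tms", kink = "kink")
  kf <- c(helix = 0, tms = 0, kink = 0)
  if (any(matched)) {
    t <- table(fam[per$kind[matched]])
    kf[names(t)] <- 100 * as.numeric(t) / sum(matched)
  }
  list(per_pulse = per,
       matched_fraction = if (length(pulses)) mean(matched) else NA_real_,
       kind_fractions = kf)
}

#' Prolines and pulses in the vicinity of kinks
#'
#' Counts the prolines of the sequence and the G1 pulses lying within
#' `tolerance` residues of any kink; each proline/pulse is counted once.
#'
#' @param seq Residue string.
#' @param kinks Integer vector of kink positions.
#' @param g1 An `hpp_pulses` object or integer pulse vector.
#' @param tolerance Maximum distance in residues (default 3).
#' @return List: `n_kinks`, `n_prolines`, `prolines_near_kinks`,
#'   `n_pulses`, `pulses_near_kinks`.
#' @export
proline_kink_stats <- function(seq, kinks, g1, tolerance = 3) {
  r <- seq_residues(seq)
  pulses <- pulse_positions(g1)
  kinks <- as.integer(kinks)
  pro <- which(r == "P")
  near <- function(x) {
    if (length(kinks) == 0L) return(logical(length(x)))
    vapply(x, function(p) any(abs(kinks - p) <= tolerance), logical(1))
  }
  if (length(kinks) == 0L) {
    message("proline_kink_stats: empty kink list, all counts are zero")
  }
  list(n_kinks = length(kinks),
       n_prolines = length(pro), prolines_near_kinks = sum(near(pro)),
       n_pulses = length(pulses), pulses_near_kinks = sum(near(pulses)))
}

# Group sorted start positions into rows: a start opens a new row when it
# exceeds the current row's minimum by more than `radius`. A row may hold at
# most one start per structure; a cluster violating this is split at its
# largest internal gap (recursively), since two starts of one structure are
# necessarily two distinct sub-helices.
group_start_rows <- function(starts, structure_id = NULL, radius = 6) {
  ord <- order(starts)
  s <- starts[ord]
  sid <- if (is.null(structure_id)) seq_along(starts) else
    as.character(structure_id)[ord]
  grp <- integer(length(s))
  cur <- 0L; cur_min <- -Inf
  for (i in seq_along(s)) {
    if (s[i] - cur_min > radius) {
      cur <- cur + 1L
      cur_min <- s[i]
    }
    grp[i] <- cur
  }
  if (!is.null(structure_id)) {
    repeat {
      changed <- FALSE
      for (g in unique(grp)) {
        idx <- which(grp == g)
        if (length(idx) > 1L && anyDuplicated(sid[idx])) {
          gaps <- diff(s[idx])
          cut <- which.max(gaps)  # earliest largest gap
          grp[idx[(cut + 1L):length(idx)]] <- max(grp) + 1L
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  # renumber groups by ascending minimum position
  mins <- tapply(s, grp, min)
  grp <- as.integer(factor(as.character(grp), levels = names(sort(mins))))
  out <- integer(length(starts))
  out[ord] <- grp
  out
}

# Order-preserving one-to-one matching of rows to pulses: maximize the number
# of matched pairs with |distance| <= radius, then minimize the total
# distance. Both lists are positional, so crossings are never meaningful.
monotone_match <- function(row_members, pulses, radius) {
  R <- length(row_members); P <- length(pulses)
  cost <- matrix(Inf, R, P)
  for (r in seq_len(R)) {
    cost[r, ] <- vapply(pulses, function(p) min(abs(row_members[[r]] - p)),
                        numeric(1))
  }
  cost[cost > radius] <- Inf
  # dp over prefixes: value = pairs * BIG - total distance (maximize)
  BIG <- 1e6
  f <- matrix(0, R + 1L, P + 1L)
  for (r in seq_len(R)) for (p in seq_len(P)) {
    v <- max(f[r, p + 1L], f[r + 1L, p])
    if (is.finite(cost[r, p])) v <- max(v, f[r, p] + BIG - cost[r, p])
    f[r + 1L, p + 1L] <- v
  }
  match_p <- rep(NA_integer_, R)
  r <- R; p <- P
  while (r > 0L && p > 0L) {
    if (is.finite(cost[r, p]) &&
        f[r + 1L, p + 1L] == f[r, p] + BIG - cost[r, p]) {
      match_p[r] <- p; r <- r - 1L; p <- p - 1L
    } else if (f[r + 1L, p + 1L] == f[r, p + 1L]) {
      r <- r - 1L
    } else {
      p <- p - 1L
    }
  }
  match_p
}

#' Multi-conformation sub-helix start report
#'
#' Aligns sub-helix start positions reported for several structures
#' (conformations) of one protein into rows (starts within `group_radius` of
#' a row's first start share the row), then pairs each row with a G1 pulse by
#' greedy injective nearest matching within `pairing_radius` (row-to-pulse
#' distance = minimum over the row's member starts; each pulse serves at most
#' one row). Reports which rows are populated in every structure, which are
#' pulse-associated, and the pulse false-positive fraction per structure and
#' over all conformations (a pulse paired with no row at all).
#'
#' @param starts Data frame with columns `structure_id` and `start`
#'   (1-based sub-helix start positions, one row per observation).
#' @param pulses Integer vector (or `hpp_pulses`) of G1 pulse positions; if
#'   `NULL`, computed from `seq` with [detect_hpulses()].
#' @param seq Optional residue string used when `pulses` is `NULL`.
#' @param group_radius Row-grouping radius in residues (default 6).
#' @param pairing_radius Maximum row-to-pulse pairing distance (default 7).
#' @return List with `rows` (row_id, starts per structure as a wide data
#'   frame, present_in_all, pulse, distance), `n_rows`, `n_present_in_all`,
#'   `n_associated`, `n_pulses`, `false_positives` (named integer per
#'   structure), `fp_all_conformations`, and the fractions
#'   `associated_pct`, `fp_pct` (per structure), `fp_all_pct`.
#' @export
conformation_report <- function(starts, pulses = NULL, seq = NULL,
                                group_radius = 6, pairing_radius = 7) {
  stopifnot(is.data.frame(starts),
            all(c("structure_id", "start") %in% names(starts)))
  structures <- unique(as.character(starts$structure_id))
  if (length(structures) < 2L && is.null(pulses) && is.null(seq)) {
    stop("need start lists from >= 2 structures, or explicit pulses",
         call. = FALSE)
  }
  if (is.null(pulses)) {
    if (is.null(seq)) stop("either pulses or seq must be given", call. = FALSE)
    pulses <- detect_hpulses(seq, "G1")$pulses
  }
  pulses <- pulse_positions(pulses)
  starts$row <- group_start_rows(starts$start, starts$structure_id,
                                 radius = group_radius)
  n_rows <- max(starts$row)
  # wide table: one column per structure (first start kept if duplicated)
  wide <- data.frame(row_id = seq_len(n_rows))
  for (s in structures) {
    col <- rep(NA_integer_, n_rows)
    sub <- starts[starts$structure_id == s, ]
    for (i in seq_len(nrow(sub))) {
      if (is.na(col[sub$row[i]])) col[sub$row[i]] <- sub$start[i]
    }
    wide[[s]] <- col
  }
  wide$present_in_all <-
    rowSums(!is.na(wide[, structures, drop = FALSE])) == length(structures)
  # order-preserving injective pairing (row members vs sorted pulses)
  members <- split(starts$start, starts$row)
  members <- members[as.character(seq_len(n_rows))]
  row_pulse <- rep(NA_integer_, n_rows)
  row_dist <- rep(NA_integer_, n_rows)
  if (length(pulses) > 0L && n_rows > 0L) {
    mp <- monotone_match(members, pulses, pairing_radius)
    hit <- !is.na(mp)
    row_pulse[hit] <- pulses[mp[hit]]
    row_dist[hit] <- vapply(which(hit), function(r)
      min(abs(members[[r]] - row_pulse[r])), numeric(1))
  }
  wide$pulse <- row_pulse
  wide$distance <- row_dist
  paired_rows <- which(!is.na(row_pulse))
  fp <- vapply(structures, function(s) {
    ok_rows <- which(!is.na(wide[[s]]))
    sum(!(pulses %in% row_pulse[intersect(paired_rows, ok_rows)]))
  }, integer(1))
  fp_all <- sum(!(pulses %in% row_pulse[paired_rows]))
  n_assoc <- length(paired_rows)
  list(rows = wide, n_rows = n_rows,
       n_present_in_all = sum(wide$present_in_all),
       n_associated = n_assoc,
       n_pulses = length(pulses),
       false_positives = fp,
       fp_all_conformations = fp_all,
       associated_pct = if (n_rows) 100 * n_assoc / n_rows else NA_real_,
       fp_pct = if (length(pulses)) 100 * fp / length(pulses) else NA_real_,
       fp_all_pct = if (length(pulses)) 100 * fp_all / length(pulses) else NA_real_)
}
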