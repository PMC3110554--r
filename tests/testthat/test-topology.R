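test_that("landmark frames cover the helices intersecting each TMS", {
  ann <- two_tmh_annotation()
  lm <- derive_landmarks(ann)
  expect_identical(lm$A, c(10L, 60L))
  expect_identical(lm$B, c(15L, 65L))
  expect_identical(lm$C, c(35L, 85L))
  expect_identical(lm$D, c(40L, 90L))
  expect_false(any(lm$helix_less))

  # two helices intersecting one TMS -> smallest cover
  hel <- rep(FALSE, 50); hel[10:20] <- TRUE; hel[23:40] <- TRUE
  mem <- rep(FALSE, 50); mem[15:35] <- TRUE
  lm2 <- derive_landmarks(membrane_annotation(hel, mem))
  expect_identical(lm2$A, 10L)
  expect_identical(lm2$D, 40L)

  # helix exactly equal to its TMS -> zero-length [A;B] and [C;D]
  hel <- rep(FALSE, 50); hel[15:35] <- TRUE
  lm3 <- derive_landmarks(membrane_annotation(hel, mem))
  expect_identical(lm3$A, lm3$B)
  expect_identical(lm3$C, lm3$D)

  # TMS with no helix is flagged
  lm4 <- derive_landmarks(membrane_annotation(rep(FALSE, 50), mem))
  expect_true(lm4$helix_less)
  expect_error(derive_landmarks(membrane_annotation(hel, rep(FALSE, 50))),
               "no transmembrane segment")
})

test_that("successive pairs enforce the three inclusion criteria", {
  pairs <- successive_pairs(derive_landmarks(two_tmh_annotation()))
  expect_identical(nrow(pairs), 1L)
  expect_true(pairs$included)
  expect_identical(pairs$span_start, (15L + 35L) %/% 2L)
  expect_identical(pairs$span_end, (65L + 85L) %/% 2L)

  # loop of 45 residues between helices -> excluded by the 40-residue cap
  hel <- rep(FALSE, 160); hel[10:40] <- TRUE; hel[86:120] <- TRUE
  mem <- rep(FALSE, 160); mem[15:35] <- TRUE; mem[91:115] <- TRUE
  p2 <- successive_pairs(derive_landmarks(membrane_annotation(hel, mem)))
  expect_false(p2$included)
  expect_match(p2$fail_reason, ">= 40")

  # C = D (helix ends with its TMS) -> not strictly positive
  hel <- rep(FALSE, 100); hel[10:35] <- TRUE; hel[60:90] <- TRUE
  mem <- rep(FALSE, 100); mem[15:35] <- TRUE; mem[65:85] <- TRUE
  p3 <- successive_pairs(derive_landmarks(membrane_annotation(hel, mem)))
  expect_false(p3$included)
  expect_match(p3$fail_reason, "C;D")
})

test_that("G2 pulses are localized into mutually exclusive intervals", {
  pairs <- successive_pairs(derive_landmarks(two_tmh_annotation()))
  # frame: C=35 D=40 E=60 F=65

  # pulse exactly at E belongs to [E;F]
  locE <- localize_g2(pairs, 60L)
  expect_identical(locE$per_pair$locus, "[E;F]")

  # no pulse in span -> none
  loc0 <- localize_g2(pairs, integer())
  expect_identical(loc0$per_pair$locus, "none")
  expect_identical(loc0$n_none, 1L)

  # one mid-loop pulse -> [D;E], pulse fractions 0/100/0
  loc1 <- localize_g2(pairs, 50L)
  expect_identical(loc1$per_pair$locus, "[D;E]")
  expect_equal(loc1$summary$pulse_pct, c(0, 100, 0))
  expect_equal(sum(loc1$summary$residue_pct), 100)

  # surplus pulses in [C;F]: keep the one closest to E, count the discard
  loc2 <- localize_g2(pairs, c(45L, 59L))
  expect_identical(loc2$per_pair$pulse, 59L)
  expect_identical(loc2$n_discarded, 1L)

  # boundary conventions: C -> TMS side, D -> [D;E]
  expect_identical(localize_g2(pairs, 35L)$per_pair$locus, "TMS")
  expect_identical(localize_g2(pairs, 40L)$per_pair$locus, "[D;E]")
  expect_identical(localize_g2(pairs, 39L)$per_pair$locus, "[C;D]")
})

test_that("TMUs tile the region for any pulse configuration", {
  ann <- two_tmh_annotation()
  # no pulses -> one TMU spanning the region
  t0 <- segment_tmus(integer(), ann)
  expect_identical(nrow(t0), 1L)
  expect_identical(c(t0$start, t0$end), c(1L, 100L))
  # k pulses -> k+1 ordered non-overlapping intervals
  set.seed(11)
  for (rep in 1:20) {
    k <- sample(0:8, 1)
    pulses <- sort(sample(2:100, k))
    tm <- segment_tmus(pulses, ann)
    expect_identical(nrow(tm), k + 1L)
    expect_identical(tm$start[1], 1L)
    expect_identical(tm$end[nrow(tm)], 100L)
    expect_true(all(tm$end >= tm$start))
    if (nrow(tm) > 1) expect_true(all(tm$start[-1] == tm$end[-nrow(tm)] + 1L))
    covered <- sum(tm$end - tm$start + 1L)
    expect_identical(covered, 100L)
  }
})

test_that("a TMH and an adjacent interfacial helix share a TMU when no pulse separates them", {
  hel <- rep(FALSE, 100); hel[10:40] <- TRUE; hel[48:55] <- TRUE
  mem <- rep(FALSE, 100); mem[15:35] <- TRUE
  ann <- membrane_annotation(hel, mem)
  tm <- segment_tmus(c(5L, 70L), ann)
  joint <- which(tm$start <= 10 & tm$end >= 48)
  expect_length(joint, 1L)
  expect_identical(tm$helices[[joint]], c(1L, 2L))
  expect_identical(tm$n_helices[joint], 2L)
})

test_that("pulse-vs-helix cross-tabulation counts loop contents", {
  ann <- two_tmh_annotation()
  pairs <- successive_pairs(derive_landmarks(ann))  # D=40, E=60
  t1 <- count_pulses_between_tmhs(pairs, 50L, ann)
  expect_identical(t1["1", "no_helix"], 1L)
  expect_identical(sum(t1), 1L)

  # an 8-residue helix inside the loop moves the count to one_helix
  hel <- ann$helical; hel[45:52] <- TRUE
  ann2 <- membrane_annotation(hel, ann$in_membrane)
  pairs2 <- successive_pairs(derive_landmarks(ann2))
  t2 <- count_pulses_between_tmhs(pairs2, 56L, ann2)
  expect_identical(t2["1", "one_helix"], 1L)

  # empty pair list -> all-zero table
  empty <- successive_pairs(derive_landmarks(ann))[0, ]
  expect_identical(sum(count_pulses_between_tmhs(empty, 50L, ann)), 0L)
})

test_that("context association flags pulses stacked on non-helical TM residues", {
  # TM context fixture: 65% helical TM residues, all pulses on the
  # non-helical 35% -> strong association
  hel <- rep(c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
               TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE,
               FALSE, FALSE, FALSE), 10)
  mem <- rep(FALSE, 200); mem[1:180] <- TRUE
  ann <- membrane_annotation(hel, mem)
  pulses <- which(!hel & seq_len(200) <= 180)[1:30]
  ca <- context_association(pulses, ann, flank = 5)
  expect_lt(ca$p_values[["TM"]], 1e-4)
  expect_equal(sum(ca$counts$pulses), 30)

  # zero pulses -> degenerate table, undefined p-values
  ca0 <- context_association(integer(), ann)
  expect_true(is.na(ca0$p_values[["TM"]]))
  expect_identical(sum(ca0$counts$pulses), 0L)
})

test_that("kd_classic reproduces a direct windowed mean and threshold behaviour", {
  polyI <- kd_classic(strrep("I", 40))
  expect_true(all(polyI$average[10:31] == 4.5))
  expect_true(kd_has_peak(polyI, 1, 40))
  polyG <- kd_classic(strrep("G", 40))
  expect_false(kd_has_peak(polyG, 1, 40))

  set.seed(12)
  s <- rand_seq(60)
  kd <- kd_classic(s)
  r <- strsplit(s, "")[[1]]
  for (i in c(10, 25, 51)) {
    expect_equal(kd$average[i], mean(KD_ORACLE[r[(i - 9):(i + 9)]]))
  }
  expect_true(all(is.na(kd$average[c(1:9, 52:60)])))
  expect_error(kd_classic(rand_seq(10)), "shorter")
})

test_that("TMS missed by the KD threshold are reported with their rescue status", {
  # 3 TMS: strong, weak (poly-G block, below threshold), strong
  seqs <- make_block_sequence(list(
    c("S", 20), c("I", 21), c("S", 20), c("G", 21), c("S", 20),
    c("I", 21), c("S", 20)))
  mem <- rep(FALSE, nchar(seqs))
  mem[21:41] <- TRUE; mem[62:82] <- TRUE; mem[103:123] <- TRUE
  hel <- mem
  ann <- membrane_annotation(hel, mem)
  kd <- kd_classic(seqs)
  g2 <- detect_hpulses(seqs, "G2")
  r <- undetected_tms_rescue(ann, kd, g2)
  expect_identical(r$peaked, c(TRUE, FALSE, TRUE))
  # brute-force interval scan for the middle TMS
  expected <- any(g2$pulses > 41 & g2$pulses <= 82)
  expect_identical(r$rescued[2], expected)
  expect_true(is.na(r$rescued[1]))
})
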