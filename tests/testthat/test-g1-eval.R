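test_that("extremities are assigned their globally nearest pulse, injectively", {
  a <- assign_closest_pulses(100L, c(97L, 120L))
  expect_identical(a$assignments$pulse, 97L)
  expect_identical(a$assignments$distance, -3L)

  # greedy global order: 100 takes the exact pulse, 101 falls back to 130
  b <- assign_closest_pulses(c(100L, 101L), c(100L, 130L))
  expect_identical(b$assignments$pulse, c(100L, 130L))
  expect_identical(b$assignments$distance, c(0L, 29L))

  # pulses exactly at extremities -> all-zero distance spike
  ext <- c(10L, 30L, 50L)
  c_ <- assign_closest_pulses(ext, ext)
  expect_true(all(c_$assignments$distance == 0L))
  expect_identical(as.integer(names(c_$histogram)), 0L)

  # injectivity and order-invariance
  set.seed(21)
  for (rep in 1:10) {
    e <- sample(1:200, 12)
    p <- sample(1:200, 20)
    r1 <- assign_closest_pulses(e, p)$assignments
    r2 <- assign_closest_pulses(sample(e), sample(p))$assignments
    expect_identical(r1, r2)
    used <- r1$pulse[!is.na(r1$pulse)]
    expect_identical(anyDuplicated(used), 0L)
    expect_false(any(is.na(r1$pulse)))  # pulses outnumber extremities
  }

  # no pulses -> all extremities unassigned
  z <- assign_closest_pulses(c(5L, 9L), integer())
  expect_true(all(is.na(z$assignments$pulse)))
})

test_that("ties on |distance| prefer the upstream pulse", {
  a <- assign_closest_pulses(100L, c(97L, 103L))
  expect_identical(a$assignments$pulse, 97L)
  expect_identical(a$assignments$distance, -3L)
})

test_that("helices near the membrane contribute extremities, distant ones do not", {
  hel <- rep(FALSE, 300); hel[10:40] <- TRUE; hel[60:70] <- TRUE
  hel[200:220] <- TRUE  # 125 residues from the TMS: out of range
  mem <- rep(FALSE, 300); mem[15:35] <- TRUE
  ann <- membrane_annotation(hel, mem)
  expect_identical(membrane_helix_extremities(ann, "begin"), c(10L, 60L))
  expect_identical(membrane_helix_extremities(ann, "both"),
                   c(10L, 40L, 60L, 70L))
})

test_that("pulses match structural events within the tolerance, nearest kind first", {
  hel <- rep(FALSE, 100); hel[52:70] <- TRUE
  mem <- rep(FALSE, 100); mem[55:65] <- TRUE
  ann <- membrane_annotation(hel, mem, kinks = 60L)
  # helix-begin at 52, tms-begin 55, tms-end 65, helix-end 70, kink 60
  m <- match_events(50L, ann, tolerance = 3)
  expect_identical(m$per_pulse$kind, "helix_begin")
  expect_identical(m$per_pulse$distance, 2L)

  # nearest event 4 away -> unmatched at tolerance 3
  m2 <- match_events(48L, ann, tolerance = 3)
  expect_identical(m2$per_pulse$kind, "unmatched")

  # pulses exactly at kinks -> matched fraction 1, all kink
  ann2 <- membrane_annotation(hel, mem, kinks = c(58L, 62L))
  m3 <- match_events(c(58L, 62L), ann2, tolerance = 3)
  expect_equal(m3$matched_fraction, 1)
  expect_equal(unname(m3$kind_fractions["kink"]), 100)

  # matched fractions over matched pulses sum to 100
  expect_equal(sum(m3$kind_fractions), 100)
})

test_that("the matched fraction is non-decreasing in the tolerance", {
  set.seed(22)
  hel <- rep(FALSE, 400)
  for (s in c(30, 120, 210, 300)) hel[s:(s + 25)] <- TRUE
  mem <- rep(FALSE, 400)
  for (s in c(35, 125, 215, 305)) mem[s:(s + 15)] <- TRUE
  ann <- membrane_annotation(hel, mem)
  pulses <- sort(sample(1:400, 40))
  fr <- vapply(0:8, function(tol)
    match_events(pulses, ann, tolerance = tol)$matched_fraction, numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("prolines and pulses near kinks are counted once each", {
  s <- paste0(strrep("A", 29), "P", "APP", strrep("A", 30))
  # prolines at 30, 32, 33
  stats <- proline_kink_stats(s, kinks = 30L, g1 = c(28L, 40L), tolerance = 3)
  expect_identical(stats$prolines_near_kinks, 3L)  # 30, 32, 33 all within 3
  expect_identical(stats$pulses_near_kinks, 1L)
  expect_message(proline_kink_stats(s, integer(), 28L), "empty kink list")

  # a proline 4 residues from the kink is not counted
  s2 <- paste0(strrep("A", 33), "P", strrep("A", 30))
  expect_identical(proline_kink_stats(s2, 30L, integer())$prolines_near_kinks, 0L)
})

test_that("planted pulse jitter keeps assignments within [-4, +4]", {
  set.seed(23)
  ok <- 0L; total <- 0L
  for (rep in 1:30) {
    ext <- cumsum(sample(30:60, 8, replace = TRUE))
    jit <- sample(-2:2, length(ext), replace = TRUE)
    a <- assign_closest_pulses(ext, ext + jit)$assignments
    ok <- ok + sum(abs(a$distance) <= 4, na.rm = TRUE)
    total <- total + nrow(a)
  }
  expect_gte(ok / total, 0.95)
})

test_that("conformation rows group printed starts and pair with pulses", {
  # one structure, starts identical to pulses -> zero false positives
  st <- data.frame(structure_id = "X", start = c(10L, 40L, 80L))
  r <- conformation_report(st, pulses = c(10L, 40L, 80L))
  expect_identical(r$n_rows, 3L)
  expect_identical(unname(r$false_positives), 0L)
  expect_identical(r$fp_all_conformations, 0L)
  expect_true(all(r$rows$distance == 0L))

  # a pulse with no start in any structure is an all-conformation FP
  r2 <- conformation_report(st, pulses = c(10L, 40L, 80L, 200L))
  expect_identical(r2$fp_all_conformations, 1L)

  # all-conformation FP count never increases as structures are added
  st2 <- rbind(st, data.frame(structure_id = "Y", start = c(11L, 199L)))
  r3 <- conformation_report(st2, pulses = c(10L, 40L, 80L, 200L))
  expect_lte(r3$fp_all_conformations, r2$fp_all_conformations)
  expect_identical(r3$fp_all_conformations, 0L)
})

test_that("row grouping splits clusters that would duplicate a structure", {
  st <- data.frame(structure_id = c("A", "B", "A", "B", "C"),
                   start = c(2L, 2L, 7L, 7L, 8L))
  rows <- hpulse:::group_start_rows(st$start, st$structure_id, radius = 6)
  expect_identical(length(unique(rows)), 2L)
  expect_identical(rows[1], rows[2])
  expect_identical(rows[3], rows[5])
  expect_false(rows[1] == rows[3])
})
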