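# Shared fixtures and independent oracles, built in code at test time.

CANONICAL <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
               "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# KD table declared independently of the package constant.
KD_ORACLE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
               E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
               M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
               Y = -1.3, V = 4.2)

rand_seq <- function(n) paste(sample(CANONICAL, n, replace = TRUE), collapse = "")

# Naive direct-summation oracle for the variation score.
naive_variation <- function(seq, i, n) {
  r <- strsplit(seq, "")[[1]]
  tot <- 0
  for (k in seq_len(n)) {
    w <- sin(k * pi / (n + 1))
    tot <- tot + w * KD_ORACLE[[r[i + k]]] - w * KD_ORACLE[[r[i - k]]]
  }
  tot
}

# Brute-force re-simulation of the 4-of-5 consensus automaton over a
# 5 x m sign table (+1 / -1 / 0 entries). Returns state characters.
naive_consensus <- function(signs) {
  m <- ncol(signs)
  states <- character(m)
  cur <- "NEGATIVE"
  for (t in seq_len(m)) {
    np <- sum(signs[, t] > 0)
    nn <- sum(signs[, t] < 0)
    if (np >= 4) cur <- "POSITIVE" else if (nn >= 4) cur <- "NEGATIVE"
    states[t] <- cur
  }
  states
}

# Wrap a raw 5 x L score matrix in an hpp_scores shell (group G1 layout).
fake_scores <- function(mat, radii = 2:6) {
  rownames(mat) <- paste0("n", radii)
  structure(list(sequence_id = "fake", group = "G1", radii = radii,
                 residues = rep("A", ncol(mat)), scores = mat),
            class = "hpp_scores")
}

# A consensus track built directly from state letters ("P"/"N").
fake_consensus <- function(letters, start = 1L) {
  states <- ifelse(letters == "P", "POSITIVE", "NEGATIVE")
  structure(list(sequence_id = "fake", group = "G1", start = start,
                 end = start + length(states) - 1L, states = states),
            class = "hpp_consensus")
}

# Minimal STRIDE output: one ASG record per residue of `codes`.
stride_text <- function(codes, chain = "A",
                        resnames = rep("ALA", length(codes))) {
  c("REM  --------------------",
    "REM  STRIDE fixture",
    sprintf("ASG  %s %s %4d %4d    %s          %-11s   -60.00    -40.00     10.0",
            resnames, chain, seq_along(codes), seq_along(codes), codes,
            "State"))
}

# Minimal PDBTM-like XML with one chain and the given regions.
pdbtm_text <- function(regions, chain = "A") {
  reg <- vapply(regions, function(r) {
    sprintf('    <REGION seq_beg="%d" seq_end="%d" pdb_beg="%d" pdb_end="%d" type="%s"/>',
            r[[1]], r[[2]], r[[1]], r[[2]], r[[3]])
  }, character(1))
  c('<?xml version="1.0"?>',
    '<pdbtm xmlns="http://pdbtm.enzim.hu" ID="0xxx">',
    sprintf('  <CHAIN CHAINID="%s" NUM_TM="1" TYPE="alpha">', chain),
    reg,
    "  </CHAIN>",
    "</pdbtm>")
}

# Annotation with 2 TMS for quick topology tests: helices [10;40],[60;90],
# TMS [15;35],[65;85], length 100.
two_tmh_annotation <- function() {
  hel <- rep(FALSE, 100); hel[10:40] <- TRUE; hel[60:90] <- TRUE
  mem <- rep(FALSE, 100); mem[15:35] <- TRUE; mem[65:85] <- TRUE
  membrane_annotation(hel, mem, sequence_id = "two_tmh")
}

lacy_starts <- function() {
  utils::read.delim(system.file("extdata", "lacy_subhelix_starts.tsv",
                                package = "hpulse"))
}

lacy_pulses <- function() {
  utils::read.delim(system.file("extdata", "lacy_g1_pulses.tsv",
                                package = "hpulse"))$pulse
}
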