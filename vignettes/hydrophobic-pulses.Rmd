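---
title: "Hydrophobic pulses: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hydrophobic pulses: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hpulse)
```

## The model

α-helical integral membrane proteins alternate hydrophobic
membrane-spanning helices with polar loops. Classic hydropathy analysis
smooths the Kyte–Doolittle (KD) profile and thresholds its mean; `hpulse`
works on the profile's *variation* instead. The hydrophobicity-variation
score at position $i$ for window radius $n$ is

$$\mathrm{score}_n(i) \;=\; \sum_{k=1}^{n}
  \sin\!\Big(\frac{k\pi}{n+1}\Big)\,
  \big[\,KD(aa_{i+k}) - KD(aa_{i-k})\,\big],$$

a sine-tapered first-difference operator over a $2n+1$-residue window. The
taper weights mid-flank residues most, falls smoothly to zero at the window
edge (avoiding the boundary jitter of a hard cutoff), and gives the central
residue zero net weight (it cancels from the difference). The operator is
antisymmetric under sequence reversal, exactly zero on homopolymers, and
local: a residue change can only affect scores within $n$ positions. All
three properties are enforced by the test suite, together with an
independent naive-summation oracle.

A single radius resolves only events of its own scale, so scores are
computed for five radii per group:

* **G1**, $n = 2\ldots 6$ — small events. $n = 2$ is the shortest window
  that can see one helical turn (the $i \to i+4$ hydrogen bond).
* **G2**, $n = 12\ldots 16$ — whole transmembrane helices. A straight
  membrane-perpendicular helix needs about 21 residues ($n \approx 10$) to
  span the bilayer, and windows beyond $n = 16$ risk covering two helices
  at once, since consecutive helices can be separated by only one or two
  residues. Intermediate radii ($n = 7\ldots 11$) merely interpolate
  between the two regimes and are deliberately not offered.

### The consensus automaton

The five tracks of a group are fused by a two-state finite-state automaton
over their common defined range $[n_{\max}+1,\,L-n_{\max}]$:

* $\geq 4$ of 5 scores $> 0$ → state POSITIVE;
* $\geq 4$ of 5 scores $< 0$ → state NEGATIVE;
* anything else (3–2 splits, ties involving exact zeros) → **hold** the
  current state.

A **hydrophobic pulse** is the first position of each maximal POSITIVE run.
Two choices here were genuinely open and are resolved as follows:

* *Initial state*: NEGATIVE. Starting POSITIVE would fabricate a pulse at
  the very first track position of any sequence that opens decisively
  positive; starting NEGATIVE can at worst delay the first pulse to the
  first decisive positive consensus, which is the conservative direction
  for a detector of *rises*.
* *Indecision handling*: state hold, not a third emitted symbol. The device
  is a state machine with memory; emitting "undefined" would fragment
  positive runs and multiply pulses on noisy tracks.

Exact zeros count as neither positive nor negative; on an all-zero track
the automaton never leaves its initial state and no pulse fires.

### Scores are undefined, never padded

Where a window of radius $n$ does not fit, the score is explicitly `NA`.
Zero-padding or extrapolating would manufacture artificial variation at
the termini — precisely where polar-to-hydrophobic transitions matter.
Consequently the consensus exists only where all five radii are defined,
and a sequence must be at least $2 n_{\max}+1$ residues long for its group
($\geq 13$ for G1, $\geq 33$ for G2); shorter input is a structured error
naming the minimum.

## Topology layer

Per-residue annotations carry one structural state (helical or not; α-helix
only, 3₁₀ turns excluded by default since many α-helices merely begin or
end with one — an opt-in flag merges adjacent 3₁₀ turns for sensitivity
analysis) and one membrane state. Maximal runs define helices and TMS. The
landmark frame of a TMS $[B;C]$ is the TMH $[A;D]$, the smallest interval
covering all helices intersecting the TMS; successive frames
$(A\ldots D, E\ldots H)$ enter pair analyses when $D-C > 0$, $F-E > 0$ and
$E-D < 40$ residues. Interval "length" is consistently *end − start*; the
analysis span runs from the floor-midpoint of $[B;C]$ to that of $[F;G]$.

Localization uses half-open conventions $[C;D)$, $[D;E)$, $[E;F]$ so the
three loci tile $[C;F]$ and are mutually exclusive; position $E$ — the
observed pulse hot spot at the start of the next TMH — belongs to $[E;F]$
and is therefore countable. When several pulses fall between $C$ and $F$,
the one closest to $E$ is kept (ties toward the earlier position) and the
surplus is reported as discarded; the selection rule is a package decision,
made to respect the empirical hot spot at $E$.

TMU segmentation cuts the region at every G2 pulse; each pulse opens a new
unit, helices belong to the unit containing their start, and the units
provably tile the region (property-tested for random pulse sets).

The context-association analysis splits residues into a TM context (within
40 residues of any TMS — the same ±40 flank used everywhere a "near the
membrane" notion is needed) and a non-TM context, and compares the pulse
distribution over helical/non-helical residues against residue-proportional
expectations with a chi-square goodness-of-fit test (one per context). The
choice of test is the package's own; its null calibration is measured (the
acceptance script places uniform-random pulses and reports the rejection
rate at the 5% level over 100 replicates of a 1000-residue fixture).

The classic comparison baseline is the 19-residue centered KD mean with
peak threshold 1.6 KD units; a TMS without any above-threshold position is
"missed", and a missed TMS counts as rescued when a G2 pulse lies in
(previous TMS end, this TMS end].

## G1 evaluation layer

* **Extremity assignment** is greedy globally-nearest one-to-one matching:
  repeatedly take the (extremity, pulse) pair with smallest |pulse −
  extremity|, retiring both. Ties prefer the upstream pulse — helix
  N-capping transitions precede the helix — then earlier positions, making
  the result independent of input order.
* **Event matching** accepts a ±3-residue error against five event kinds
  (helix begin/end, TMS begin/end, kink); equal-distance ties rank helix
  extremities over TMS extremities over kinks. The matched fraction is
  non-decreasing in the tolerance (property-tested).
* **The multi-conformation report** aligns sub-helix starts from several
  structures into rows, grouping starts whose spread from the row's first
  start is ≤ 6 residues, with the additional constraint that a row holds at
  most one start per structure — a cluster violating it is split at its
  largest internal gap, because two starts of one structure are necessarily
  two distinct sub-helices. Rows are then paired to G1 pulses by
  *order-preserving* one-to-one matching within a 7-residue radius,
  maximizing the number of pairs and then minimizing total distance. Both
  lists are positional, so crossing pairings are never meaningful; greedy
  nearest matching was rejected because it can capture a pulse for an
  already-served neighbourhood and strand the true partner row. The
  grouping radius (6) and pairing radius (7) default to the largest
  within-row spread and the largest row-to-pulse distance observed in the
  shipped five-conformation lactose permease table, and both are exposed
  as arguments.

## Synthetic fixtures

`make_tm_protein()` renders alternating polar loops and hydrophobic TMS
blocks with ground-truth annotations. Defaults — the study conditions for
every property test — are: 4 TMHs, 21-residue TMS (membrane-spanning helix
length), 15-residue loops (short enough that successive pairs pass the
40-residue criterion), helices extending 2 residues past each TMS (so
$[A;B]$ and $[C;D]$ have positive length), hydrophobic alphabet
{I, L, V, F} versus polar {R, K, D, Q, S} (strong KD separation makes pulse
recovery unambiguous), optional 8-residue interfacial helices mid-loop, and
no boundary jitter. Randomness comes from R's seeded generator, locally
scoped so the caller's RNG state is untouched; a fixed seed reproduces the
fixture exactly.

What the generator does *not* emulate: realistic amino-acid composition,
composition gradients within helices, re-entrant loops, signal peptides, or
marginally hydrophobic TMS. Passing the recovery properties on these
fixtures therefore shows the pipeline is correct and well-calibrated on
clean topology, not that its real-data sensitivity matches any benchmark
figure; real-data performance depends on structure-derived annotations
(STRIDE, PDBTM, kink lists) that are consumed as inputs.

## Problem sizes and tolerances

The test suite and the acceptance script use: 200 random 50-mers for the
scoring oracle battery, 500 random 5-track sign tables for the consensus
oracle, 50 random pulse sets for TMU tiling, 25 seeded fixtures for G2
recovery and KD rescue, 100 jittered replicates for assignment accuracy
(pass bar: ≥ 95% of signed distances in [−4, +4]), and 100 replicates of a
1000-residue fixture for null calibration. Scoring agreement with the
direct-summation oracle is exact up to floating-point accumulation
(observed ≈ 1e−14); consensus agreement is exact by construction.

## Known limitations

* The pulse caller sees nothing within $n_{\max}$ residues of the termini;
  a first TMS starting inside that margin yields a pulse clamped to the
  track start (visible as a pulse at position $n_{\max}+1$).
* Pulse positions are sequence-based while annotations are
  structure-based: unresolved residues in crystal structures must be
  handled by the caller's position mapping (readers keep author-sequential
  numbering and never renumber silently).
* Sidedness (cytoplasmic/extracellular orientation) is out of scope, as
  are alternative hydropathy scales and pulse intensity/length descriptors.
* The case-study table analysis reproduces row grouping and pairing from
  positions alone; recomputing the pulse list itself requires the protein's
  sequence as FASTA input to `detect_hpulses()`.
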