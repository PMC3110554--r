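# hpulse

Hydrophobic pulse detection for α-helical integral membrane proteins (IMPs).

Hydropathy analysis is classically used to find transmembrane segments
(TMS): stretches whose *average* Kyte–Doolittle (KD) hydropathy exceeds a
threshold. `hpulse` instead analyses the *variation* of hydropathy along
the chain. A **hydrophobic pulse (HPulse)** is a rise-then-fall of
hydrophobicity; such pulses turn out to carry structural information beyond
the membrane-embedded core: at a large window scale they delimit whole
transmembrane helices (TMHs) and group them with adjacent small helices into
**transmembrane units (TMUs)**, while at a small scale they mark α-helix
extremities, kinks and other local irregularities — including extremities
that only appear in some conformations of a dynamic transporter or channel.

## The score and the pulse caller

For a residue at position `i` and a window radius `n`, the
hydrophobicity-variation score is a sine-tapered difference between the
following and preceding flanks of the window (2n+1 residues in total):

```
score_n(i) = Σ_{k=1..n} sin(kπ/(n+1)) · [ KD(aa(i+k)) − KD(aa(i−k)) ]
```

Scores are computed for five radii per group — **G1** (n = 2–6, small
structural events) and **G2** (n = 12–16, whole TMHs; intermediate radii
carry no extra information and are not offered). A two-state finite-state
automaton sweeps the common defined range of the five tracks: at least 4 of
5 strictly positive scores switch it to POSITIVE, at least 4 of 5 strictly
negative scores to NEGATIVE, anything else holds the current state (initial
state NEGATIVE). **A pulse is the first position of each POSITIVE run.**

Downstream analyses follow the landmark frame of a TMH pair — `[A;D]` a
TMH, `[B;C]` its TMS, `[E;H]`/`[F;G]` the next pair — and include: G2 pulse
localization between successive TMHs, TMU segmentation, pulse/helicity
association by membrane context, comparison with the classic 19-residue
KD window (threshold 1.6) and G2 "rescue" of TMS it misses, nearest-pulse
assignment of G1 pulses to helix extremities, ±3-residue structural-event
matching, proline/kink statistics, and a multi-conformation sub-helix
report.

## Worked example

A synthetic 4-TMH bundle (21-residue TMS, 15-residue polar loops) and its
G2 analysis:

```r
library(hpulse)
fx <- make_tm_protein(tm_fixture_spec(n_tmh = 4, seed = 7))
g2 <- detect_hpulses(fx$sequence, "G2")
g2
#> <hpp_pulses> seq, group G2: 4 pulse(s) at 17, 45, 80, 116

segment_tmus(g2, fx$annotation)[, c("start", "end", "n_helices")]
#>   start end n_helices
#> 1     1  16         1
#> 2    17  44         0
#> 3    45  79         1
#> 4    80 115         1
#> 5   116 159         1

pairs <- successive_pairs(derive_landmarks(fx$annotation))
localize_g2(pairs, g2)$summary
#>   interval residues residue_pct pulses pulse_pct
#> 1    [C;D]        6    11.76471      0         0
#> 2    [D;E]       36    70.58824      3       100
#> 3    [E;F]        9    17.64706      0         0
```

One G2 pulse precedes every TMS; all three pulses between successive TMHs
fall in the inter-helix interval `[D;E]`, and the TMUs delimited by the
pulses tile the sequence, one TMS-bearing helix each.

The multi-conformation case study of the lactose permease transporter
(five crystal structures: 1PV6, 1PV7, 2V8N, 2CFP, 2CFQ) ships as a
plain-text table of sub-helix start positions plus the matching G1-pulse
list (`inst/extdata/`):

```r
starts <- read.delim(system.file("extdata", "lacy_subhelix_starts.tsv", package = "hpulse"))
g1 <- read.delim(system.file("extdata", "lacy_g1_pulses.tsv", package = "hpulse"))$pulse
rep <- conformation_report(starts, pulses = g1)
```

which prints (via the summary fields): `rows 27 | in all five 10 |
pulse-associated 25 (92.6%)` and `false positives: 1PV6 11/27 (40.7%),
all conformations 2/27 (7.4%)` — sub-helix starts shared by all five
conformations are always pulse-associated, and pulses that look like false
positives against a single structure mostly match a start in *another*
conformation, i.e. they flag alternatively used structural weak points.

## Command line

A thin wrapper lives at `inst/scripts/hpp`:

```sh
Rscript inst/scripts/hpp pulses --group G2 protein.fasta
Rscript inst/scripts/hpp simulate --n-tmh 4 --seed 7 --prefix fx
Rscript inst/scripts/hpp evaluate --annotation fx.tsv fx.fasta
```

Subcommands: `score`, `pulses`, `tmu`, `kd-compare`, `evaluate`,
`conformations`, `simulate`. Outputs (TSV or JSON) are byte-identical
across runs for identical inputs.

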