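---
title: "Detecting periodic DNA and protein repeats with periscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting periodic DNA and protein repeats with periscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(periscan)
```

## The problem

Periodically repeating sequences — short tandem repeats, degenerate protein
repeat families such as TALEs, zinc fingers, TPR/ANK/WD40 units, and
interspaced arrays such as CRISPRs — share one signature that is independent
of their biology: identical or near-identical k-mers recur at a roughly
constant spacing. `periscan` detects such regions in nucleotide and
amino-acid sequences from that signature alone, without family-specific
models, and annotates each region with its repeat period, a periodicity
score, the individual repeat units and a masked consensus motif.

## The screening model

Screening is a three-phase funnel. All internal coordinates are 0-based
half-open; GenBank output converts to 1-based inclusive intervals.

**Phase 1 — highly repetitive regions (HRRs).** A window of size $w$ slides
along the sequence one position at a time (trailing windows are clipped at
the sequence end). At window position $i$ the left-most k-mer is the seed;
when it occurs $n_i \ge 2$ times in the window, $n_i$ is added to the
cumulative score $c$ of every seed position and 1 to every position of each
other occurrence. A window whose seed is unique contributes nothing, so $c$
drops to zero in unique sequence and the score track separates repeats from
background. Maximal runs of $c > 0$ whose peak reaches $s$ are *cumulative
k-mer peak areas* (CKPAs); chains of CKPAs separated by at most $g$
positions merge into one HRR spanning the outermost peak areas.

Positive runs whose peak stays below $s$ never extend a chain. This matters
in practice: with the protein defaults ($k = 3$), random trimer coincidences
produce sub-threshold score blips every few positions, and chaining through
them would bridge whole sequences, dilute the phase-2 score with background
mass and attach arbitrary flanking sequence to every repeat region.

**Phase 2 — periodicity.** For each HRR of size $h$, the surrounding region
$[\mathrm{start} - m, \mathrm{end} + m)$ is rescanned with a window of size
$h$. For every window, the occurrences $p_1 < p_2 < \dots < p_n$ of the
seed k-mer form a chain; the pair $(p_1, p_2)$ adds $n$ and every later
consecutive pair adds 1, at the matrix row equal to the pair distance, to
all columns covered by the two k-mer spans. The result is the
*position-period matrix* (PPM): rows are candidate periods, columns are
positions. The dominant period $d$ is the row with the largest marginal
(ties toward the smaller period), and the periodicity score is the mass in
rows $\lfloor 0.8d \rfloor .. \lceil 1.2d \rceil$ divided by the mass in all
rows up to half the region size. HRRs scoring at least $P$ become *periodic
repeat regions* (PRRs). Row depth is capped at half the region size,
matching the score denominator.

**Phase 3 — motif.** The seed k-mer $k_{seed}$ is the k-mer whose
consecutive-occurrence pairs at distances inside the $0.8d..1.2d$ band carry
the most mass; each pair counts once, weighted by the PPM columns it covers.
Under this accounting every rotation of a perfect repeat unit ties exactly,
and ties resolve first toward the k-mer whose occurrence pairs lie most
purely inside the band, then toward the left-most one — so the seed of a
clean tandem array sits at the array start rather than at an arbitrary
phase. Fragments of length $d$ are cut at every seed occurrence, aligned
with a deterministic center-star progressive aligner (DNA match +1 /
mismatch −1, protein BLOSUM62; affine gaps 4/1), and profiled per column:
information content $b = \log_2|A| - H$ of the non-gap letters, gap
fraction $f$, and letter consistency $l = b\,(1 - f)$. Columns with
$f > q$ are removed; the remaining columns are treated as a ring and the
longest circular run of nonconsensus columns ($l < u$) longer than $r$ is
excised, rotating the alignment to start right after it — this is what
separates a CRISPR repeat from its spacers when the extracted fragments are
repeat+spacer concatenations. The columnwise most-frequent letter gives the
representative, which is mapped back onto the PRR: exact scanning when the
representative is no longer than $k$, otherwise an iterative masked local
(Smith–Waterman) search with short-query scoring (DNA +1/−3 gaps 5/2;
protein PAM30 gaps 9/1) keeping hits with alignment length at least half
the query or Karlin–Altschul E-value at most 0.01. Mapped units rebuild a
per-position letter frequency profile; positions whose top letter frequency
falls below 60% are masked with `*` in the final motif.

## Parameters

| name | meaning | nucleotide | amino acid |
|------|---------|-----------:|-----------:|
| `w`  | phase-1 window (positions) | 1000 | 300 |
| `k`  | k-mer size | 10 | 3 |
| `s`  | CKPA peak-height threshold | 20 | 6 |
| `g`  | maximum merge gap (positions) | 300 | 50 |
| `m`  | phase-2 flank (positions) | 1000 | 300 |
| `P`  | minimum periodicity score | 0.5 | 0.3 |
| `q`  | maximum column gap fraction | 0.5 | 0.5 |
| `u`  | consistency threshold (gap-weighted bits) | 0.8 | 0.8 |
| `r`  | minimum removable nonconsensus run (columns) | 5 | 5 |

`u` lives on the $l = b(1-f)$ scale: a column must carry at least 0.8
bit-equivalents after down-weighting gaps to count as consensus, a scale on
which one default serves both the 2-bit DNA and the ~4.3-bit protein
alphabet. The published definition multiplies $b$ by the *gap* frequency;
taken literally that would score gap-rich columns as the most consistent
and invert the $l < u$ nonconsensus rule, so the complement is used.

## The synthetic-repeat generator

`repeat_spec()`/`generate_repeat()` build
`flank + unit (+ spacer) + ... + unit + flank` arrays with known ground
truth: tandem (`spacer_none()`), fixed-gap, or CRISPR-like
(`spacer_uniform(lo, hi)`, random spacer content). Noise is
substitution-only: every unit-copy position independently mutates to a
uniformly chosen *different* letter with probability `noise_rate`; spacers
and flanks stay clean. Random units are rejection-sampled to be primitive
(not a power of a shorter string) so the intended period is unambiguous,
and the flank letters adjacent to the array are resampled when they would
extend the periodic pattern, keeping the ground-truth unit tiling exact.
Flanks default to 2000 (DNA) / 300 (protein) random letters so windows
overlap non-repeat context. The truth period is the modal distance between
consecutive unit starts (ties toward the smaller value, matching the
detector's tie rule); for tandem and fixed-spacer arrays this is exact, for
variable spacers it is the modal realized distance.

What the generator does **not** emulate: insertions and deletions,
compositional bias, nested or interleaved repeat families, ambiguity codes,
and genome-scale background. Tests passing on generator output therefore
demonstrate correctness of the periodicity machinery under substitution
noise, not performance on real genomes.

## Noise tolerance and its copy-number ceiling

`noise_tolerance_sweep()` measures, per (unit size, spacer law, noise
level) cell, the fraction of seeded replicates whose true period is
recovered by phases 1–2. Recovery means a detected PRR overlaps the true
array with period within ±1 of the truth; for variable-spacer arrays, whose
realized unit-start distances span several values by construction, any
period inside the $0.8..1.2$ band of the modal distance counts.

The reachable noise level has a structural ceiling that depends on the copy
number. With substitution rate $e$, a k-mer survives one copy with
$r = (1-e)^k$; occurrence chains skip broken copies, so for $C$ copies the
in-band fraction of PPM mass is approximately
$(C-1) / \sum_{g\ge1} (C-g)(1-r)^{g-1}$ — it *decreases* as $C$ grows,
because long arrays accumulate skip-pair mass at period multiples. At the
study conditions used here (10 copies, $k = 10$, $P = 0.5$) DNA recovery at
the 90% level holds to roughly 4–6% substitution noise, while at 5 copies
the same arithmetic crosses $P = 0.5$ near 10%. Protein screening
($k = 3$, $P = 0.3$) tolerates ~28–30% noise at 10 copies. The acceptance
script (`scripts/acceptance.R`) computes both ceilings from scratch at 50
replicates per cell in 2% noise steps; because recovery is monotone
non-increasing in noise, the scan stops two levels after the 90% target is
first missed, which cannot change the reported maximum.

## Numerical and design choices

- Dominant-period ties break toward the smaller period;
  representative-letter ties break alphabetically; equally long
  nonconsensus runs break toward the earliest start — all for determinism.
- The periodicity band $\lfloor 0.8d\rfloor..\lceil 1.2d\rceil$ floors the
  lower and ceils the upper bound so the band never excludes $d$ itself at
  small periods.
- Phase-1 and phase-2 windows are anchored at every k-mer position with
  trailing windows clipped; stopping at the last full window would leave
  sequences shorter than $w$ (and repeats near a clipped region end)
  unscanned.
- Punctuation removes exactly one (the longest) circular nonconsensus run;
  all-gap columns carry $b = 0$; an alignment whose columns are all removed
  raises a degenerate-motif error and the PRR is reported without a motif.
  A PRR whose representative maps to zero units is likewise demoted but
  kept in the table with `NA` motif columns.
- The unit aligner is the internal center-star by default; an external
  MAFFT backend (`align_units(backend = "mafft")`) is cross-checked in the
  test suite to yield identical masked motifs on low-noise fixtures.
- Interval benchmarking (`evaluate_predictions()`) matches predictions to
  truth regions greedily, 1-to-1, by descending region overlap agreement;
  the interspace of a repeat descriptor is the median gap between
  consecutive mapped units (robust to edge truncation).
- Only the given strand of a nucleotide record is scanned; reverse
  complements are a caller responsibility.

## Known limitations

- The dense PPM (`build_ppm()`) is quadratic in region size; the screening
  pipeline therefore uses an exact marginal-only accumulator
  (`ppm_row_marginal()` of the same counts) and the dense matrix is meant
  for inspection and plotting at locus scale.
- E-values of the internal short-query search use plain Karlin–Altschul
  statistics without BLAST's finite-length corrections; they are accurate
  to well within the accept/reject decisions the pipeline makes but are not
  byte-identical to BLAST+ output.
- Exact-scan mapping of very short representatives (length ≤ k) undercounts
  degenerate copies, since only letter-identical occurrences match.
- For interspaced arrays with strongly variable spacer lengths, single-gap
  PPM mass splits across the realized distance values while skip-pair sums
  can coincide, so at moderate noise the arg-max period may land on a
  period multiple and the score gate then rejects the region — variable
  spacers degrade faster with noise than tandem arrays.

## Problem sizes used by the test suite

Oracle-equivalence tests run the literal window-by-window scorer and pair
enumerator against the production scan on 200 random and repeat-bearing
sequences of length up to 2000 in both alphabets. Recovery tests cover unit
sizes 3–10, 28, 31, 34, 36, 42, 60 and 72 at 10 copies. The noise sweeps
use 50 replicates per cell with per-replicate seeds streamed from one
master seed, so every run is exactly reproducible.
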