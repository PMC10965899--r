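---
title: "Methods: circular mitogenome characterization with mitomine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: circular mitogenome characterization with mitomine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitomine)
```

`mitomine` reproduces the standard characterization of an annotated animal
mitochondrial genome — junction ledger, composition and skews, codon usage
and RSCU, gene-order comparison, control-region mining, supermatrix
preparation — from a feature table and (optionally) the circular sequence.
This vignette explains the models and conventions, the tunable parameters,
the synthetic-data generator, and the numerical choices, so that a reader
can judge exactly what the package computes and what its tests do and do
not establish.

## Coordinate model

All coordinates are 1-based, fully inclusive, on the majority (J) strand
of a circle of length $L$; position $L+1$ wraps to 1. A feature crossing
the origin is encoded with `start > stop` (`wraps = TRUE`), so its length
is $(L - \mathrm{start} + 1) + \mathrm{stop}$. The signed junction gap
between consecutive features in start order is

$$g = \mathrm{start}(\mathrm{next}) - \mathrm{stop}(\mathrm{prev}) - 1
\pmod{L},$$

mapped to the signed interval $(-L/2,\, L/2]$: small residues are
intergenic spacers, residues near $L$ are overlaps reported negative. The
mapping reads each junction "the short way round", which is the only
physically sensible choice for dense annotations; for a hypothetical
annotation with a true spacer longer than $L/2$ the sign would flip, a
case that cannot arise in a real mitogenome (the largest published
mitochondrial spacers are a few hundred bp). Under this convention the
telescoping identity $\sum \mathrm{length} + \sum g = L$ holds for every
valid annotation, and the suite asserts it on 1000 random annotations.

Nested or overlapping features (the D-loop annotation sits inside the
NADH1/trnL1 neighborhood in the reference fixture) are handled purely by
start order, with each gap attributed to its upstream feature's row —
matching how published annotation tables lay out their intergenic column.
One consequence is honest bookkeeping rather than curation: the reference
fixture's coordinates yield 21 positive spacers totalling 384 nt where the
source text counts 20 and 381 (it evidently excluded the 3 nt trnM→trnI
spacer), and the D-loop row's printed size/gap cells (86, −33) disagree
with its own printed coordinates (6532..6618 ⇒ 87, −34). The package
reports the coordinate-derived values and the tests document the
two-cell exception; we do not guess the intended stop coordinate.

## Composition and skews

Per-class composition concatenates each member feature's residues on its
*coding* strand (reverse complement for minority-strand genes) and
counts bases; the `genome` class counts the full majority strand.
Overlapping features contribute their full spans to their own classes, so
shared bases are deliberately double-counted across classes — classes are
reported independently, as in published composition tables. AT and GC skew
are $(A-T)/(A+T)$ and $(G-C)/(G+C)$; both are scale-free, so they can be
evaluated from raw counts or from percentages printed at 1 decimal place.
Percentages rounded to 1 dp propagate up to about $\pm 0.002$ into a skew
with denominator near 80, which is why the percentage route is expected to
agree with the count route only within that tolerance (the rRNA AT-skew
cell of the reference table is the visible instance: 0.013 from printed
percentages vs 0.012 printed). Report rounding follows the field's
convention: percentages 1 dp, skews 3 dp. Degenerate classes (a zero
$A+T$ or $G+C$ denominator) report `NA` for the affected skew; requesting
a class with no features is an error.

## Codon usage and RSCU

CDS are extracted strand-aware and wrap-aware. Codon counting drops each
CDS's initiation codon and, by default (`stop_policy = "separate"`),
tallies terminal stop codons into a dedicated stop family while
`n_analyzed` excludes both — the only combination consistent with a
published table whose stop rows carry counts and RSCU values while its
footnote says initiation and termination codons were excluded. On the
reference counts the non-stop total is 3711 while the printed "3724
analyzed" equals the sum *including* the 13 terminal stops; the footnote
is implemented literally and the discrepancy is simply noted here.

RSCU for codon $c$ in synonymous family $F$ is
$\mathrm{RSCU}(c) = n_c \, |F| / \sum_{c' \in F} n_{c'}$, undefined
(reported blank/`NA`) for families with zero total. Families are derived
from the genetic code's translation products — not from the amino-acid
letters a table happens to print. The default code is NCBI transl_table 5
(invertebrate mitochondrial: AGA/AGG → Ser giving an 8-codon family,
AUA → Met, UGA → Trp); tables 1 and 2 are also registered, and the map is
cross-checked against the Biostrings registry in the tests. This grouping
choice is diagnostic: the reference table annotates AGA/AGG as Arg and
UGA as a stop, yet its printed RSCU values (AGA $= 81 \times 8 / 316 =
2.05$, UGA $= 91 \times 2 / 95 = 1.92$) are reproducible only under the
table-5 families with stops separate, which is what the package
implements. RSCU is reported at 2 dp.

## Gene-order comparison

Gene orders are signed circular token sequences, rotation-normalized to a
configurable anchor (default: the control region; absent that, the
lexicographically smallest token — a deterministic tie-break). The
comparison statistic is the signed, orientation-aware breakpoint
distance: the number of adjacencies $(a, b)$ of one order, with
$(a,b) \equiv (-b,-a)$, absent from the other. It is symmetric, zero iff
the orders are equivalent up to rotation (or whole-circle reflection with
all signs flipped), and is validated against an exhaustive
adjacency-enumeration oracle. The registries encode the insect ancestral
arrangement and the lepidopteran ancestral arrangement, which differ
exactly by the I-Q-M → M-I-Q block between the control region and NADH2;
trnM is registered on the majority strand, following the reference
annotation table over a contradictory sentence in the source text. The
named qMGR score is not reimplemented — it is not publicly specified, and
every claim the analysis makes (identity/non-identity, the MIQ block) is
expressible with breakpoint distance plus the per-gene
kept/translocated/inverted classification. Duplications and deletions are
rejected as token-set mismatches rather than scored.

## Control-region mining

All finders are deterministic, with positions 1-based within the region
and absolute genome positions reported alongside.

- **Tandem repeats** (default unit 6–300 bp, ≥ 2.0 copies, identity 1.0):
  maximal arrays by direct periodicity extension; the final copy may be
  fractional. Reports collapse to the leftmost phase; arrays nested inside
  a longer-unit span are dropped; overlapping arrays in different phases
  that reach beyond a reported span are kept (the scanner advances one
  position at a time — an earlier span-skipping variant provably missed
  such arrays, caught by the quadratic oracle). `min_identity < 1` lets
  the extension run through isolated mismatches while the running identity
  stays above threshold; the array still ends on a match. The probabilistic
  motif discovery used in the source workflow is replaced by this exact
  search over the same unit range: it finds literal repeat units
  bit-exactly and is testable against a brute-force scanner.
- **Microsatellites**: maximal perfect $(\mathrm{TA})_n$ runs, $n \ge 5$
  whole copies by default; the threshold is configurable because published
  descriptions rarely state their minimum $n$.
- **Homopolymers**: maximal runs meeting per-base thresholds, default
  `c(T = 7, A = 5)` after the poly-T(7)/poly-A(5) convention.
- **Origin motifs**: exact matches of ATAGT (and the ATAGA variant),
  given strand by default.
- **Stem-loops**: inverted repeats with stem ≥ 6 bp, ≤ 1 mismatched pair,
  loop 3–30 bp. Two normalization rules matter. First, the innermost stem
  pair must match: a mismatch at the loop boundary is the same hairpin
  with a wider loop and is reported at that center (without this rule, any
  perfect stem of length $k$ is out-ranked by a spurious $k+1$ hit with
  one mismatch one step inside the loop). Second, arms always end on a
  matching pair. Hits are ranked by stem length, then fewest mismatches,
  then position, and pruned to non-overlapping local maxima
  (`prune = FALSE` returns the full candidate set, which is exactly
  mirror-symmetric under reverse complement — a tested property). No
  thermodynamic folding is attempted; a hairpin here is a combinatorial
  object.

## The synthetic generator

`generate_mitogenome(generator_spec(), seed)` emits a circular genome,
its annotation, and an exact truth manifest. The defaults are the study
conditions of the reference mitogenome: the lepidopteran ancestral gene
order with its strand assignments; the 13 published PCG lengths with the
published start codons (ATN) and stops (TAA, TAG for the NADH3 analog);
codon sampling weighted by the published 64-codon counts (restricted to
non-stop codons internally, so no internal stops can arise); tRNA lengths
61–71 bp and rRNA lengths 1346/762 bp with class-specific base
probabilities from the published composition table (tRNA 80.9% A+T, rRNA
84.7%, control 95.6%, spacers genome-like); a 1363 bp control region; the
7 bp ATGATAA overlap joining the ATP8 analog's last codons
(...A-TGA-TAA) to the ATP6 analog's first (ATG-ATA-A..); and the trnN
analog spanning the origin with 27 bases before it. Intergenic spacers
default to 0–25 bp, giving a realized genome of ~16.5 kb.

The control region plants, at recorded coordinates: two tandem arrays
(57 and 159 bp units, two copies each — the two unit lengths the source
describes), four $(\mathrm{TA})_n$ runs ($n$ = 6, 7, 8, 6), five
poly-T(7) and five poly-A(5) stretches, one ATAGT motif, and one hairpin
(24 bp stem, 8 bp loop). Exact recovery is engineered, not hoped for:
filler is sampled under run constraints (no A-run ≥ 5, no T-run ≥ 7, no
TA-alternation ≥ 9 bases, no ATAG), planted elements carry breaker bases
that block extension on both sides, tandem units are rejection-sampled to
be aperiodic and to create no secondary features across copy boundaries,
and the hairpin uses a G/C-anchored stem with an all-C loop (a 95% A+T
background produces chance A:T stems up to ~16 bp under the 1-mismatch
budget, so a 24 bp planted stem is required for the planted hairpin to be
the top-ranked hit, and an all-C loop cannot pair with itself). The
breakers and the G/C arm cost the realized control region a few points of
A+T (~91% against the 95.6% target); the truth manifest always records
realized, not target, quantities.

What the generator does **not** emulate: real tRNA/rRNA secondary
structure (those sequences are i.i.d. within composition targets), codon
autocorrelation along genes, strand-specific mutational asymmetry beyond
the class composition targets, sequencing or assembly error, and
uniqueness of planted motifs (an AT-rich 16 kb circle inevitably contains
chance ATGATAA/ATAGT occurrences — the source genome itself has seven
ATGATAA sites — so recovery tests assert presence at planted coordinates,
not global uniqueness). Passing the recovery suite therefore demonstrates
coordinate-exact bookkeeping through every pipeline stage, not biological
realism of the sequence model.

## Problem sizes and numerical conventions

The default suite runs in about a minute on one CPU: 1000 random
annotations for the telescoping identity, 20 generator seeds for full
pipeline-vs-truth recovery, tandem-oracle equivalence on regions of
300–1363 bp, and exhaustive small-circle walks ($L = 50$) for the
junction arithmetic oracle. Rounding for reports: percentages 1 dp, skews
3 dp, RSCU 2 dp. Comparisons against printed values use the printed
precision of each cell (a genome GC skew printed as −0.17 is matched at
2 dp). Ties in gene-order rotation break lexicographically; stem-loop
ranking breaks ties by position. Degenerate inputs (empty feature lists,
single-feature circles, zero-denominator skews, families with zero
counts, CDS with incomplete terminators) return errors, `NA`s, or flags
as documented on each function rather than silent values.

## Limitations

- GenBank parsing covers the subset of the flat-file grammar that
  mitogenome records use (single-interval and two-interval
  origin-spanning locations, `complement()`, the common feature keys);
  exotic locations are rejected loudly.
- The supermatrix module exports *unaligned* concatenations with per-taxon
  partition tables; alignment order (concatenate-then-align vs
  align-then-concatenate) is left to the user's aligner, and tree
  inference is out of scope.
- Reproduction of the reference characterization is from the printed
  tables; nothing is asserted about the deposited sequence itself, which
  the package neither ships nor fetches.
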