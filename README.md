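# mitomine

Desk-side characterization analytics for annotated circular mitochondrial
genomes, built around the published mitogenome of the coffee leaf miner
*Leucoptera coffeella* (GenBank OR753213, 16,407 bp) and reusable for any
animal mitogenome annotation.

Animal mitogenomes are ~16 kb circles carrying 13 protein-coding genes
(PCGs), 22 tRNAs, 2 rRNAs and an A+T-rich control region. Their published
characterizations revolve around a handful of statistics that `mitomine`
computes from an annotation table (and, where available, the sequence):

- **Junction arithmetic.** On a circle of length *L* with 1-based inclusive
  coordinates, a feature's length is `stop − start + 1` (or
  `(L − start + 1) + stop` when it spans the origin), and the signed gap at
  each junction is `start(next) − stop(prev) − 1` modulo *L* — positive for
  intergenic spacers, negative for gene overlaps. The telescoping identity
  `Σ length + Σ gap = L` holds for every valid annotation.
- **Composition and skew.** Per feature class, base percentages and the
  strand-asymmetry statistics `AT skew = (A − T)/(A + T)` and
  `GC skew = (G − C)/(G + C)`, computable from counts or directly from
  published percentages.
- **Codon usage and RSCU.** Relative synonymous codon usage
  `RSCU(c) = count(c) · |F| / Σ_{c'∈F} count(c')` for codon *c* in
  synonymous family *F*, with families derived from a pluggable genetic
  code — default the invertebrate mitochondrial code (transl_table 5:
  AGA/AGG → Ser, AUA → Met, UGA → Trp) with stop codons as their own
  family — plus start/stop codon typing and translation.
- **Gene-order comparison.** Signed circular gene orders, orientation-aware
  breakpoint distance against ancestral-arrangement registries (insect
  ancestor, lepidopteran ancestor with the derived trnM-trnI-trnQ block),
  and per-gene kept/translocated/inverted classification.
- **Control-region mining.** Deterministic finders for tandem repeat
  arrays (6–300 bp units), (TA)n microsatellites, poly-A/T homopolymers,
  replication-origin motifs (ATAGT/ATAGA) and stem-loop (inverted repeat)
  candidates.
- **Phylogenomic prep.** Concatenated nucleotide or amino-acid
  supermatrices of the 13 PCGs with RAxML-style partition files
  (alignment and tree inference stay external).
- **Synthetic mitogenomes.** A generator that emits an AT-rich annotated
  circle shaped like the study genome — biased codon usage, fixed
  start/stop codons, one origin-spanning gene, a planted 7 bp ATGATAA
  ATP8/ATP6 overlap, and a control region with planted repeats, motifs and
  a hairpin — together with an exact ground-truth manifest, so every stage
  is testable without downloads.

The printed annotation, composition and codon-usage tables published with
the *L. coffeella* mitogenome ship as data fixtures
(`lcoffeella_feature_table()`, `lcoffeella_composition_table()`,
`lcoffeella_codon_usage()`); the deposited sequence itself is not required
or included.

## Worked example

```r
library(mitomine)

ann <- lcoffeella_annotation()          # published Table-1 coordinates
ledger <- build_junction_ledger(ann)
layout_summary(ledger)
#> <layout_summary> 21 spacers (384 nt, 2..64), 12 overlaps (largest 47 nt)
```

Twenty-one coordinate-derived spacers totalling 384 nt (the published
description counts 20/381, excluding the 3 nt trnM→trnI spacer), and
overlaps up to 47 nt (NADH1/D-loop).

```r
cu <- lcoffeella_codon_usage()          # published 64-codon counts
r <- rscu(codon_usage_from_counts(setNames(cu$count, cu$codon)))
head(r[order(-r$rscu_2dp), c("codon", "aa", "count", "rscu_2dp")], 4)
#>    codon aa count rscu_2dp
#> 3    UUA  L   491     5.40
#> 31   CGA  R    36     2.82
#> 5    UCU  S   108     2.73
#> 63   GGA  G   130     2.60
```

UUA-leucine dominates its six-codon family (RSCU 5.40), the hallmark of
the A/T third-position bias in lepidopteran mitogenomes.

```r
skews_from_percentages(lcoffeella_composition_table())
#>     class at_skew gc_skew
#> 1     PCG  -0.141   0.048
#> 2    tRNA   0.016   0.131
#> 3    rRNA   0.013   0.333
#> 4 control  -0.033  -0.409
#> 5  genome   0.011  -0.171

go <- gene_order(ann, include = c("PCG", "tRNA", "rRNA", "control"))
breakpoint_distance(go, reference_order("lepidoptera_ancestor"))
#> [1] 0
```

Breakpoint distance 0: the published gene order carries the ancestral
lepidopteran arrangement, including the MIQ block after the control
region.

```r
sim <- generate_mitogenome(generator_spec(), seed = 1)
sim
#> <synthetic_mitogenome> seed 1: 16529 bp, 38 features (wrap: trnN)
control_region_report(sim$sequence, sim$annotation)
```

The generator's `truth` manifest records every planted feature with exact
coordinates; the test suite reruns the whole pipeline against it.

A command-line front end is available as `inst/cli/mitomine`
(subcommands `profile`, `layout`, `codon`, `rearrange`, `cr`,
`phyloprep`, `simulate`, `fixtures`; every run writes a JSON manifest).

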