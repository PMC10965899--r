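# Circular layout arithmetic: sizes, junction ledger, gene order, motifs.

test_that("feature lengths match the published sizes, wrap included", {
  L <- lcoffeella_genome_length()
  expect_equal(feature_length(list(start = 273, stop = 1985), L), 1713)
  expect_equal(feature_length(list(start = 16381, stop = 41), L), 68)
  expect_equal(feature_length(list(start = 5, stop = 5), L), 1)
})

test_that("junction gaps reproduce spacer, overlap and abutting cases", {
  L <- lcoffeella_genome_length()
  # trnS1 (42..102) -> trnE (107..172): 4 nt spacer
  expect_equal(junction_gap(list(stop = 102), list(start = 107), L), 4)
  # trnV (8000..8066) -> rrnS (8066..8827): 1 nt overlap
  expect_equal(junction_gap(list(stop = 8066), list(start = 8066), L), -1)
  # trnN (16381..41) -> trnS1 (42..102): abutting across the origin
  expect_equal(junction_gap(list(stop = 41), list(start = 42), L), 0)
})

test_that("junction gap agrees with a circle-walking oracle", {
  set.seed(42)
  L <- 50L
  for (i in 1:200) {
    prev_stop <- sample(L, 1)
    next_start <- sample(L, 1)
    got <- junction_gap(list(stop = prev_stop), list(start = next_start), L)
    want <- oracle_junction_gap(prev_stop, next_start, L)
    expect_identical(as.integer(got), as.integer(want))
  }
  # lengths too, including wrapping placements
  for (i in 1:100) {
    s <- sample(L, 1)
    e <- sample(L, 1)
    expect_identical(
      as.integer(feature_length(list(start = s, stop = e), L)),
      oracle_feature_length(s, e, L))
  }
})

test_that("the junction ledger reproduces the printed intergenic column", {
  ann <- lcoffeella_annotation()
  tab <- lcoffeella_feature_table()
  ledger <- build_junction_ledger(ann)
  gap <- setNames(ledger$gap_nt, ledger$upstream)
  # NADH1 -> D-loop overlap and COII -> trnK overlap as printed
  expect_equal(gap[["NADH1"]], -47)
  expect_equal(gap[["COII"]], -35)
  # every printed cell except the internally inconsistent D-loop row
  other <- tab[tab$name != "DLOOP", ]
  expect_equal(unname(gap[other$name]), other$gap_printed)
  # the D-loop row: coordinates give -34 where the table prints -33
  expect_equal(gap[["DLOOP"]], -34)
})

test_that("two abutting features tiling the circle have zero gaps", {
  ann <- mito_annotation(
    data.frame(name = c("A1", "B1"), category = "other", strand = "+",
               start = c(1, 51), stop = c(50, 100)), 100)
  ledger <- build_junction_ledger(ann)
  expect_equal(ledger$gap_nt, c(0, 0))
  expect_error(build_junction_ledger(
    mito_annotation(data.frame(name = "A1", category = "other",
                               strand = "+", start = 1, stop = 50), 100)),
    ">= 2 features")
})

test_that("telescoping identity holds on fixtures and random annotations", {
  ann <- lcoffeella_annotation()
  ledger <- build_junction_ledger(ann)
  expect_equal(sum(feature_length(ann)) + sum(ledger$gap_nt),
               ann$genome_length)
  set.seed(7)
  for (i in 1:50) {
    a <- random_annotation(n_features = sample(3:12, 1))
    led <- build_junction_ledger(a)
    expect_equal(sum(feature_length(a)) + sum(led$gap_nt),
                 a$genome_length)
  }
})

test_that("layout summary totals the coordinate-derived ledger", {
  ledger <- build_junction_ledger(lcoffeella_annotation())
  s <- layout_summary(ledger)
  # coordinate-derived: 21 positive gaps totalling 384 nt (the published
  # text counts 20 and 381; the 3 nt trnM->trnI spacer accounts for the
  # difference), overlaps up to 47 nt
  expect_equal(s$n_spacers, 21)
  expect_equal(s$total_spacer_nt, 384)
  expect_equal(s$min_spacer, 2)
  expect_equal(s$max_spacer, 64)
  expect_equal(s$largest_overlap, 47)
})

test_that("gene order anchors at the control region with signed tokens", {
  go <- gene_order(lcoffeella_annotation(),
                   include = c("PCG", "tRNA", "rRNA", "control"))
  expect_equal(go$tokens[1:5],
               c("+CR", "+trnM", "+trnI", "-trnQ", "+NADH2"))
  expect_equal(length(go$tokens), 38)
  one <- mito_annotation(
    data.frame(name = "COI", category = "PCG", strand = "+",
               start = 10, stop = 900), 1000)
  expect_equal(gene_order(one)$tokens, "+COI")
})

test_that("motif scan finds planted, wrap-spanning and strand hits", {
  s <- circular_sequence("GGGGATGATAAGGGGG")
  hits <- motif_scan(s, "ATGATAA")
  expect_equal(hits$start, 5)
  expect_equal(hits$strand, "+")
  # reverse-complement occurrence is reported on the minus strand
  s2 <- circular_sequence(paste0("GGGG", revcomp("ATGATAA"), "GGGGG"))
  hits2 <- motif_scan(s2, "ATGATAA")
  expect_equal(hits2$strand, "-")
  # motif spanning the origin
  s3 <- circular_sequence(paste0("TAAGGGGGGGGGATGA"))
  hits3 <- motif_scan(s3, "ATGATAA")
  expect_equal(hits3$start, 13)
  expect_equal(hits3$end, 3)
  # motif absent from both strands
  expect_equal(nrow(motif_scan(s3, "CATCAT")), 0)
  expect_error(motif_scan(s3, ""), "non-empty")
})

test_that("planted ATGATAA overlap is annotated with both ATP genes", {
  sim <- generate_mitogenome(generator_spec(), seed = 2)
  hits <- motif_scan(sim$sequence, "ATGATAA", sim$annotation)
  at_junction <- hits[grepl("ATP8", hits$features) &
                        grepl("ATP6", hits$features), ]
  expect_equal(nrow(at_junction), 1)
  expect_equal(at_junction$strand, "+")
})
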