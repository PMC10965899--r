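# Genetic code, CDS extraction, codon counting, RSCU, translation.

test_that("transl_table 5 agrees with the Biostrings registry", {
  code <- genetic_code(5)
  ref <- Biostrings::getGeneticCode("5")
  expect_equal(code$codon_to_aa[names(ref)], ref, ignore_attr = TRUE)
  # the three diagnostic reassignments of the invertebrate code
  expect_equal(unname(code$codon_to_aa[c("AGA", "AGG", "ATA", "TGA")]),
               c("S", "S", "M", "W"))
  expect_equal(sort(code$families[["*"]]), c("TAA", "TAG"))
  expect_length(code$families[["S"]], 8)
  # families partition the 64 codons
  expect_equal(sort(unlist(code$families)), sort(names(code$codon_to_aa)),
               ignore_attr = TRUE)
  expect_error(genetic_code(99), "unknown translation table")
})

test_that("CDS extraction is strand-aware and wrap-aware", {
  sim <- generate_mitogenome(generator_spec(), seed = 10)
  f <- sim$annotation$features
  # minus-strand CDS comes back 5'->3': starts with its start codon
  nadh5 <- f[f$name == "NADH5", ]
  expect_equal(nadh5$strand, "-")
  cds <- extract_cds(sim$sequence, nadh5)
  expect_equal(substr(cds, 1, 3), sim$truth$start_codons[["NADH5"]])
  # plus strand is the identity slice
  coi <- f[f$name == "COI", ]
  expect_equal(extract_cds(sim$sequence, coi),
               circ_substr(sim$sequence, coi$start, coi$stop))
})

test_that("a CDS planted across the origin is extracted intact", {
  # synthetic 60 bp circle with a 21 nt CDS spanning the origin
  cds_true <- "ATGAAATTTGGGCCCTAA"
  prefix <- substr(cds_true, 8, 18)  # positions 1..11 of the circle
  filler <- strrep("C", 42)
  genome <- circular_sequence(paste0(prefix, filler, substr(cds_true, 1, 7)))
  feat <- list(start = 54, stop = 11, strand = "+")
  expect_equal(extract_cds(genome, feat), cds_true)
})

test_that("start/stop typing matches the published patterns", {
  sim <- generate_mitogenome(generator_spec(), seed = 1)
  rep <- start_stop_report(sim$sequence, sim$annotation)
  expect_equal(setNames(rep$start_codon, rep$gene)[names(sim$truth$start_codons)],
               sim$truth$start_codons, ignore_attr = TRUE)
  expect_equal(setNames(rep$stop_codon, rep$gene)[names(sim$truth$stop_codons)],
               sim$truth$stop_codons, ignore_attr = TRUE)
  # the NADH3-style TAG terminator is present exactly once
  expect_equal(sum(rep$stop_codon == "TAG"), 1)
  expect_equal(rep$gene[rep$stop_codon == "TAG"], "NADH3")
  # direct cases
  expect_equal(type_start_stop("ATGTAA")[c("start", "stop")],
               list(start = "ATG", stop = "TAA"))
  ts <- type_start_stop("ATGAAATA")  # incomplete terminator
  expect_false(ts$complete)
  expect_equal(ts$stop, "TA")
})

test_that("codon counting matches the footnote semantics and an oracle", {
  u <- count_codons("ATGAAATAA")
  expect_equal(unname(u$counts[c("AAA", "TAA")]), c(1L, 1L))
  expect_equal(u$n_analyzed, 1L)
  expect_equal(sum(u$counts), 2L)
  # stop policy "exclude" drops the terminal stop entirely
  u2 <- count_codons("ATGAAATAA", stop_policy = "exclude")
  expect_equal(sum(u2$counts), 1L)
  expect_equal(u2$n_analyzed, 1L)
  # 13 CDS ending TAA except one TAG: stop family tallies (12, 1)
  sim <- generate_mitogenome(generator_spec(), seed = 1)
  f <- sim$annotation$features
  pcgs <- f[f$category == "PCG", , drop = FALSE]
  cds <- vapply(seq_len(nrow(pcgs)), function(i)
    extract_cds(sim$sequence, pcgs[i, ]), character(1))
  usage <- count_codons(cds)
  expect_equal(unname(usage$counts[c("TAA", "TAG")]), c(12L, 1L))
  # oracle equivalence on the same CDS set
  want <- oracle_codon_counts(cds)
  got <- usage$counts[usage$counts > 0]
  expect_equal(got[order(names(got))], want, ignore_attr = TRUE)
  expect_equal(names(got)[order(names(got))], names(want))
})

test_that("RSCU reproduces the published worked examples", {
  leu <- c(UUA = 491, UUG = 2, CUU = 40, CUC = 0, CUA = 12, CUG = 1)
  r <- rscu(codon_usage_from_counts(leu))
  expect_equal(r$rscu_2dp[r$codon == "UUA"], 5.40)
  ser <- c(UCU = 108, UCC = 6, UCA = 84, UCG = 4, AGU = 32, AGC = 1,
           AGA = 81, AGG = 0)
  r2 <- rscu(codon_usage_from_counts(ser))
  expect_equal(r2$rscu_2dp[r2$codon == "AGA"], 2.05)
  # any family with equal counts is unbiased
  r3 <- rscu(codon_usage_from_counts(c(GGU = 5, GGC = 5, GGA = 5, GGG = 5)))
  expect_equal(r3$rscu[substr(r3$codon, 1, 2) == "GG"], rep(1, 4))
})

test_that("RSCU family sums equal family sizes for arbitrary counts", {
  code <- genetic_code(5)
  set.seed(11)
  for (i in 1:25) {
    counts <- setNames(rpois(64, lambda = sample(c(1, 5, 50), 1)),
                       chartr("T", "U", names(code$codon_to_aa)))
    r <- rscu(codon_usage_from_counts(counts, code), code)
    dna <- chartr("U", "T", r$codon)
    for (fam in code$families) {
      vals <- r$rscu[match(fam, dna)]
      tot <- sum(r$count[match(fam, dna)])
      if (tot > 0) {
        expect_equal(sum(vals), length(fam), tolerance = 1e-9)
      } else {
        expect_true(all(is.na(vals)))
      }
    }
  }
})

test_that("translation follows table 5 and flags internal stops", {
  code <- genetic_code(5)
  expect_equal(translate_cds("AGA", code), "S")
  expect_equal(translate_cds("TGA", code), "W")
  expect_equal(translate_cds("ATG", code), "M")
  expect_equal(translate_cds("ATGAAATAA", code), "MK*")
  expect_error(translate_cds("ATGTAAAAA", code), "internal stop.*codon position 2")
  expect_equal(translate_cds("ATGTAAAAA", code, internal_stop = "mask"),
               "MXK")
  expect_error(translate_cds("ATGA", code), "not divisible")
})

test_that("generator codon counts are recovered through the genome", {
  sim <- generate_mitogenome(generator_spec(), seed = 12)
  f <- sim$annotation$features
  pcgs <- f[f$category == "PCG", , drop = FALSE]
  cds <- vapply(seq_len(nrow(pcgs)), function(i)
    extract_cds(sim$sequence, pcgs[i, ]), character(1))
  usage <- count_codons(cds)
  expect_identical(usage$counts, sim$truth$codon_counts$counts)
  expect_identical(usage$n_analyzed, sim$truth$codon_counts$n_analyzed)
  # no internal stops anywhere, by construction
  for (s in cds) expect_silent(translate_cds(s, genetic_code(5)))
})
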