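# Annotation model and feature-table / GenBank IO.

test_that("feature table reads with wrap inference and validation errors", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\tcategory\tstrand\tstart\tstop\tanticodon",
               "trnS1\ttRNA\t+\t42\t102\tgct",
               "trnN\ttRNA\t+\t16381\t41\tgtt"), tmp)
  ann <- read_feature_table(tmp, 16407)
  f <- ann$features
  expect_equal(f$name, c("trnS1", "trnN"))  # sorted by start
  expect_false(f$wraps[f$name == "trnS1"])
  expect_true(f$wraps[f$name == "trnN"])

  writeLines(c("name\tcategory\tstrand\tstart\tstop",
               "trnS1\ttRNA\t+\t0\t102"), tmp)
  expect_error(read_feature_table(tmp, 16407), "out of range.*trnS1")

  writeLines(c("name\tcategory\tstrand\tstart\tstop",
               "trnS1\ttRNA\t+\t42\t102",
               "trnS1\ttRNA\t+\t200\t260"), tmp)
  expect_error(read_feature_table(tmp, 16407), "duplicate")
})

test_that("feature-table round-trip is the identity", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  # published fixture
  ann <- lcoffeella_annotation()
  write_feature_table(ann, tmp)
  back <- read_feature_table(tmp, ann$genome_length,
                             source_id = ann$source_id)
  expect_equal(back$features, ann$features)
  # single feature
  one <- mito_annotation(
    data.frame(name = "COI", category = "PCG", strand = "+",
               start = 10, stop = 900), 1000)
  write_feature_table(one, tmp)
  expect_equal(read_feature_table(tmp, 1000)$features, one$features)
  # generator output, several seeds
  for (sd in c(4, 11)) {
    sim <- generate_mitogenome(generator_spec(), seed = sd)
    write_feature_table(sim$annotation, tmp)
    back <- read_feature_table(tmp, sim$annotation$genome_length)
    expect_equal(back$features, sim$annotation$features)
  }
})

test_that("gene names normalize across submitter dialects", {
  expect_equal(normalize_gene_name(c("ND5", "COX1", "COB", "16S", "12S")),
               c("NADH5", "COI", "CYTB", "rrnL", "rrnS"))
  expect_equal(normalize_gene_name(c("tRNA-Ser1", "trnL2", "tRNA-Met")),
               c("trnS1", "trnL2", "trnM"))
  expect_equal(normalize_gene_name("NADH4L"), "NADH4L")
})

test_that("GenBank parsing maps locations, strands and wrap joins", {
  tmp <- withr::local_tempfile(fileext = ".gb")
  writeLines(c(
    "LOCUS       test_mito        16407 bp    DNA     circular INV 01-JAN-2026",
    "FEATURES             Location/Qualifiers",
    "     source          1..16407",
    "     CDS             complement(273..1985)",
    "                     /gene=\"ND5\"",
    "     tRNA            join(16381..16407,1..41)",
    "                     /gene=\"trnN\"",
    "     misc_feature    8885..10247",
    "                     /note=\"control region\"",
    "//"), tmp)
  gb <- read_genbank(tmp)
  expect_null(gb$sequence)
  f <- gb$annotation$features
  nadh5 <- f[f$name == "NADH5", ]
  expect_equal(nadh5$strand, "-")
  expect_equal(c(nadh5$start, nadh5$stop), c(273L, 1985L))
  trnn <- f[f$name == "trnN", ]
  expect_true(trnn$wraps)
  expect_equal(feature_length(trnn, 16407), 68)
  expect_equal(f$category[f$name == "CR"], "control")
})

test_that("GenBank linear topology is refused and unknown genes warn", {
  tmp <- withr::local_tempfile(fileext = ".gb")
  writeLines(c(
    "LOCUS       test_lin        500 bp    DNA     linear INV 01-JAN-2026",
    "FEATURES             Location/Qualifiers",
    "     source          1..500",
    "     CDS             10..300",
    "                     /gene=\"mysterygene\"",
    "//"), tmp)
  expect_error(read_genbank(tmp), "not circular")
  gb <- NULL
  expect_warning(gb <- read_genbank(tmp, allow_linear = TRUE),
                 "unknown gene")
  expect_equal(gb$annotation$features$category, "other")
})

test_that("GenBank round-trip of generator output preserves everything", {
  sim <- generate_mitogenome(generator_spec(), seed = 7)
  tmp <- withr::local_tempfile(fileext = ".gb")
  write_genbank(sim$sequence, sim$annotation, tmp)
  back <- read_genbank(tmp)
  expect_equal(unclass(back$sequence), unclass(sim$sequence),
               ignore_attr = TRUE)
  expect_equal(back$annotation$features[, c("name", "strand", "start",
                                            "stop", "wraps")],
               sim$annotation$features[, c("name", "strand", "start",
                                           "stop", "wraps")])
})

test_that("completeness check distinguishes full and partial gene sets", {
  expect_true(is_complete_mitogenome(lcoffeella_annotation()))
  partial <- mito_annotation(
    data.frame(name = c("COI", "trnM"), category = c("PCG", "tRNA"),
               strand = "+", start = c(1, 2000), stop = c(1500, 2060)),
    16000)
  chk <- is_complete_mitogenome(partial)
  expect_false(chk)
  expect_true("ATP8" %in% attr(chk, "missing"))
  empty <- mito_annotation(
    data.frame(name = character(), category = character(),
               strand = character(), start = integer(), stop = integer()),
    16000)
  expect_false(is_complete_mitogenome(empty))
})
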