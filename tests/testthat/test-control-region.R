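# Control-region miners: tandem repeats, microsatellites, homopolymers,
# origin motifs, stem-loops.

test_that("tandem finder handles constructed and planted arrays", {
  # ACG repeated thrice, found at the smallest allowed unit
  hits <- find_tandem_repeats("ACGACGACG", min_unit = 3)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$unit_length, 3)
  expect_equal(hits$copy_number, 3.0)
  expect_equal(hits$unit_sequence, "ACG")
  # planted 57 bp unit, two copies, inside generator output
  sim <- generate_mitogenome(generator_spec(), seed = 1)
  rep <- control_region_report(sim$sequence, sim$annotation)
  for (t in sim$truth$control_region$tandem) {
    hit <- rep$tandem_repeats[
      rep$tandem_repeats$start == t$start &
        rep$tandem_repeats$unit_length == t$unit_length, ]
    expect_equal(nrow(hit), 1)
    expect_equal(hit$copy_number, t$copy_number)
    expect_equal(hit$unit_sequence, t$unit_sequence)
    expect_equal(hit$identity, 1)
  }
  expect_error(find_tandem_repeats("ACGT", min_unit = 10, max_unit = 5),
               "min_unit")
})

test_that("tandem finder is equivalent to the quadratic oracle", {
  # random AT-rich regions plus one real generated control region
  regions <- c(
    random_region(300, seed = 21),
    random_region(500, seed = 22),
    random_region(400, seed = 23,
                  probs = c(A = 0.3, T = 0.3, G = 0.2, C = 0.2)))
  sim <- generate_mitogenome(generator_spec(), seed = 2)
  f <- sim$annotation$features
  cr <- f[f$name == "CR", ]
  regions <- c(regions, circ_substr(sim$sequence, cr$start, cr$stop))
  for (region in regions) {
    got <- find_tandem_repeats(region)
    want <- oracle_tandem_repeats(region)
    expect_equal(got[c("start", "unit_length", "copy_number")], want,
                 ignore_attr = TRUE)
  }
})

test_that("microsatellite runs are maximal perfect repeats", {
  hits <- find_microsatellites("GGTATATATATAGG", min_repeats = 5)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 3)
  expect_equal(hits$copy_number, 5)
  expect_equal(nrow(find_microsatellites("GGGGCCCC")), 0)
  expect_error(find_microsatellites("ACGT", unit = ""), "non-empty")
  # four planted runs in generator output, nothing else
  sim <- generate_mitogenome(generator_spec(), seed = 3)
  rep <- control_region_report(sim$sequence, sim$annotation)
  truth <- sim$truth$control_region$microsat
  expect_equal(nrow(rep$microsatellites), length(truth))
  for (m in truth) {
    hit <- rep$microsatellites[rep$microsatellites$start == m$start, ]
    expect_equal(hit$copy_number, m$copy_number)
  }
})

test_that("homopolymer stretches respect per-base thresholds", {
  expect_equal(find_homopolymers("CCTTTTTTTCC"),
               data.frame(base = "T", start = 3L, length = 7L))
  expect_equal(find_homopolymers("AAAAA"),
               data.frame(base = "A", start = 1L, length = 5L))
  expect_equal(nrow(find_homopolymers("AAAATTTTTT")), 0)  # below both
  expect_error(find_homopolymers("AAAA", c(A = 1)), ">= 2")
  # planted counts recovered exactly
  sim <- generate_mitogenome(generator_spec(), seed = 4)
  rep <- control_region_report(sim$sequence, sim$annotation)
  tr <- sim$truth$control_region
  expect_equal(sum(rep$homopolymers$base == "T"), length(tr$polyT))
  expect_equal(sum(rep$homopolymers$base == "A"), length(tr$polyA))
  for (p in c(tr$polyT, tr$polyA)) {
    expect_true(any(rep$homopolymers$start == p$start &
                      rep$homopolymers$base == p$base &
                      rep$homopolymers$length == p$length))
  }
})

test_that("origin motifs are located exactly", {
  hits <- find_ori_motif("TTTATAGTTTT")
  expect_equal(hits$motif, "ATAGT")
  expect_equal(hits$start, 4)
  expect_equal(nrow(find_ori_motif("TTTTTTT")), 0)
  expect_error(find_ori_motif("ACGT", motifs = character()), "non-empty")
  sim <- generate_mitogenome(generator_spec(), seed = 5)
  rep <- control_region_report(sim$sequence, sim$annotation)
  ori <- sim$truth$control_region$ori[[1]]
  expect_true(ori$start %in%
                rep$ori_motifs$start[rep$ori_motifs$motif == ori$motif])
})

test_that("stem-loop finder reports the planted hairpin on top", {
  sim <- generate_mitogenome(generator_spec(), seed = 6)
  rep <- control_region_report(sim$sequence, sim$annotation)
  st <- sim$truth$control_region$stem[[1]]
  top <- rep$stem_loops[1, ]
  expect_equal(top$stem_length, st$stem_length)
  expect_equal(top$loop_length, st$loop_length)
  expect_equal(top$stem_start5, st$start)
  expect_equal(top$mismatches, 0)
  # no self-complementarity in a homopolymer
  expect_equal(nrow(find_stem_loops(strrep("A", 100))), 0)
})

test_that("stem-loop hits mirror under reverse complement", {
  region <- random_region(200, seed = 31)
  n <- nchar(region)
  fwd <- find_stem_loops(region, prune = FALSE)
  rev <- find_stem_loops(revcomp(region), prune = FALSE)
  key <- function(df, mirror = FALSE) {
    s5 <- if (mirror) n - (df$stem_start3 + df$stem_length - 1L) + 1L else
      df$stem_start5
    sort(paste(s5, df$stem_length, df$loop_length, df$mismatches))
  }
  expect_equal(key(rev, mirror = TRUE), key(fwd))
})

test_that("the full report carries region stats and absolute coordinates", {
  sim <- generate_mitogenome(generator_spec(), seed = 7)
  rep <- control_region_report(sim$sequence, sim$annotation)
  expect_equal(rep$region_length, 1363)
  expect_gt(rep$pct_AT, 90)
  f <- sim$annotation$features
  cr_start <- f$start[f$name == "CR"]
  expect_equal(rep$ori_motifs$abs_start,
               cr_start + rep$ori_motifs$start - 1L)
  tmp <- withr::local_tempfile(fileext = ".json")
  write_control_region_report(rep, tmp)
  expect_true(jsonlite::validate(paste(readLines(tmp), collapse = "")))
})
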