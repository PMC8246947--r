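test_that("genome simulation is deterministic and respects parameters", {
  g1 <- simulate_genomes(1, 5e4, homology = 0, seed = 7)
  expect_length(g1, 1)
  expect_equal(nchar(g1[[1]]), 50000)
  expect_true(grepl("^[ACGT]+$", g1[[1]]))
  g2 <- simulate_genomes(2, 1e5, homology = 0.1, seed = 1)
  g3 <- simulate_genomes(2, 1e5, homology = 0.1, seed = 1)
  expect_identical(g2, g3)
  g4 <- simulate_genomes(2, 1e5, homology = 0.1, seed = 2)
  expect_false(identical(as.character(g2), as.character(g4)))
  expect_error(simulate_genomes(2, 1e5, homology = 1.5, seed = 1),
               "fractions")
})

test_that("declared homology yields verbatim shared segments of the right total size", {
  g <- simulate_genomes(2, 1e5, homology = 0.1, seed = 1)
  # independent scan: 300-bp windows of the recipient searched in the donor
  win <- seq(1, 1e5 - 300, by = 150)
  shared <- vapply(win, function(p) {
    grepl(substr(g[[2]], p, p + 299), g[[1]], fixed = TRUE)
  }, logical(1))
  expect_true(any(shared))  # at least one verbatim segment >= 300 bp
  # ~10 kb shared in ~2 kb segments; window granularity and segment
  # overlap allow a generous band
  expect_gt(sum(shared) * 150, 6000)
  expect_lt(sum(shared) * 150, 14000)
})

test_that("restriction sites are seeded into every genome", {
  g <- simulate_genomes(3, 5e4, seed = 3)
  for (s in as.character(g)) {
    expect_true(grepl("TTAATTAA", s, fixed = TRUE))
    expect_true(grepl("ATGCAT", s, fixed = TRUE))
  }
})

test_that("digest keeps heterologous fragments above the size minimum", {
  # single heterologous fragment between a PacI and an NsiI site
  mid <- paste(rep("C", 200), collapse = "")
  g <- paste0("AAA", "TTAATTAA", mid, "ATGCAT", "GGG")
  fr <- digest_genome(g, size_min = 100)
  expect_equal(nrow(fr), 1)
  expect_equal(fr$enzyme5, "site1")
  expect_equal(fr$enzyme3, "site2")
  expect_equal(fr$length, 4 + 200 + 3)  # cut offsets at motif midpoints
  expect_equal(fr$seq, substr(g, fr$start + 1, fr$end))

  # two PacI sites, no NsiI: homologous ends never amplify
  g2 <- paste0("AAA", "TTAATTAA", mid, "TTAATTAA", "GGG")
  expect_equal(nrow(digest_genome(g2, size_min = 10)), 0)
  # no cut sites at all: empty result, not an error
  expect_equal(nrow(digest_genome(paste(rep("A", 500), collapse = ""))), 0)
})

test_that("digest matches a brute-force position-scan oracle", {
  set.seed(3)
  g <- paste(sample(c("A", "C", "G", "T"), 1e5, replace = TRUE),
             collapse = "")
  # seed some sites so both enzymes certainly occur
  for (p in c(1000, 22000, 47000, 71000))
    substr(g, p, p + 7) <- "TTAATTAA"
  for (p in c(9000, 30000, 58000, 90000))
    substr(g, p, p + 5) <- "ATGCAT"
  got <- digest_genome(g, size_min = 150)
  exp <- oracle_digest(g, size_min = 150)
  expect_equal(got$start, exp$start)
  expect_equal(got$end, exp$end)
})

test_that("sample and design specifications validate their invariants", {
  expect_error(sample_spec("s", "monoculture",
                           c(sp1 = 0.5, sp2 = 0.5), 100),
               "exactly one species")
  expect_error(sample_spec("s", "calibration",
                           c(sp1 = 0.7, sp2 = 0.3), 100), "equal")
  expect_error(sample_spec("s", "mixture", c(sp1 = 0.6, sp2 = 0.3), 100),
               "sum to 1")
  s <- sample_spec("s", "mixture", c(sp1 = 0.6, sp2 = 0.4), 100)
  expect_error(library_design(list(s), duplication_rate = 1.2, seed = 1))
  expect_error(library_design(list(s), yield_factor = c(sp1 = -1), seed = 1),
               "yield factors")
  expect_error(
    simulate_library(simulate_genomes(1, 1e4 + 1, seed = 1),
                     library_design(list(
                       sample_spec("s", "monoculture", c(spX = 1), 10)),
                       seed = 1)),
    "spX")
})

test_that("error-free monoculture reads are exact substrings of the genome", {
  sim <- clean_sim()
  lib <- sim$library
  pp <- preprocess_reads(lib)
  mono1 <- pp$reads[pp$reads$sample_id == "mono_sp1" &
                      pp$reads$mode == "merged", ]
  idx <- sample(nrow(mono1), 50)
  for (s in mono1$sequence[idx])
    expect_true(grepl(s, sim$genomes[["sp1"]], fixed = TRUE))
})

test_that("library simulation conserves molecules and marks true duplicates", {
  sim <- clean_sim()
  counts <- sim$library$truth$counts
  # per sample, fresh molecules sum to the requested fragment count
  tot <- tapply(counts$true_fragments, counts$sample_id, sum)
  expect_true(all(tot == 3000))
  expect_true(all(!sim$library$truth$pairs$is_duplicate))  # rate 0

  # duplication_rate 0.5: about half of emitted pairs repeat an earlier
  # (fragment, UMI pair) molecule. Uniform locus weights keep chance
  # (fragment, UMI) collisions between distinct molecules negligible.
  g <- simulate_genomes(1, 1e5, seed = 21)
  des <- library_design(list(
    sample_spec("m", "monoculture", c(sp1 = 1), 10000)),
    duplication_rate = 0.5, error_rate = 0, locus_weight_sdlog = 0,
    short_bias_bp = Inf, seed = 22)
  lib <- simulate_library(g, des)
  p <- lib$truth$pairs
  key <- paste(p$fragment, p$umi1, p$umi2)
  expect_equal(sum(p$is_duplicate), nrow(p) - 10000)  # re-emissions only
  dup_frac <- mean(duplicated(key))
  expect_equal(dup_frac, 0.5, tolerance = 0.05)
  # every duplicate repeats an existing molecule: no new (fragment, UMI)
  expect_true(all(!p$is_duplicate | duplicated(key) |
                    key %in% key[!p$is_duplicate]))
})

test_that("read share follows proportion x yield factor", {
  g <- simulate_genomes(4, 1e5, seed = 31)
  des <- library_design(list(
    sample_spec("cal", "calibration",
                setNames(rep(0.25, 4), names(g)), 20000)),
    duplication_rate = 0, error_rate = 0,
    yield_factor = setNames(c(1, 1, 1, 4), names(g)), seed = 32)
  lib <- simulate_library(g, des)
  share <- prop.table(table(lib$truth$pairs$species_id))[names(g)]
  expect_equal(as.numeric(share), c(1, 1, 1, 4) / 7, tolerance = 0.05)
})

test_that("simulation is byte-identical under a fixed seed", {
  args <- list(n_species = 2, genome_length = 2e4, n_calibration = 3,
               depth_monoculture = 300, depth_calibration = 300,
               depth_mixture = 300, seed = 99)
  a <- do.call(simulate_msgbs_dataset, args)
  b <- do.call(simulate_msgbs_dataset, args)
  expect_identical(a$library$reads1, b$library$reads1)
  expect_identical(a$library$reads2, b$library$reads2)
  expect_identical(a$library$truth$pairs, b$library$truth$pairs)
})

test_that("unassignable contamination is emitted at the requested rate", {
  g <- simulate_genomes(1, 1e5, seed = 41)
  des <- library_design(list(
    sample_spec("m", "monoculture", c(sp1 = 1), 5000)),
    duplication_rate = 0, error_rate = 0,
    phix_rate = 0.07, dimer_rate = 0.03, seed = 42)
  lib <- simulate_library(g, des)
  frac <- mean(lib$truth$pairs$origin != "sample")
  expect_equal(frac, 0.1, tolerance = 0.02)
  dm <- demultiplex(lib$reads1, lib$reads2, lib$qual1, lib$qual2, lib$sheet)
  expect_equal(dm$report[["assigned"]] / dm$report[["input"]], 0.9,
               tolerance = 0.02)
})
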