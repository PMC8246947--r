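toy_ref <- function(centroids, species) {
  per <- split(centroids, species)
  build_meta_reference(lapply(per, function(s)
    data.frame(centroid = s, member_count = 1, abundance = 2)))
}

toy_reads <- function(seqs, sample = "s1", umi = NULL) {
  if (is.null(umi)) umi <- rep("AAATTT", length(seqs))
  data.frame(read_id = seq_along(seqs), sample_id = sample,
             umi = umi, sequence = seqs, mode = "merged")
}

test_that("reads map to their centroid at full identity, or not at all", {
  set.seed(81)
  cents <- random_seqs(4, 200)
  ref <- toy_ref(cents, c("A", "A", "B", "B"))
  mp <- map_reads(toy_reads(cents[2]), ref)
  expect_equal(mp$mapped$cluster_id, "A_2")
  expect_equal(mp$mapped$identity, 1)
  # reverse-complement reads map as well
  mp_rc <- map_reads(toy_reads(revcomp(cents[2])), ref)
  expect_equal(mp_rc$mapped$cluster_id, "A_2")
  # 80% identity stays below the 0.95 threshold
  far <- mutate_seq(cents[1], 40)
  mp2 <- map_reads(toy_reads(far), ref)
  expect_equal(nrow(mp2$mapped), 0)
  expect_equal(mp2$report[["unmapped"]], 1)
  expect_error(map_reads(toy_reads(cents[1]), ref[0, ]), "empty")
})

test_that("cross-species best-hit ties are discarded, same-species ties kept", {
  set.seed(82)
  shared <- random_seqs(1, 200)
  other <- random_seqs(1, 200)
  # same centroid present in two species: ambiguous
  ref2 <- toy_ref(c(shared, other, shared), c("A", "A", "B"))
  mp <- map_reads(toy_reads(shared), ref2)
  expect_equal(nrow(mp$mapped), 0)
  expect_equal(mp$report[["ambiguous"]], 1)
  # duplicate centroid within one species: lowest cluster wins
  ref3 <- toy_ref(c(shared, shared, other), c("A", "A", "A"))
  mp3 <- map_reads(toy_reads(shared), ref3)
  expect_equal(mp3$mapped$cluster_id, "A_1")
})

test_that("seeded diagonal identity agrees with semi-global alignment", {
  set.seed(83)
  refs <- random_seqs(25, 260)
  reads <- vapply(sample(refs, 150, TRUE), function(s)
    mutate_seq(substr(s, 6, 255), sample(0:8, 1)), character(1))
  m <- msgbs:::cpp_map_reads(reads, refs, 0.9)
  for (i in seq_along(reads)) {
    if (is.na(m$identity[i])) next
    dp <- max(vapply(refs, function(r)
      max(msgbs:::cpp_semiglobal_identity(reads[i], r),
          msgbs:::cpp_semiglobal_identity(revcomp(reads[i]), r)),
      numeric(1)))
    # gapped DP can only match or improve the ungapped diagonal score
    expect_lte(m$identity[i], dp + 1e-12)
    expect_gt(m$identity[i], dp - 0.01)
  }
})

test_that("duplicate marking works per (sample, cluster, UMI) group", {
  set.seed(84)
  cents <- random_seqs(2, 200)
  ref <- toy_ref(cents, c("A", "B"))
  # two reads, same sample + cluster + UMI: exactly one flagged
  rd <- toy_reads(rep(cents[1], 2), umi = c("AAAAAA", "AAAAAA"))
  mk <- mark_duplicates(map_reads(rd, ref)$mapped)
  expect_equal(sum(mk$is_duplicate), 1)
  expect_false(mk$is_duplicate[order(mk$read_id)][1])  # first kept
  # same UMI in different clusters: neither flagged
  rd2 <- toy_reads(cents, umi = c("AAAAAA", "AAAAAA"))
  mk2 <- mark_duplicates(map_reads(rd2, ref)$mapped)
  expect_equal(sum(mk2$is_duplicate), 0)
  # same UMI, different samples: neither flagged
  rd3 <- rbind(toy_reads(cents[1], "s1"), toy_reads(cents[1], "s2"))
  rd3$read_id <- 1:2
  mk3 <- mark_duplicates(map_reads(rd3, ref)$mapped)
  expect_equal(sum(mk3$is_duplicate), 0)
  # missing UMI is a data error
  rd4 <- toy_reads(cents[1], umi = "")
  expect_error(mark_duplicates(map_reads(rd4, ref)$mapped), "UMI")
})

test_that("duplicate flags equal simulated truth at duplication_rate 0.3", {
  g <- simulate_genomes(2, 1e5, seed = 85)
  des <- library_design(list(
    sample_spec("m1", "monoculture", c(sp1 = 1), 4000),
    sample_spec("m2", "monoculture", c(sp2 = 1), 4000)),
    duplication_rate = 0.3, error_rate = 0, monoculture_impurity = 0,
    seed = 86)
  lib <- simulate_library(g, des)
  res <- run_msgbs(lib, params = filter_params(f3 = 0), calibrate = FALSE)
  pp <- preprocess_reads(lib)
  mp <- map_reads(pp$reads, res$reference)
  mk <- mark_duplicates(mp$mapped)
  p <- lib$truth$pairs
  truth_dup <- duplicated(paste(p$sample_id, p$fragment, p$species_id,
                                p$umi1, p$umi2))
  # flags equal truth among mapped reads (UMI collisions are possible in
  # principle but absent at this depth and seed)
  expect_equal(sum(mk$is_duplicate), sum(truth_dup[mk$read_id]))
})

test_that("duplicate false positives stay within the UMI collision bound", {
  sim <- clean_sim()  # duplication_rate 0
  res <- clean_run()
  pp <- preprocess_reads(sim$library)
  mp <- map_reads(pp$reads, res$reference)
  mk <- mark_duplicates(mp$mapped)
  # expected collisions: sum over (sample, cluster) groups of C(n,2) / 4^6
  n <- table(paste(mk$sample_id, mk$cluster_id))
  bound <- sum(n * (n - 1) / 2) / 4^6
  expect_lte(sum(mk$is_duplicate), 10 * bound)
})

test_that("qc flagging thresholds identity as specified", {
  set.seed(87)
  cents <- random_seqs(1, 300)
  ref <- toy_ref(cents, "A")
  rd <- toy_reads(c(cents, mutate_seq(cents, 6)))  # identities 1 and 0.98
  mp <- map_reads(rd, ref)$mapped
  expect_equal(sum(mark_qc_fail(mp, 0)$qc_fail), 0)
  expect_equal(sum(mark_qc_fail(mp, 1)$qc_fail), 1)
  flagged <- mark_qc_fail(mp, 0.99)
  expect_equal(flagged$qc_fail, flagged$identity < 0.99)
})

test_that("count matrix excludes flags and drops sparse clusters", {
  set.seed(88)
  cents <- random_seqs(2, 200)
  ref <- toy_ref(cents, c("A", "B"))
  sheet <- data.frame(sample_id = c("s1", "s2"), role = "mixture",
                      index1 = c("AA", "CC"), index2 = c("GG", "TT"),
                      species_id = NA)
  rd <- rbind(toy_reads(rep(cents[1], 12), "s1"),
              toy_reads(rep(cents[2], 9), "s2"))
  rd$read_id <- seq_len(nrow(rd))
  rd$umi <- random_seqs(nrow(rd), 6)
  mp <- map_reads(rd, ref)$mapped
  cm <- build_count_matrix(mp, ref, sheet, min_cluster_total = 10)
  expect_equal(rownames(cm), "A_1")  # 9-read cluster dropped
  expect_equal(unname(cm["A_1", "s1"]), 12)
  cm0 <- build_count_matrix(mp, ref, sheet, min_cluster_total = 0)
  expect_equal(unname(rowSums(cm0)), c(12, 9))
  # flagged reads contribute nothing
  mp$is_duplicate[1] <- TRUE
  mp$qc_fail[2] <- TRUE
  cmf <- build_count_matrix(mp, ref, sheet, min_cluster_total = 0)
  expect_equal(sum(cmf), nrow(mp) - 2)
})

test_that("read counts are conserved through mapping and counting", {
  res <- messy_run()
  r <- res$map_report
  expect_equal(r[["mapped"]] + r[["unmapped"]] + r[["ambiguous"]],
               r[["input"]])
  expect_equal(r[["input"]], res$reads_report[["assembled"]])
})
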