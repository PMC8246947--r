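#' Demultiplex paired reads by adapter index
#'
#' Assigns each read pair to a sample when both mate indices match one
#' sample's index pair within `max_mismatch` mismatches, strips the UMI
#' and index prefixes from the sequences, and records the 6-nt combined
#' UMI. Pairs matching no sample (or more than one) are counted as
#' unassigned and not emitted.
#'
#' @param reads1,reads2 character vectors of raw mate sequences
#'   (UMI + index + insert layout).
#' @param qual1,qual2 matching per-base quality strings.
#' @param sheet sample sheet data.frame with `sample_id`, `index1`,
#'   `index2` (see [sample_sheet()]).
#' @param max_mismatch allowed mismatches per index (default 0).
#' @param umi_length UMI nucleotides per mate (default 3).
#' @return list with `reads` (data.frame: `sample_id`, `umi`, `seq1`,
#'   `seq2`, `qual1`, `qual2`) and `report` (assigned / unassigned
#'   counts).
#' @export
demultiplex <- function(reads1, reads2, qual1, qual2, sheet,
                        max_mismatch = 0, umi_length = 3) {
  stopifnot(length(reads1) == length(reads2))
  key <- paste(sheet$index1, sheet$index2)
  if (anyDuplicated(key))
    stop("ambiguous sample sheet: two samples share an index pair",
         call. = FALSE)
  ilen <- unique(nchar(c(sheet$index1, sheet$index2)))
  if (length(ilen) != 1)
    stop("all index tags must have equal length", call. = FALSE)
  mind <- min_index_distance(sheet)
  if (nrow(sheet) > 1 && mind <= 2 * max_mismatch)
    stop("index pairs are not distinguishable at max_mismatch = ",
         max_mismatch, " (minimum pair distance ", mind, ")", call. = FALSE)
  u <- umi_length
  umi1 <- substr(reads1, 1L, u)
  umi2 <- substr(reads2, 1L, u)
  idx1 <- substr(reads1, u + 1L, u + ilen)
  idx2 <- substr(reads2, u + 1L, u + ilen)
  if (max_mismatch == 0) {
    hit <- match(paste(idx1, idx2), key)
  } else {
    n <- length(reads1)
    hit <- rep(NA_integer_, n)
    nhit <- integer(n)
    for (s in seq_len(nrow(sheet))) {
      mm <- index_mismatches(idx1, sheet$index1[s], ilen) +
        index_mismatches(idx2, sheet$index2[s], ilen)
      ok <- mm <= 2 * max_mismatch &
        index_mismatches(idx1, sheet$index1[s], ilen) <= max_mismatch &
        index_mismatches(idx2, sheet$index2[s], ilen) <= max_mismatch
      hit[ok] <- s
      nhit <- nhit + ok
    }
    hit[nhit > 1] <- NA_integer_  # ambiguous
  }
  keep <- !is.na(hit)
  out <- data.frame(
    sample_id = sheet$sample_id[hit[keep]],
    umi = paste0(umi1[keep], umi2[keep]),
    seq1 = substr(reads1[keep], u + ilen + 1L, nchar(reads1[keep])),
    seq2 = substr(reads2[keep], u + ilen + 1L, nchar(reads2[keep])),
    qual1 = substr(qual1[keep], u + ilen + 1L, nchar(qual1[keep])),
    qual2 = substr(qual2[keep], u + ilen + 1L, nchar(qual2[keep])))
  list(reads = out,
       report = c(input = length(reads1), assigned = sum(keep),
                  unassigned = sum(!keep)))
}

#' @noRd
index_mismatches <- function(tags, pattern, ilen) {
  mm <- integer(length(tags))
  for (p in seq_len(ilen))
    mm <- mm + (substr(tags, p, p) != substr(pattern, p, p))
  mm
}

#' @noRd
min_index_distance <- function(sheet) {
  n <- nrow(sheet)
  if (n < 2) return(Inf)
  pairs <- paste0(sheet$index1, sheet$index2)
  d <- Inf
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n))
    d <- min(d, hamming_dist(pairs[i], pairs[j]))
  d
}

#' Trim adapter traces and low-quality 3' tails
#'
#' Known adapter occurrences that run into the 3' end are removed first,
#' then the maximal suffix of bases below `q_threshold` is removed.
#' Empty reads after trimming are legal here and dropped downstream.
#'
#' @param seqs,quals character vectors of sequences and quality strings.
#' @param q_threshold phred cut-off (default 10); bases strictly below it
#'   are trimmed from the 3' end.
#' @param adapter adapter sequence to remove, or `NULL` to skip adapter
#'   trimming.
#' @param min_adapter_match minimum matching adapter prefix at the read
#'   end (default 5 nt).
#' @param offset phred ASCII offset (default 33).
#' @return list with trimmed `seqs` and `quals`.
#' @export
quality_trim <- function(seqs, quals, q_threshold = 10, adapter = NULL,
                         min_adapter_match = 5, offset = 33) {
  if (!is.null(adapter)) {
    cut <- cpp_find_adapter(seqs, adapter, min_adapter_match)
    seqs <- substr(seqs, 1L, cut)
    quals <- substr(quals, 1L, cut)
  }
  keep <- cpp_trim_qual(quals, q_threshold, offset)
  list(seqs = substr(seqs, 1L, keep), quals = substr(quals, 1L, keep))
}

#' Merge or join mate pairs into assembled reads
#'
#' Mate 1 and the reverse complement of mate 2 are merged into a consensus
#' when they overlap by at least `min_overlap` bases at >=
#' `min_identity` identity (the higher-quality base wins at mismatches,
#' mate 1 at quality ties); otherwise the pair is joined with a fixed run
#' of `sep_length` N characters between the mates so a joined read can
#' never spuriously align across the junction.
#'
#' @param seq1,seq2,qual1,qual2 mate sequences/qualities (insert only, no
#'   UMI/index).
#' @param min_overlap minimum merge overlap in bp (default 20).
#' @param min_identity minimum fraction of matching bases in the overlap
#'   (default 0.9).
#' @param sep_length joined-read separator length (default 10).
#' @return list with `seq`, `qual` and `mode` (`"merged"`/`"joined"`)
#'   vectors.
#' @export
assemble_pairs <- function(seq1, seq2, qual1, qual2, min_overlap = 20,
                           min_identity = 0.9, sep_length = 10) {
  m <- cpp_merge_pairs(seq1, seq2, qual1, qual2, min_overlap, min_identity)
  sep <- strrep("N", sep_length)
  sepq <- strrep("!", sep_length)
  joined <- !m$merged
  seq <- m$seq
  qual <- m$qual
  if (any(joined)) {
    seq[joined] <- paste0(seq1[joined], sep, revcomp(seq2[joined]))
    qual[joined] <- paste0(qual1[joined], sepq,
                           cpp_reverse_strings(qual2[joined]))
  }
  list(seq = seq, qual = qual,
       mode = ifelse(m$merged, "merged", "joined"))
}

#' Preprocess a raw paired-end read set into assembled reads
#'
#' Runs the full first stage: demultiplexing, UMI extraction, adapter and
#' quality trimming, and overlap merging/joining, returning one assembled
#' read per surviving pair.
#'
#' @param lib an `msgbs_library` (from [simulate_library()]) or a list
#'   with `reads1`, `reads2`, `qual1`, `qual2` and `sheet`.
#' @param q_threshold,adapter,min_adapter_match see [quality_trim()];
#'   `adapter` defaults to the library design's adapter when available.
#' @param min_overlap,merge_identity,sep_length see [assemble_pairs()].
#' @param max_mismatch,umi_length see [demultiplex()].
#' @param min_length minimum mate length after trimming; pairs with a
#'   shorter mate are dropped and counted.
#' @return list with `reads` (data.frame: `read_id`, `sample_id`, `umi`,
#'   `sequence`, `mode`) and `report` (named counts: input, assigned,
#'   unassigned, dropped_short, assembled, merged, joined).
#' @export
preprocess_reads <- function(lib, q_threshold = 10, adapter = NULL,
                             min_adapter_match = 5, min_overlap = 20,
                             merge_identity = 0.9, sep_length = 10,
                             max_mismatch = 0, umi_length = 3,
                             min_length = 20) {
  if (is.null(adapter) && !is.null(lib$design)) adapter <- lib$design$adapter
  dm <- demultiplex(lib$reads1, lib$reads2, lib$qual1, lib$qual2,
                    lib$sheet, max_mismatch = max_mismatch,
                    umi_length = umi_length)
  rd <- dm$reads
  t1 <- quality_trim(rd$seq1, rd$qual1, q_threshold, adapter,
                     min_adapter_match)
  t2 <- quality_trim(rd$seq2, rd$qual2, q_threshold, adapter,
                     min_adapter_match)
  ok <- nchar(t1$seqs) >= min_length & nchar(t2$seqs) >= min_length
  asm <- assemble_pairs(t1$seqs[ok], t2$seqs[ok], t1$quals[ok],
                        t2$quals[ok], min_overlap, merge_identity,
                        sep_length)
  reads <- data.frame(read_id = which(ok),
                      sample_id = rd$sample_id[ok],
                      umi = rd$umi[ok],
                      sequence = asm$seq,
                      mode = asm$mode)
  report <- c(dm$report,
              dropped_short = sum(!ok),
              assembled = nrow(reads),
              merged = sum(asm$mode == "merged"),
              joined = sum(asm$mode == "joined"))
  list(reads = reads, report = report)
}
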