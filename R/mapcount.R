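#' Map assembled reads to the meta-reference
#'
#' Best-hit mapping of every read against all cluster centroids, both
#' orientations. A read is assigned when its best identity reaches
#' `min_identity`. Ties across clusters of the same species resolve to
#' the lowest cluster in reference order; ties across clusters of
#' different species are conservative evidence of shared sequence and the
#' read is discarded as ambiguous (counted). Joined reads carry an N
#' junction whose positions are excluded from identity on both sides, so
#' they effectively score as two sub-alignments.
#'
#' Mapping uses exact k-mer seeding followed by ungapped diagonal scoring
#' (identity = matching bases / scored read bases), which matches the
#' gapped semi-global alignment score whenever the best alignment is
#' indel-free; the internal `cpp_semiglobal_identity()` kernel provides
#' the gapped score for small-scale verification.
#'
#' @param reads preprocessed read data.frame (needs `sequence`,
#'   `sample_id`, `umi`, `read_id`).
#' @param ref an `msgbs_reference`.
#' @param min_identity minimum identity (default 0.95).
#' @return list with `mapped` (data.frame: `read_id`, `sample_id`, `umi`,
#'   `cluster_id`, `species`, `identity`, `is_duplicate`, `qc_fail`) and
#'   `report` (input, mapped, unmapped, ambiguous counts).
#' @export
map_reads <- function(reads, ref, min_identity = 0.95) {
  if (!nrow(ref)) stop("empty meta-reference", call. = FALSE)
  hits <- cpp_map_reads(reads$sequence, ref$centroid, min_identity)
  best <- hits$best
  # resolve ties: same species -> first cluster; cross-species -> discard
  ambiguous <- logical(length(best))
  for (i in which(lengths(hits$ties) > 1L)) {
    if (length(unique(ref$species[hits$ties[[i]]])) > 1L)
      ambiguous[i] <- TRUE
  }
  keep <- !is.na(best) & !ambiguous
  mapped <- data.frame(read_id = reads$read_id[keep],
                       sample_id = reads$sample_id[keep],
                       umi = reads$umi[keep],
                       cluster_id = ref$cluster_id[best[keep]],
                       species = ref$species[best[keep]],
                       identity = hits$identity[keep],
                       is_duplicate = logical(sum(keep)),
                       qc_fail = logical(sum(keep)))
  list(mapped = mapped,
       report = c(input = nrow(reads), mapped = nrow(mapped),
                  unmapped = sum(is.na(best)),
                  ambiguous = sum(ambiguous)))
}

#' Mark PCR duplicates
#'
#' Within each (sample, cluster) group, reads sharing an identical
#' combined UMI are duplicates: the first read in deterministic order
#' (identity descending, then read id) is kept, the rest are flagged.
#'
#' @param mapped mapped-read data.frame from [map_reads()].
#' @return the same data.frame with `is_duplicate` set.
#' @export
mark_duplicates <- function(mapped) {
  if (any(is.na(mapped$umi) | !nzchar(mapped$umi))) {
    bad <- mapped$read_id[which(is.na(mapped$umi) | !nzchar(mapped$umi))[1]]
    stop("read ", bad, " has no UMI tag", call. = FALSE)
  }
  o <- order(mapped$sample_id, mapped$cluster_id, mapped$umi,
             -mapped$identity, mapped$read_id, method = "radix")
  key <- paste(mapped$sample_id[o], mapped$cluster_id[o], mapped$umi[o],
               sep = "\r")
  dup <- duplicated(key)
  mapped$is_duplicate[o] <- dup
  mapped
}

#' Flag reads with mapping identity below a quality threshold
#'
#' @param mapped mapped-read data.frame.
#' @param min_score identity threshold; reads strictly below are flagged.
#'   Defaults to 0 (no flags), as the mapping threshold itself already
#'   bounds identity; set higher for a stricter post-hoc cut.
#' @return the same data.frame with `qc_fail` set.
#' @export
mark_qc_fail <- function(mapped, min_score = 0) {
  mapped$qc_fail <- mapped$identity < min_score
  mapped
}

#' Build the cluster x sample count matrix
#'
#' Counts retained (non-duplicate, non-qc-fail) reads per cluster and
#' sample and drops clusters whose total over all samples is below
#' `min_cluster_total`.
#'
#' @param mapped mapped-read data.frame (after [mark_duplicates()] /
#'   [mark_qc_fail()]).
#' @param ref the `msgbs_reference` the reads were mapped to.
#' @param sheet the sample sheet (defines the sample columns and roles).
#' @param min_cluster_total minimum per-cluster row sum (default 10).
#' @return object of class `msgbs_counts`: an integer matrix (clusters x
#'   samples) with attributes `cluster_species` (named map cluster ->
#'   species) and `sample_roles` (named map sample -> role).
#' @export
build_count_matrix <- function(mapped, ref, sheet, min_cluster_total = 10) {
  use <- !mapped$is_duplicate & !mapped$qc_fail
  m <- table(factor(mapped$cluster_id[use], levels = ref$cluster_id),
             factor(mapped$sample_id[use], levels = sheet$sample_id))
  m <- matrix(as.integer(m), nrow = nrow(m),
              dimnames = dimnames(m))
  keep <- rowSums(m) >= min_cluster_total
  m <- m[keep, , drop = FALSE]
  mono <- sheet$role == "monoculture" & !is.na(sheet$species_id)
  structure(m,
            cluster_species = setNames(ref$species, ref$cluster_id)[
              rownames(m)],
            sample_roles = setNames(sheet$role, sheet$sample_id),
            mono_species = setNames(sheet$species_id[mono],
                                    sheet$sample_id[mono]),
            class = c("msgbs_counts", class(m)))
}

#' @export
print.msgbs_counts <- function(x, ...) {
  roles <- attr(x, "sample_roles")[colnames(x)]
  cat("msGBS count matrix:", nrow(x), "clusters x", ncol(x), "samples",
      sprintf("(%d monoculture, %d calibration, %d mixture)\n",
              sum(roles == "monoculture"), sum(roles == "calibration"),
              sum(roles == "mixture")))
  cat("  total counted reads:", sum(x), "\n")
  cat("  species:", paste(unique(attr(x, "cluster_species")),
                          collapse = ", "), "\n")
  invisible(x)
}

# Subset a count matrix while preserving annotations.
#' @noRd
subset_counts <- function(x, rows = NULL, cols = NULL) {
  cs <- attr(x, "cluster_species")
  sr <- attr(x, "sample_roles")
  ms <- attr(x, "mono_species")
  m <- unclass(x)
  attr(m, "cluster_species") <- NULL
  attr(m, "sample_roles") <- NULL
  attr(m, "mono_species") <- NULL
  if (!is.null(rows)) m <- m[rows, , drop = FALSE]
  if (!is.null(cols)) m <- m[, cols, drop = FALSE]
  structure(m, cluster_species = cs[rownames(m)], sample_roles = sr,
            mono_species = ms[intersect(names(ms), colnames(m))],
            class = c("msgbs_counts", class(m)))
}
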