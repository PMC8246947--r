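#' Dereplicate assembled reads
#'
#' Collapses exact-duplicate sequences into unique sequences with
#' abundances, discards uniques seen fewer than `min_unique_size` times,
#' and orders the result by abundance descending with ties broken by
#' lexicographic sequence order (the input order expected by
#' [cluster_sequences()]).
#'
#' @param seqs character vector of assembled read sequences from one
#'   monoculture sample.
#' @param min_unique_size minimum abundance of a retained unique sequence
#'   (default 2; 3 is appropriate for high-depth monocultures, where
#'   singleton error sequences are more frequent).
#' @return data.frame with columns `sequence` and `abundance`.
#' @export
dereplicate <- function(seqs, min_unique_size = 2) {
  stopifnot(min_unique_size >= 1)
  tab <- table(seqs)
  ab <- as.integer(tab)
  sq <- names(tab)
  keep <- ab >= min_unique_size
  ab <- ab[keep]; sq <- sq[keep]
  o <- order(-ab, sq, method = "radix")
  data.frame(sequence = sq[o], abundance = ab[o])
}

#' Greedy centroid clustering of dereplicated sequences
#'
#' Scans the uniques in their given (abundance-then-lexicographic) order;
#' each sequence joins the first already-founded centroid it reaches the
#' identity threshold with — in either orientation — or founds a new
#' centroid. Identity is `1 - d / max(length)` with `d` the unit-cost
#' global alignment (Levenshtein) distance, so end gaps are penalized.
#' Deterministic given the input order.
#'
#' @param uniques data.frame from [dereplicate()] (columns `sequence`,
#'   `abundance`).
#' @param identity identity threshold in \[0, 1\] (default 0.95).
#' @return data.frame with one row per cluster: `centroid` (the founding
#'   sequence), `member_count` (number of unique sequences in the
#'   cluster) and `abundance` (summed read abundance), in founding order.
#' @export
cluster_sequences <- function(uniques, identity = 0.95) {
  if (!nrow(uniques))
    return(data.frame(centroid = character(), member_count = integer(),
                      abundance = integer()))
  assign <- cpp_greedy_cluster(uniques$sequence, identity)
  founders <- sort(unique(assign))
  data.frame(
    centroid = uniques$sequence[founders],
    member_count = as.integer(table(factor(assign, levels = founders))),
    abundance = as.integer(tapply(uniques$abundance,
                                  factor(assign, levels = founders), sum)))
}

#' Combine per-species clusters into a species-labelled meta-reference
#'
#' @param per_species_clusters named list (species id ->
#'   [cluster_sequences()] result). A species with zero clusters is kept
#'   in the index with a warning.
#' @return object of class `msgbs_reference`: data.frame with
#'   `cluster_id` (species tag + ordinal, e.g. `spA_1`), `species`,
#'   `centroid`, `member_count`, plus a `species_index` attribute
#'   (species -> cluster ids).
#' @export
build_meta_reference <- function(per_species_clusters) {
  species <- names(per_species_clusters)
  if (is.null(species) || anyDuplicated(species))
    stop("per-species cluster list must have unique species names",
         call. = FALSE)
  parts <- lapply(species, function(sp) {
    cl <- per_species_clusters[[sp]]
    if (!nrow(cl)) {
      warning("species ", sp, " contributed no clusters", call. = FALSE)
      return(data.frame(cluster_id = character(), species = character(),
                        centroid = character(), member_count = integer()))
    }
    data.frame(cluster_id = paste0(sp, "_", seq_len(nrow(cl))),
               species = sp, centroid = cl$centroid,
               member_count = cl$member_count)
  })
  ref <- do.call(rbind, parts)
  rownames(ref) <- NULL
  attr(ref, "species_index") <- split(ref$cluster_id, ref$species)[species]
  class(ref) <- c("msgbs_reference", "data.frame")
  ref
}

#' @export
print.msgbs_reference <- function(x, ...) {
  cat("msGBS meta-reference:", nrow(x), "clusters,",
      length(attr(x, "species_index")), "species\n")
  tab <- table(x$species)
  for (sp in names(attr(x, "species_index")))
    cat("  ", sp, ": ", if (sp %in% names(tab)) tab[[sp]] else 0L,
        " clusters\n", sep = "")
  invisible(x)
}

#' Taxonomic cleansing of a meta-reference
#'
#' Removes clusters annotated as non-Eukaryota or as Fungi, keeping
#' unannotated clusters (an annotation source never covers everything).
#' The annotation table typically derives from an external homology
#' search of the centroids against a taxonomic database.
#'
#' @param ref an `msgbs_reference`.
#' @param annotations data.frame with columns `cluster_id` and `verdict`
#'   (one of `"Eukaryota-nonFungi"`, `"Fungi"`, `"Bacteria"`, `"Archaea"`,
#'   `"Virus"`, `"other"`, `"unknown"`). Annotations for unknown cluster
#'   ids are ignored with a warning.
#' @return list with `reference` (the cleansed `msgbs_reference`) and
#'   `report` (removal counts by verdict).
#' @export
taxonomic_filter <- function(ref, annotations) {
  keep_verdicts <- c("Eukaryota-nonFungi", "unknown")
  if (is.null(annotations) || !nrow(annotations))
    return(list(reference = ref,
                report = data.frame(verdict = character(),
                                    removed = integer())))
  unknown <- setdiff(annotations$cluster_id, ref$cluster_id)
  if (length(unknown)) {
    warning("ignoring annotations for unknown clusters: ",
            paste(utils::head(unknown, 5), collapse = ", "),
            if (length(unknown) > 5) ", ...", call. = FALSE)
    annotations <- annotations[!annotations$cluster_id %in% unknown, ,
                               drop = FALSE]
  }
  bad <- annotations[!annotations$verdict %in% keep_verdicts, , drop = FALSE]
  out <- ref[!ref$cluster_id %in% bad$cluster_id, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "species_index") <-
    lapply(attr(ref, "species_index"),
           function(ids) setdiff(ids, bad$cluster_id))
  class(out) <- class(ref)
  report <- as.data.frame(table(verdict = bad$verdict),
                          stringsAsFactors = FALSE)
  names(report)[2] <- "removed"
  list(reference = out, report = report)
}

#' Build a meta-reference from preprocessed monoculture reads
#'
#' Convenience wrapper: dereplicates and clusters the assembled reads of
#' every monoculture sample and combines the per-species clusters.
#'
#' @param reads preprocessed read data.frame (from [preprocess_reads()]).
#' @param sheet sample sheet (to identify monoculture samples and their
#'   species).
#' @param min_unique_size,identity see [dereplicate()] and
#'   [cluster_sequences()].
#' @return an `msgbs_reference`.
#' @export
meta_reference_from_monocultures <- function(reads, sheet,
                                             min_unique_size = 2,
                                             identity = 0.95) {
  mono <- sheet[sheet$role == "monoculture", , drop = FALSE]
  if (!nrow(mono)) stop("no monoculture samples in sheet", call. = FALSE)
  by_species <- split(mono$sample_id, mono$species_id)
  per_species <- lapply(by_species, function(ids) {
    s <- reads$sequence[reads$sample_id %in% ids]
    cluster_sequences(dereplicate(s, min_unique_size), identity)
  })
  build_meta_reference(per_species)
}
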