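#' Write reads to FASTQ
#'
#' @param seqs,quals character vectors of sequences and quality strings.
#' @param headers read headers (defaults to `read1..readN`).
#' @param path output path; `.gz` suffix triggers compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(seqs, quals, headers = NULL, path) {
  if (is.null(headers)) headers <- paste0("read", seq_along(seqs))
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- headers
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(quals),
                              compress = endsWith(path, ".gz"))
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path FASTQ path (optionally gzipped).
#' @return list with `seqs`, `quals`, `headers` character vectors.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  list(seqs = unname(as.character(x)),
       quals = unname(as.character(S4Vectors::mcols(x)$qualities)),
       headers = names(x))
}

#' Write a meta-reference to FASTA
#'
#' Cluster ids become record ids; the source species is carried in the
#' description as `species=<id>`.
#'
#' @param ref an `msgbs_reference`.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_meta_reference <- function(ref, path) {
  x <- Biostrings::DNAStringSet(ref$centroid)
  names(x) <- paste0(ref$cluster_id, " species=", ref$species)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a meta-reference from FASTA
#'
#' @param path FASTA written by [write_meta_reference()].
#' @return an `msgbs_reference` (member counts unavailable from FASTA are
#'   set to `NA`).
#' @export
read_meta_reference <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  ids <- sub(" .*$", "", names(x))
  species <- sub("^.*species=([^ ]+).*$", "\\1", names(x))
  ref <- data.frame(cluster_id = ids, species = species,
                    centroid = as.character(x), member_count = NA_integer_)
  attr(ref, "species_index") <- split(ref$cluster_id, ref$species)
  class(ref) <- c("msgbs_reference", "data.frame")
  ref
}

#' Write an annotated count matrix to CSV
#'
#' Layout: first column `cluster_id`, second `species`, then one column
#' per sample.
#'
#' @param counts an `msgbs_counts`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(counts, path) {
  df <- data.frame(cluster_id = rownames(counts),
                   species = attr(counts, "cluster_species"),
                   unclass(counts), check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a count matrix written by [write_count_matrix()]
#'
#' @param path CSV path.
#' @param sheet the sample sheet (restores sample roles).
#' @return an `msgbs_counts`.
#' @export
read_count_matrix <- function(path, sheet) {
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -(1:2), drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$cluster_id
  mono <- sheet$role == "monoculture" & !is.na(sheet$species_id)
  structure(m,
            cluster_species = setNames(df$species, df$cluster_id),
            sample_roles = setNames(sheet$role, sheet$sample_id),
            mono_species = setNames(sheet$species_id[mono],
                                    sheet$sample_id[mono]),
            class = c("msgbs_counts", class(m)))
}
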