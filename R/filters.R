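#' Cluster-filter parameters
#'
#' The three tunables of the monoculture-based cluster filter: `f1`, the
#' minimum target read count a cluster must collect from its own species'
#' monoculture; `f2`, the divisor bounding non-target monoculture counts
#' at `target / f2` (so the maximum admissible non-target signal is
#' `100 / f2` percent); and `f3`, the minimum per-sample total read count
#' after cluster filtering.
#'
#' @param f1 minimum target read count (default 8).
#' @param f2 non-target divisor (default 15; larger values such as 300
#'   suit high-depth designs).
#' @param f3 minimum per-sample total reads (default 1000; 2000 for
#'   high-depth designs).
#' @param nontarget_sum if `FALSE` (default) every individual non-target
#'   monoculture count must satisfy the `target / f2` bound; if `TRUE`
#'   the bound applies to the sum over all non-target monocultures.
#' @return a `filter_params` list.
#' @export
filter_params <- function(f1 = 8, f2 = 15, f3 = 1000,
                          nontarget_sum = FALSE) {
  stopifnot(f1 >= 1, f2 > 1, f3 >= 0)
  structure(list(f1 = f1, f2 = f2, f3 = f3,
                 nontarget_sum = isTRUE(nontarget_sum)),
            class = "filter_params")
}

#' Monoculture-based cluster filtering
#'
#' Evaluates every cluster against the monoculture samples only. Reads
#' from the monoculture of the cluster's own species are its target
#' count; reads from every other monoculture are non-target counts
#' (summed per species when a species has several monoculture samples).
#' Three steps: (a) prefilter — the target count must be the strict
#' maximum over all per-species monoculture counts (ties fail, since the
#' highest count is then not uniquely the target species); (b) target
#' count filter — target >= `f1`; (c) non-target count filter — every
#' individual non-target species count (or their sum, with
#' `nontarget_sum = TRUE`) must be <= target / `f2`. Clusters passing all
#' steps are retained with the counts of all samples.
#'
#' @param counts an `msgbs_counts` matrix containing at least one
#'   monoculture sample for every species with clusters.
#' @param params a [filter_params()].
#' @return list with `counts` (the filtered `msgbs_counts`) and
#'   `verdicts` (data.frame: `cluster_id`, `species`, `target_count`,
#'   `max_nontarget`, `sum_nontarget`, `failed_step` in
#'   `c("prefilter", "target_min", "nontarget_max", "none")`, `passed`).
#' @export
monoculture_filter <- function(counts, params = filter_params()) {
  stopifnot(inherits(counts, "msgbs_counts"))
  roles <- attr(counts, "sample_roles")[colnames(counts)]
  cs <- attr(counts, "cluster_species")
  mono_cols <- colnames(counts)[roles == "monoculture"]
  mono_species <- mono_species_map(counts, mono_cols)
  need <- unique(cs)
  missing <- setdiff(need, names(mono_species))
  if (length(missing))
    stop("no monoculture sample for species: ",
         paste(missing, collapse = ", "), call. = FALSE)
  # per-species monoculture counts per cluster (sum over replicates)
  mono_counts <- vapply(names(mono_species), function(sp)
    rowSums(unclass(counts)[, mono_species[[sp]], drop = FALSE]),
    numeric(nrow(counts)))
  if (nrow(counts) == 1L)
    mono_counts <- matrix(mono_counts, nrow = 1,
                          dimnames = list(rownames(counts),
                                          names(mono_species)))
  own <- match(cs, colnames(mono_counts))
  target <- mono_counts[cbind(seq_len(nrow(counts)), own)]
  nt <- mono_counts
  nt[cbind(seq_len(nrow(counts)), own)] <- NA
  max_nt <- apply(nt, 1, max, na.rm = TRUE)
  sum_nt <- rowSums(nt, na.rm = TRUE)
  failed <- rep("none", nrow(counts))
  bound <- if (params$nontarget_sum) sum_nt else max_nt
  failed[bound > target / params$f2] <- "nontarget_max"
  failed[target < params$f1] <- "target_min"
  failed[target <= max_nt] <- "prefilter"  # strict max required
  verdicts <- data.frame(cluster_id = rownames(counts), species = cs,
                         target_count = target, max_nontarget = max_nt,
                         sum_nontarget = sum_nt, failed_step = failed,
                         passed = failed == "none")
  rownames(verdicts) <- NULL
  list(counts = subset_counts(counts, rows = verdicts$passed),
       verdicts = verdicts)
}

#' @noRd
mono_species_map <- function(counts, mono_cols) {
  # monoculture sample -> species: the species whose clusters it feeds is
  # recorded in the sheet; here we infer it from the sample role table
  # attached by build_count_matrix via the sample sheet column.
  sp <- attr(counts, "mono_species")
  if (!is.null(sp)) return(split(names(sp), sp))
  # fallback: dominant species of each monoculture column
  cs <- attr(counts, "cluster_species")
  res <- vapply(mono_cols, function(col) {
    v <- tapply(unclass(counts)[, col], cs, sum)
    names(v)[which.max(v)]
  }, character(1))
  split(mono_cols, res)
}

#' Per-sample total-read filter
#'
#' Removes samples whose total retained read count (column sum over the
#' filtered clusters) is below `f3`.
#'
#' @param counts a filtered `msgbs_counts`.
#' @param f3 minimum per-sample total (default 1000).
#' @return list with `counts` and `dropped` (character vector of removed
#'   sample ids).
#' @export
sample_total_filter <- function(counts, f3 = 1000) {
  tot <- colSums(counts)
  drop <- colnames(counts)[tot < f3]
  list(counts = subset_counts(counts, cols = tot >= f3), dropped = drop)
}

#' Monoculture specificity cross-table
#'
#' For every monoculture sample, the percentage of its retained reads
#' landing in each species' clusters. The diagonal is the target signal,
#' off-diagonal entries are non-target signal; rows sum to 100%.
#'
#' @param counts a (filtered) `msgbs_counts`.
#' @param digits decimals for the returned percentages (default 2).
#' @return matrix (monoculture samples x species) of percentages with a
#'   `total_reads` attribute (per-sample totals). Monocultures with zero
#'   retained reads yield `NaN` rows and a warning.
#' @export
crosstab_monocultures <- function(counts, digits = 2) {
  roles <- attr(counts, "sample_roles")[colnames(counts)]
  cs <- attr(counts, "cluster_species")
  mono <- colnames(counts)[roles == "monoculture"]
  species <- sort(unique(cs))
  m <- vapply(species, function(sp)
    colSums(unclass(counts)[cs == sp, mono, drop = FALSE]),
    numeric(length(mono)))
  if (length(mono) == 1L)
    m <- matrix(m, nrow = 1, dimnames = list(mono, species))
  tot <- rowSums(m)
  if (any(tot == 0))
    warning("monoculture sample(s) with zero retained reads: ",
            paste(mono[tot == 0], collapse = ", "), call. = FALSE)
  pct <- round(100 * m / tot, digits)
  structure(pct, total_reads = tot)
}
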