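#' Run the full msGBS analysis on a read set
#'
#' Composes the whole pipeline: preprocessing, meta-reference
#' construction from the monoculture samples, optional taxonomic
#' cleansing, read mapping, duplicate/quality marking, count-matrix
#' extraction, monoculture-based cluster filtering, the per-sample total
#' filter, and the non-calibrated (and, when calibration samples are
#' available, calibrated) abundance estimates.
#'
#' @param lib an `msgbs_library` (or list with `reads1`, `reads2`,
#'   `qual1`, `qual2`, `sheet`).
#' @param params [filter_params()] for the cluster and sample filters.
#' @param min_unique_size,cluster_identity meta-reference parameters
#'   (see [dereplicate()], [cluster_sequences()]).
#' @param map_identity minimum mapping identity (default 0.95).
#' @param min_cluster_total minimum per-cluster total count (default 10).
#' @param outlier_sd calibration outlier threshold (default 2.5).
#' @param annotations optional cluster annotation table for
#'   [taxonomic_filter()].
#' @param cluster_filter apply the monoculture-based cluster filter
#'   (default `TRUE`; disable to quantify its effect).
#' @param calibrate compute the calibration key and across-species
#'   abundance when >= 3 calibration samples are present (default
#'   `TRUE`).
#' @param ... further preprocessing arguments for [preprocess_reads()].
#' @return object of class `msgbs_result`: list with `reads_report`,
#'   `reference`, `map_report`, `counts_raw` (post total-count threshold,
#'   pre cluster filter), `counts` (filtered), `verdicts`,
#'   `dropped_samples`, `within`, `key`, `across` (the last two `NULL`
#'   when not calibrated), and `crosstab`.
#' @export
run_msgbs <- function(lib, params = filter_params(), min_unique_size = 2,
                      cluster_identity = 0.95, map_identity = 0.95,
                      min_cluster_total = 10, outlier_sd = 2.5,
                      annotations = NULL, cluster_filter = TRUE,
                      calibrate = TRUE, ...) {
  pp <- preprocess_reads(lib, ...)
  ref <- meta_reference_from_monocultures(pp$reads, lib$sheet,
                                          min_unique_size,
                                          cluster_identity)
  tax_report <- NULL
  if (!is.null(annotations)) {
    tf <- taxonomic_filter(ref, annotations)
    ref <- tf$reference
    tax_report <- tf$report
  }
  mp <- map_reads(pp$reads, ref, map_identity)
  mapped <- mark_qc_fail(mark_duplicates(mp$mapped))
  counts_raw <- build_count_matrix(mapped, ref, lib$sheet,
                                   min_cluster_total)
  if (cluster_filter) {
    fl <- monoculture_filter(counts_raw, params)
    counts <- fl$counts
    verdicts <- fl$verdicts
  } else {
    counts <- counts_raw
    verdicts <- NULL
  }
  sf <- sample_total_filter(counts, params$f3)
  counts <- sf$counts
  within <- within_species_abundance(counts)
  key <- NULL; across <- NULL
  roles <- attr(counts, "sample_roles")[colnames(counts)]
  if (calibrate && sum(roles == "calibration") >= 3) {
    key <- calibration_key(counts, outlier_sd)
    across <- across_species_abundance(within, key)
  }
  structure(list(reads_report = pp$report, reference = ref,
                 tax_report = tax_report, map_report = mp$report,
                 counts_raw = counts_raw, counts = counts,
                 verdicts = verdicts, dropped_samples = sf$dropped,
                 within = within, key = key, across = across,
                 crosstab = crosstab_monocultures(counts)),
            class = "msgbs_result")
}

#' @export
print.msgbs_result <- function(x, ...) {
  r <- x$reads_report
  cat("msGBS analysis result\n")
  cat(sprintf("  reads: %d input, %d assigned (%.1f%%), %d assembled (%d merged / %d joined)\n",
              r[["input"]], r[["assigned"]],
              100 * r[["assigned"]] / r[["input"]], r[["assembled"]],
              r[["merged"]], r[["joined"]]))
  cat(sprintf("  reference: %d clusters; mapped %d / unmapped %d / ambiguous %d\n",
              nrow(x$reference), x$map_report[["mapped"]],
              x$map_report[["unmapped"]], x$map_report[["ambiguous"]]))
  if (!is.null(x$verdicts))
    cat(sprintf("  cluster filter: %d of %d clusters retained\n",
                sum(x$verdicts$passed), nrow(x$verdicts)))
  if (length(x$dropped_samples))
    cat("  samples dropped by total-read filter:",
        paste(x$dropped_samples, collapse = ", "), "\n")
  if (!is.null(x$key))
    cat("  calibrated:", length(x$key$retained_samples),
        "calibration samples retained\n")
  invisible(x)
}

#' Recompute abundances from a count matrix
#'
#' The tail of the pipeline (optional cluster filter, sample-total
#' filter, within- and across-species abundance) applied to an existing
#' count matrix; convenient for comparing filtered and unfiltered
#' analyses without re-mapping.
#'
#' @param counts an `msgbs_counts`.
#' @param params [filter_params()].
#' @param cluster_filter,calibrate,outlier_sd see [run_msgbs()].
#' @return list with `counts`, `verdicts`, `dropped_samples`, `within`,
#'   `key`, `across`.
#' @export
abundance_pipeline <- function(counts, params = filter_params(),
                               cluster_filter = TRUE, calibrate = TRUE,
                               outlier_sd = 2.5) {
  verdicts <- NULL
  if (cluster_filter) {
    fl <- monoculture_filter(counts, params)
    counts <- fl$counts
    verdicts <- fl$verdicts
  }
  sf <- sample_total_filter(counts, params$f3)
  counts <- sf$counts
  within <- within_species_abundance(counts)
  key <- NULL; across <- NULL
  roles <- attr(counts, "sample_roles")[colnames(counts)]
  if (calibrate && sum(roles == "calibration") >= 3) {
    key <- calibration_key(counts, outlier_sd)
    across <- across_species_abundance(within, key)
  }
  list(counts = counts, verdicts = verdicts, dropped_samples = sf$dropped,
       within = within, key = key, across = across)
}

#' Run the pipeline from a configuration file, with provenance
#'
#' Simulates (or loads) the inputs described by a YAML configuration,
#' runs [run_msgbs()], and writes all products (sample sheet,
#' meta-reference FASTA, raw and filtered count matrices, verdicts,
#' abundance tables, calibration key, crosstab) plus a provenance record
#' (`provenance.json`: config hash, per-file md5, package version, seed)
#' into `out_dir`.
#'
#' @param config path to a YAML file or an equivalent named list.
#'   Recognized blocks: `seed` (mandatory), `simulate` (arguments of
#'   [simulate_msgbs_dataset()]), `filter` (`f1`, `f2`, `f3`,
#'   `nontarget_sum`), `metaref` (`min_unique_size`, `identity`),
#'   `map` (`min_identity`), `calibration` (`outlier_sd`).
#' @param out_dir output directory (created if needed).
#' @return the [run_msgbs()] result, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  known <- c("seed", "simulate", "filter", "metaref", "map", "calibration")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (is.null(cfg$seed)) stop("config must set a seed", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- do.call(simulate_msgbs_dataset,
                 c(cfg$simulate %||% list(), list(seed = cfg$seed)))
  fp <- do.call(filter_params, cfg$filter %||% list())
  mr <- cfg$metaref %||% list()
  res <- run_msgbs(sim$library, params = fp,
                   min_unique_size = mr$min_unique_size %||% 2,
                   cluster_identity = mr$identity %||% 0.95,
                   map_identity = (cfg$map %||% list())$min_identity %||% 0.95,
                   outlier_sd = (cfg$calibration %||% list())$outlier_sd %||% 2.5)
  files <- c(sheet = "sample_sheet.csv",
             reference = "meta_reference.fasta",
             counts_raw = "counts_raw.csv",
             counts = "counts_filtered.csv",
             verdicts = "cluster_verdicts.csv",
             within = "within_abundance.csv",
             crosstab = "monoculture_crosstab.csv",
             mixtures = "mixture_design.csv")
  write.csv(sim$sheet, file.path(out_dir, files["sheet"]), row.names = FALSE)
  write_meta_reference(res$reference, file.path(out_dir, files["reference"]))
  write_count_matrix(res$counts_raw, file.path(out_dir, files["counts_raw"]))
  write_count_matrix(res$counts, file.path(out_dir, files["counts"]))
  write.csv(res$verdicts, file.path(out_dir, files["verdicts"]),
            row.names = FALSE)
  write.csv(data.frame(sample_id = rownames(res$within),
                       unclass(res$within), check.names = FALSE),
            file.path(out_dir, files["within"]), row.names = FALSE)
  write.csv(as.data.frame(res$crosstab),
            file.path(out_dir, files["crosstab"]))
  write.csv(data.frame(sample_id = rownames(sim$mixtures), sim$mixtures,
                       check.names = FALSE),
            file.path(out_dir, files["mixtures"]), row.names = FALSE)
  if (!is.null(res$across)) {
    files <- c(files, across = "across_abundance.csv",
               key = "calibration_key.csv")
    write.csv(data.frame(sample_id = rownames(res$across),
                         unclass(res$across), check.names = FALSE),
              file.path(out_dir, "across_abundance.csv"), row.names = FALSE)
    write.csv(data.frame(species = names(res$key$key), key = res$key$key),
              file.path(out_dir, "calibration_key.csv"), row.names = FALSE)
  }
  prov <- list(
    package = "msgbs",
    version = as.character(utils::packageVersion("msgbs")),
    seed = cfg$seed,
    config_hash = digest_config(cfg),
    created = format(Sys.time(), tz = "UTC"),
    files = as.list(tools::md5sum(file.path(out_dir, unname(files)))))
  names(prov$files) <- unname(files)
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}

#' @noRd
digest_config <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Verify the provenance record of a pipeline output directory
#'
#' Recomputes the md5 checksum of every recorded product and fails if
#' any file is missing or was modified after the run.
#'
#' @param out_dir directory written by [run_pipeline()].
#' @return `TRUE` invisibly if everything matches; otherwise an error
#'   naming the tampered or missing file.
#' @export
verify_provenance <- function(out_dir) {
  pfile <- file.path(out_dir, "provenance.json")
  if (!file.exists(pfile))
    stop("no provenance.json in ", out_dir, call. = FALSE)
  prov <- jsonlite::read_json(pfile)
  for (f in names(prov$files)) {
    path <- file.path(out_dir, f)
    if (!file.exists(path))
      stop("provenance error: missing product file ", f, call. = FALSE)
    h <- unname(tools::md5sum(path))
    if (!identical(h, prov$files[[f]]))
      stop("provenance error: checksum mismatch for ", f, call. = FALSE)
  }
  invisible(TRUE)
}
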