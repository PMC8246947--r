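#' Within-species (non-calibrated) abundance
#'
#' Per sample, the per-species read count (summed over that species'
#' clusters) divided by the sample total. Comparable across samples
#' within a species; not comparable across species, because read yield
#' per unit biomass is species specific.
#'
#' @param counts a filtered `msgbs_counts`.
#' @return object of class `msgbs_abundance`: matrix (samples x species)
#'   of proportions with attribute `mode = "within"`; rows sum to 1.
#'   Zero-total samples are excluded with a warning.
#' @export
within_species_abundance <- function(counts) {
  cs <- attr(counts, "cluster_species")
  species <- sort(unique(cs))
  m <- vapply(species, function(sp)
    colSums(unclass(counts)[cs == sp, , drop = FALSE]),
    numeric(ncol(counts)))
  if (ncol(counts) == 1L)
    m <- matrix(m, nrow = 1, dimnames = list(colnames(counts), species))
  tot <- rowSums(m)
  if (any(tot == 0)) {
    warning("excluding zero-count sample(s): ",
            paste(rownames(m)[tot == 0], collapse = ", "), call. = FALSE)
    m <- m[tot > 0, , drop = FALSE]
    tot <- tot[tot > 0]
  }
  structure(m / tot, mode = "within",
            sample_roles = attr(counts, "sample_roles"),
            class = c("msgbs_abundance", "matrix", "array"))
}

#' Subset an abundance table, preserving its mode annotation
#'
#' @param x an `msgbs_abundance`.
#' @param i,j row/column indices.
#' @param drop as for matrices; a matrix result keeps the class and mode.
#' @param ... ignored.
#' @return an `msgbs_abundance` (or a plain vector when `drop` applies).
#' @export
`[.msgbs_abundance` <- function(x, i, j, ..., drop = TRUE) {
  m <- unclass(x)
  out <- if (missing(i) && missing(j)) m
         else if (missing(i)) m[, j, drop = drop]
         else if (missing(j)) m[i, , drop = drop]
         else m[i, j, drop = drop]
  if (is.matrix(out))
    out <- structure(out, mode = attr(x, "mode"),
                     sample_roles = attr(x, "sample_roles"),
                     class = c("msgbs_abundance", "matrix", "array"))
  out
}

#' @export
print.msgbs_abundance <- function(x, digits = 4, ...) {
  cat("msGBS", attr(x, "mode"), "abundance:", nrow(x), "samples x",
      ncol(x), "species\n")
  print(round(unclass(x)[seq_len(min(6, nrow(x))), , drop = FALSE], digits))
  if (nrow(x) > 6) cat("  ... (", nrow(x) - 6, " more samples)\n", sep = "")
  invisible(x)
}

#' Estimate the calibration key from calibration samples
#'
#' Calibration samples contain equal biomass of every species, so their
#' relative read counts measure the species-specific read yield per unit
#' biomass. Each calibration sample's per-species relative counts are
#' computed; a sample is flagged as an outlier when any species' relative
#' value deviates more than `outlier_sd` standard deviations (sample SD
#' over all calibration samples, candidate included; one pass) from that
#' species' mean. The key is the per-species mean over retained samples,
#' renormalized to sum to 1.
#'
#' @param counts an `msgbs_counts` containing >= 3 calibration samples.
#' @param outlier_sd SD threshold for outlier removal (default 2.5).
#' @return object of class `msgbs_calkey`: list with `key` (named,
#'   sums to 1), `retained_samples`, `removed_outliers`, `outlier_sd`
#'   and `relative` (the per-sample relative count matrix).
#' @export
calibration_key <- function(counts, outlier_sd = 2.5) {
  roles <- attr(counts, "sample_roles")[colnames(counts)]
  cal <- colnames(counts)[roles == "calibration"]
  if (length(cal) < 3)
    stop("need at least 3 calibration samples, found ", length(cal),
         call. = FALSE)
  ab <- within_species_abundance(subset_counts(counts, cols = cal))
  rel <- unclass(ab)
  mu <- colMeans(rel)
  sdv <- apply(rel, 2, sd)
  dev <- abs(sweep(rel, 2, mu)) > outlier_sd * rep(sdv, each = nrow(rel))
  out <- rownames(rel)[rowSums(dev, na.rm = TRUE) > 0]
  keep <- setdiff(rownames(rel), out)
  if (!length(keep))
    stop("all calibration samples flagged as outliers; degenerate ",
         "calibration set", call. = FALSE)
  key <- colMeans(rel[keep, , drop = FALSE])
  key <- key / sum(key)
  structure(list(key = key, retained_samples = keep,
                 removed_outliers = out, outlier_sd = outlier_sd,
                 relative = rel),
            class = "msgbs_calkey")
}

#' @export
print.msgbs_calkey <- function(x, digits = 2, ...) {
  cat("msGBS calibration key (", length(x$retained_samples),
      " samples retained, ", length(x$removed_outliers),
      " outlier(s) removed at ", x$outlier_sd, " SD):\n", sep = "")
  print(round(x$key, digits))
  invisible(x)
}

#' Across-species (calibrated) abundance
#'
#' Divides each sample's within-species abundance by the calibration key
#' and renormalizes, yielding proportions comparable across species — a
#' proxy for relative biomass. With a uniform key the result equals the
#' within-species abundance.
#'
#' @param within an `msgbs_abundance` in `"within"` mode.
#' @param key an [calibration_key()] result (or named numeric key).
#' @return an `msgbs_abundance` with `mode = "across"`; rows sum to 1.
#' @export
across_species_abundance <- function(within, key) {
  if (inherits(key, "msgbs_calkey")) key <- key$key
  m <- unclass(within)
  miss <- colnames(m)[!(colnames(m) %in% names(key)) &
                        colSums(m) > 0]
  if (length(miss))
    stop("species with signal but no calibration key: ",
         paste(miss, collapse = ", "), call. = FALSE)
  k <- key[colnames(m)]
  zero <- !is.na(k) & k == 0 & colSums(m) > 0
  if (any(zero))
    stop("species with signal but zero calibration key: ",
         paste(colnames(m)[zero], collapse = ", "), call. = FALSE)
  cal <- sweep(m, 2, k, "/")
  cal[, is.na(k)] <- 0
  res <- cal / rowSums(cal)
  structure(res, mode = "across",
            sample_roles = attr(within, "sample_roles"),
            class = c("msgbs_abundance", "matrix", "array"))
}

#' Coefficient of variation of calibration-sample signals
#'
#' Per species, the sample SD divided by the mean of the relative read
#' counts across calibration samples — a measure of calibration
#' repeatability. Invariant under global count scaling.
#'
#' @param counts an `msgbs_counts` with calibration samples.
#' @param key optionally a [calibration_key()]; when supplied, only its
#'   retained (non-outlier) samples enter the computation.
#' @return named numeric vector of per-species CVs (`NaN` where the mean
#'   is zero).
#' @export
calibration_cv <- function(counts, key = NULL) {
  roles <- attr(counts, "sample_roles")[colnames(counts)]
  cal <- colnames(counts)[roles == "calibration"]
  if (!is.null(key)) cal <- intersect(cal, key$retained_samples)
  if (length(cal) < 2)
    stop("need at least 2 calibration samples", call. = FALSE)
  rel <- unclass(within_species_abundance(subset_counts(counts, cols = cal)))
  apply(rel, 2, sd) / colMeans(rel)
}
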