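#' False positive signal (FPS) per species
#'
#' The mean estimated abundance of a species over the samples in which it
#' is truly absent. Species present in every sample have no defined FPS
#' and are omitted.
#'
#' @param table an `msgbs_abundance` (within or across mode).
#' @param truth matrix of true proportions (samples x species) covering
#'   all samples in `table`; 0 means truly absent.
#' @return named numeric vector of per-species FPS (proportions).
#' @export
evaluate_fps <- function(table, truth) {
  m <- align_truth(table, truth)
  fps <- vapply(colnames(table), function(sp) {
    absent <- m[, sp] == 0
    if (!any(absent)) return(NA_real_)
    mean(unclass(table)[absent, sp])
  }, numeric(1))
  fps[!is.na(fps)]
}

#' False negative signals (FNS)
#'
#' Truly present (sample, species) pairs whose estimated abundance falls
#' below the detection threshold. In calibrated mode the threshold is a
#' fixed across-species abundance (default 1%). In non-calibrated mode
#' the threshold is species specific: 1/`noncal_fraction` of the mean
#' within-species signal of that species' 50%-biomass samples (species
#' without a 50% anchor sample are skipped with a warning).
#'
#' @param table an `msgbs_abundance`; its mode selects the rule.
#' @param truth matrix of true proportions (samples x species).
#' @param calibrated_threshold across-abundance threshold (default 0.01).
#' @param noncal_fraction divisor of the 50%-biomass mean signal
#'   (default 50).
#' @param anchor true proportion defining the anchor samples for the
#'   non-calibrated rule (default 0.5).
#' @return data.frame with columns `sample_id`, `species`, `value`,
#'   `threshold`; zero rows when no FNS occur.
#' @export
evaluate_fns <- function(table, truth, calibrated_threshold = 0.01,
                         noncal_fraction = 50, anchor = 0.5) {
  m <- align_truth(table, truth)
  est <- unclass(table)
  res <- NULL
  if (identical(attr(table, "mode"), "across")) {
    thr <- matrix(calibrated_threshold, nrow(est), ncol(est),
                  dimnames = dimnames(est))
  } else {
    thr <- matrix(NA_real_, nrow(est), ncol(est), dimnames = dimnames(est))
    for (sp in colnames(est)) {
      a <- abs(m[, sp] - anchor) < 1e-9
      if (!any(a)) {
        warning("no ", anchor * 100, "% biomass sample for species ", sp,
                "; skipped in FNS evaluation", call. = FALSE)
        next
      }
      thr[, sp] <- mean(est[a, sp]) / noncal_fraction
    }
  }
  hit <- which(m > 0 & !is.na(thr) & est < thr, arr.ind = TRUE)
  res <- data.frame(sample_id = rownames(est)[hit[, 1]],
                    species = colnames(est)[hit[, 2]],
                    value = est[hit], threshold = thr[hit])
  res[order(res$sample_id, res$species), , drop = FALSE]
}

#' @noRd
align_truth <- function(table, truth) {
  if (!all(rownames(table) %in% rownames(truth)))
    stop("truth matrix does not cover all samples", call. = FALSE)
  if (!all(colnames(table) %in% colnames(truth)))
    stop("truth matrix does not cover all species", call. = FALSE)
  truth[rownames(table), colnames(table), drop = FALSE]
}

#' Relative FPS within congener groups
#'
#' For a group of congeneric (same-genus) species — the hardest case for
#' taxonomic resolution — the mean signal of truly absent group members
#' divided by the mean signal of the present members, as a percentage.
#' Eligible samples are those in which (a) not all group species are
#' present (and at least one is), and (b) at least one present member has
#' a detected signal. Computed on within-species (non-calibrated)
#' abundances. The default aggregates as a ratio of means over all
#' eligible (sample, species) cells; `order = "mean_of_ratios"` instead
#' averages per-sample ratios.
#'
#' @param table an `msgbs_abundance` in `"within"` mode.
#' @param groups named list: group name -> character vector of member
#'   species ids.
#' @param presence logical matrix (samples x species): `TRUE` where a
#'   species is truly present.
#' @param order `"ratio_of_means"` (default) or `"mean_of_ratios"`.
#' @return data.frame with `group`, `n_samples`, `mean_present`,
#'   `mean_absent` (percent within-species abundance) and `rfps`
#'   (percent; `NA` when the present-species mean is zero).
#' @export
rfps <- function(table, groups, presence,
                 order = c("ratio_of_means", "mean_of_ratios")) {
  order <- match.arg(order)
  stopifnot(identical(attr(table, "mode"), "within"))
  est <- unclass(table)
  rows <- lapply(names(groups), function(g) {
    sp <- groups[[g]]
    stopifnot(all(sp %in% colnames(est)), all(sp %in% colnames(presence)))
    pr <- presence[rownames(est), sp, drop = FALSE]
    npresent <- rowSums(pr)
    detected <- vapply(seq_len(nrow(est)), function(i)
      any(est[i, sp][pr[i, ]] > 0), logical(1))
    elig <- npresent > 0 & npresent < length(sp) & detected
    if (!any(elig))
      return(data.frame(group = g, n_samples = 0L, mean_present = NA_real_,
                        mean_absent = NA_real_, rfps = NA_real_))
    e <- est[elig, sp, drop = FALSE] * 100
    p <- pr[elig, , drop = FALSE]
    mp <- mean(e[p]); ma <- mean(e[!p])
    val <- if (order == "ratio_of_means") {
      if (mp == 0) NA_real_ else 100 * ma / mp
    } else {
      r <- vapply(seq_len(nrow(e)), function(i) {
        pi <- mean(e[i, ][p[i, ]])
        if (pi == 0) NA_real_ else 100 * mean(e[i, ][!p[i, ]]) / pi
      }, numeric(1))
      mean(r, na.rm = TRUE)
    }
    data.frame(group = g, n_samples = sum(elig), mean_present = mp,
               mean_absent = ma, rfps = val)
  })
  do.call(rbind, rows)
}

#' Per-species regression of estimates on true proportions
#'
#' Ordinary least squares of estimated abundance on true biomass
#' proportion, per species, with the squared Pearson correlation as R2.
#'
#' @param table an `msgbs_abundance`.
#' @param truth matrix of true proportions (samples x species).
#' @return data.frame with `species`, `n`, `slope`, `intercept`, `r2`
#'   (`NA` where the truth has no variance or fewer than 3 pairs).
#' @export
regression_eval <- function(table, truth) {
  m <- align_truth(table, truth)
  est <- unclass(table)
  rows <- lapply(colnames(est), function(sp) {
    x <- m[, sp]; y <- est[, sp]
    if (length(x) < 3 || sd(x) == 0)
      return(data.frame(species = sp, n = length(x), slope = NA_real_,
                        intercept = NA_real_, r2 = NA_real_))
    fit <- lm(y ~ x)
    data.frame(species = sp, n = length(x),
               slope = unname(coef(fit)[2]),
               intercept = unname(coef(fit)[1]),
               r2 = cor(x, y)^2)
  })
  do.call(rbind, rows)
}
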