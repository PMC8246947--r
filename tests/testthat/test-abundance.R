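ab_counts <- function(m, roles = NULL) {
  species <- unique(sub("_\\d+$", "", rownames(m)))
  if (is.null(roles))
    roles <- setNames(rep("mixture", ncol(m)), colnames(m))
  make_counts(m, setNames(sub("_\\d+$", "", rownames(m)), rownames(m)),
              roles, character(0))
}

abund <- function(values, mode = "within", roles = NULL) {
  if (is.null(roles)) roles <- setNames(rep("mixture", nrow(values)),
                                        rownames(values))
  structure(values, mode = mode, sample_roles = roles,
            class = c("msgbs_abundance", "matrix", "array"))
}

test_that("within-species abundance is the per-species read share", {
  m <- matrix(c(30L, 70L, 0L), 3, 1,
              dimnames = list(c("sp1_1", "sp2_1", "sp3_1"), "s1"))
  ab <- within_species_abundance(ab_counts(m))
  expect_equal(unname(ab["s1", ]), c(0.3, 0.7, 0))
  # a single-species sample gets 1 for it and 0 elsewhere
  m2 <- matrix(c(55L, 0L, 0L), 3, 1, dimnames = dimnames(m))
  expect_equal(unname(within_species_abundance(ab_counts(m2))["s1", ]),
               c(1, 0, 0))
  # cluster-level counts aggregate within species
  m3 <- matrix(c(10L, 20L, 70L), 3, 1,
               dimnames = list(c("sp1_1", "sp1_2", "sp2_1"), "s1"))
  expect_equal(unname(within_species_abundance(ab_counts(m3))["s1", ]),
               c(0.3, 0.7))
})

test_that("equal-yield mixtures recover true proportions within sampling error", {
  sim <- clean_sim()
  res <- clean_run()
  mix <- intersect(rownames(sim$mixtures), rownames(res$within))
  est <- unclass(res$within)[mix, colnames(sim$mixtures)]
  truth <- sim$mixtures[mix, ]
  n <- min(colSums(unclass(res$counts))[mix])
  # 4 binomial SEs at the realized depth
  tol <- 4 * sqrt(0.25 / n) + 0.01
  expect_lt(max(abs(est - truth)), tol)
})

test_that("calibration key reproduces the worked per-species averages", {
  counts <- c(633, 4429, 2652, 3119, 3046, 13137, 2414, 5147)
  m <- matrix(rep(as.integer(counts), 3), ncol = 3,
              dimnames = list(paste0("sp", 1:8, "_1"),
                              paste0("cal", 1:3)))
  cm <- ab_counts(m, roles = setNames(rep("calibration", 3), colnames(m)))
  key <- calibration_key(cm)
  expect_equal(unname(round(key$key, 2)),
               c(0.02, 0.13, 0.08, 0.09, 0.09, 0.38, 0.07, 0.15))
  expect_equal(sum(key$key), 1)
  expect_equal(length(key$removed_outliers), 0)
})

test_that("identical calibration samples produce no outliers", {
  m <- matrix(rep(c(100L, 300L), 10), nrow = 2,
              dimnames = list(c("sp1_1", "sp2_1"), paste0("cal", 1:10)))
  cm <- ab_counts(m, setNames(rep("calibration", 10), colnames(m)))
  key <- calibration_key(cm)
  expect_equal(key$removed_outliers, character(0))
  expect_equal(unname(key$key), c(0.25, 0.75))
})

test_that("a planted deviant calibration sample is removed at 2.5 SD", {
  set.seed(101)
  base <- c(0.2, 0.3, 0.5)
  m <- vapply(1:10, function(i) {
    p <- base + c(1, -1, 0) * 0.002 * (i - 5.5) / 4.5
    as.integer(round(10000 * p))
  }, integer(3))
  m[, 10] <- as.integer(round(10000 * c(0.45, 0.18, 0.37)))  # deviant
  dimnames(m) <- list(paste0("sp", 1:3, "_1"), paste0("cal", 1:10))
  cm <- ab_counts(m, setNames(rep("calibration", 10), colnames(m)))
  key <- calibration_key(cm, outlier_sd = 2.5)
  expect_equal(key$removed_outliers, "cal10")
  expect_equal(length(key$retained_samples), 9)
  # the key averages only the retained samples
  rel <- key$relative[key$retained_samples, ]
  expect_equal(unname(key$key),
               unname(colMeans(rel) / sum(colMeans(rel))))
  expect_error(calibration_key(cm[, 1:2]), "at least 3")
})

test_that("across-species abundance inverts the key", {
  w <- abund(matrix(c(0.3, 0.7), 1, dimnames = list("s1", c("sp1", "sp2"))))
  # uniform key: across equals within
  a1 <- across_species_abundance(w, c(sp1 = 0.5, sp2 = 0.5))
  expect_equal(unclass(a1), unclass(w), ignore_attr = TRUE)
  # within equal to the key: across is uniform
  a2 <- across_species_abundance(w, c(sp1 = 0.3, sp2 = 0.7))
  expect_equal(unname(a2["s1", ]), c(0.5, 0.5))
  expect_equal(unname(rowSums(a2)), 1)
  # a species with signal but no (or zero) key entry is an error
  expect_error(across_species_abundance(w, c(sp1 = 1)), "sp2")
  expect_error(across_species_abundance(w, c(sp1 = 1, sp2 = 0)), "sp2")
})

test_that("calibration corrects yield bias in simulation", {
  sim <- messy_sim()  # 20-fold yield spread
  res <- messy_run()
  mix <- intersect(rownames(sim$mixtures), rownames(res$across))
  reg <- regression_eval(res$across[mix, , drop = FALSE], sim$mixtures)
  expect_true(all(reg$slope > 0.85 & reg$slope < 1.15))
  expect_true(all(reg$r2 > 0.95))
})

test_that("FPS averages estimates over truly absent samples only", {
  tr <- matrix(c(0, 0.5, 1, 0.5, 0, 0), 3, 2,
               dimnames = list(paste0("s", 1:3), c("sp1", "sp2")))
  est <- abund(matrix(c(0.01, 0.6, 0.99, 0.4, 0.02, 0.03), 3, 2,
                      dimnames = dimnames(tr)))
  fps <- evaluate_fps(est, tr)
  expect_equal(unname(fps["sp1"]), 0.01)        # only s1 has sp1 absent
  expect_equal(unname(fps["sp2"]), mean(c(0.02, 0.03)))
  # species present everywhere has no FPS entry
  tr2 <- tr; tr2[, "sp1"] <- 0.5
  expect_false("sp1" %in% names(evaluate_fps(est, tr2)))
  # perfectly specific estimates give zero FPS
  est0 <- abund(tr / pmax(rowSums(tr), 1e-9))
  expect_true(all(evaluate_fps(est0, tr) == 0))
})

test_that("FNS applies the fixed calibrated and anchored non-calibrated rules", {
  tr <- matrix(c(0.5, 0.5, 0.5, 0.5, 0, 0.2,
                 0.5, 0.3, 0.3), 3, 3,
               dimnames = list(paste0("s", 1:3), paste0("sp", 1:3)))
  # calibrated mode: fixed 1% threshold on present entries
  est <- abund(matrix(c(0.49, 0.009, 0.52, 0.48, 0, 0.19,
                        0.03, 0.691, 0.29), 3, 3,
                      dimnames = dimnames(tr)), mode = "across")
  fns <- evaluate_fns(est, tr)
  expect_equal(nrow(fns), 1)
  expect_equal(fns$sample_id, "s2")
  expect_equal(fns$species, "sp1")
  # all estimates above threshold: empty list
  est2 <- abund(tr / rowSums(tr), mode = "across")
  expect_equal(nrow(evaluate_fns(est2, tr)), 0)
  # non-calibrated: threshold is 1/50 of the 50%-anchor mean signal
  w <- abund(matrix(c(0.6, 0.004, 0.5, 0.39, 0.796, 0.3,
                      0.01, 0.2, 0.2), 3, 3,
                    dimnames = dimnames(tr)), mode = "within")
  fnsw <- evaluate_fns(w, tr)
  # sp1 anchor mean = mean(0.6, 0.5)... s1,s2,s3 all have 0.5 truth
  thr1 <- mean(c(0.6, 0.004, 0.5)) / 50
  expect_true(all(fnsw$species == "sp1"))
  expect_equal(fnsw$sample_id, "s2")
  expect_equal(fnsw$threshold, thr1)
  # a species with no 50% anchor is skipped with a warning
  tr3 <- tr; tr3[, "sp1"] <- 0.3
  expect_warning(evaluate_fns(w, tr3), "sp1")
})

test_that("rFPS relates absent to present congener signal", {
  pres <- matrix(c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE), 3, 2,
                 dimnames = list(paste0("s", 1:3), c("Ra", "Rr")))
  groups <- list(Ranunculus = c("Ra", "Rr"))
  # absent congener signal 0 everywhere: rfps 0
  w0 <- abund(matrix(c(0.2, 0.15, 0, 0, 0.2, 0.3), 3, 2,
                     dimnames = dimnames(pres)))
  r0 <- rfps(w0, groups, pres)
  expect_equal(r0$rfps, 0)
  expect_equal(r0$n_samples, 2)  # s2 has both members present
  # worked ratio: mean present 13.94%, mean absent 4.97% -> 35.65
  w <- abund(matrix(c(0.1394, 0.1394, 0.0497, 0.0497, 0.1394, 0.1394),
                    3, 2, dimnames = dimnames(pres)))
  r <- rfps(w, groups, pres)
  expect_equal(r$mean_present, 13.94)
  expect_equal(r$mean_absent, 4.97)
  expect_equal(round(r$rfps, 1), 35.7)
  # samples with all members present, or no detected present signal,
  # are excluded
  pres2 <- rbind(pres, s4 = c(TRUE, TRUE))
  w2 <- abund(matrix(c(0.1, 0, 0.05, 0.3, 0.05, 0, 0, 0.3), 4, 2,
                     dimnames = list(paste0("s", 1:4), c("Ra", "Rr"))))
  r2 <- rfps(w2, groups, pres2)
  # s2 and s4 fail rule (a) (all members present); s3 fails rule (b)
  # (its present member Rr has no signal)
  expect_equal(r2$n_samples, 1)
  # disjoint groups are evaluated independently
  w3 <- abund(cbind(unclass(w2), Pa = c(0.1, 0.2, 0.1, 0.1),
                    Pb = c(0, 0.05, 0, 0)))
  pres3 <- cbind(pres2, Pa = TRUE, Pb = c(FALSE, FALSE, TRUE, TRUE))
  r3 <- rfps(w3, list(Ranunculus = c("Ra", "Rr"), Papaver = c("Pa", "Pb")),
             pres3)
  expect_equal(r3$group, c("Ranunculus", "Papaver"))
  expect_equal(r3$rfps[1], r2$rfps)
})

test_that("regression recovers exact and scaled relationships", {
  tr <- matrix(seq(0, 0.5, length.out = 6), 6, 1,
               dimnames = list(paste0("s", 1:6), "sp1"))
  est <- abund(tr)
  r <- regression_eval(est, tr)
  expect_equal(r$slope, 1)
  expect_equal(r$r2, 1)
  r2 <- regression_eval(abund(tr * 0.5), tr)
  expect_equal(r2$slope, 0.5)
  expect_equal(r2$r2, 1)
  # OLS matches the closed form on noisy data
  set.seed(102)
  noisy <- tr + rnorm(6, 0, 0.02)
  r3 <- regression_eval(abund(noisy), tr)
  x <- tr[, 1]; y <- noisy[, 1]
  slope_cf <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(r3$slope, slope_cf)
  expect_equal(r3$intercept, mean(y) - slope_cf * mean(x))
  expect_equal(r3$r2, cor(x, y)^2)
  # zero-variance truth is reported as undefined
  tr0 <- tr; tr0[, 1] <- 0.3
  expect_true(is.na(regression_eval(est, tr0)$slope))
})

test_that("calibration CV matches hand computation and scales invariantly", {
  m <- matrix(c(100L, 900L, 200L, 800L), 2, 2,
              dimnames = list(c("sp1_1", "sp2_1"), c("cal1", "cal2")))
  cm <- ab_counts(m, setNames(rep("calibration", 2), colnames(m)))
  cv <- calibration_cv(cm)
  # relative sp1 values (0.1, 0.2): sd/mean = 0.0707.../0.15
  expect_equal(unname(cv["sp1"]), sd(c(0.1, 0.2)) / 0.15)
  expect_equal(round(unname(cv["sp1"]), 3), 0.471)
  cm10 <- ab_counts(m * 10L, setNames(rep("calibration", 2), colnames(m)))
  expect_equal(calibration_cv(cm10), cv)
  # identical samples give zero CV
  mi <- matrix(rep(c(100L, 300L), 3), 2,
               dimnames = list(c("sp1_1", "sp2_1"), paste0("cal", 1:3)))
  cmi <- ab_counts(mi, setNames(rep("calibration", 3), colnames(mi)))
  expect_true(all(calibration_cv(cmi) == 0))
})
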