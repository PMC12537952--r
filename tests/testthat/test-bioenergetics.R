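test_that("specific activity is the duplicate mean minus the non-specific control", {
  expect_equal(as.numeric(specific_activity(10, 12, 1)), 10)
  expect_equal(as.numeric(specific_activity(5, 5, 5)), 0)
  set.seed(61)
  r1 <- runif(20, 5, 50); r2 <- runif(20, 5, 50); ns <- runif(20, 0, 8)
  expect_equal(as.numeric(specific_activity(r1, r2, ns)), (r1 + r2) / 2 - ns)
  # negatives retained and flagged, never clamped
  sa <- specific_activity(1, 2, 5)
  expect_equal(as.numeric(sa), -3.5)
  expect_true(attr(sa, "negative"))
  expect_error(specific_activity(NA, NA, 1), "both duplicates missing")
})

make_plates <- function(effects, n_ref = 5, n_samp = 4, ref_level = 100) {
  rows <- list()
  for (p in seq_along(effects)) {
    for (r in seq_len(n_ref)) {
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = sprintf("ref%d_%d", p, r), plate_id = paste0("P", p),
        assay = "CI", specific = ref_level * effects[p], is_reference = TRUE)
    }
    for (s in seq_len(n_samp)) {
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = sprintf("s%d_%d", p, s), plate_id = paste0("P", p),
        assay = "CI", specific = (50 + 10 * s) * effects[p],
        is_reference = FALSE)
    }
  }
  do.call(rbind, rows)
}

test_that("plate normalization equalizes reference means, undoes a known 2x effect, and is idempotent", {
  one <- make_plates(1)
  norm1 <- plate_normalize(one)
  expect_equal(norm1$specific, one$specific)
  expect_true(all(norm1$plate_factor == 1))

  two <- make_plates(c(1, 2))
  norm2 <- plate_normalize(two)
  ref_means <- tapply(norm2$specific[norm2$is_reference],
                      norm2$plate_id[norm2$is_reference], mean)
  expect_lt(diff(range(ref_means)) / mean(ref_means), 1e-9)
  # the low plate got the factor that removes the 2x effect
  expect_equal(unique(norm2$plate_factor[norm2$plate_id == "P2"]),
               unique(norm2$plate_factor[norm2$plate_id == "P1"]) / 2)
  # sample activities agree across plates once the effect is removed
  expect_equal(norm2$specific[!norm2$is_reference & norm2$plate_id == "P1"],
               norm2$specific[!norm2$is_reference & norm2$plate_id == "P2"])

  again <- plate_normalize(norm2[names(two)])
  expect_equal(again$specific, norm2$specific, tolerance = 1e-12)

  noref <- two[!two$is_reference, ]
  expect_error(plate_normalize(noref), "no reference samples")
})

test_that("mean-centering divides by the cohort mean and is idempotent", {
  expect_equal(mean_center(c(3, 3, 3)), c(1, 1, 1))
  expect_equal(mean_center(c(2, 4)), c(2 / 3, 4 / 3))
  set.seed(67)
  v <- rlnorm(30, 2, 0.4)
  cv <- mean_center(v)
  expect_equal(mean(cv), 1, tolerance = 1e-12)
  expect_equal(mean_center(cv), cv, tolerance = 1e-12)
  expect_error(mean_center(c(-1, 1)), "zero")
})

test_that("MHI is 100 for an all-average animal and matches the formula on random features", {
  expect_equal(mhi(1, 1, 1, 1, 1), 100)
  expect_equal(mhi(0, 0, 0, 1, 1), 0)
  set.seed(71)
  f <- matrix(rlnorm(50, 0, 0.3), ncol = 5)
  expect_equal(mhi(f[, 1], f[, 2], f[, 3], f[, 4], f[, 5]),
               (f[, 1] + f[, 2] + f[, 3]) / (f[, 4] + f[, 5] + 1) * 100)
  expect_error(mhi(1, 1, 1, -1, -1), "denominator")
})

test_that("MRC applies square roots to the chain and cube roots to content", {
  expect_equal(mrc(1, 1, 1, 1, 1), 150)
  expect_equal(mrc(4, 4, 4, 1, 1, per_animal = TRUE), 300)
  set.seed(73)
  f <- matrix(rlnorm(40, 0, 0.3), ncol = 5)
  num <- sqrt(f[, 1]) + sqrt(f[, 2]) + sqrt(f[, 3])
  den <- f[, 5]^(1 / 3) + f[, 4]^(1 / 3)
  expect_equal(mrc(f[, 1], f[, 2], f[, 3], f[, 4], f[, 5]),
               mean(num) / mean(den) * 100, tolerance = 1e-12)
  expect_equal(mrc(f[, 1], f[, 2], f[, 3], f[, 4], f[, 5], per_animal = TRUE),
               num / den * 100, tolerance = 1e-12)
  expect_error(mrc(-0.1, 1, 1, 1, 1), "non-negative")
})

test_that("mtDNA copy number inverts delta-Ct, doubles per cycle, and applies triplicate QC", {
  expect_equal(as.numeric(mtdna_cn(rep(25, 3), rep(25, 3))), 2)
  expect_equal(as.numeric(mtdna_cn(rep(20, 3), rep(25, 3))), 64)
  # strictly increasing in delta-Ct, doubling per unit
  for (dct in c(-2, 0, 1, 5)) {
    a <- as.numeric(mtdna_cn(rep(24 - dct, 3), rep(24, 3)))
    b <- as.numeric(mtdna_cn(rep(24 - dct - 1, 3), rep(24, 3)))
    expect_equal(a, 2^dct * 2)
    expect_equal(b, 2 * a)
  }
  # single >1-Ct outlier dropped before averaging
  cn <- mtdna_cn(c(20, 20.1, 24), c(25, 25, 25.1))
  expect_equal(attr(cn, "delta_ct"), mean(c(25, 25, 25.1)) - mean(c(20, 20.1)))
  expect_error(mtdna_cn(21, c(25, 25, 25)), "fewer than 2")
  expect_error(mtdna_cn(c(50, 50, 50), rep(25, 3)), "outside")
})

test_that("mtDNA density follows the printed linearization, with the inverse switch as reciprocal", {
  expect_equal(as.numeric(mtdna_density(c(10, 10, 10))), 1024 * 1e-12)
  set.seed(79)
  ct <- runif(3, 20, 20.8)  # tight triplicate: QC drops nothing
  expect_equal(as.numeric(mtdna_density(ct)), 2^mean(ct) * 1e-12)
  expect_equal(as.numeric(mtdna_density(ct, "inverse")), 2^(-mean(ct)) * 1e12)
})

test_that("the feature-table pipeline centers to mean one and scores an all-average cohort at MHI 100", {
  cfg <- sim_config(seed = 5, n_animals = 6,
                    enzymes = list(duplicate_cv = 0, biological_cv = 0.2))
  enz <- simulate_enzyme_plates(cfg)
  qp <- simulate_qpcr(cfg)
  feat <- mito_features(enz, qp)
  for (f in c("CI", "CII", "CIV", "CS", "mtdna_density")) {
    expect_equal(mean(feat[[paste0(f, "_centered")]]), 1, tolerance = 1e-12)
  }
  expect_equal(feat$mhi,
               (feat$CI_centered + feat$CII_centered + feat$CIV_centered) /
                 (feat$CS_centered + feat$mtdna_density_centered + 1) * 100)
  expect_true(is.finite(attr(feat, "mrc_cohort")))

  # a cohort of identical animals is all-average: every MHI is exactly 100
  cfg0 <- sim_config(seed = 6, n_animals = 5,
                     enzymes = list(duplicate_cv = 0, biological_cv = 0,
                                    reference_cv = 0),
                     qpcr = list(noise_sd = 0,
                                 mtdnacn = c(400, 400, 400, 400)))
  feat0 <- mito_features(simulate_enzyme_plates(cfg0), simulate_qpcr(cfg0))
  expect_equal(feat0$mhi, rep(100, nrow(feat0)), tolerance = 1e-9)
  expect_equal(attr(feat0, "mrc_cohort"), 150, tolerance = 1e-9)
})
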