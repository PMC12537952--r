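test_that("trial generator honours the mixture limits and the closed-form censoring rate", {
  cfg0 <- sim_config(seed = 2, n_animals = 4)
  cfg0$behavior$groups$omega[] <- 0
  tr0 <- simulate_trials(cfg0)
  expect_true(all(tr0$latency_s == 60))

  cfg1 <- sim_config(seed = 2, n_animals = 4)
  cfg1$behavior$groups$omega[] <- 1
  cfg1$behavior$groups$mu[] <- log(10)
  cfg1$behavior$groups$sigma[] <- 1e-8
  tr1 <- simulate_trials(cfg1)
  expect_equal(tr1$latency_s, rep(10, nrow(tr1)), tolerance = 1e-4)

  # censored fraction ~ (1 - omega) + omega * (1 - F_LN(60))
  set.seed(91)
  y <- rlatency(10000, mixture_params(0.7, log(20), 0.4))
  expected <- 0.3 + 0.7 * (1 - plnorm(60, log(20), 0.4))
  expect_lt(abs(mean(y == 60) - expected), 0.02)
})

test_that("generators are reproducible: same seed, byte-identical CSV files", {
  d <- withr::local_tempdir()
  for (run in 1:2) {
    sim <- simulate_all(sim_config(seed = 77, n_animals = 3))
    for (nm in names(sim)) {
      write_table(sim[[nm]], file.path(d, sprintf("%s_%d.csv", nm, run)))
    }
  }
  for (nm in c("trials", "enzymes", "qpcr", "ocr")) {
    h <- tools::md5sum(file.path(d, sprintf("%s_%d.csv", nm, 1:2)))
    expect_identical(unname(h[1]), unname(h[2]))
  }
})

test_that("every generated table passes its own input validation", {
  d <- withr::local_tempdir()
  sim <- simulate_all(sim_config(seed = 13, n_animals = 3))
  for (nm in names(sim)) {
    p <- file.path(d, paste0(nm, ".csv"))
    write_table(sim[[nm]], p)
    expect_silent(read_table(p, nm))
  }
})

test_that("noise-free enzyme plates are returned unchanged when plate effects are 1", {
  cfg <- sim_config(seed = 3, n_animals = 4,
                    enzymes = list(duplicate_cv = 0, reference_cv = 0,
                                   plate_effects = c(1, 1)))
  enz <- simulate_enzyme_plates(cfg)
  expect_equal(enz$rep1, enz$rep2)
  enz$specific <- specific_activity(enz$rep1, enz$rep2, enz$nonspecific)
  norm <- plate_normalize(enz)
  expect_equal(norm$specific, enz$specific, tolerance = 1e-9)
})

test_that("a 2x plate effect is removed by normalization on generated plates", {
  cfg <- sim_config(seed = 4, n_animals = 4,
                    enzymes = list(duplicate_cv = 0, plate_effects = c(1, 2)))
  enz <- simulate_enzyme_plates(cfg)
  enz$specific <- specific_activity(enz$rep1, enz$rep2, enz$nonspecific)
  norm <- plate_normalize(enz)
  for (a in unique(norm$assay)) {
    ref <- norm[norm$is_reference & norm$assay == a, ]
    m <- tapply(ref$specific, ref$plate_id, mean)
    expect_lt(diff(range(m)) / mean(m), 1e-9)
  }
})

test_that("qPCR generator inverts exactly at zero noise and approximately under noise", {
  cfg <- sim_config(seed = 8, qpcr = list(noise_sd = 0,
                                          mtdnacn = c(64, 64, 64, 64)))
  qp <- simulate_qpcr(cfg)
  mt <- unlist(qp[qp$amplicon == "mt", c("ct1", "ct2", "ct3")][1, ])
  nu <- unlist(qp[qp$amplicon == "n", c("ct1", "ct2", "ct3")][1, ])
  expect_equal(as.numeric(mtdna_cn(mt, nu)), 64, tolerance = 1e-12)

  cfg2 <- sim_config(seed = 9, n_animals = 50,
                     qpcr = list(noise_sd = 0.2,
                                 mtdnacn = c(400, 400, 400, 400)))
  qp2 <- simulate_qpcr(cfg2)
  cns <- vapply(unique(qp2$sample_id), function(sid) {
    rec <- qp2[qp2$sample_id == sid, ]
    as.numeric(mtdna_cn(unlist(rec[rec$amplicon == "mt", 3:5]),
                        unlist(rec[rec$amplicon == "n", 3:5])))
  }, numeric(1))
  expect_lt(abs(median(cns) - 400) / 400, 0.1)
  # triplicate spread stays within normal-tail expectations
  spreads <- vapply(unique(qp2$sample_id), function(sid) {
    rec <- qp2[qp2$sample_id == sid, ]
    max(unlist(rec[rec$amplicon == "mt", 3:5])) -
      min(unlist(rec[rec$amplicon == "mt", 3:5]))
  }, numeric(1))
  expect_gte(mean(spreads <= 3 * 0.2 * 2), 0.95)
})

test_that("OCR generator recovers plateaus exactly at zero noise and keeps phases ordered", {
  cfg <- sim_config(seed = 10, n_animals = 2,
                    ocr = list(noise_sd = 0, substrates = "pyruvate_malate"))
  ocr <- simulate_ocr(cfg)
  w <- ocr[ocr$well_id == ocr$well_id[1], ]
  st <- compute_states(w)
  plat <- cfg$ocr$plateaus["WT.SPF", ]
  p <- w$protein_ug[1]
  expect_equal(st$state3, (plat[["adp"]] - plat[["rot_aa"]]) / p,
               tolerance = 1e-12)
  expect_equal(st$state3u, (plat[["fccp"]] - plat[["rot_aa"]]) / p,
               tolerance = 1e-12)
  # constructive phase-order guarantee
  for (wid in unique(ocr$well_id)) {
    expect_silent(compute_states(ocr[ocr$well_id == wid, ]))
  }
})
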