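#' Synthetic-study configuration
#'
#' Bundles one master seed with the generative parameters of every
#' simulator, mirroring the design of the mouse study the analyses were
#' built for: four groups (WT/ASO genotype x SPF/GF microbiome), 1-3
#' trials per mouse on two timed motor tests censored at 60 s, duplicate
#' enzymatic assays with five reference samples per plate, triplicate qPCR
#' wells, and quintuplicate Seahorse wells per mouse with phase-plateau
#' OCR traces. Default effect directions are qualitative: conventionally
#' colonized (SPF) ASO mice complete motor tasks less often and more
#' slowly and show elevated ADP-stimulated and uncoupled respiration,
#' while germ-free (GF) ASO mice sit near wild-type.
#'
#' @param seed master integer seed; each generator derives its own
#'   sub-seed from it by a fixed offset.
#' @param n_animals animals per group.
#' @param behavior,enzymes,qpcr,ocr optional lists overriding individual
#'   defaults (partial overrides are merged).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_animals = 10, behavior = list(),
                       enzymes = list(), qpcr = list(), ocr = list()) {
  groups <- data.frame(
    genotype = c("WT", "ASO", "WT", "ASO"),
    condition = c("SPF", "SPF", "GF", "GF"),
    stringsAsFactors = FALSE
  )
  beh <- utils::modifyList(list(
    groups = cbind(groups,
                   omega = c(0.95, 0.60, 0.95, 0.90),
                   mu = log(c(6, 18, 6, 9)),
                   sigma = c(0.40, 0.50, 0.40, 0.45)),
    tests = c("beam", "pole"),
    trials_min = 1, trials_max = 3,
    censor_point = 60
  ), behavior)
  enz <- utils::modifyList(list(
    # cohort mean activities (mU/mg tissue) and biological CV per assay
    assay_means = c(CI = 120, CII = 80, CIV = 200, CS = 400),
    biological_cv = 0.15,
    duplicate_cv = 0.05,
    reference_cv = 0.05,
    nonspecific = c(CI = 10, CII = 6, CIV = 15, CS = 20),
    n_plates = 2,
    plate_effects = c(1.0, 1.2),
    n_ref = 5
  ), enzymes)
  qp <- utils::modifyList(list(
    # true mtDNA copy number per group (WT.SPF, ASO.SPF, WT.GF, ASO.GF)
    mtdnacn = c(400, 360, 400, 420),
    ct_anchor = 24,       # nuclear (B2M) Ct
    noise_sd = 0.15,      # per-replicate Ct noise
    n_replicates = 3
  ), qpcr)
  oc <- utils::modifyList(list(
    # phase plateau means in pmol O2/min per group, pyruvate+malate
    plateaus = rbind(
      WT.SPF  = c(substrate = 50, adp = 150, oligomycin = 60, fccp = 200, rot_aa = 10),
      ASO.SPF = c(substrate = 55, adp = 195, oligomycin = 65, fccp = 260, rot_aa = 10),
      WT.GF   = c(substrate = 50, adp = 150, oligomycin = 60, fccp = 200, rot_aa = 10),
      ASO.GF  = c(substrate = 52, adp = 160, oligomycin = 62, fccp = 210, rot_aa = 10)
    ),
    substrates = c("pyruvate_malate", "succinate_rotenone"),
    succinate_scale = 1.4,  # CII-driven rates run higher
    noise_sd = 5,
    wells_per_mouse = 5,
    cycles_per_phase = 3,
    protein_mean = 4, protein_sd = 0.5  # 3-5 ug mitochondrial extract
  ), ocr)
  structure(
    list(seed = seed, n_animals = n_animals, groups = groups,
         behavior = beh, enzymes = enz, qpcr = qp, ocr = oc),
    class = "sim_config"
  )
}

.animal_ids <- function(config) {
  g <- config$groups
  do.call(rbind, lapply(seq_len(nrow(g)), function(i) {
    data.frame(
      animal_id = sprintf("%s.%s_%02d", g$genotype[i], g$condition[i],
                          seq_len(config$n_animals)),
      genotype = g$genotype[i], condition = g$condition[i],
      stringsAsFactors = FALSE
    )
  }))
}

#' Simulate motor-trial latencies
#'
#' Runs the censored mixture forward per group: each trial is a
#' Bernoulli(omega) completion; completers draw a LogNormal(mu, sigma)
#' time censored at 60 s, failures score 60. Each animal performs 1-3
#' trials per test.
#'
#' @param config a [sim_config()].
#' @return validated trial data.frame (`animal_id`, `genotype`,
#'   `condition`, `test`, `trial`, `latency_s`, `censored`).
#' @export
simulate_trials <- function(config) {
  set.seed(seed_stream(config$seed, 1))
  beh <- config$behavior
  animals <- .animal_ids(config)
  rows <- list()
  for (i in seq_len(nrow(animals))) {
    gi <- which(beh$groups$genotype == animals$genotype[i] &
                beh$groups$condition == animals$condition[i])
    p <- mixture_params(beh$groups$omega[gi], beh$groups$mu[gi],
                        beh$groups$sigma[gi], beh$censor_point)
    for (test in beh$tests) {
      n_tr <- sample(beh$trials_min:beh$trials_max, 1)
      rows[[length(rows) + 1]] <- data.frame(
        animal_id = animals$animal_id[i],
        genotype = animals$genotype[i], condition = animals$condition[i],
        test = test, trial = seq_len(n_tr),
        latency_s = rlatency(n_tr, p),
        stringsAsFactors = FALSE
      )
    }
  }
  validate_trials(do.call(rbind, rows), beh$censor_point)
}

#' Simulate enzymatic-activity plates
#'
#' Per-animal true specific activities are lognormal around the assay
#' cohort mean; plates impose a multiplicative batch effect on the
#' specific component, uniform within plate; duplicates add multiplicative
#' measurement noise on top of a constant non-specific background. Each
#' plate carries reference samples drawn from one common reference
#' distribution, which is what [plate_normalize()] exploits.
#'
#' @param config a [sim_config()].
#' @return data.frame in the enzymes input schema.
#' @export
simulate_enzyme_plates <- function(config) {
  set.seed(seed_stream(config$seed, 2))
  enz <- config$enzymes
  animals <- .animal_ids(config)
  n <- nrow(animals)
  plate_of <- rep_len(seq_len(enz$n_plates), n)
  rows <- list()
  dup_noise <- function(k) {
    if (enz$duplicate_cv == 0) rep(1, k)
    else stats::rlnorm(k, -enz$duplicate_cv^2 / 2, enz$duplicate_cv)
  }
  for (a in names(enz$assay_means)) {
    true <- enz$assay_means[[a]] *
      stats::rlnorm(n, -enz$biological_cv^2 / 2, enz$biological_cv)
    for (i in seq_len(n)) {
      spec <- true[i] * enz$plate_effects[plate_of[i]]
      reps <- spec * dup_noise(2)
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = animals$animal_id[i],
        plate_id = sprintf("plate%d", plate_of[i]), assay = a,
        rep1 = reps[1] + enz$nonspecific[[a]],
        rep2 = reps[2] + enz$nonspecific[[a]],
        nonspecific = enz$nonspecific[[a]], is_reference = FALSE,
        stringsAsFactors = FALSE
      )
    }
    for (p in seq_len(enz$n_plates)) {
      ref_true <- enz$assay_means[[a]] *
        stats::rlnorm(enz$n_ref, -enz$reference_cv^2 / 2, enz$reference_cv)
      for (r in seq_len(enz$n_ref)) {
        spec <- ref_true[r] * enz$plate_effects[p]
        reps <- spec * dup_noise(2)
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = sprintf("ref_p%d_%d", p, r),
          plate_id = sprintf("plate%d", p), assay = a,
          rep1 = reps[1] + enz$nonspecific[[a]],
          rep2 = reps[2] + enz$nonspecific[[a]],
          nonspecific = enz$nonspecific[[a]], is_reference = TRUE,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate triplicate qPCR records
#'
#' For a group's true copy number M the generative delta-Ct is
#' log2(M / 2); nuclear Ct replicates scatter around a fixed anchor and
#' mitochondrial Ct replicates around (anchor - delta Ct), with iid
#' normal noise per replicate, so [mtdna_cn()] recovers M exactly at zero
#' noise.
#'
#' @param config a [sim_config()].
#' @return data.frame in the qpcr input schema (one `mt` and one `n` row
#'   per sample).
#' @export
simulate_qpcr <- function(config) {
  set.seed(seed_stream(config$seed, 3))
  qp <- config$qpcr
  animals <- .animal_ids(config)
  grp <- match(paste(animals$genotype, animals$condition, sep = "."),
               paste(config$groups$genotype, config$groups$condition, sep = "."))
  rows <- list()
  for (i in seq_len(nrow(animals))) {
    M <- qp$mtdnacn[grp[i]]
    dct <- log2(M / 2)
    ct_n <- qp$ct_anchor + stats::rnorm(qp$n_replicates, 0, qp$noise_sd)
    ct_mt <- (qp$ct_anchor - dct) + stats::rnorm(qp$n_replicates, 0, qp$noise_sd)
    rows[[length(rows) + 1]] <- data.frame(
      sample_id = animals$animal_id[i], amplicon = c("mt", "n"),
      ct1 = c(ct_mt[1], ct_n[1]), ct2 = c(ct_mt[2], ct_n[2]),
      ct3 = c(ct_mt[3], ct_n[3]), stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate injection-phased OCR traces
#'
#' Phase-plateau means per group plus iid cycle noise, five wells per
#' mouse and substrate, cycles ordered substrate -> ADP -> oligomycin ->
#' FCCP -> rotenone+antimycin A, and a positive protein mass per well.
#'
#' @param config a [sim_config()].
#' @return data.frame in the ocr input schema.
#' @export
simulate_ocr <- function(config) {
  set.seed(seed_stream(config$seed, 4))
  oc <- config$ocr
  animals <- .animal_ids(config)
  grp_key <- paste(animals$genotype, animals$condition, sep = ".")
  phases <- colnames(oc$plateaus)
  n_cyc <- oc$cycles_per_phase
  rows <- list()
  for (i in seq_len(nrow(animals))) {
    base <- oc$plateaus[grp_key[i], ]
    for (sub in oc$substrates) {
      scale <- if (sub == "succinate_rotenone") oc$succinate_scale else 1
      for (w in seq_len(oc$wells_per_mouse)) {
        protein <- max(stats::rnorm(1, oc$protein_mean, oc$protein_sd), 0.5)
        ocr_vals <- rep(base * scale, each = n_cyc) +
          stats::rnorm(length(phases) * n_cyc, 0, oc$noise_sd)
        rows[[length(rows) + 1]] <- data.frame(
          well_id = sprintf("%s_%s_w%d", animals$animal_id[i],
                            substr(sub, 1, 3), w),
          mouse_id = animals$animal_id[i], substrate = sub,
          cycle = seq_len(length(phases) * n_cyc),
          phase = rep(phases, each = n_cyc),
          ocr = ocr_vals, protein_ug = protein,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate every pipeline input
#'
#' @param config a [sim_config()].
#' @return named list: `trials`, `enzymes`, `qpcr`, `ocr`.
#' @export
simulate_all <- function(config) {
  list(
    trials = simulate_trials(config),
    enzymes = simulate_enzyme_plates(config),
    qpcr = simulate_qpcr(config),
    ocr = simulate_ocr(config)
  )
}
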