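#' Specific enzymatic activity from duplicate wells
#'
#' Each sample is assayed in duplicate alongside a non-specific activity
#' control; the specific activity is the duplicate mean minus that control.
#' Negative results are retained (clamping would bias the downstream
#' mean-centering) and flagged via `attr(, "negative")`.
#'
#' @param rep1,rep2 duplicate total activities (activity units per mg
#'   tissue); one of the two may be NA.
#' @param nonspecific non-specific (negative-control) activity.
#' @return numeric specific activities with a logical `negative` attribute.
#' @export
specific_activity <- function(rep1, rep2, nonspecific) {
  both_missing <- is.na(rep1) & is.na(rep2)
  if (any(both_missing)) {
    stop("both duplicates missing for ", sum(both_missing), " record(s)")
  }
  tot <- rowMeans(cbind(rep1, rep2), na.rm = TRUE)
  out <- tot - nonspecific
  attr(out, "negative") <- out < 0
  out
}

#' Plate (batch) normalization against reference samples
#'
#' Five reference samples are carried on every plate; per assay, each
#' plate's normalization factor is the grand mean of all plates' reference
#' specific activities divided by that plate's own reference mean, and all
#' of the plate's samples are multiplied by it. After normalization the
#' reference means agree across plates, and applying the procedure twice
#' equals applying it once.
#'
#' @param records data.frame with columns `sample_id`, `plate_id`, `assay`,
#'   `specific` (see [specific_activity()]) and logical `is_reference`.
#' @return the input with `specific` replaced by its normalized value and a
#'   `plate_factor` column appended.
#' @export
plate_normalize <- function(records) {
  need <- c("sample_id", "plate_id", "assay", "specific", "is_reference")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0) stop("missing column(s): ", paste(miss, collapse = ", "))
  out <- records
  out$plate_factor <- NA_real_
  for (a in unique(records$assay)) {
    ia <- records$assay == a
    ref <- ia & records$is_reference
    plates <- unique(records$plate_id[ia])
    no_ref <- plates[!plates %in% records$plate_id[ref]]
    if (length(no_ref) > 0) {
      stop(sprintf("plate '%s' has no reference samples for assay '%s'",
                   no_ref[1], a))
    }
    grand <- mean(records$specific[ref])
    plate_mean <- tapply(records$specific[ref], records$plate_id[ref], mean)
    fac <- grand / plate_mean[as.character(records$plate_id[ia])]
    out$specific[ia] <- records$specific[ia] * fac
    out$plate_factor[ia] <- fac
  }
  out
}

#' Mean-center a feature across the cohort
#'
#' Divides by the cohort mean, expressing each animal's value relative to
#' all other animals; the centered feature has mean exactly 1.
#'
#' @param values per-sample feature values.
#' @return `values / mean(values)`.
#' @export
mean_center <- function(values) {
  m <- mean(values)
  if (!is.finite(m) || m == 0) stop("cohort mean is zero or not finite")
  values / m
}

#' Mitochondrial Health Index
#'
#' Composite per-mitochondrion score of respiratory-chain activity:
#' \deqn{\mathrm{MHI} = \frac{CI + CII + CIV}{CS + \mathrm{mtDNA\ density} + 1}
#'   \times 100} computed on mean-centered features, so the respiratory
#' complexes (numerator) are expressed relative to two indirect markers of
#' mitochondrial content (denominator). The constant 1 is a balancing
#' third denominator term and is never centered; an animal at the cohort
#' average on all five features scores exactly 100.
#'
#' @param ci,cii,civ mean-centered Complex I/II/IV activities.
#' @param cs mean-centered citrate synthase activity.
#' @param mtdna_density mean-centered mtDNA density.
#' @return MHI score(s).
#' @export
mhi <- function(ci, cii, civ, cs, mtdna_density) {
  den <- cs + mtdna_density + 1
  if (any(den <= 0)) stop("MHI denominator <= 0")
  (ci + cii + civ) / den * 100
}

#' Mitochondrial Respiratory Capacity
#'
#' MHI variant with allometric scaling: square roots (surface area of
#' cristae-bound ETC complexes) in the numerator and cube roots (volume of
#' mitochondrial content) in the denominator, on mean-centered features:
#' \deqn{\mathrm{MRC} = \frac{mean(\sqrt{CI}+\sqrt{CII}+\sqrt{CIV})}
#'   {mean(\sqrt[3]{\mathrm{mtDNA\ density}}+\sqrt[3]{CS})} \times 100.}
#' The cohort value averages the rooted sums over animals before taking
#' the ratio; `per_animal = TRUE` instead applies the ratio animal-wise.
#'
#' @param ci,cii,civ,cs,mtdna_density mean-centered features, all >= 0.
#' @param per_animal return one value per animal instead of the cohort
#'   scalar.
#' @return MRC (scalar, or vector when `per_animal`).
#' @export
mrc <- function(ci, cii, civ, cs, mtdna_density, per_animal = FALSE) {
  if (any(c(ci, cii, civ, cs, mtdna_density) < 0)) {
    stop("MRC requires non-negative centered features (roots undefined)")
  }
  num <- sqrt(ci) + sqrt(cii) + sqrt(civ)
  den <- cbrt(mtdna_density) + cbrt(cs)
  if (per_animal) {
    if (any(den == 0)) stop("MRC denominator 0")
    num / den * 100
  } else {
    if (mean(den) == 0) stop("MRC denominator 0")
    mean(num) / mean(den) * 100
  }
}

# Triplicate QC: with three replicates, drop a single one deviating more
# than 1 Ct from the median; two valid replicates are the minimum.
.ct_clean <- function(ct, label) {
  ct <- ct[is.finite(ct)]
  if (any(ct <= 0 | ct >= 45)) stop(label, " Ct outside (0, 45)")
  if (length(ct) == 3) {
    dev <- abs(ct - stats::median(ct))
    if (sum(dev > 1) == 1) ct <- ct[dev <= 1]
  }
  if (length(ct) < 2) stop("fewer than 2 valid ", label, " Ct replicates")
  list(mean = mean(ct), spread = max(ct) - min(ct))
}

#' mtDNA copy number from qPCR triplicates
#'
#' \eqn{\Delta Ct} is the mean nuclear-amplicon Ct (B2M) minus the mean
#' mitochondrial-amplicon Ct (COX1); the copy number is
#' \eqn{2^{\Delta Ct} \times 2}, the factor 2 accounting for the diploid
#' nuclear genome. A triplicate member deviating more than 1 Ct from the
#' replicate median is dropped; a post-QC spread above 1 Ct raises a
#' `qc_flag` attribute.
#'
#' @param ct_mt mitochondrial (COX1) Ct replicates.
#' @param ct_n nuclear (B2M) Ct replicates.
#' @return scalar mtDNA copy number with attributes `delta_ct`, `qc_flag`.
#' @export
mtdna_cn <- function(ct_mt, ct_n) {
  mt <- .ct_clean(ct_mt, "mtDNA")
  nu <- .ct_clean(ct_n, "nDNA")
  dct <- nu$mean - mt$mean
  out <- 2^dct * 2
  attr(out, "delta_ct") <- dct
  attr(out, "qc_flag") <- mt$spread > 1 || nu$spread > 1
  out
}

#' mtDNA density per unit tissue
#'
#' Linearizes the mean mitochondrial Ct as \eqn{2^{Ct} / (1/10^{-12})},
#' i.e. \eqn{2^{Ct} \times 10^{-12}}, exactly as the index is defined.
#' Note this direction increases with Ct while template abundance
#' decreases with Ct; `direction = "inverse"` provides the reciprocal
#' reading \eqn{2^{-Ct} \times 10^{12}} without changing the default.
#'
#' @param ct_mt mitochondrial Ct replicates.
#' @param direction `"as_printed"` (default) or `"inverse"`.
#' @return scalar relative mtDNA density.
#' @export
mtdna_density <- function(ct_mt, direction = c("as_printed", "inverse")) {
  direction <- match.arg(direction)
  mt <- .ct_clean(ct_mt, "mtDNA")
  out <- switch(direction,
    as_printed = 2^mt$mean * 1e-12,
    inverse = 2^(-mt$mean) * 1e12
  )
  attr(out, "qc_flag") <- mt$spread > 1
  out
}

#' Per-animal mitochondrial feature table
#'
#' End-to-end bioenergetics pipeline: duplicate-averaged specific
#' activities, plate normalization against the reference samples,
#' cohort mean-centering of the five features (CI, CII, CIV, CS, mtDNA
#' density), and the composite indices MHI and MRC, plus mtDNA copy
#' number. The mean-centering cohort is every animal in the run.
#'
#' @param enzymes data.frame: `sample_id`, `plate_id`, `assay` (CI, CII,
#'   CIV, CS), `rep1`, `rep2`, `nonspecific`, `is_reference`.
#' @param qpcr data.frame: `sample_id`, `amplicon` (mt or n), `ct1`, `ct2`,
#'   `ct3`.
#' @param density_direction passed to [mtdna_density()].
#' @return data.frame, one row per (non-reference) sample: raw and
#'   centered features, `mhi`, `mrc_animal`, `mtdnacn`, `mtdna_density`,
#'   QC flag columns; the cohort MRC is in `attr(, "mrc_cohort")`.
#' @export
mito_features <- function(enzymes, qpcr,
                          density_direction = c("as_printed", "inverse")) {
  density_direction <- match.arg(density_direction)
  enzymes$specific <- specific_activity(enzymes$rep1, enzymes$rep2,
                                        enzymes$nonspecific)
  neg <- attr(enzymes$specific, "negative")
  enzymes <- plate_normalize(enzymes)
  enzymes$neg_flag <- neg

  samples <- enzymes[!enzymes$is_reference, ]
  wide <- stats::reshape(
    samples[, c("sample_id", "assay", "specific")],
    idvar = "sample_id", timevar = "assay", direction = "wide"
  )
  names(wide) <- sub("^specific\\.", "", names(wide))
  for (a in c("CI", "CII", "CIV", "CS")) {
    if (!a %in% names(wide) || any(is.na(wide[[a]]))) {
      stop("missing assay '", a, "' for one or more samples")
    }
  }

  qc <- vapply(wide$sample_id, function(sid) {
    rec <- qpcr[qpcr$sample_id == sid, ]
    mt <- unlist(rec[rec$amplicon == "mt", c("ct1", "ct2", "ct3")])
    nu <- unlist(rec[rec$amplicon == "n", c("ct1", "ct2", "ct3")])
    if (length(mt) == 0 || length(nu) == 0) {
      stop("no qPCR record for sample '", sid, "'")
    }
    cn <- mtdna_cn(mt, nu)
    dens <- mtdna_density(mt, density_direction)
    c(mtdnacn = as.numeric(cn), mtdna_density = as.numeric(dens),
      qpcr_flag = as.numeric(attr(cn, "qc_flag") || attr(dens, "qc_flag")))
  }, numeric(3))

  wide$mtdnacn <- qc["mtdnacn", ]
  wide$mtdna_density <- qc["mtdna_density", ]
  wide$qpcr_flag <- qc["qpcr_flag", ] > 0
  wide$neg_flag <- vapply(
    wide$sample_id,
    function(sid) any(enzymes$neg_flag[enzymes$sample_id == sid]),
    logical(1)
  )

  for (f in c("CI", "CII", "CIV", "CS", "mtdna_density")) {
    wide[[paste0(f, "_centered")]] <- mean_center(wide[[f]])
  }
  wide$mhi <- mhi(wide$CI_centered, wide$CII_centered, wide$CIV_centered,
                  wide$CS_centered, wide$mtdna_density_centered)
  wide$mrc_animal <- mrc(wide$CI_centered, wide$CII_centered,
                         wide$CIV_centered, wide$CS_centered,
                         wide$mtdna_density_centered, per_animal = TRUE)
  attr(wide, "mrc_cohort") <- mrc(wide$CI_centered, wide$CII_centered,
                                  wide$CIV_centered, wide$CS_centered,
                                  wide$mtdna_density_centered)
  rownames(wide) <- NULL
  wide
}
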