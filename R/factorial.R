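#' 2x2 factorial linear model for bioenergetic endpoints
#'
#' Ordinary least squares for `value ~ genotype + condition +
#' genotype:condition` with treatment coding (reference levels WT and the
#' control housing/treatment), the model used for respirometry, enzymatic
#' activity, mtDNA and oxidative-stress endpoints. The saturated 2x2 model
#' reproduces the four cell means exactly.
#'
#' @param values per-animal endpoint values.
#' @param genotype factor-like, e.g. WT / ASO.
#' @param condition factor-like, e.g. SPF / GF or vehicle / drug.
#' @param ref_genotype,ref_condition reference levels (defaults "WT" and
#'   the first level present, preferring "SPF").
#' @return object of class `factorial_fit`: the `lm` fit, `coefficients`
#'   table, `cell_means`, `cell_n`, `sigma2` (pooled residual variance),
#'   `df_residual`.
#' @export
fit_two_factor <- function(values, genotype, condition,
                           ref_genotype = "WT", ref_condition = NULL) {
  g <- factor(genotype)
  cnd <- factor(condition)
  if (ref_genotype %in% levels(g)) g <- stats::relevel(g, ref_genotype)
  if (is.null(ref_condition)) {
    ref_condition <- if ("SPF" %in% levels(cnd)) "SPF" else levels(cnd)[1]
  }
  if (ref_condition %in% levels(cnd)) cnd <- stats::relevel(cnd, ref_condition)
  tab <- table(g, cnd)
  if (any(tab == 0)) {
    stop("empty design cell: ",
         paste(outer(rownames(tab), colnames(tab), paste, sep = ".")[tab == 0],
               collapse = ", "))
  }
  dat <- data.frame(value = values, genotype = g, condition = cnd)
  fit <- stats::lm(value ~ genotype * condition, data = dat)
  if (fit$rank < ncol(stats::model.matrix(fit))) stop("rank-deficient design")
  if (fit$df.residual < 1) stop("no residual degrees of freedom")
  if (fit$df.residual < 5) {
    warning("fewer than 5 residual degrees of freedom; estimates are fragile")
  }
  cell <- c(tapply(dat$value, interaction(g, cnd, sep = "."), mean))
  cn <- c(tapply(dat$value, interaction(g, cnd, sep = "."), length))
  structure(
    list(
      lm = fit,
      coefficients = summary(fit)$coefficients,
      cell_means = cell, cell_n = cn,
      sigma2 = sum(stats::residuals(fit)^2) / fit$df.residual,
      df_residual = fit$df.residual
    ),
    class = "factorial_fit"
  )
}

#' Pairwise cell contrasts with BH adjustment
#'
#' Differences of cell means with standard errors from the pooled
#' (homoscedastic) residual variance of the factorial fit, two-sided t
#' tests on the residual degrees of freedom, and Benjamini-Hochberg
#' adjustment across the requested family of comparisons.
#'
#' @param fit a [fit_two_factor()] result.
#' @param pairs character vector like `"ASO.SPF-WT.SPF"`, naming cells as
#'   `genotype.condition`.
#' @return data.frame: `contrast`, `estimate`, `se`, `t`, `df`, `p_raw`,
#'   `p_bh`.
#' @export
pairwise_contrasts <- function(fit, pairs) {
  stopifnot(inherits(fit, "factorial_fit"))
  cells <- names(fit$cell_means)
  parsed <- strsplit(pairs, "-", fixed = TRUE)
  bad <- vapply(parsed, function(p) length(p) != 2 || !all(p %in% cells),
                logical(1))
  if (any(bad)) {
    stop("unknown cell in contrast '", pairs[bad][1], "'; cells are: ",
         paste(cells, collapse = ", "))
  }
  a <- vapply(parsed, `[`, character(1), 1)
  b <- vapply(parsed, `[`, character(1), 2)
  est <- fit$cell_means[a] - fit$cell_means[b]
  se <- sqrt(fit$sigma2 * (1 / fit$cell_n[a] + 1 / fit$cell_n[b]))
  tstat <- est / se
  p_raw <- 2 * stats::pt(abs(tstat), df = fit$df_residual, lower.tail = FALSE)
  data.frame(
    contrast = pairs, estimate = unname(est), se = unname(se),
    t = unname(tstat), df = fit$df_residual, p_raw = unname(p_raw),
    p_bh = bh_adjust(unname(p_raw)), stringsAsFactors = FALSE
  )
}
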