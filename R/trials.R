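#' Validate a motor-trial table
#'
#' Checks the invariants of latency-to-complete trial records: every latency
#' lies in (0, censor_point] and the `censored` flag (added if absent) is
#' true exactly when the recorded latency equals the censoring point. A
#' score equal to the censoring point is assigned to every trial the mouse
#' failed to complete, so completion times and outright failures share that
#' single recorded value.
#'
#' @param trials data.frame with columns `animal_id`, `latency_s` and
#'   optionally `genotype`, `condition`, `test`, `trial`, `censored`.
#' @param censor_point censoring ceiling in seconds (default 60).
#' @return the validated data.frame with a logical `censored` column.
#' @export
validate_trials <- function(trials, censor_point = 60) {
  stopifnot(is.data.frame(trials))
  need <- c("animal_id", "latency_s")
  miss <- setdiff(need, names(trials))
  if (length(miss) > 0) {
    stop("trials table missing column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(trials) == 0) stop("no observations")
  y <- trials$latency_s
  bad <- which(!is.finite(y) | y <= 0 | y > censor_point)
  if (length(bad) > 0) {
    stop(sprintf(
      "latency_s must lie in (0, %g]; violated at row(s) %s",
      censor_point, paste(utils::head(bad, 5), collapse = ", ")
    ))
  }
  cens <- y == censor_point
  if ("censored" %in% names(trials)) {
    mismatch <- which(as.logical(trials$censored) != cens)
    if (length(mismatch) > 0) {
      stop(sprintf(
        "censored flag inconsistent with latency at row(s) %s (censored <=> latency == %g)",
        paste(utils::head(mismatch, 5), collapse = ", "), censor_point
      ))
    }
  }
  trials$censored <- cens
  trials
}

#' Per-animal median latency summary
#'
#' Collapses repeated trials (typically 1-3 per mouse) to one median latency
#' per animal, the summary statistic used for group comparisons: the median
#' is robust to the censored 60-s scores that would distort a mean.
#' An even trial count yields the midpoint of the two central values.
#'
#' @param trials validated trial table; grouping label columns among
#'   `genotype`, `condition`, `test` are carried through.
#' @param censor_point censoring ceiling, seconds.
#' @return data.frame with one row per animal (x test where present):
#'   label columns, `n_trials`, `median_latency_s`.
#' @export
median_summary <- function(trials, censor_point = 60) {
  trials <- validate_trials(trials, censor_point)
  labs <- intersect(c("animal_id", "genotype", "condition", "test"), names(trials))
  key <- interaction(trials[labs], drop = TRUE, sep = "\r")
  idx <- split(seq_len(nrow(trials)), key)
  out <- do.call(rbind, lapply(idx, function(i) {
    row <- trials[i[1], labs, drop = FALSE]
    row$n_trials <- length(i)
    row$median_latency_s <- stats::median(trials$latency_s[i])
    row
  }))
  rownames(out) <- NULL
  out[order(out$animal_id), , drop = FALSE]
}
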