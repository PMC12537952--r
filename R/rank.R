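#' Benjamini-Hochberg step-up adjustment
#'
#' Computes \eqn{q_{(i)} = \min_{j \ge i} (m/j)\, p_{(j)}}, capped at 1,
#' and returns the adjusted values in the input order. This is the
#' false-discovery-rate control applied to every family of pairwise
#' comparisons in the package.
#'
#' @param p numeric vector of raw p-values in [0, 1].
#' @return adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  stopifnot(is.numeric(p))
  if (any(!is.finite(p) | p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  ps <- p[o]
  q <- rev(cummin(rev(ps * m / seq_len(m))))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# mid-ranks, total N, group index list, and the tie term sum(t^3 - t)
.rank_setup <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  if (any(!is.finite(values))) stop("group values must be finite")
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need >= 2 groups")
  if (any(tabulate(g) == 0)) stop("empty group")
  r <- rank(values, ties.method = "average")
  tt <- table(values)
  list(g = g, r = r, N = length(values),
       tie_sum = sum(tt^3 - tt), has_ties = any(tt > 1))
}

#' Kruskal-Wallis test with tie correction
#'
#' Computes the H statistic from mid-ranks,
#' \eqn{H = \frac{12}{N(N+1)} \sum_i n_i (\bar R_i - \bar R)^2}, divided by
#' the tie-correction factor \eqn{1 - \sum(t^3 - t)/(N^3 - N)}, with the
#' p-value from a chi-square distribution on k-1 degrees of freedom.
#'
#' @param values numeric responses (per-animal medians or assay values).
#' @param groups group labels, same length.
#' @return list of class `kw_test`: `H`, `p`, `df`, `tie_corrected`,
#'   `n`, `groups`.
#' @export
kruskal_wallis <- function(values, groups) {
  s <- .rank_setup(values, groups)
  N <- s$N
  if (N < 3) stop("need total N >= 3")
  rbar <- tapply(s$r, s$g, mean)
  ni <- tabulate(s$g)
  H0 <- 12 / (N * (N + 1)) * sum(ni * (rbar - (N + 1) / 2)^2)
  C <- 1 - s$tie_sum / (N^3 - N)
  if (C <= 0) {
    # all values identical: no evidence against homogeneity by convention
    H <- 0
    p <- 1
  } else {
    H <- H0 / C
    p <- stats::pchisq(H, df = nlevels(s$g) - 1, lower.tail = FALSE)
  }
  structure(
    list(H = H, p = p, df = nlevels(s$g) - 1, tie_corrected = s$has_ties,
         n = N, groups = levels(s$g)),
    class = "kw_test"
  )
}

.pairs_of <- function(levels) {
  k <- length(levels)
  do.call(rbind, lapply(seq_len(k - 1), function(i) {
    data.frame(group_a = levels[i], group_b = levels[(i + 1):k],
               stringsAsFactors = FALSE)
  }))
}

#' Conover-Iman post-hoc comparisons after Kruskal-Wallis
#'
#' Pairwise t statistics on mean ranks with the pooled rank variance
#' \eqn{S^2 = (\sum R_i^2 - N(N+1)^2/4)/(N-1)}:
#' \deqn{t_{ab} = \frac{\bar R_a - \bar R_b}
#'   {\sqrt{S^2 \frac{N-1-H}{N-k}\left(\frac{1}{n_a}+\frac{1}{n_b}\right)}},}
#' with H the tie-corrected Kruskal-Wallis statistic, two-sided p from
#' Student t on N-k degrees of freedom, and a Benjamini-Hochberg column
#' over all pairs.
#'
#' @param values,groups as in [kruskal_wallis()].
#' @param kw optional precomputed [kruskal_wallis()] result on the same
#'   data (recomputed if NULL).
#' @return data.frame: `group_a`, `group_b`, `statistic`, `p_raw`, `p_bh`.
#' @export
conover_posthoc <- function(values, groups, kw = NULL) {
  s <- .rank_setup(values, groups)
  N <- s$N
  k <- nlevels(s$g)
  if (N - k <= 0) stop("insufficient residual degrees of freedom")
  if (is.null(kw)) kw <- kruskal_wallis(values, groups)
  H <- kw$H
  S2 <- (sum(s$r^2) - N * (N + 1)^2 / 4) / (N - 1)
  rbar <- tapply(s$r, s$g, mean)
  ni <- tabulate(s$g)
  pairs <- .pairs_of(levels(s$g))
  ia <- match(pairs$group_a, levels(s$g))
  ib <- match(pairs$group_b, levels(s$g))
  if (S2 == 0) {
    # every value identical: all mean ranks equal, no contrast
    tstat <- rep(0, nrow(pairs))
  } else {
    se <- sqrt(S2 * ((N - 1 - H) / (N - k)) * (1 / ni[ia] + 1 / ni[ib]))
    tstat <- (rbar[ia] - rbar[ib]) / se
  }
  p_raw <- 2 * stats::pt(abs(tstat), df = N - k, lower.tail = FALSE)
  data.frame(pairs, statistic = unname(tstat), p_raw = unname(p_raw),
             p_bh = bh_adjust(unname(p_raw)), stringsAsFactors = FALSE)
}

#' Dunn post-hoc comparisons after Kruskal-Wallis
#'
#' Pairwise z statistics on mean ranks with the tie-corrected null
#' variance,
#' \deqn{z_{ab} = \frac{\bar R_a - \bar R_b}
#'   {\sqrt{\left(\frac{N(N+1)}{12} - \frac{\sum(t^3-t)}{12(N-1)}\right)
#'   \left(\frac{1}{n_a}+\frac{1}{n_b}\right)}},}
#' two-sided normal p-values and a Benjamini-Hochberg column. Used for
#' endpoints with small group sizes where the Conover t refinement has
#' little support.
#'
#' @param values,groups as in [kruskal_wallis()].
#' @return data.frame: `group_a`, `group_b`, `statistic`, `p_raw`, `p_bh`.
#' @export
dunn_posthoc <- function(values, groups) {
  s <- .rank_setup(values, groups)
  N <- s$N
  rbar <- tapply(s$r, s$g, mean)
  ni <- tabulate(s$g)
  v <- N * (N + 1) / 12 - s$tie_sum / (12 * (N - 1))
  pairs <- .pairs_of(levels(s$g))
  ia <- match(pairs$group_a, levels(s$g))
  ib <- match(pairs$group_b, levels(s$g))
  if (v <= 0) {
    z <- rep(0, nrow(pairs))
  } else {
    z <- (rbar[ia] - rbar[ib]) / sqrt(v * (1 / ni[ia] + 1 / ni[ib]))
  }
  p_raw <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  data.frame(pairs, statistic = unname(z), p_raw = unname(p_raw),
             p_bh = bh_adjust(unname(p_raw)), stringsAsFactors = FALSE)
}
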