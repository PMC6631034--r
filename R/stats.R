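## The assay's statistical battery.  These are deliberately self-contained
## implementations (the package's analysis layer), cross-checked in the
## test suite against independent oracles and, where one exists, against
## the corresponding base-R routine.

omrTest <- function(method, statistic, df = NULL, p.value, n,
                    flags = character(), data.name = "data") {
  out <- list(statistic = statistic, p.value = p.value, n = n,
              method = method, data.name = data.name, flags = flags)
  if (!is.null(df)) out$parameter <- c(df = df)
  stopifnot(is.na(p.value) || (p.value >= 0 && p.value <= 1 + 1e-12))
  out$p.value <- min(out$p.value, 1)
  class(out) <- c("omrTest", "htest")
  out
}

#' Bowker's test of symmetry
#'
#' Tests whether a square transition table (initial vs final area) is
#' symmetric: under the null of no systematic positional shift,
#' n_ij and n_ji are exchangeable for every pair i < j.  The statistic is
#' `sum over i<j of (n_ij - n_ji)^2 / (n_ij + n_ji)` restricted to
#' informative pairs (n_ij + n_ji > 0), with one df per informative pair,
#' referred to the upper chi-square tail.  On a 2 x 2 table it reduces to
#' McNemar's test (without continuity correction).
#'
#' With `exact = TRUE` the conditional exact p-value is computed instead:
#' given each pair total m = n_ij + n_ji, n_ij is Binomial(m, 1/2) under
#' symmetry, independently across pairs; the null distribution of the
#' statistic is enumerated by convolution and the p-value is
#' P(T >= observed).
#'
#' @param table square contingency matrix of counts (initial in rows,
#'   final in columns), e.g. from [transitionTable()].
#' @param exact logical: compute the exact conditional p-value.
#' @return an object of class `omrTest`/`htest` with `statistic`,
#'   `parameter` (df), `p.value`, `n`, and a `no_movement` flag when every
#'   off-diagonal pair is empty (then p = 1, df = 0).
#' @export
bowkerTest <- function(table, exact = FALSE) {
  table <- as.matrix(table)
  if (nrow(table) != ncol(table))
    stop("table must be square")
  if (any(table < 0) || any(table != round(table)))
    stop("table must contain non-negative integer counts")
  k <- nrow(table)
  pairs <- which(upper.tri(table), arr.ind = TRUE)
  a <- table[pairs]                       # n_ij, i < j
  b <- t(table)[pairs]                    # n_ji
  m <- a + b
  keep <- m > 0
  if (!any(keep)) {
    return(omrTest("Bowker's test of symmetry", c(`chi-squared` = 0),
                   df = 0L, p.value = 1, n = sum(table),
                   flags = "no_movement"))
  }
  stat <- sum((a[keep] - b[keep])^2 / m[keep])
  df <- sum(keep)
  if (!exact) {
    p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
    meth <- "Bowker's test of symmetry"
  } else {
    ## convolve the per-pair statistic distributions
    dist <- data.frame(t = 0, p = 1)
    for (mi in m[keep]) {
      kk <- 0:mi
      contrib <- (2 * kk - mi)^2 / mi
      pr <- stats::dbinom(kk, mi, 0.5)
      g <- expand.grid(i = seq_len(nrow(dist)), j = seq_along(kk))
      t2 <- dist$t[g$i] + contrib[g$j]
      p2 <- dist$p[g$i] * pr[g$j]
      agg <- rowsum(p2, group = round(t2, 10))
      dist <- data.frame(t = as.numeric(rownames(agg)), p = agg[, 1])
    }
    p <- sum(dist$p[dist$t >= stat - 1e-9])
    meth <- "Bowker's test of symmetry (exact conditional)"
  }
  omrTest(meth, c(`chi-squared` = stat), df = df, p.value = p,
          n = sum(table))
}

#' Two-sided exact binomial test of improvement
#'
#' Tests whether larvae that changed area were equally likely to improve
#' or decrease alignment.  Larvae with no change are excluded by design;
#' under the null, the number improved among the n that moved is
#' Binomial(n, 1/2).  The default two-sided p-value is the
#' minimum-likelihood convention (the sum of all outcome probabilities no
#' larger than the observed one); `method = "double"` doubles the smaller
#' one-sided tail instead (capped at 1).
#'
#' @param nImproved,nDecreased counts of larvae with positive / negative
#'   change scores.
#' @param method `"minlik"` (default) or `"double"`.
#' @return an `omrTest`/`htest`; with n = 0 the p-value is 1 and a
#'   `degenerate` flag is set.
#' @export
exactBinomialImprovement <- function(nImproved, nDecreased,
                                     method = c("minlik", "double")) {
  method <- match.arg(method)
  stopifnot(nImproved >= 0, nDecreased >= 0,
            nImproved == round(nImproved), nDecreased == round(nDecreased))
  n <- nImproved + nDecreased
  if (n == 0)
    return(omrTest("Exact binomial test of improvement",
                   c(`n improved` = 0), p.value = 1, n = 0,
                   flags = "degenerate"))
  pmf <- stats::dbinom(0:n, n, 0.5)
  if (method == "minlik") {
    p <- sum(pmf[pmf <= pmf[nImproved + 1] * (1 + 1e-7)])
  } else {
    p <- min(1, 2 * min(sum(pmf[seq_len(nImproved + 1)]),
                        sum(pmf[(nImproved + 1):(n + 1)])))
  }
  omrTest("Exact binomial test of improvement",
          c(`n improved` = nImproved), p.value = p, n = n)
}

## exact permutation two-sided p for the Mann-Whitney U (ties allowed):
## enumerate all assignments of the pooled values to group a
mwPermutationP <- function(x, y) {
  na <- length(x); nb <- length(y)
  pooled <- c(x, y)
  rk <- rank(pooled)           # midranks
  mu <- na * nb / 2
  combs <- utils::combn(na + nb, na)
  ua <- colSums(matrix(rk[combs], nrow = na)) - na * (na + 1) / 2
  uobs <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  mean(abs(ua - mu) >= abs(uobs - mu) - 1e-9)
}

#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' Two-sided test that two samples come from the same distribution,
#' suited to the assay's ordinal scores (final positions, change scores,
#' startle counts) where ties are heavy.  U is computed from midranks.
#' When the full permutation enumeration is affordable
#' (`choose(na + nb, na) <= maxEnum`) the exact two-sided permutation
#' p-value `P(|U - mean| >= |observed - mean|)` is used, ties included;
#' otherwise the normal approximation with midrank tie correction and a
#' 0.5 continuity correction.
#'
#' @param x,y numeric samples (non-empty).
#' @param exact force (`TRUE`) or forbid (`FALSE`) the enumeration path;
#'   default `NULL` chooses by `maxEnum`.
#' @param maxEnum largest enumeration size attempted.
#' @return an `omrTest`/`htest` with the U statistic (for sample `x`).
#' @export
mannWhitneyTest <- function(x, y, exact = NULL, maxEnum = 2e5) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  na <- length(x); nb <- length(y)
  rk <- rank(c(x, y))
  u <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  doExact <- if (is.null(exact)) choose(na + nb, na) <= maxEnum else exact
  if (doExact) {
    if (choose(na + nb, na) > 5e6)
      stop("exact enumeration infeasible for these sample sizes")
    p <- mwPermutationP(x, y)
    meth <- "Wilcoxon-Mann-Whitney test (exact permutation)"
  } else {
    nt <- na + nb
    mu <- na * nb / 2
    tie <- table(c(x, y))
    sig2 <- na * nb / 12 * (nt + 1 - sum(tie^3 - tie) / (nt * (nt - 1)))
    if (sig2 <= 0) {          # all values identical across both groups
      return(omrTest("Wilcoxon-Mann-Whitney test", c(U = u),
                     p.value = 1, n = nt, flags = "no_variance"))
    }
    z <- (abs(u - mu) - 0.5) / sqrt(sig2)
    z <- max(z, 0)
    p <- 2 * stats::pnorm(z, lower.tail = FALSE)
    meth <- "Wilcoxon-Mann-Whitney test (normal approximation)"
  }
  omrTest(meth, c(U = u), p.value = min(1, p), n = na + nb)
}

#' One-way analysis of variance
#'
#' Ordinary fixed-effects one-way ANOVA for comparing startle-response
#' scores (or any numeric read-out) across k groups: F with (k - 1, N - k)
#' degrees of freedom from the between/within mean squares, upper-tail
#' F p-value.
#'
#' @param groups list of numeric vectors, each of length >= 2.
#' @return an `omrTest`/`htest`; when every group is the same constant the
#'   `no_variance` flag is set and p = 1.
#' @export
oneWayAnovaTest <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(vapply(groups, length, 1L) < 2))
    stop("each group must have at least 2 observations")
  k <- length(groups)
  ns <- vapply(groups, length, 1L)
  N <- sum(ns)
  means <- vapply(groups, mean, 1)
  grand <- sum(unlist(groups)) / N
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  if (ssw <= 0 && ssb <= 0)
    return(omrTest("One-way ANOVA", c(F = NA_real_), df = k - 1L,
                   p.value = 1, n = N, flags = "no_variance"))
  if (ssw <= 0) {             # perfectly separated constants
    return(omrTest("One-way ANOVA", c(F = Inf), df = k - 1L,
                   p.value = 0, n = N, flags = "zero_within_variance"))
  }
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  p <- stats::pf(f, k - 1, N - k, lower.tail = FALSE)
  out <- omrTest("One-way ANOVA", c(F = f), df = k - 1L, p.value = p, n = N)
  out$parameter <- c(df1 = k - 1L, df2 = N - k)
  out
}

#' Run the assay's statistical battery on trial records
#'
#' Convenience wrapper producing the standard analyses for one cohort:
#' Bowker's symmetry test on the 4 x 4 transition table (population
#' analysis) and the two-sided exact binomial improvement test on the
#' change-score signs (post-stimulus analysis); optionally a
#' Wilcoxon-Mann-Whitney test of final positions against a comparison
#' cohort.
#'
#' @param records trial-record data.frame.
#' @param reference optional second cohort's records for the
#'   Mann-Whitney comparison of final positions.
#' @param bonferroni logical: Bonferroni-adjust the p-values across the
#'   battery (off by default; the standard analysis reports unadjusted
#'   p-values).
#' @return named list of `omrTest` objects.
#' @export
analyzeTrial <- function(records, reference = NULL, bonferroni = FALSE) {
  out <- list(
    bowker = bowkerTest(transitionTable(records)),
    binomial = exactBinomialImprovement(sum(records$change_score > 0),
                                        sum(records$change_score < 0))
  )
  if (!is.null(reference))
    out$mann_whitney <- mannWhitneyTest(records$final_area,
                                        reference$final_area)
  if (bonferroni) {
    k <- length(out)
    for (nm in names(out)) out[[nm]]$p.value <- min(1, out[[nm]]$p.value * k)
  }
  out
}
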