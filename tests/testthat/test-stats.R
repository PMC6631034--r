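test_that("symmetric tables give a zero Bowker statistic and p = 1", {
  tab <- matrix(c(4, 2, 1, 0,
                  2, 5, 3, 1,
                  1, 3, 6, 2,
                  0, 1, 2, 7), 4, 4, byrow = TRUE)
  res <- bowkerTest(tab)
  expect_equal(unname(res$statistic), 0)
  expect_equal(res$p.value, 1)
})

test_that("Bowker reduces to McNemar on a 2x2 table", {
  tab <- matrix(c(0, 5, 1, 0), 2, 2, byrow = TRUE)    # n12 = 5, n21 = 1
  res <- bowkerTest(tab)
  expect_equal(unname(res$statistic), (5 - 1)^2 / 6, tolerance = 1e-12)
  expect_equal(res$p.value,
               pchisq((5 - 1)^2 / 6, 1, lower.tail = FALSE))
})

test_that("Bowker agrees with the base-R k-sample McNemar generalisation", {
  set.seed(5)
  tab <- matrix(rpois(16, 8), 4, 4)
  res <- bowkerTest(tab)
  ref <- stats::mcnemar.test(tab, correct = FALSE)
  expect_equal(unname(res$statistic), unname(ref$statistic))
  expect_equal(res$p.value, ref$p.value)
  expect_equal(unname(res$parameter["df"]), 6)
})

test_that("df counts only informative off-diagonal pairs", {
  tab <- matrix(0L, 4, 4); diag(tab) <- 5L
  tab[1, 2] <- 3L; tab[2, 1] <- 1L
  res <- bowkerTest(tab)
  expect_equal(unname(res$parameter["df"]), 1)
  allDiag <- diag(c(3L, 4L, 5L, 6L))
  res0 <- bowkerTest(allDiag)
  expect_equal(res0$p.value, 1)
  expect_identical(res0$flags, "no_movement")
})

test_that("Bowker statistic grows as mass moves from symmetric to asymmetric", {
  stats <- vapply(0:5, function(k) {
    tab <- matrix(0L, 4, 4)
    tab[1, 3] <- 5L + k; tab[3, 1] <- 5L - k
    unname(bowkerTest(tab)$statistic)
  }, numeric(1))
  expect_true(all(diff(stats) > 0))
})

test_that("Bowker is invariant under table transposition", {
  set.seed(6)
  tab <- matrix(rpois(16, 3), 4, 4)
  expect_equal(bowkerTest(tab)$statistic, bowkerTest(t(tab))$statistic)
})

test_that("the exact conditional Bowker p matches a simulation oracle", {
  tab <- matrix(c(3, 4, 1, 2,
                  1, 2, 3, 0,
                  0, 1, 1, 1,
                  0, 0, 1, 0), 4, 4)
  pe <- bowkerTest(tab, exact = TRUE)$p.value
  ## oracle: resample each discordant pair as Binomial(m, 1/2)
  a <- tab[upper.tri(tab)]; b <- t(tab)[upper.tri(tab)]
  m <- a + b
  obs <- sum(((a - b)^2 / m)[m > 0])
  set.seed(6)
  sims <- replicate(2e5, {
    k <- rbinom(length(m), m, 0.5)
    sum((((2 * k - m)^2) / m)[m > 0])
  })
  expect_equal(pe, mean(sims >= obs - 1e-9), tolerance = 0.01)
})

test_that("chi-square and exact Bowker p-values converge for large counts", {
  set.seed(7)
  tab <- matrix(rpois(16, 12), 4, 4)
  expect_equal(bowkerTest(tab)$p.value, bowkerTest(tab, exact = TRUE)$p.value,
               tolerance = 0.05)
})

test_that("the exact binomial test matches full pmf enumeration up to n = 12", {
  for (n in 1:12) {
    pmf <- choose(n, 0:n) * 0.5^n      # independent enumeration
    for (k in 0:n) {
      expected <- sum(pmf[pmf <= pmf[k + 1] + 1e-12])
      got <- exactBinomialImprovement(k, n - k)$p.value
      expect_equal(got, expected, tolerance = 1e-12)
      ## symmetry p(k, n-k) = p(n-k, k)
      expect_equal(got, exactBinomialImprovement(n - k, k)$p.value)
      ## agrees with the base-R exact binomial test
      expect_equal(got, binom.test(k, n, 0.5)$p.value, tolerance = 1e-12)
    }
  }
})

test_that("binomial edge cases: balance, one-sided extremes, empty", {
  expect_equal(exactBinomialImprovement(5, 5)$p.value, 1)
  expect_equal(exactBinomialImprovement(8, 0)$p.value, 2 * 0.5^8)
  res0 <- exactBinomialImprovement(0, 0)
  expect_equal(res0$p.value, 1)
  expect_identical(res0$flags, "degenerate")
  ## tail-doubling option never undercuts the one-sided tail
  expect_equal(exactBinomialImprovement(8, 0, method = "double")$p.value,
               2 * 0.5^8)
})

test_that("Mann-Whitney enumerates exactly on small samples", {
  res <- mannWhitneyTest(c(4, 4, 3), c(1, 1, 2))
  expect_equal(unname(res$statistic), 9)     # all 9 pairwise wins
  expect_equal(res$p.value, 2 / 20)          # 2 of C(6,3) arrangements
})

test_that("identical groups give U = n1*n2/2 and p = 1", {
  x <- rep(c(1, 2, 3), 6)
  res <- mannWhitneyTest(x, x, exact = FALSE)
  expect_equal(unname(res$statistic), length(x)^2 / 2)
  expect_equal(res$p.value, 1)
  cst <- mannWhitneyTest(rep(2, 15), rep(2, 18), exact = FALSE)
  expect_equal(cst$p.value, 1)
  expect_identical(cst$flags, "no_variance")
})

test_that("the tie-corrected approximation tracks a permutation oracle", {
  set.seed(2)
  a <- sample(1:4, 20, replace = TRUE, prob = c(.2, .2, .3, .3))
  b <- sample(1:4, 20, replace = TRUE, prob = c(.5, .2, .2, .1))
  papprox <- mannWhitneyTest(a, b, exact = FALSE)$p.value
  rk <- rank(c(a, b)); mu <- 200
  uobs <- sum(rk[1:20]) - 210
  set.seed(3)
  perm <- replicate(1e5, {
    s <- sample(40, 20)
    abs(sum(rk[s]) - 210 - mu) >= abs(uobs - mu) - 1e-9
  })
  expect_equal(papprox, mean(perm), tolerance = 0.01)
  ## and reproduces the base-R continuity-corrected approximation exactly
  ref <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
  expect_equal(papprox, ref$p.value, tolerance = 1e-12)
})

test_that("one-way ANOVA matches the base-R fit and the t-test identity", {
  set.seed(8)
  g <- list(rnorm(10), rnorm(10) + 0.8, rnorm(12) - 0.3)
  res <- oneWayAnovaTest(g)
  y <- unlist(g); f <- factor(rep(seq_along(g), lengths(g)))
  ref <- summary(stats::aov(y ~ f))[[1]]
  expect_equal(unname(res$statistic), ref[1, "F value"], tolerance = 1e-10)
  expect_equal(res$p.value, ref[1, "Pr(>F)"], tolerance = 1e-10)
  ## two groups: F equals the square of the pooled t statistic
  t2 <- stats::t.test(g[[1]], g[[2]], var.equal = TRUE)$statistic^2
  expect_equal(unname(oneWayAnovaTest(g[1:2])$statistic), unname(t2),
               tolerance = 1e-10)
})

test_that("degenerate ANOVA inputs are flagged, not divided by zero", {
  same <- oneWayAnovaTest(list(rep(2, 5), rep(2, 6)))
  expect_equal(same$p.value, 1)
  expect_identical(same$flags, "no_variance")
  sep <- oneWayAnovaTest(list(rep(1, 5), rep(2, 5)))
  expect_identical(sep$flags, "zero_within_variance")
  expect_equal(sep$p.value, 0)
  expect_error(oneWayAnovaTest(list(1, c(2, 3))), "at least 2")
})

test_that("ANOVA holds its nominal size under the null", {
  set.seed(3)
  rej <- mean(replicate(1e4, oneWayAnovaTest(
    list(rnorm(10), rnorm(10), rnorm(10)))$p.value < 0.05))
  expect_gt(rej, 0.04)
  expect_lt(rej, 0.06)
})

test_that("all battery p-values stay in [0, 1] on random inputs", {
  set.seed(9)
  for (i in 1:25) {
    tab <- matrix(rpois(16, sample(1:6, 1)), 4, 4)
    p1 <- bowkerTest(tab)$p.value
    p2 <- exactBinomialImprovement(rpois(1, 5), rpois(1, 5))$p.value
    p3 <- mannWhitneyTest(sample(1:4, 8, TRUE), sample(1:4, 9, TRUE))$p.value
    expect_true(all(c(p1, p2, p3) >= 0 & c(p1, p2, p3) <= 1))
  }
})

test_that("the battery wrapper reports the standard analyses", {
  set.seed(10)
  tr <- runTrial(phenotypePreset("control"), 48, defaultGeom,
                 timeline = c(0, 30), seed = 30)
  ref <- runTrial(phenotypePreset("mbl"), 48, defaultGeom,
                  timeline = c(0, 30), seed = 31)
  out <- analyzeTrial(tr$records, reference = ref$records)
  expect_named(out, c("bowker", "binomial", "mann_whitney"))
  expect_s3_class(out$bowker, "htest")
  ## a responsive cohort shifts significantly
  expect_lt(out$bowker$p.value, 0.05)
  expect_lt(out$binomial$p.value, 0.05)
  ## Bonferroni option scales p-values
  adj <- analyzeTrial(tr$records, reference = ref$records, bonferroni = TRUE)
  expect_equal(adj$binomial$p.value,
               min(1, out$binomial$p.value * 3))
})

test_that("the battery holds its size on simulated non-responsive cohorts", {
  set.seed(55)
  ncoh <- 2000; nper <- 48
  tr <- runTrial(phenotypePreset("mbl"), ncoh * nper, defaultGeom,
                 timeline = c(0, 30), dt = 0.25)
  fa <- matrix(tr$records$final_area, nrow = nper)
  sgn <- matrix(tr$records$change_score, nrow = nper)
  ## Mann-Whitney across independent null cohort pairs
  pmw <- vapply(seq_len(ncoh / 2), function(k)
    mannWhitneyTest(fa[, 2 * k - 1], fa[, 2 * k])$p.value, numeric(1))
  expect_gt(mean(pmw < 0.05), 0.03)
  expect_lt(mean(pmw < 0.05), 0.07)
  ## the exact binomial never exceeds its nominal level
  pbin <- vapply(seq_len(ncoh), function(k)
    exactBinomialImprovement(sum(sgn[, k] > 0),
                             sum(sgn[, k] < 0))$p.value, numeric(1))
  expect_lte(mean(pbin < 0.05), 0.05)
})
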