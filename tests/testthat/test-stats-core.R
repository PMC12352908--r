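test_that("Fisher 2x2 matches enumeration and the frozen small example", {
  expect_equal(fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2))$p.value, 1 / 3,
               tolerance = 1e-12)
  # zero margin: only one possible table
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2))$p.value, 1)
  expect_error(fisher_exact_2x2(matrix(c(-1, 0, 0, 2), 2)), "negative")

  withr::with_seed(42, {
    for (i in 1:40) {
      tab <- matrix(rpois(4, 4), 2)
      p <- fisher_exact_2x2(tab)$p.value
      expect_equal(p, fisher_enum_oracle(tab), tolerance = 1e-12)
      # cross-check against the reference implementation
      expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-9)
    }
  })
})

test_that("one-sided Fisher tails are hypergeometric tails", {
  tab <- matrix(c(1, 9, 11, 3), 2)
  expect_equal(fisher_exact_2x2(tab, "less")$p.value,
               stats::fisher.test(tab, alternative = "less")$p.value,
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(tab, "greater")$p.value,
               stats::fisher.test(tab, alternative = "greater")$p.value,
               tolerance = 1e-12)
})

test_that("chi-square GOF statistic, df and limiting behavior", {
  res <- chi_square_gof(c(50, 50), c(0.5, 0.5))
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 1)

  res2 <- chi_square_gof(c(75, 25), c(0.5, 0.5))
  expect_equal(res2$statistic, 25)
  expect_equal(res2$df, 1)

  expect_error(chi_square_gof(c(1, 2), c(0.5, 0.4)), "sum to 1")
  expect_error(chi_square_gof(c(1, 2), c(1, 0)), "zero expected")

  # k = 2 equivalence with the two-sided normal approximation of the binomial
  n <- 10000; k <- 5100
  chi_p <- chi_square_gof(c(k, n - k), c(0.5, 0.5))$p.value
  z <- (k - n / 2) / sqrt(n / 4)
  norm_p <- 2 * pnorm(-abs(z))
  expect_equal(chi_p, norm_p, tolerance = 1e-3)
})

test_that("Wilcoxon rank-sum exact path equals full enumeration", {
  res <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p.value, 0.1, tolerance = 1e-12)

  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p.value, 1)
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "empty")

  withr::with_seed(7, {
    for (i in 1:20) {
      nx <- sample(2:6, 1); ny <- sample(2:6, 1)
      x <- rnorm(nx); y <- rnorm(ny)
      p <- wilcoxon_rank_sum(x, y)$p.value
      expect_equal(p, wilcoxon_enum_oracle(x, y), tolerance = 1e-12)
      expect_equal(p, stats::wilcox.test(x, y, exact = TRUE)$p.value,
                   tolerance = 1e-9)
    }
  })
})

test_that("the normal-approximation Wilcoxon path agrees with wilcox.test", {
  withr::with_seed(8, {
    x <- rnorm(30); y <- rnorm(25) + 0.4
    expect_equal(wilcoxon_rank_sum(x, y)$p.value,
                 stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value,
                 tolerance = 1e-9)
    # with ties
    xt <- round(rnorm(25), 1); yt <- round(rnorm(25), 1)
    expect_equal(wilcoxon_rank_sum(xt, yt)$p.value,
                 stats::wilcox.test(xt, yt, exact = FALSE, correct = TRUE)$p.value,
                 tolerance = 1e-9)
  })
})

test_that("BH and Holm adjustments match the step formulas", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  expect_equal(adjust_pvalues(c(0.01, 0.04), "holm"), c(0.02, 0.04))
  expect_equal(adjust_pvalues(0.37, "BH"), 0.37)
  expect_error(adjust_pvalues(c(0.5, 1.2), "BH"), "\\[0, 1\\]")

  withr::with_seed(9, {
    p <- runif(50)
    expect_equal(adjust_pvalues(p, "BH"), p.adjust(p, "BH"),
                 tolerance = 1e-12)
    expect_equal(adjust_pvalues(p, "holm"), p.adjust(p, "holm"),
                 tolerance = 1e-12)
  })
})

test_that("Poisson-binomial pmf/cdf equal closed forms and enumeration", {
  expect_equal(poisson_binomial_cdf(c(0.5, 0.5), 2)$upper, 0.25)

  # equal probabilities collapse to the binomial
  p <- 0.3; n <- 15
  f <- poisson_binomial_pmf(rep(p, n))
  expect_equal(f, dbinom(0:n, n, p), tolerance = 1e-12)

  withr::with_seed(10, {
    for (i in 1:10) {
      probs <- runif(sample(3:10, 1))
      k <- sample(0:length(probs), 1)
      got <- poisson_binomial_cdf(probs, k)
      want <- poisbin_enum_oracle(probs, k)
      expect_equal(got$lower, want$lower, tolerance = 1e-12)
      expect_equal(got$upper, want$upper, tolerance = 1e-12)
      # tail consistency: P(X <= k) + P(X >= k + 1) = 1
      f <- poisson_binomial_pmf(probs)
      upper_next <- if (k < length(probs))
        sum(f[(k + 2):(length(probs) + 1)]) else 0
      expect_equal(got$lower + upper_next, 1, tolerance = 1e-12)
    }
  })
  expect_error(poisson_binomial_pmf(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("null rejection rates are calibrated near the nominal level", {
  n_rep <- 4000
  withr::with_seed(123, {
    # Wilcoxon exact path, n = 10 + 10
    rej_w <- mean(replicate(n_rep,
      wilcoxon_rank_sum(rnorm(10), rnorm(10))$p.value <= 0.05))
    expect_gte(rej_w, 0.03); expect_lte(rej_w, 0.07)
    # chi-square GOF with 3 balanced cells
    rej_c <- mean(replicate(n_rep, {
      o <- tabulate(sample.int(3, 120, TRUE), 3)
      chi_square_gof(o, rep(1 / 3, 3))$p.value <= 0.05
    }))
    expect_gte(rej_c, 0.03); expect_lte(rej_c, 0.07)
  })
})
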