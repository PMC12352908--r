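#' Test-result container
#'
#' Light S3 container for the package's statistical tests. All p values
#' are two-sided unless the method label says otherwise.
#'
#' @param statistic Test statistic.
#' @param df Degrees of freedom (or NA).
#' @param p Two-sided p value in \[0, 1\].
#' @param method Label of the test.
#' @return List of class `cs_test`.
#' @export
cs_test <- function(statistic, df, p, method) {
  structure(list(statistic = unname(statistic), df = unname(df),
                 p.value = min(max(unname(p), 0), 1), method = method),
            class = "cs_test")
}

#' @export
print.cs_test <- function(x, ...) {
  cat(x$method, ": statistic = ", format(x$statistic),
      if (!is.na(x$df)) paste0(", df = ", format(x$df)),
      ", p = ", format(x$p.value), "\n", sep = "")
  invisible(x)
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact conditional test given fixed margins. The two-sided p value is
#' the probability-mass rule: the sum of hypergeometric probabilities of
#' all tables no more probable than the observed one, with a relative
#' tolerance of 1e-7 guarding floating-point ties.
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @param alternative `"two.sided"` (default), or the one-sided tails
#'   `"less"` / `"greater"` on the top-left cell.
#' @return A [cs_test()] (df is NA; statistic is the observed top-left
#'   cell count).
#' @export
fisher_exact_2x2 <- function(table, alternative = c("two.sided", "less",
                                                    "greater")) {
  alternative <- match.arg(alternative)
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(table < 0) || any(!is.finite(table))) stop("negative or non-finite counts")
  a <- table[1, 1]
  m <- sum(table[1, ]); n <- sum(table[2, ]); k <- sum(table[, 1])
  p <- switch(alternative,
    two.sided = {
      support <- max(0, k - n):min(k, m)
      probs <- stats::dhyper(support, m, n, k)
      p_obs <- stats::dhyper(a, m, n, k)
      sum(probs[probs <= p_obs * (1 + 1e-7)])
    },
    less = stats::phyper(a, m, n, k),
    greater = stats::phyper(a - 1, m, n, k, lower.tail = FALSE))
  cs_test(a, NA_real_, p, paste0("Fisher's exact test (", alternative, ")"))
}

#' Chi-square goodness-of-fit test
#'
#' Pearson's statistic against stated expected proportions; upper-tail
#' p on k-1 degrees of freedom.
#'
#' @param observed Vector of nonnegative counts.
#' @param expected_proportions Vector summing to 1, all > 0.
#' @return A [cs_test()].
#' @export
chi_square_gof <- function(observed, expected_proportions) {
  if (length(observed) != length(expected_proportions))
    stop("length mismatch")
  if (abs(sum(expected_proportions) - 1) > 1e-8)
    stop("expected proportions must sum to 1")
  if (any(expected_proportions <= 0)) stop("zero expected cell")
  n <- sum(observed)
  if (n <= 0) stop("observed sum must be positive")
  E <- n * expected_proportions
  stat <- sum((observed - E)^2 / E)
  df <- length(observed) - 1
  cs_test(stat, df, stats::pchisq(stat, df, lower.tail = FALSE),
          "Chi-square goodness-of-fit test")
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact null distribution of the Mann-Whitney U statistic (computed by
#' the count-recursion over rank assignments) when the combined sample
#' size is at most `exact_limit` and there are no ties; otherwise the
#' normal approximation with tie correction and continuity correction.
#'
#' @param x,y Numeric samples (each nonempty).
#' @param exact_limit Combined-size threshold for the exact path.
#' @return A [cs_test()] whose statistic is U for `x`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_limit = 20L) {
  if (!length(x) || !length(y)) stop("empty group")
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  if (!ties && nx + ny <= exact_limit) {
    counts <- mann_whitney_counts(nx, ny)      # counts of U = 0..nx*ny
    total <- sum(counts)
    pl <- sum(counts[seq_len(U + 1)]) / total          # P(U <= u)
    pu <- sum(counts[(U + 1):length(counts)]) / total  # P(U >= u)
    p <- min(1, 2 * min(pl, pu))
    method <- "Wilcoxon rank-sum test (exact)"
  } else {
    mu <- nx * ny / 2
    tie_tab <- table(c(x, y))
    sigma2 <- nx * ny / 12 *
      (nx + ny + 1 - sum(tie_tab^3 - tie_tab) / ((nx + ny) * (nx + ny - 1)))
    z <- U - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)     # continuity correction
    p <- 2 * stats::pnorm(-abs(z))
    method <- "Wilcoxon rank-sum test (normal approximation)"
  }
  cs_test(U, NA_real_, p, method)
}

# Number of rank assignments giving each U value 0..m*n: the classic
# recursion c(u; m, n) = c(u - n; m - 1, n) + c(u; m, n - 1), memoized;
# full tables are cached per (m, n) for repeated calls.
.mw_cache <- new.env(parent = emptyenv())

mann_whitney_counts <- function(m, n) {
  key <- paste(m, n, sep = "x")
  hit <- .mw_cache[[key]]
  if (!is.null(hit)) return(hit)
  memo <- new.env(parent = emptyenv())
  cw <- function(u, m, n) {
    if (u < 0 || u > m * n) return(0)
    if (m == 0 || n == 0) return(as.numeric(u == 0))
    k <- paste(u, m, n)
    v <- memo[[k]]
    if (is.null(v)) {
      v <- cw(u - n, m - 1, n) + cw(u, m, n - 1)
      memo[[k]] <- v
    }
    v
  }
  out <- vapply(0:(m * n), cw, numeric(1), m = m, n = n)
  .mw_cache[[key]] <- out
  out
}

#' Multiple-testing adjustment (Benjamini-Hochberg or Holm)
#'
#' Standard step-up (BH) or step-down (Holm) adjusted p values with
#' monotonicity enforced and capping at 1, returned in the input order.
#'
#' @param pvals Vector of p values in \[0, 1\].
#' @param method `"BH"` or `"holm"`.
#' @return Adjusted p values, same length and order as the input.
#' @export
adjust_pvalues <- function(pvals, method = c("BH", "holm")) {
  method <- match.arg(method)
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p values must lie in [0, 1]")
  n <- length(pvals)
  if (n <= 1L) return(pvals)
  if (method == "BH") {
    o <- order(pvals, decreasing = TRUE)
    adj <- pmin(1, cummin(n / (n:1) * pvals[o]))
    out <- numeric(n); out[o] <- adj
  } else {
    o <- order(pvals)
    adj <- pmin(1, cummax((n - seq_len(n) + 1) * pvals[o]))
    out <- numeric(n); out[o] <- adj
  }
  out
}

#' Poisson-binomial distribution by exact convolution
#'
#' Distribution of the number of successes among independent Bernoulli
#' trials with heterogeneous probabilities; the overlap-count null of
#' the margin-aware mutual-exclusivity test. The pmf is built by exact
#' dynamic-programming convolution, so both tails are consistent:
#' P(X <= k) + P(X >= k+1) = 1 to floating-point accuracy.
#'
#' @param probs Vector of success probabilities in \[0, 1\].
#' @param k Count at which to evaluate the tails.
#' @return `poisson_binomial_pmf` returns the full pmf over 0..n;
#'   `poisson_binomial_cdf` returns a list with `lower` = P(X <= k) and
#'   `upper` = P(X >= k).
#' @export
poisson_binomial_pmf <- function(probs) {
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  f <- 1
  for (p in probs)
    f <- c(f * (1 - p), 0) + c(0, f * p)
  f
}

#' @rdname poisson_binomial_pmf
#' @export
poisson_binomial_cdf <- function(probs, k) {
  f <- poisson_binomial_pmf(probs)
  n <- length(probs)
  k <- min(max(k, 0), n)
  list(lower = sum(f[seq_len(k + 1)]), upper = sum(f[(k + 1):(n + 1)]))
}
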