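# Independent brute-force oracles used to validate the package's own
# implementations. These deliberately use naive enumeration / plain
# dynamic programming, not the code paths they check.

# Plain affine-gap Needleman-Wunsch, score only. Gap of length k costs
# open + k * extend.
nw_affine_score <- function(read, ref, match = 2, mismatch = -2,
                            open = 6, extend = 1) {
  a <- strsplit(read, "")[[1]]; b <- strsplit(ref, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # ends in match/mismatch
  X <- matrix(NEG, n + 1, m + 1)   # gap in ref (insertion in read)
  Y <- matrix(NEG, n + 1, m + 1)   # gap in read (deletion)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -open - (i - 1) * extend
  for (j in 2:(m + 1)) Y[1, j] <- -open - (j - 1) * extend
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (a[i - 1] == b[j - 1] && a[i - 1] != "N") match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - open - extend, X[i - 1, j] - extend)
      Y[i, j] <- max(M[i, j - 1] - open - extend, Y[i, j - 1] - extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Two-sided Fisher p by full enumeration of tables with fixed margins.
fisher_enum_oracle <- function(tab) {
  a <- tab[1, 1]; m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- vapply(support, function(x)
    choose(m, x) * choose(n, k - x) / choose(m + n, k), numeric(1))
  p_obs <- probs[match(a, support)]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact two-sided Wilcoxon rank-sum p by enumeration over all rank
# assignments.
wilcoxon_enum_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  U_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(nx + ny, nx)
  Us <- apply(combos, 2, function(ix) sum(ix) - nx * (nx + 1) / 2)
  pl <- mean(Us <= U_obs); pu <- mean(Us >= U_obs)
  min(1, 2 * min(pl, pu))
}

# Poisson-binomial tails by explicit 2^n enumeration.
poisbin_enum_oracle <- function(probs, k) {
  n <- length(probs)
  lower <- 0; upper <- 0
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask))[seq_len(n)]
    pr <- prod(ifelse(bits == 1, probs, 1 - probs))
    s <- sum(bits)
    if (s <= k) lower <- lower + pr
    if (s >= k) upper <- upper + pr
  }
  list(lower = lower, upper = upper)
}

# Overlap-count tail under the product background model by joint
# enumeration over all 2^n outcomes of the two genes' indicators.
discover_enum_oracle <- function(qa, qb, k) {
  n <- length(qa)
  # overlap in sample j occurs with probability qa_j * qb_j
  poisbin_enum_oracle(qa * qb, k)
}

# Joint Newton solve of the margin-matching logistic background model,
# independent of the package's alternating-update fit. Gauge: nu[1]
# free; the system is solved in (mu, nu) jointly with a ridge on the
# gauge direction.
background_joint_oracle <- function(M, tol = 1e-12, iters = 200) {
  ng <- nrow(M); ns <- ncol(M)
  r <- rowSums(M); cc <- colSums(M)
  th <- numeric(ng + ns)
  for (it in seq_len(iters)) {
    mu <- th[seq_len(ng)]; nu <- th[ng + seq_len(ns)]
    P <- stats::plogis(outer(mu, nu, "+"))
    F <- c(rowSums(P) - r, colSums(P) - cc)
    if (max(abs(F)) < tol) break
    W <- P * (1 - P)
    J <- rbind(cbind(diag(rowSums(W), ng), W),
               cbind(t(W), diag(colSums(W), ns)))
    # gauge direction (1, ..., 1, -1, ..., -1) is null; regularize
    g <- c(rep(1, ng), rep(-1, ns))
    J <- J + tcrossprod(g) / length(g)
    th <- th - solve(J, F)
  }
  stats::plogis(outer(th[seq_len(ng)], th[ng + seq_len(ns)], "+"))
}

# Projected-gradient NNLS run to convergence; independent check of the
# active-set objective value.
nnls_pg_oracle <- function(A, b, iters = 200000, tol = 1e-12) {
  AtA <- crossprod(A); Atb <- crossprod(A, b)
  L <- max(eigen(AtA, symmetric = TRUE, only.values = TRUE)$values)
  x <- numeric(ncol(A))
  for (i in seq_len(iters)) {
    g <- AtA %*% x - Atb
    x_new <- pmax(0, x - g / L)
    if (max(abs(x_new - x)) < tol) { x <- x_new; break }
    x <- x_new
  }
  list(x = drop(x), obj = sum((A %*% x - b)^2))
}
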