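#' Kaplan-Meier product-limit estimate
#'
#' Survival curve over the distinct event times; censored subjects leave
#' the risk set without contributing an event factor. Greenwood's
#' formula gives the pointwise standard error.
#'
#' @param time Nonnegative follow-up times.
#' @param event 1 = event, 0 = censored.
#' @return data.frame of class `km_curve` with `time`, `n_risk`,
#'   `n_event`, `surv`, `se` (one row per distinct event time).
#' @export
km_curve <- function(time, event) {
  if (length(time) < 1L) stop("need at least one record")
  if (any(time < 0)) stop("negative times")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  et <- sort(unique(time[event == 1]))
  n_risk <- vapply(et, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(et, function(t) sum(time == t & event == 1), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  gw <- cumsum(n_event / (n_risk * (n_risk - n_event)))
  se <- surv * sqrt(gw)
  structure(data.frame(time = et, n_risk = n_risk, n_event = n_event,
                       surv = surv, se = se),
            class = c("km_curve", "data.frame"))
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' @param curve A [km_curve()].
#' @param t Times at which to evaluate the step function.
#' @return Survival probabilities (1 before the first event time).
#' @export
km_surv <- function(curve, t) {
  idx <- findInterval(t, curve$time)
  ifelse(idx == 0, 1, curve$surv[pmax(idx, 1)])
}

#' Log-rank test for two or more survival curves
#'
#' Observed-minus-expected events over the pooled distinct event times,
#' with the hypergeometric variance of the per-time event allocation;
#' the statistic is the quadratic form over the first K-1 groups and is
#' chi-squared with K-1 degrees of freedom under the null.
#'
#' @param time,event Follow-up times and 0/1 event indicators.
#' @param group Group labels (>= 2 distinct values).
#' @return A [cs_test()] with the chi-square statistic.
#' @export
logrank_test <- function(time, event, group) {
  group <- factor(group)
  K <- nlevels(group)
  if (K < 2L) stop("need at least two groups")
  if (sum(event) < 1L) stop("no events")
  et <- sort(unique(time[event == 1]))
  U <- numeric(K)
  V <- matrix(0, K, K)
  for (t in et) {
    at_risk <- time >= t
    n <- sum(at_risk)
    d <- sum(time == t & event == 1)
    n_g <- vapply(levels(group), function(g) sum(at_risk & group == g),
                  numeric(1))
    d_g <- vapply(levels(group), function(g)
      sum(time == t & event == 1 & group == g), numeric(1))
    U <- U + d_g - n_g * d / n
    if (n > 1) {
      f <- d * (n - d) / (n - 1)
      V <- V + f * (diag(n_g / n, K) - tcrossprod(n_g / n))
    }
  }
  idx <- seq_len(K - 1L)
  stat <- drop(t(U[idx]) %*% solve(V[idx, idx, drop = FALSE], U[idx]))
  cs_test(stat, K - 1L, stats::pchisq(stat, K - 1L, lower.tail = FALSE),
          "Log-rank test")
}

#' Cox proportional-hazards model
#'
#' Newton-Raphson maximization of the partial likelihood with Efron
#' (default) or Breslow handling of tied event times. Convergence is
#' declared when the largest coefficient update falls below `tol` (or
#' after `max_iter` iterations, flagged unconverged). Interaction terms
#' are supplied as product columns of the covariate matrix.
#'
#' The score test evaluated at beta = 0 is also reported; for a single
#' binary covariate without ties it coincides with the two-group
#' log-rank statistic.
#'
#' @param time,event Follow-up times and 0/1 event indicators.
#' @param X Covariate matrix (or data.frame); columns are covariates.
#' @param ties `"efron"` or `"breslow"`.
#' @param tol Convergence tolerance on max |change in beta|.
#' @param max_iter Maximum Newton iterations.
#' @return List of class `cox_fit`: `coefficients`, `hazard_ratios`,
#'   `se`, `z`, `p`, `loglik` (null and final), `score_test`,
#'   `iterations`, `converged`.
#' @export
cox_ph_fit <- function(time, event, X, ties = c("efron", "breslow"),
                       tol = 1e-9, max_iter = 25L) {
  ties <- match.arg(ties)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (sum(event) < 1L) stop("no events")
  p <- ncol(X)
  o <- order(time)
  time <- time[o]; event <- event[o]; X <- X[o, , drop = FALSE]
  qrx <- qr(sweep(X, 2, colMeans(X)))
  if (qrx$rank < p) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1):p]]
    stop("collinear covariate(s): ", paste(bad, collapse = ", "))
  }
  beta <- numeric(p)
  score_test <- NULL
  loglik0 <- NA_real_
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    d <- cox_derivatives(time, event, X, beta, ties)
    if (iter == 1L) {
      loglik0 <- d$loglik
      stat <- drop(t(d$U) %*% solve(d$I, d$U))
      score_test <- cs_test(stat, p,
                            stats::pchisq(stat, p, lower.tail = FALSE),
                            "Cox score test at beta = 0")
    }
    step <- solve(d$I, d$U)
    beta <- beta + step
    if (any(!is.finite(beta)) || any(abs(beta) > 20)) {
      worst <- colnames(X)[which.max(abs(beta))]
      stop("monotone partial likelihood (complete separation) for ",
           "covariate ", worst)
    }
    if (max(abs(step)) < tol) { converged <- TRUE; break }
  }
  d <- cox_derivatives(time, event, X, beta, ties)
  covb <- solve(d$I)
  se <- sqrt(diag(covb))
  z <- beta / se
  structure(list(coefficients = stats::setNames(beta, colnames(X)),
                 hazard_ratios = stats::setNames(exp(beta), colnames(X)),
                 se = stats::setNames(se, colnames(X)),
                 z = z, p = 2 * stats::pnorm(-abs(z)),
                 loglik = c(null = loglik0, final = d$loglik),
                 score_test = score_test,
                 iterations = iter, converged = converged, ties = ties),
            class = "cox_fit")
}

# Partial-likelihood value, score vector and information matrix at beta.
# Inputs must be sorted by time.
cox_derivatives <- function(time, event, X, beta, ties) {
  n <- nrow(X); p <- ncol(X)
  eta <- drop(X %*% beta)
  eta <- eta - max(eta)                  # overflow guard; cancels in ratios
  w <- exp(eta)
  wx <- X * w
  # reverse cumulative risk-set sums (times sorted ascending)
  rc0 <- rev(cumsum(rev(w)))
  rc1 <- apply(wx, 2, function(v) rev(cumsum(rev(v))))
  rc2 <- array(0, c(n, p, p))
  for (j in seq_len(p)) for (k in j:p) {
    v <- rev(cumsum(rev(wx[, j] * X[, k])))
    rc2[, j, k] <- v; rc2[, k, j] <- v
  }
  loglik <- 0; U <- numeric(p); I <- matrix(0, p, p)
  i <- 1L
  while (i <= n) {
    grp <- which(time == time[i])        # contiguous after sorting
    i_next <- grp[length(grp)] + 1L
    D <- grp[event[grp] == 1]
    d <- length(D)
    if (d > 0L) {
      S0 <- rc0[grp[1]]
      S1 <- rc1[grp[1], ]
      S2 <- rc2[grp[1], , ]
      if (d == 1L || ties == "breslow") {
        for (l in seq_len(d)) {
          loglik <- loglik - log(S0)
          U <- U - S1 / S0
          I <- I + S2 / S0 - tcrossprod(S1 / S0)
        }
      } else {                            # Efron
        S0D <- sum(w[D]); S1D <- colSums(wx[D, , drop = FALSE])
        S2D <- crossprod(X[D, , drop = FALSE], wx[D, , drop = FALSE])
        for (l in 0:(d - 1L)) {
          a0 <- S0 - l / d * S0D
          a1 <- S1 - l / d * S1D
          a2 <- S2 - l / d * S2D
          loglik <- loglik - log(a0)
          U <- U - a1 / a0
          I <- I + a2 / a0 - tcrossprod(a1 / a0)
        }
      }
      loglik <- loglik + sum(eta[D])
      U <- U + colSums(X[D, , drop = FALSE])
    }
    i <- i_next
  }
  list(loglik = loglik, U = U, I = I)
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox proportional-hazards fit (", x$ties, " ties), ",
      x$iterations, " iteration(s)",
      if (!x$converged) " [NOT converged]", "\n", sep = "")
  print(data.frame(coef = x$coefficients, HR = x$hazard_ratios,
                   se = x$se, z = x$z, p = x$p))
  invisible(x)
}
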