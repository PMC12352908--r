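#' Raw Mut:WT* ratio of one sample
#'
#' The internally controlled readout of a CRISPR-Select sample: the
#' count of mutation-of-interest knock-in reads divided by the count of
#' synonymous-control knock-in reads. Only the two knock-in classes
#' enter; AMBIGUOUS and DISCARDED reads are excluded.
#'
#' A zero WT* count leaves the ratio undefined and is an error (not an
#' infinity). A zero Mut count with nonzero WT* is an observable
#' extinction and yields 0 with a warning.
#'
#' @param table One row of an outcome table, or any object with
#'   `n_MUT_KI` and `n_WTSTAR_KI` fields.
#' @return Numeric ratio r = MUT_KI / WTSTAR_KI.
#' @export
mut_wtstar_ratio <- function(table) {
  mut <- table$n_MUT_KI; wts <- table$n_WTSTAR_KI
  if (any(wts == 0)) stop("undefined ratio: WT* knock-in count is zero")
  if (any(mut == 0)) warning("zero Mut knock-in count: ratio is 0")
  mut / wts
}

#' Normalize per-timepoint ratios to the baseline day
#'
#' R(t) = r(t) / r(baseline), so R(baseline) = 1 and a fitness deficit
#' of the mutation of interest shows as R < 1 at later days. Replicates
#' are normalized independently (each replicate's own baseline); no
#' pooling occurs before testing.
#'
#' @param ratios data.frame with columns `timepoint`, `r`, and
#'   optionally `condition`/`replicate` (normalization is done within
#'   each condition x replicate group).
#' @param baseline_day The baseline timepoint (default 2).
#' @return The input with a column `R` appended.
#' @export
normalize_to_baseline <- function(ratios, baseline_day = 2) {
  ratios <- as.data.frame(ratios)
  grp_cols <- intersect(c("condition", "replicate"), names(ratios))
  key <- if (length(grp_cols))
    interaction(ratios[grp_cols], drop = TRUE) else factor(rep(1, nrow(ratios)))
  ratios$R <- NA_real_
  for (g in levels(key)) {
    i <- which(key == g)
    base <- ratios$r[i][ratios$timepoint[i] == baseline_day]
    if (length(base) != 1L)
      stop("baseline day ", baseline_day, " missing (or duplicated) in group ", g)
    ratios$R[i] <- ratios$r[i] / base
  }
  ratios
}

#' Selection coefficient from a normalized ratio
#'
#' Log-linear summary of the endpoint ratio: s = ln(R) / dt, the implied
#' per-day log fitness difference between the mutation of interest and
#' the synonymous control. s = 0 iff R = 1.
#'
#' @param R Normalized Mut:WT* ratio (> 0).
#' @param dt Elapsed days between baseline and measurement (> 0).
#' @return Selection coefficient per day.
#' @export
selection_coefficient <- function(R, dt) {
  if (any(R <= 0)) stop("R must be positive")
  if (any(dt <= 0)) stop("dt must be positive")
  log(R) / dt
}

#' Compare normalized ratios between conditions across replicates
#'
#' Two-sided t test of replicate-level normalized ratios, paired across
#' replicates (the default, matching the treated-vs-untreated contrast
#' of a single cell line) or unpaired with Welch's correction (for
#' cross-cell-line comparisons).
#'
#' @param x,y Numeric vectors of replicate-level R values (e.g. treated
#'   and untreated).
#' @param paired Pair replicate i of `x` with replicate i of `y`.
#' @return List of class `cs_test`: `statistic`, `df`, `p.value`,
#'   `method`.
#' @export
compare_conditions <- function(x, y, paired = TRUE) {
  if (length(x) < 2L || length(y) < 2L) stop("need at least 2 replicates")
  if (paired) {
    if (length(x) != length(y)) stop("paired test needs equal lengths")
    d <- x - y
    n <- length(d)
    sdd <- stats::sd(d)
    if (sdd == 0) {
      if (all(d == 0))
        return(cs_test(0, n - 1, 1, "paired t test"))
      stop("degenerate data: constant nonzero difference between conditions")
    }
    t <- mean(d) / (sdd / sqrt(n))
    df <- n - 1
    method <- "paired t test"
  } else {
    vx <- stats::var(x); vy <- stats::var(y)
    nx <- length(x); ny <- length(y)
    se2 <- vx / nx + vy / ny
    if (se2 == 0) {
      if (mean(x) == mean(y))
        return(cs_test(0, nx + ny - 2, 1, "Welch two-sample t test"))
      stop("degenerate data: zero variance in both groups")
    }
    t <- (mean(x) - mean(y)) / sqrt(se2)
    df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
    method <- "Welch two-sample t test"
  }
  cs_test(t, df, 2 * stats::pt(-abs(t), df), method)
}

#' Full selection analysis of an outcome table
#'
#' Computes per-replicate raw ratios r, baseline-normalized ratios R and
#' selection coefficients s for every sample, and tests the endpoint
#' treated-vs-untreated contrast across replicates.
#'
#' @param tables An `outcome_table` with one row per sample (columns
#'   `timepoint`, `condition`, `replicate` populated).
#' @param baseline_day,endpoint_day Baseline and endpoint days.
#' @param paired Use the paired replicate test for the endpoint
#'   contrast.
#' @return List of class `select_result` with `per_replicate` (long
#'   data.frame: timepoint, condition, replicate, r, R, s), `summary`
#'   (mean/SD of R per timepoint x condition) and `test` (endpoint
#'   treated-vs-untreated `cs_test`, or NULL if only one condition).
#' @export
select_analysis <- function(tables, baseline_day = 2, endpoint_day = 12,
                            paired = TRUE) {
  df <- as.data.frame(tables)
  df$r <- mut_wtstar_ratio(df)
  df <- normalize_to_baseline(df[, c("timepoint", "condition", "replicate",
                                     "r")], baseline_day)
  df$s <- ifelse(df$timepoint == baseline_day, 0,
                 log(df$R) / (df$timepoint - baseline_day))
  agg <- stats::aggregate(R ~ timepoint + condition, df,
                          function(v) c(mean = mean(v), sd = stats::sd(v)))
  summary <- data.frame(timepoint = agg$timepoint, condition = agg$condition,
                        mean_R = agg$R[, "mean"], sd_R = agg$R[, "sd"])
  test <- NULL
  conds <- unique(df$condition)
  if (all(c("treated", "untreated") %in% conds)) {
    at <- function(cond) {
      sub <- df[df$timepoint == endpoint_day & df$condition == cond, ]
      sub$R[order(sub$replicate)]
    }
    test <- compare_conditions(at("treated"), at("untreated"), paired = paired)
  }
  structure(list(per_replicate = df, summary = summary, test = test),
            class = "select_result")
}

#' @export
print.select_result <- function(x, ...) {
  cat("CRISPR-Select analysis\n")
  print(x$summary, row.names = FALSE)
  if (!is.null(x$test))
    cat(sprintf("Endpoint treated vs untreated: t = %.3f, df = %.1f, p = %.4g\n",
                x$test$statistic, x$test$df, x$test$p.value))
  invisible(x)
}
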