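#' Build binary alteration matrices from a mutation table
#'
#' One matrix per sequencing stratum (e.g. WES vs targeted panel), genes
#' in rows and samples in columns; an entry is 1 when the sample has at
#' least one passing variant in the gene. The default filter keeps
#' nonbenign exonic and splice-site variant classes, mirroring the
#' construction used for mutual-exclusivity testing.
#'
#' @param mutations data.frame with `sample`, `gene`, `variant_class`,
#'   `pathogenicity_label` and (optionally) `platform_class` columns.
#' @param genes Genes to include (rows); must be non-empty.
#' @param samples Optional full sample set (columns); defaults to the
#'   samples present in the table.
#' @param keep_classes Variant classes that pass the filter.
#' @param drop_labels Pathogenicity labels excluded as benign.
#' @param stratum Column defining strata; `NULL` for a single matrix.
#' @return Named list of binary matrices (one per stratum).
#' @export
build_alteration_matrix <- function(mutations, genes, samples = NULL,
                                    keep_classes = c("missense", "stopgain",
                                                     "frameshift", "nonstop",
                                                     "splice"),
                                    drop_labels = c("benign", "likely_benign"),
                                    stratum = "platform_class") {
  if (!length(genes)) stop("gene list is empty")
  mutations <- as.data.frame(mutations)
  if (nrow(mutations) == 0L) warning("empty mutation table: all-zero matrix")
  pass <- mutations$variant_class %in% keep_classes &
    !(tolower(as.character(mutations$pathogenicity_label)) %in% drop_labels)
  mm <- mutations[pass & mutations$gene %in% genes, , drop = FALSE]
  strata <- if (!is.null(stratum) && stratum %in% names(mutations))
    unique(as.character(mutations[[stratum]])) else "all"
  if (is.null(samples)) samples <- unique(as.character(mutations$sample))
  out <- list()
  for (s in strata) {
    cols <- if (s == "all") samples
            else unique(as.character(
              mutations$sample[mutations[[stratum]] == s]))
    M <- matrix(0L, length(genes), length(cols),
                dimnames = list(genes, cols))
    sub <- if (s == "all") mm else mm[mm[[stratum]] == s, , drop = FALSE]
    if (nrow(sub)) {
      ij <- cbind(match(sub$gene, genes), match(sub$sample, cols))
      ij <- ij[!is.na(ij[, 1]) & !is.na(ij[, 2]), , drop = FALSE]
      M[ij] <- 1L
    }
    out[[s]] <- M
  }
  out
}

#' Fit the margin-aware background model of alteration probabilities
#'
#' The null model behind the mutual-exclusivity test: independent
#' Bernoulli entries p_ij = plogis(mu_i + nu_j) whose expected row sums
#' (per-gene alteration counts) and column sums (per-tumor alteration
#' counts) match the observed margins — the maximum-entropy model
#' constrained to the observed per-gene and per-tumor rates. Fitted by
#' alternating Newton updates on the gene and sample parameters from a
#' zero initialization, so the fit is deterministic.
#'
#' Degenerate rows/columns (all 0 or all 1) have no finite parameter;
#' they are excluded from fitting and reported in `dropped`.
#'
#' @param matrix Binary genes x samples matrix.
#' @param tol Convergence: maximum absolute margin residual.
#' @param max_iter Maximum alternating sweeps.
#' @return List of class `background_model`: `p` (probability matrix
#'   over retained rows/columns), `mu`, `nu`, `residual`, `dropped`.
#' @export
fit_background <- function(matrix, tol = 1e-8, max_iter = 500L) {
  M <- as.matrix(matrix)
  if (any(!M %in% c(0L, 1L))) stop("matrix must be binary")
  drop_r <- rowSums(M) %in% c(0L, ncol(M))
  drop_c <- colSums(M) %in% c(0L, nrow(M))
  dropped <- list(genes = rownames(M)[drop_r], samples = colnames(M)[drop_c])
  if (any(drop_r) || any(drop_c))
    message("excluding ", sum(drop_r), " degenerate gene(s) and ",
            sum(drop_c), " degenerate sample(s) from background fit")
  M <- M[!drop_r, !drop_c, drop = FALSE]
  ng <- nrow(M); ns <- ncol(M)
  if (ng == 0L || ns == 0L) stop("no informative rows/columns left")
  r <- rowSums(M); c <- colSums(M)
  mu <- numeric(ng); nu <- numeric(ns)
  residual <- Inf
  for (it in seq_len(max_iter)) {
    P <- stats::plogis(outer(mu, nu, "+"))
    # Newton step per gene parameter
    mu <- mu + (r - rowSums(P)) / pmax(rowSums(P * (1 - P)), 1e-12)
    P <- stats::plogis(outer(mu, nu, "+"))
    nu <- nu + (c - colSums(P)) / pmax(colSums(P * (1 - P)), 1e-12)
    P <- stats::plogis(outer(mu, nu, "+"))
    residual <- max(max(abs(rowSums(P) - r)), max(abs(colSums(P) - c)))
    if (residual < tol) break
  }
  if (residual >= tol)
    stop("background fit did not converge: residual ", format(residual),
         " after ", max_iter, " iterations")
  structure(list(p = P, mu = stats::setNames(mu, rownames(M)),
                 nu = stats::setNames(nu, colnames(M)),
                 residual = residual, dropped = dropped),
            class = "background_model")
}

#' Margin-aware pairwise exclusivity / cooccurrence test
#'
#' Under the background model the overlap count of two genes is
#' Poisson-binomial with per-sample success probabilities
#' q_j = p_Aj * p_Bj. Mutual exclusivity is evidenced by a small overlap
#' (p = P(X <= k)); cooccurrence by a large one (p = P(X >= k)).
#'
#' @param matrix Binary genes x samples matrix.
#' @param background A [fit_background()] result for `matrix`.
#' @param geneA,geneB Gene names (order does not matter).
#' @param direction `"exclusive"` or `"cooccurring"`.
#' @return data.frame of class `pair_test`: pair, direction, overlap
#'   `k`, `p`.
#' @export
discover_pair_test <- function(matrix, background, geneA, geneB,
                               direction = c("exclusive", "cooccurring")) {
  direction <- match.arg(direction)
  M <- as.matrix(matrix)
  for (g in c(geneA, geneB))
    if (!g %in% rownames(M)) stop("gene absent from matrix: ", g)
  common <- intersect(colnames(M), names(background$nu))
  a <- M[geneA, common]; b <- M[geneB, common]
  k <- sum(a == 1L & b == 1L)
  if (!geneA %in% rownames(background$p) ||
      !geneB %in% rownames(background$p))
    stop("gene was dropped from the background fit: cannot test")
  q <- background$p[geneA, common] * background$p[geneB, common]
  tails <- poisson_binomial_cdf(q, k)
  p <- if (direction == "exclusive") tails$lower else tails$upper
  data.frame(geneA = geneA, geneB = geneB, direction = direction,
             k = k, p = p, stringsAsFactors = FALSE)
}

#' Screen gene pairs with the margin-aware test
#'
#' Runs [discover_pair_test()] over a set of pairs within one stratum
#' and adjusts p values by Benjamini-Hochberg within each direction.
#'
#' @param matrix Binary genes x samples matrix (one stratum).
#' @param pairs 2-column matrix/data.frame of gene pairs; defaults to
#'   all pairs of matrix rows retained in the background fit.
#' @param directions Directions to test.
#' @param background Optional pre-fitted background.
#' @param alpha Significance threshold on the adjusted p (default 0.01).
#' @return data.frame with `p_adj` and `significant` per pair and
#'   direction.
#' @export
discover_screen <- function(matrix, pairs = NULL,
                            directions = c("exclusive", "cooccurring"),
                            background = NULL, alpha = 0.01) {
  M <- as.matrix(matrix)
  if (is.null(background)) background <- fit_background(M)
  keep <- rownames(background$p)
  if (is.null(pairs)) {
    if (length(keep) < 2L) stop("fewer than 2 testable genes")
    pairs <- t(utils::combn(keep, 2L))
  }
  pairs <- as.matrix(pairs)
  out <- list()
  for (d in directions) {
    res <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i)
      discover_pair_test(M, background, pairs[i, 1], pairs[i, 2], d)))
    res$p_adj <- adjust_pvalues(res$p, "BH")
    res$significant <- res$p_adj < alpha
    out[[d]] <- res
  }
  do.call(rbind, out)
}

#' Fisher's-exact-test screen of gene pairs
#'
#' The conventional 2x2 cross-tabulation screen with BH adjustment at a
#' 0.01 significance threshold. Reported alongside the margin-aware
#' test: with heterogeneous per-tumor alteration rates the Fisher test
#' is conservative for mutual exclusivity and anticonservative for
#' cooccurrence, which the margin-aware null corrects.
#'
#' @param matrix Binary genes x samples matrix.
#' @param pairs 2-column matrix of gene pairs (default: all row pairs).
#' @param alpha BH-adjusted significance threshold (default 0.01).
#' @return data.frame with per-pair 2x2 counts, `p`, `p_adj`,
#'   `significant`.
#' @export
fisher_cooccurrence_screen <- function(matrix, pairs = NULL, alpha = 0.01) {
  M <- as.matrix(matrix)
  if (is.null(pairs)) pairs <- t(utils::combn(rownames(M), 2L))
  pairs <- as.matrix(pairs)
  res <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    a <- M[pairs[i, 1], ]; b <- M[pairs[i, 2], ]
    tab <- matrix(c(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b)), 2)
    ft <- fisher_exact_2x2(tab)
    data.frame(geneA = pairs[i, 1], geneB = pairs[i, 2],
               n11 = tab[1, 1], n10 = tab[2, 1], n01 = tab[1, 2],
               n00 = tab[2, 2], p = ft$p.value, stringsAsFactors = FALSE)
  }))
  res$p_adj <- adjust_pvalues(res$p, "BH")
  res$significant <- res$p_adj < alpha
  res
}
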