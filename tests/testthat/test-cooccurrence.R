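test_that("alteration matrices binarize, filter, and split strata", {
  mut <- data.frame(
    sample = c("s1", "s1", "s1", "s2", "s3", "s3"),
    gene = c("TP53", "TP53", "TP53", "RB1", "TP53", "RB1"),
    variant_class = c("missense", "stopgain", "frameshift", "missense",
                      "synonymous", "missense"),
    pathogenicity_label = c("pathogenic", "VUS", "VUS", "benign",
                            "pathogenic", "VUS"),
    platform_class = c("WES", "WES", "WES", "WES", "panel", "panel"),
    stringsAsFactors = FALSE)
  mats <- build_alteration_matrix(mut, genes = c("TP53", "RB1"),
                                  samples = c("s1", "s2", "s3"))
  expect_setequal(names(mats), c("WES", "panel"))
  # three passing TP53 variants in s1 -> a single 1
  expect_equal(mats$WES["TP53", "s1"], 1L)
  # benign-only RB1 in s2 -> 0
  expect_equal(mats$WES["RB1", "s2"], 0L)
  # synonymous TP53 in s3 filtered; RB1 passes in the panel stratum
  expect_equal(mats$panel["TP53", "s3"], 0L)
  expect_equal(mats$panel["RB1", "s3"], 1L)
  expect_error(build_alteration_matrix(mut, genes = character(0)), "empty")
})

test_that("background fit matches observed margins everywhere", {
  withr::with_seed(20, {
    for (i in 1:5) {
      M <- matrix(rbinom(30 * 60, 1, runif(1, 0.2, 0.5)), 30, 60,
                  dimnames = list(paste0("g", 1:30), paste0("s", 1:60)))
      bg <- tryCatch(fit_background(M), error = function(e) NULL)
      if (is.null(bg)) next
      keep_r <- rownames(bg$p); keep_c <- colnames(bg$p)
      expect_lt(max(abs(rowSums(bg$p) - rowSums(M[keep_r, keep_c]))), 1e-6)
      expect_lt(max(abs(colSums(bg$p) - colSums(M[keep_r, keep_c]))), 1e-6)
    }
  })
})

test_that("uniform margins give a constant background probability", {
  # block design: every row sum and column sum equal by symmetry
  M <- rbind(c(1, 1, 0, 0), c(0, 1, 1, 0), c(0, 0, 1, 1), c(1, 0, 0, 1))
  dimnames(M) <- list(paste0("g", 1:4), paste0("s", 1:4))
  bg <- fit_background(M)
  expect_lt(diff(range(bg$p)), 1e-8)
  expect_equal(mean(bg$p), mean(M), tolerance = 1e-8)
})

test_that("background probabilities match an independent joint Newton solve", {
  withr::with_seed(22, {
    M <- matrix(c(1, 0, 0,
                  1, 1, 0,
                  0, 1, 1), 3, 3, byrow = TRUE,
                dimnames = list(paste0("g", 1:3), paste0("s", 1:3)))
    bg <- fit_background(M, tol = 1e-10)
    P_oracle <- background_joint_oracle(M)
    expect_lt(max(abs(bg$p - P_oracle)), 1e-8)
  })
})

test_that("pair test equals joint enumeration for small cohorts", {
  withr::with_seed(23, {
    M <- matrix(rbinom(4 * 10, 1, 0.4), 4, 10,
                dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
    bg <- tryCatch(fit_background(M), error = function(e) NULL)
    if (!is.null(bg) && all(c("g1", "g2") %in% rownames(bg$p))) {
      common <- colnames(bg$p)
      k <- sum(M["g1", common] & M["g2", common])
      qa <- bg$p["g1", common]; qb <- bg$p["g2", common]
      want <- discover_enum_oracle(qa, qb, k)
      excl <- discover_pair_test(M, bg, "g1", "g2", "exclusive")
      cooc <- discover_pair_test(M, bg, "g1", "g2", "cooccurring")
      expect_equal(excl$p, want$lower, tolerance = 1e-12)
      expect_equal(cooc$p, want$upper, tolerance = 1e-12)
      # symmetry in the gene order
      expect_equal(discover_pair_test(M, bg, "g2", "g1", "exclusive")$p,
                   excl$p, tolerance = 1e-12)
    }
  })
})

test_that("a perfectly exclusive planted pair is strongly significant", {
  cohort <- simulate_cohort(
    n_samples = 200L,
    gene_rates = c(A = 0.3, B = 0.3, C = 0.25, D = 0.2),
    sample_rate_dispersion = 0.5,
    planted_pairs = data.frame(geneA = "A", geneB = "B",
                               direction = "exclusive", strength = 1),
    survival = list(gene = "A", hazard_mut = 0.03, hazard_wt = 0.06,
                    censor_hazard = 0.02),
    locus = list(gene = "A", chrom = "chr1", start = 1000L, end = 20000L),
    seed = 29)
  M <- cohort$alteration_truth
  bg <- fit_background(M)
  res <- discover_pair_test(M, bg, "A", "B", "exclusive")
  expect_lt(res$p, 1e-3)
})

test_that("the Fisher screen delegates to the exact 2x2 test", {
  withr::with_seed(25, {
    M <- matrix(rbinom(3 * 40, 1, 0.3), 3, 40,
                dimnames = list(c("a", "b", "c"), paste0("s", 1:40)))
    res <- fisher_cooccurrence_screen(M)
    i <- which(res$geneA == "a" & res$geneB == "b")
    tab <- matrix(c(sum(M["a", ] & M["b", ]), sum(M["a", ] & !M["b", ]),
                    sum(!M["a", ] & M["b", ]), sum(!M["a", ] & !M["b", ])), 2)
    expect_equal(res$p[i], fisher_exact_2x2(tab)$p.value, tolerance = 1e-12)
    expect_equal(res$p_adj, adjust_pvalues(res$p, "BH"), tolerance = 1e-12)
  })
})

test_that("identical and disjoint gene rows sit at the Fisher extremes", {
  M <- rbind(a = c(1, 1, 1, 0, 0, 0, 0, 0),
             b = c(1, 1, 1, 0, 0, 0, 0, 0),
             c = c(0, 0, 0, 1, 1, 1, 0, 0))
  colnames(M) <- paste0("s", 1:8)
  res <- fisher_cooccurrence_screen(M)
  p_ab <- res$p[res$geneA == "a" & res$geneB == "b"]  # identical: cooccur
  p_ac <- res$p[res$geneA == "a" & res$geneB == "c"]  # disjoint: exclusive
  # identical rows give the minimal achievable p for these margins
  tabs_ab <- sapply(0:3, function(k) fisher_exact_2x2(
    matrix(c(k, 3 - k, 3 - k, 2 + k), 2))$p.value)
  expect_equal(p_ab, min(tabs_ab), tolerance = 1e-12)
  expect_lte(p_ac, 1)
})

test_that("degenerate genes are excluded from fitting and reported", {
  M <- rbind(dead = rep(0L, 6), alive = c(1, 0, 1, 0, 1, 0),
             other = c(0, 1, 1, 0, 0, 1))
  colnames(M) <- paste0("s", 1:6)
  expect_message(bg <- fit_background(M), "degenerate")
  expect_true("dead" %in% bg$dropped$genes)
  expect_error(discover_pair_test(M, bg, "dead", "alive", "exclusive"),
               "dropped")
  expect_error(discover_pair_test(M, bg, "nope", "alive", "exclusive"),
               "absent")
})
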