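test_that("helicase-domain status rule: class and position both matter", {
  hd <- data.frame(start = c(100, 400), end = c(200, 600))
  mk <- function(class, pos) data.frame(variant_class = class,
                                        protein_pos = pos)
  expect_equal(classify_ercc2_status(mk("missense", 150), hd), "MUT")
  expect_equal(classify_ercc2_status(mk("stopgain", 450), hd), "MUT")
  expect_equal(classify_ercc2_status(mk("missense", 300), hd), "WT")
  expect_equal(classify_ercc2_status(mk("synonymous", 150), hd), "WT")
  expect_equal(classify_ercc2_status(NULL, hd), "WT")
  expect_warning(
    st <- classify_ercc2_status(mk("missense", NA), hd),
    "skipped")
  expect_equal(st, "WT")
  # order independence
  two <- rbind(mk("synonymous", 150), mk("missense", 120))
  expect_equal(classify_ercc2_status(two, hd),
               classify_ercc2_status(two[2:1, ], hd))
})

test_that("TP53 status follows pathogenicity labels and deep deletions", {
  expect_equal(classify_tp53_status(
    data.frame(pathogenicity_label = "pathogenic")), "MUT")
  expect_equal(classify_tp53_status(
    data.frame(pathogenicity_label = "likely_pathogenic")), "MUT")
  expect_equal(classify_tp53_status(
    data.frame(pathogenicity_label = "VUS")), "WT")
  expect_equal(classify_tp53_status(NULL, deep_deletion_flag = TRUE), "MUT")
  expect_equal(classify_tp53_status(NULL), "WT")
})

test_that("LOH requires an overlapping segment with minor copy number 0", {
  gene <- list(chrom = "chr19", start = 1000, end = 2000)
  seg <- function(start, end, minor, chrom = "chr19")
    data.frame(chrom = chrom, start = start, end = end,
               major_cn = minor + 1, minor_cn = minor)
  expect_equal(call_loh(gene, seg(500, 1500, 0)), "LOH")
  expect_equal(call_loh(gene, seg(500, 2500, 1)), "no_LOH")
  expect_true(is.na(call_loh(gene, seg(5000, 6000, 0))))
  expect_true(is.na(call_loh(gene, seg(1000, 2000, 0, chrom = "chr1"))))
  expect_error(call_loh(gene, seg(2000, 1000, 0)), "malformed")
})

test_that("TMB division uses the registered platform footprints exactly", {
  expect_equal(compute_tmb(76, "WES")$tmb, 2.0)
  expect_equal(compute_tmb(14, "Caris")$tmb, 10.0)
  expect_equal(compute_tmb(10, "OncoPanel_v3")$tmb, 10 / 1.315078,
               tolerance = 1e-12)
  expect_equal(compute_tmb(10, "OncoPanel_v3")$tmb, 7.604, tolerance = 1e-3)
  expect_equal(compute_tmb(5, "MSK341")$tmb, 5 / 0.896665, tolerance = 1e-12)
  expect_error(compute_tmb(5, "nanopore"), "unknown platform")
})

test_that("TMB harmonization standardizes log10(tmb+1) within strata", {
  rec <- data.frame(platform = rep("WES", 3), tmb = 10^c(1, 2, 3) - 1)
  out <- harmonize_tmb(rec)
  expect_equal(out$z, c(-1, 0, 1))

  # permutation stability
  rec2 <- data.frame(platform = c("A", "B", "A", "B", "A"),
                     tmb = c(1, 5, 7, 2, 4))
  o1 <- harmonize_tmb(rec2)
  perm <- c(3, 1, 5, 2, 4)
  o2 <- harmonize_tmb(rec2[perm, ])
  expect_equal(o2$z, o1$z[perm])

  expect_warning(h1 <- harmonize_tmb(data.frame(platform = c("A", "A", "B"),
                                                tmb = c(1, 2, 3))),
                 "fewer than 2")
  expect_true(is.na(h1$z[3]))
  expect_warning(h0 <- harmonize_tmb(data.frame(platform = "A",
                                                tmb = c(2, 2))[c(1, 1), ]),
                 "zero spread")
})

test_that("spectrum channels collapse purine-reference sites to the pyrimidine strand", {
  # reference AAA -> C>A at center of A C A context
  ref <- c(chr1 = "AACAA")
  mut <- data.frame(chrom = "chr1", pos = 3, ref = "C", alt = "A")
  sp <- build_spectrum96(mut, ref)
  expect_equal(unname(sp["A[C>A]A"]), 1L)
  expect_equal(sum(sp), 1L)

  # G>T with 5'T 3'T: TGT revcomps to ACA, G>T to C>A
  ref2 <- c(chr1 = "ATGTA")
  mut2 <- data.frame(chrom = "chr1", pos = 3, ref = "G", alt = "T")
  sp2 <- build_spectrum96(mut2, ref2)
  expect_equal(unname(sp2["A[C>A]A"]), 1L)

  # indels excluded; ref mismatches skipped with warning
  mut3 <- data.frame(chrom = "chr1", pos = c(3, 3), ref = c("C", "CT"),
                     alt = c("A", "C"))
  sp3 <- build_spectrum96(mut3, ref)
  expect_equal(sum(sp3), 1L)
  expect_equal(attr(sp3, "n_excluded"), 1L)
  expect_warning(build_spectrum96(
    data.frame(chrom = "chr1", pos = 3, ref = "T", alt = "A"), ref),
    "mismatch")
})

test_that("channel order is substitution-major, trinucleotide alphabetical", {
  ch <- sbs96_channels()
  expect_length(ch, 96)
  expect_equal(ch[1], "A[C>A]A")
  expect_equal(ch[2], "A[C>A]C")
  expect_equal(ch[17], "A[C>G]A")
  expect_equal(ch[96], "T[T>G]T")
  expect_false(anyDuplicated(ch) > 0)
})

test_that("NNLS recovers exact mixtures and matches independent optimizers", {
  S <- synthetic_signature_matrix(k = 4)
  b <- drop(S %*% c(700, 300, 0, 0))
  fit <- fit_signatures_nnls(b, S)
  expect_equal(unname(fit$exposures), c(700, 300, 0, 0), tolerance = 1e-6)
  expect_lt(fit$residual_norm, 1e-8)

  one <- fit_signatures_nnls(drop(S %*% c(0, 0, 500, 0)), S)
  expect_equal(sum(one$exposures > 1e-6), 1L)

  zero <- fit_signatures_nnls(numeric(96), S)
  expect_equal(unname(zero$exposures), rep(0, 4))
  expect_error(fit_signatures_nnls(b, S[, 0, drop = FALSE]), "no signatures")

  withr::with_seed(14, {
    for (i in 1:5) {
      spec <- rpois(96, 5)
      fit <- fit_signatures_nnls(spec, S)
      obj <- sum((spec - drop(S %*% fit$exposures))^2)
      # projected-gradient oracle
      pg <- nnls_pg_oracle(S, spec)
      expect_lt(abs(obj - pg$obj), 1e-6)
      # established active-set implementation
      ls <- pracma::lsqnonneg(S, spec)
      expect_lt(abs(obj - ls$resid.norm) / max(1, obj), 1e-6)
      expect_equal(unname(fit$exposures), unname(ls$x), tolerance = 1e-4)
    }
  })
})

test_that("domain enrichment test reproduces the 87%-in-domain example", {
  res <- domain_enrichment_test(87, 100, 0.56)
  expect_equal(res$statistic, (87 - 56)^2 / 56 + (13 - 44)^2 / 44,
               tolerance = 1e-12)
  expect_equal(res$df, 1)
  expect_lt(res$p.value, 1e-9)

  # observed fraction equal to the length fraction: no signal
  expect_equal(domain_enrichment_test(56, 100, 0.56)$p.value, 1)
  expect_error(domain_enrichment_test(5, 4, 0.5), "n_total")
  expect_error(domain_enrichment_test(5, 10, 1.2), "between 0 and 1")
})

test_that("signature exposures are recovered from resampled spectra", {
  S <- synthetic_signature_matrix()
  true_e <- c(250, 0, 150, 0, 100, 0)
  lam <- drop(S %*% true_e)
  withr::with_seed(15, {
    cosims <- replicate(30, {
      spec <- rpois(96, lam)
      fit <- fit_signatures_nnls(spec, S)
      sum(fit$exposures * true_e) /
        sqrt(sum(fit$exposures^2) * sum(true_e^2))
    })
  })
  expect_gte(median(cosims), 0.95)
})
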