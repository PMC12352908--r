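test_that("aligning the reference to itself is gap-free with score 2L", {
  d <- fixture_design_single_exon()
  a <- align_read(d$reference, d$reference)
  expect_equal(a$score, 2 * nchar(d$reference))
  expect_equal(nrow(a$events), 0L)
  expect_equal(a$nmatch, nchar(d$reference))
})

test_that("a 1-bp deletion is recovered at its leftmost equivalent position", {
  d <- fixture_design_single_exon()
  ref <- d$reference
  read <- delete_at(ref, 100L, 1L)
  a <- align_read(read, ref)
  expect_equal(nrow(a$events), 1L)
  expect_equal(a$events$net_length, -1L)
  # leftmost equivalent placement: smallest p0 whose deletion yields the read
  equivalents <- which(vapply(0:(nchar(ref) - 1), function(p)
    delete_at(ref, p, 1L) == read, logical(1))) - 1L
  expect_equal(a$events$position, min(equivalents))
  # score agrees with the independent dynamic-programming oracle
  expect_equal(a$score, nw_affine_score(read, ref))
})

test_that("alignment scores match the DP oracle on random indel reads", {
  d <- fixture_design_single_exon()
  ref <- substring(d$reference, 1, 60)   # short for the O(nm) oracle
  withr::with_seed(31, {
    for (i in 1:8) {
      read <- ref
      p <- sample(10:50, 1)
      if (i %% 2 == 0) read <- delete_at(read, p, sample(1:3, 1))
      else read <- insert_at(read, p, paste(sample(c("A", "C", "G", "T"),
                                                   sample(1:3, 1), TRUE),
                                            collapse = ""))
      # add a substitution
      q <- sample(5:55, 1)
      b <- substring(read, q, q)
      substr(read, q, q) <- setdiff(c("A", "C", "G", "T"), b)[1]
      a <- align_read(read, ref)
      expect_equal(a$score, nw_affine_score(read, ref))
    }
  })
})

test_that("a read of Ns aligns with zero matches and errors on bad characters", {
  d <- fixture_design_single_exon()
  a <- align_read(strrep("N", nchar(d$reference)), d$reference)
  expect_equal(a$nmatch, 0)
  expect_error(align_read("ACGTX", d$reference), "non-ACGTN")
  expect_error(align_read("", d$reference), "empty read")
})

test_that("classify_read implements the decision order on canonical cases", {
  d <- fixture_design_exon_intron()
  ref <- d$reference
  mut_read <- apply_subs_to(ref, d$mut_substitutions)
  wts_read <- apply_subs_to(ref, d$wtstar_substitutions)

  expect_equal(classify_read(ref, d)$category, "UNEDITED")
  expect_equal(classify_read(mut_read, d)$category, "MUT_KI")
  expect_equal(classify_read(wts_read, d)$category, "WTSTAR_KI")

  both <- apply_subs_to(mut_read, d$wtstar_substitutions)
  expect_equal(classify_read(both, d)$category, "AMBIGUOUS")

  # 2-bp deletion wholly inside the intron (cut-site window reaches it)
  d_intron <- example_design("intron")
  intron_del <- delete_at(d_intron$reference, d_intron$cut_site - 1L, 2L)
  oc <- classify_read(intron_del, d_intron)
  expect_equal(oc$category, "INDEL")
  expect_false(oc$frameshift)
  expect_equal(oc$indel_region, "intronic")

  # 1-bp exonic insertion at the cut site: frameshift
  ins <- insert_at(ref, d$cut_site, "A")
  oc2 <- classify_read(ins, d)
  expect_equal(oc2$category, "INDEL")
  expect_true(oc2$frameshift)
  expect_equal(oc2$indel_region, "exonic")

  # 3-bp exonic deletion: in-frame
  del3 <- delete_at(ref, d$cut_site - 1L, 3L)
  oc3 <- classify_read(del3, d)
  expect_equal(oc3$category, "INDEL")
  expect_false(oc3$frameshift)
})

test_that("an indel far outside the cut-site window does not veto a knock-in call", {
  d <- fixture_design_single_exon()
  mut_read <- apply_subs_to(d$reference, d$mut_substitutions)
  far <- delete_at(mut_read, 10L, 1L)   # 90 bp from the cut
  oc <- classify_read(far, d)
  expect_equal(oc$category, "MUT_KI")
})

test_that("quantify_sample counts a constructed 6-read sample correctly", {
  d <- fixture_design_exon_intron()
  ref <- d$reference
  reads <- c(apply_subs_to(ref, d$mut_substitutions),
             apply_subs_to(ref, d$mut_substitutions),
             apply_subs_to(ref, d$wtstar_substitutions),
             apply_subs_to(ref, d$wtstar_substitutions),
             ref,
             delete_at(ref, d$cut_site - 1L, 2L))  # exonic 2-bp deletion
  ot <- quantify_sample(reads, d)
  expect_equal(ot$n_MUT_KI, 2)
  expect_equal(ot$n_WTSTAR_KI, 2)
  expect_equal(ot$n_UNEDITED, 1)
  expect_equal(ot$n_INDEL, 1)
  expect_equal(ot$indel_fs_exonic, 1)
  expect_equal(ot$n_total, 6)
  # category counts + discarded = total
  expect_equal(ot$n_MUT_KI + ot$n_WTSTAR_KI + ot$n_UNEDITED + ot$n_INDEL +
                 ot$n_AMBIGUOUS + ot$n_DISCARDED, ot$n_total)
})

test_that("an empty FASTQ yields an all-zero table with a warning", {
  path <- withr::local_tempfile(fileext = ".fastq")
  writeLines(character(0), path)
  d <- fixture_design_single_exon()
  expect_warning(ot <- quantify_sample(path, d), "no reads")
  expect_equal(ot$n_total, 0)
  expect_equal(ot$n_MUT_KI + ot$n_INDEL + ot$n_DISCARDED, 0)
})

test_that("classification is invariant to read order", {
  d <- fixture_design_exon_intron()
  mix <- default_genotype_mix(d, mut_cisplatin_fitness = 0.8)
  sim <- simulate_select_experiment(d, mix, timepoints = 2,
                                    conditions = "untreated", depth = 300,
                                    replicates = 1, seed = 13)
  reads <- sim$reads[[1]]
  ot1 <- quantify_sample(reads, d)
  ot2 <- quantify_sample(rev(reads), d)
  cols <- setdiff(names(ot1), c("sample_id", "timepoint", "condition",
                                "replicate"))
  expect_equal(ot1[cols], ot2[cols])
})

test_that("error-free deterministic simulation is recovered exactly", {
  d <- fixture_design_exon_intron()
  mix <- default_genotype_mix(d, mut_cisplatin_fitness = 0.8)
  sim <- simulate_select_experiment(d, mix, depth = 400, seed = 3,
                                    deterministic = TRUE)
  ot <- quantify_experiment(sim)
  for (i in seq_len(nrow(ot))) {
    f <- sim$truth$allele_fractions[[ot$sample_id[i]]]
    cat_frac <- tapply(f, sub(":.*", "", names(f)), sum)
    # exact up to largest-remainder rounding of the planted fractions
    expect_lt(abs(ot$n_MUT_KI[i] / ot$n_total[i] - cat_frac["MUT_KI"]),
              1.5 / 400)
    expect_lt(abs(ot$n_INDEL[i] / ot$n_total[i] - cat_frac["INDEL"]),
              1.5 / 400)
  }
})

test_that("truncated FASTQ records are dropped with a warning", {
  d <- fixture_design_single_exon()
  path <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", d$reference, "+", strrep("F", nchar(d$reference)),
               "@r2", d$reference), path)
  expect_warning(ot <- quantify_sample(path, d), "truncated")
  expect_equal(ot$n_total, 1)
})
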