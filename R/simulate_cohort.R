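#' Simulate a tumor-sequencing cohort with planted statistical structure
#'
#' Generates the three linked tables consumed by the cohort arm — a
#' somatic mutation table, allele-specific copy-number segments and a
#' clinical table — together with the ground truth used by tests:
#'
#' * Per-gene alteration indicators are Bernoulli with probabilities
#'   `plogis(mu_i + nu_j)`: per-sample effects `nu_j` are normal with SD
#'   `sample_rate_dispersion` (heterogeneous per-tumor alteration
#'   rates), and the per-gene intercepts `mu_i` are calibrated so each
#'   gene's marginal rate equals `gene_rates` for the drawn samples.
#' * Planted pairs perturb the joint distribution of two genes toward
#'   exclusivity or cooccurrence while preserving both margins (an
#'   altered sample of one gene is relocated with probability
#'   `strength`); strength 1 exclusivity leaves zero overlap.
#' * Samples are split across sequencing platforms with
#'   platform-specific burden scale factors; nonsynonymous counts are
#'   Poisson around a lognormal per-sample burden.
#' * Survival is exponential with group-specific hazards (mutant vs
#'   wild-type in `survival$gene`) under independent exponential
#'   censoring.
#' * A synthetic locus sequence is emitted along with locus-restricted
#'   mutations drawn from a trinucleotide signature mixture, for
#'   spectrum/refitting tests.
#' * A fraction of focal-gene-mutant samples carries a minor-copy-0
#'   segment over the locus (planted LOH), and a fraction has no
#'   overlapping segment (missing copy-number information).
#'
#' @param n_samples Number of tumors.
#' @param gene_rates Named vector of marginal alteration probabilities.
#' @param sample_rate_dispersion SD of the per-sample logit effect
#'   (0 = homogeneous samples).
#' @param planted_pairs data.frame with `geneA`, `geneB`, `direction`
#'   (`"exclusive"`/`"cooccurring"`), `strength` in \[0, 1\].
#' @param platforms data.frame with `name`, `fraction`, `tmb_scale`;
#'   names must be registered in [tmb_platform_mb()].
#' @param survival List: `gene`, `hazard_mut`, `hazard_wt`,
#'   `censor_hazard` (per month).
#' @param signature_mixture Named exposure vector over the columns of
#'   `signatures` (counts; sums to the number of locus mutations drawn).
#' @param signatures 96 x K signature matrix (columns sum to 1);
#'   default [synthetic_signature_matrix()].
#' @param locus List: `gene`, `chrom`, `start`, `end` (1-based) of the
#'   focal locus.
#' @param loh_fraction,loh_na_fraction Fractions of focal-gene-mutant
#'   samples with planted LOH and with missing segments.
#' @param hd_fraction Fraction of focal-gene variants placed inside the
#'   helicase-domain intervals.
#' @param response_rate_mut,response_rate_wt Therapy response
#'   probabilities by focal-gene status.
#' @param seed Integer seed; fixed seed reproduces all tables exactly.
#' @return List of class `cohort_bundle`: `mutations`, `segments`,
#'   `clinical`, `locus_reference`, `locus_mutations`, `alteration_truth`
#'   (binary gene x sample matrix), and `truth` (all planted parameters).
#' @export
simulate_cohort <- function(n_samples = 300L,
                            gene_rates = c(TP53 = 0.50, ERCC2 = 0.12,
                                           RB1 = 0.20, KDM6A = 0.25,
                                           FGFR3 = 0.15, ARID1A = 0.25,
                                           STAG2 = 0.12, HRAS = 0.08,
                                           KMT2D = 0.28, ERBB2 = 0.10),
                            sample_rate_dispersion = 1,
                            planted_pairs = NULL,
                            platforms = data.frame(
                              name = c("WES", "MSK468"),
                              fraction = c(0.6, 0.4),
                              tmb_scale = c(1, 2.5)),
                            survival = list(gene = "ERCC2",
                                            hazard_mut = 0.03,
                                            hazard_wt = 0.06,
                                            censor_hazard = 0.02),
                            signature_mixture = NULL,
                            signatures = synthetic_signature_matrix(),
                            locus = list(gene = "ERCC2", chrom = "chr19",
                                         start = 45350001L,
                                         end = 45370000L),
                            loh_fraction = 0.05,
                            loh_na_fraction = 0.13,
                            hd_fraction = 0.87,
                            response_rate_mut = 0.70,
                            response_rate_wt = 0.35,
                            seed = 1L) {
  if (any(gene_rates < 0 | gene_rates > 1)) stop("rates must lie in [0, 1]")
  if (sample_rate_dispersion < 0) stop("dispersion must be nonnegative")
  stopifnot(survival$hazard_mut > 0, survival$hazard_wt > 0)
  set.seed(seed)
  genes <- names(gene_rates)
  samples <- sprintf("S%04d", seq_len(n_samples))

  # --- alteration matrix with heterogeneous per-sample rates ---------
  nu <- if (sample_rate_dispersion > 0)
    stats::rnorm(n_samples, 0, sample_rate_dispersion) else numeric(n_samples)
  A <- matrix(0L, length(genes), n_samples,
              dimnames = list(genes, samples))
  P_true <- matrix(0, length(genes), n_samples,
                   dimnames = list(genes, samples))
  for (i in seq_along(genes)) {
    mu <- calibrate_logit_intercept(gene_rates[i], nu)
    P_true[i, ] <- stats::plogis(mu + nu)
    A[i, ] <- stats::rbinom(n_samples, 1L, P_true[i, ])
  }

  # --- planted exclusivity / cooccurrence, margin-preserving ---------
  if (!is.null(planted_pairs)) {
    planted_pairs <- as.data.frame(planted_pairs)
    unknown <- setdiff(unique(c(planted_pairs$geneA, planted_pairs$geneB)),
                       genes)
    if (length(unknown))
      stop("unknown gene in planted_pairs: ", paste(unknown, collapse = ", "))
    for (k in seq_len(nrow(planted_pairs))) {
      ga <- planted_pairs$geneA[k]; gb <- planted_pairs$geneB[k]
      dir <- planted_pairs$direction[k]; s <- planted_pairs$strength[k]
      a <- A[ga, ]; b <- A[gb, ]
      if (dir == "exclusive") {
        from <- which(a == 1L & b == 1L)
        to_pool <- which(a == 0L & b == 0L)
      } else {
        from <- which(a == 0L & b == 1L)
        to_pool <- which(a == 1L & b == 0L)
      }
      move <- from[stats::runif(length(from)) < s]
      move <- move[seq_len(min(length(move), length(to_pool)))]
      if (length(move)) {
        dest <- sample(to_pool, length(move))
        b[move] <- 0L; b[dest] <- 1L
        A[gb, ] <- b
      }
    }
  }

  # --- platforms and burden ------------------------------------------
  plat <- sample(platforms$name, n_samples, TRUE, prob = platforms$fraction)
  scale <- platforms$tmb_scale[match(plat, platforms$name)]
  mb <- tmb_platform_mb()[plat]
  true_tmb <- stats::rlnorm(n_samples, meanlog = log(4), sdlog = 0.6)
  nonsyn_count <- stats::rpois(n_samples, true_tmb * scale * mb)

  # --- mutation table -------------------------------------------------
  gene_info <- gene_registry(genes)
  rows <- list()
  for (i in seq_along(genes)) {
    g <- genes[i]
    carriers <- which(A[g, ] == 1L)
    if (!length(carriers)) next
    n <- length(carriers)
    focal <- g == locus$gene
    cls <- if (focal)
      sample(c("missense", "stopgain", "frameshift", "nonstop"), n, TRUE,
             prob = c(0.93, 0.03, 0.03, 0.01))
    else
      sample(c("missense", "stopgain", "frameshift", "splice", "nonstop"),
             n, TRUE, prob = c(0.60, 0.13, 0.16, 0.09, 0.02))
    plen <- gene_info$protein_length[i]
    if (focal) {
      hd <- ercc2_helicase_domains()
      hd_pos <- unlist(mapply(seq, hd$start, hd$end, SIMPLIFY = FALSE))
      out_pos <- setdiff(seq_len(plen), hd_pos)
      in_hd <- stats::runif(n) < hd_fraction
      ppos <- ifelse(in_hd, sample(hd_pos, n, TRUE), sample(out_pos, n, TRUE))
    } else {
      ppos <- sample.int(plen, n, TRUE)
    }
    label <- sample(c("pathogenic", "likely_pathogenic", "VUS"), n, TRUE,
                    prob = c(0.6, 0.2, 0.2))
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
    rows[[g]] <- data.frame(
      sample = samples[carriers], gene = g,
      chrom = gene_info$chrom[i],
      pos = gene_info$start[i] + ppos * 3L,
      ref = ref, alt = alt, variant_class = cls,
      protein_pos = ppos,
      pathogenicity_label = label,
      platform = plat[carriers],
      platform_class = ifelse(plat[carriers] == "WES", "WES", "panel"),
      stringsAsFactors = FALSE)
  }
  # benign noise rows that the alteration filter must remove
  n_noise <- stats::rbinom(1, n_samples, 0.10)
  if (n_noise > 0) {
    j <- sample.int(n_samples, n_noise)
    gi <- sample(seq_along(genes), n_noise, TRUE)
    rows[["noise"]] <- data.frame(
      sample = samples[j], gene = genes[gi],
      chrom = gene_info$chrom[gi],
      pos = gene_info$start[gi] + 5L,
      ref = "C", alt = "T", variant_class = "synonymous",
      protein_pos = sample.int(400L, n_noise, TRUE),
      pathogenicity_label = "benign",
      platform = plat[j],
      platform_class = ifelse(plat[j] == "WES", "WES", "panel"),
      stringsAsFactors = FALSE)
  }
  mutations <- do.call(rbind, rows)
  rownames(mutations) <- NULL

  # --- locus reference and signature-mixture mutations ---------------
  locus_len <- locus$end - locus$start + 1L
  locus_seq <- paste(sample(c("A", "C", "G", "T"), locus_len, TRUE),
                     collapse = "")
  if (is.null(signature_mixture)) {
    signature_mixture <- stats::setNames(numeric(ncol(signatures)),
                                         colnames(signatures))
    signature_mixture[1:2] <- c(300, 200)
  }
  locus_mutations <- draw_signature_mutations(
    locus_seq, locus$chrom, locus$start, signatures, signature_mixture,
    samples = samples[A[locus$gene, ] == 1L])
  # faidx-style region name so absolute coordinates resolve on the
  # locus-restricted sequence
  locus_reference <- stats::setNames(
    locus_seq, sprintf("%s:%d-%d", locus$chrom, locus$start, locus$end))

  # --- copy-number segments ------------------------------------------
  seg_rows <- list()
  mutant <- A[locus$gene, ] == 1L
  u <- stats::runif(n_samples)
  for (j in seq_len(n_samples)) {
    if (mutant[j] && u[j] < loh_na_fraction) next   # no overlapping segment
    minor <- if (mutant[j] && u[j] >= loh_na_fraction &&
                 u[j] < loh_na_fraction + loh_fraction) 0L
             else sample(1:2, 1, prob = c(0.8, 0.2))
    major <- minor + sample(0:2, 1, prob = c(0.5, 0.4, 0.1))
    seg_rows[[j]] <- data.frame(
      sample = samples[j], chrom = locus$chrom,
      start = locus$start - 500000L, end = locus$end + 500000L,
      major_cn = major, minor_cn = minor, stringsAsFactors = FALSE)
  }
  segments <- do.call(rbind, seg_rows)
  rownames(segments) <- NULL

  # --- clinical table -------------------------------------------------
  hz <- ifelse(mutant, survival$hazard_mut, survival$hazard_wt)
  t_event <- stats::rexp(n_samples, hz)
  t_cens <- stats::rexp(n_samples, survival$censor_hazard)
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)
  response <- stats::rbinom(n_samples, 1L,
                            ifelse(mutant, response_rate_mut,
                                   response_rate_wt))
  clinical <- data.frame(
    sample = samples, cohort = "synthetic", platform = plat,
    platform_class = ifelse(plat == "WES", "WES", "panel"),
    nonsyn_count = nonsyn_count,
    time = time, event = event,
    response = c("nonresponder", "responder")[response + 1L],
    treatment = "platinum", stringsAsFactors = FALSE)

  structure(list(mutations = mutations, segments = segments,
                 clinical = clinical,
                 locus_reference = locus_reference,
                 locus_mutations = locus_mutations,
                 alteration_truth = A,
                 truth = list(gene_rates = gene_rates, p = P_true, nu = nu,
                              planted_pairs = planted_pairs,
                              platforms = platforms, survival = survival,
                              signature_mixture = signature_mixture,
                              locus = locus, loh_fraction = loh_fraction,
                              loh_na_fraction = loh_na_fraction,
                              true_tmb = true_tmb, seed = seed)),
            class = "cohort_bundle")
}

# Newton solve for the gene intercept giving the target marginal rate
# over the drawn sample effects.
calibrate_logit_intercept <- function(rate, nu) {
  if (rate <= 0) return(-Inf)
  if (rate >= 1) return(Inf)
  mu <- stats::qlogis(rate)
  for (i in 1:50) {
    p <- stats::plogis(mu + nu)
    f <- mean(p) - rate
    if (abs(f) < 1e-12) break
    mu <- mu - f / max(mean(p * (1 - p)), 1e-12)
  }
  mu
}

# synthetic gene coordinates/protein lengths for table emission
gene_registry <- function(genes) {
  n <- length(genes)
  data.frame(gene = genes,
             chrom = paste0("chr", 1L + (seq_len(n) - 1L) %% 22L),
             start = 1000000L * seq_len(n),
             protein_length = ifelse(genes == "ERCC2", 760L,
                                     400L + 37L * seq_len(n)),
             stringsAsFactors = FALSE)
}

#' Synthetic 96-channel signature matrix
#'
#' Builds K sparse, well-separated probability columns over the 96 SBS
#' channels for simulations and tests. This is a synthetic stand-in
#' labelled as such — supply a real reference signature table (e.g. a
#' COSMIC subset as TSV via [read_signature_matrix()]) for real
#' analyses.
#'
#' @param k Number of signatures.
#' @param peaks Number of dominant channels per signature.
#' @param seed Seed for the construction (fixed default so the matrix is
#'   a constant).
#' @return 96 x k matrix, columns summing to 1, named `SYN1..SYNk`.
#' @export
synthetic_signature_matrix <- function(k = 6L, peaks = 8L, seed = 421L) {
  ch <- sbs96_channels()
  rng <- local({ set.seed(seed); lapply(seq_len(k), function(i)
    list(idx = sample(96L, peaks),
         w = stats::rgamma(peaks, 2, 1),
         floor = stats::rgamma(96L, 0.3, 1))) })
  S <- vapply(rng, function(r) {
    v <- r$floor * 0.02
    v[r$idx] <- v[r$idx] + r$w
    v / sum(v)
  }, numeric(96))
  dimnames(S) <- list(ch, paste0("SYN", seq_len(k)))
  S
}

#' Read or write a signature matrix as TSV
#'
#' 96 rows in conventional channel order; first column `channel`,
#' remaining columns one per signature.
#'
#' @param path TSV path.
#' @param signatures 96 x K matrix (for writing).
#' @return `read_signature_matrix` returns the 96 x K matrix.
#' @export
read_signature_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  S <- as.matrix(df[, -1, drop = FALSE])
  rownames(S) <- df[[1]]
  S <- S[sbs96_channels(), , drop = FALSE]
  S
}

#' @rdname read_signature_matrix
#' @export
write_signature_matrix <- function(signatures, path) {
  df <- data.frame(channel = rownames(signatures), signatures,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Draw locus-restricted SNVs whose pooled spectrum follows the
# signature mixture. Positions are chosen among locus sites matching
# each sampled channel's trinucleotide context on either strand.
draw_signature_mutations <- function(locus_seq, chrom, offset, signatures,
                                     exposures, samples) {
  n_mut <- round(sum(exposures))
  if (n_mut == 0 || !length(samples))
    return(data.frame(sample = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0),
                      alt = character(0), stringsAsFactors = FALSE))
  pc <- drop(as.matrix(signatures) %*% (exposures / sum(exposures)))
  ch <- sbs96_channels()
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  s <- strsplit(locus_seq, "", fixed = TRUE)[[1]]
  L <- length(s)
  tri_up <- s[seq_len(L - 2L)]
  tri_mid <- s[seq_len(L - 2L) + 1L]
  tri_dn <- s[seq_len(L - 2L) + 2L]
  # context key on the pyrimidine strand for every interior position
  pyr <- tri_mid %in% c("C", "T")
  key <- ifelse(pyr,
                paste0(tri_up, tri_mid, tri_dn),
                paste0(comp[tri_dn], comp[tri_mid], comp[tri_up]))
  pos_by_key <- split(seq_len(L - 2L) + 1L, key)   # locus positions (1-based)
  drawn <- sample(ch, n_mut, TRUE, prob = pc)
  out <- vector("list", n_mut)
  for (i in seq_len(n_mut)) {
    lab <- drawn[i]
    up <- substring(lab, 1, 1); refp <- substring(lab, 3, 3)
    altp <- substring(lab, 5, 5); dn <- substring(lab, 7, 7)
    cand <- pos_by_key[[paste0(up, refp, dn)]]
    if (is.null(cand)) next                        # context absent; rare
    p <- cand[sample.int(length(cand), 1)]
    if (s[p] %in% c("C", "T")) { ref <- refp; alt <- altp }
    else { ref <- s[p]; alt <- comp[altp] }
    out[[i]] <- data.frame(sample = samples[sample.int(length(samples), 1)],
                           chrom = chrom, pos = offset + p - 1L,
                           ref = ref, alt = alt, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
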