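#' Helicase-domain mutation status of one sample
#'
#' A sample is MUT when it carries at least one missense or truncating
#' (stopgain, frameshift, or nonstop) variant whose protein position
#' falls inside a helicase-domain interval. Variants of other classes,
#' or qualifying variants outside the intervals, leave the sample WT.
#'
#' @param mutations data.frame of one sample's variants in the gene of
#'   interest, with columns `variant_class` and `protein_pos`.
#' @param helicase_intervals data.frame with 1-based inclusive `start`
#'   and `end` protein-residue columns (non-overlapping).
#' @return `"MUT"` or `"WT"`.
#' @export
classify_ercc2_status <- function(mutations,
                                  helicase_intervals = ercc2_helicase_domains()) {
  qual <- c("missense", "stopgain", "frameshift", "nonstop")
  if (is.null(mutations) || nrow(mutations) == 0L) return("WT")
  m <- mutations[mutations$variant_class %in% qual, , drop = FALSE]
  if (nrow(m) == 0L) return("WT")
  if (any(is.na(m$protein_pos))) {
    warning("qualifying variant without protein position skipped")
    m <- m[!is.na(m$protein_pos), , drop = FALSE]
  }
  hit <- vapply(m$protein_pos, function(p)
    any(p >= helicase_intervals$start & p <= helicase_intervals$end),
    logical(1))
  if (any(hit)) "MUT" else "WT"
}

#' Default helicase-domain residue intervals
#'
#' Helicase-domain intervals are configuration, not code: supply the
#' residue ranges appropriate for the transcript in use. This default
#' covers the two conserved helicase domains of the XPD/ERCC2 helicase
#' fold as commonly annotated (roughly the N-terminal HD1 and C-terminal
#' HD2 ATPase lobes), and exists so that examples and simulations run
#' out of the box.
#'
#' @return data.frame with `start`/`end` residue columns (1-based,
#'   inclusive).
#' @export
ercc2_helicase_domains <- function() {
  data.frame(start = c(6L, 440L), end = c(260L, 730L))
}

#' TP53 mutation status of one sample
#'
#' MUT when any variant carries a pathogenic or likely-pathogenic label,
#' or when the gene is deeply deleted; variants of uncertain
#' significance (VUS) and benign labels leave the sample WT.
#'
#' @param mutations data.frame with a `pathogenicity_label` column
#'   (values such as `"pathogenic"`, `"likely_pathogenic"`, `"VUS"`,
#'   `"benign"`).
#' @param deep_deletion_flag Logical; homozygous deletion of the gene.
#' @return `"MUT"` or `"WT"`.
#' @export
classify_tp53_status <- function(mutations, deep_deletion_flag = FALSE) {
  if (isTRUE(deep_deletion_flag)) return("MUT")
  if (is.null(mutations) || nrow(mutations) == 0L) return("WT")
  hit <- tolower(mutations$pathogenicity_label) %in%
    c("pathogenic", "likely_pathogenic", "likely pathogenic")
  if (any(hit)) "MUT" else "WT"
}

#' Loss of heterozygosity from allele-specific copy-number segments
#'
#' LOH is registered when any copy-number segment overlapping the gene
#' interval has a minor copy number of 0. With overlapping segments all
#' at minor copy number >= 1 the call is no_LOH; with no overlapping
#' segment the call is NA (no information).
#'
#' @param gene_interval List or row with `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @param segments data.frame of one sample's segments: `chrom`,
#'   `start`, `end`, `major_cn`, `minor_cn`.
#' @return `"LOH"`, `"no_LOH"`, or `NA_character_`.
#' @export
call_loh <- function(gene_interval, segments) {
  if (any(segments$start > segments$end))
    stop("malformed segment: start > end")
  ov <- segments$chrom == gene_interval$chrom &
    segments$start <= gene_interval$end &
    segments$end >= gene_interval$start
  if (!any(ov)) return(NA_character_)
  if (any(segments$minor_cn[ov] == 0)) "LOH" else "no_LOH"
}

#' Registered sequencing-platform footprint sizes
#'
#' Megabases of genome covered per platform, used as the TMB
#' denominator: whole-exome sequencing is approximated as 38 Mb; the
#' targeted-panel footprints are the published per-version covered
#' sizes (DFCI OncoPanel v1-v3, MSK-IMPACT 341/410/468/505-gene panels,
#' Caris).
#'
#' @return Named numeric vector of Mb constants.
#' @export
tmb_platform_mb <- function() {
  c(WES = 38,
    OncoPanel_v1 = 0.753334, OncoPanel_v2 = 0.826167,
    OncoPanel_v3 = 1.315078,
    MSK341 = 0.896665, MSK410 = 1.016478, MSK468 = 1.139322,
    MSK505 = 1.25964,
    Caris = 1.4)
}

#' Tumor mutation burden of one or more samples
#'
#' TMB = nonsynonymous mutation count divided by the registered covered
#' footprint (mutations per Mb) of the sample's platform.
#'
#' @param count Nonsynonymous mutation count(s).
#' @param platform Platform name(s); must be registered (see
#'   [tmb_platform_mb()]) or present in `registry`.
#' @param registry Named Mb constants; defaults to [tmb_platform_mb()].
#' @return data.frame with `count`, `platform`, `covered_mb`, `tmb`.
#' @export
compute_tmb <- function(count, platform, registry = tmb_platform_mb()) {
  platform <- as.character(platform)
  unknown <- setdiff(unique(platform), names(registry))
  if (length(unknown))
    stop("unknown platform(s): ", paste(unknown, collapse = ", "))
  mb <- unname(registry[platform])
  data.frame(count = count, platform = platform, covered_mb = mb,
             tmb = count / mb, stringsAsFactors = FALSE)
}

#' Harmonize TMB across platforms by stratum z-scores
#'
#' Standardizes log10(TMB + 1) within each platform stratum to zero mean
#' and unit (sample) standard deviation, making burdens comparable
#' across capture footprints. Strata of size 1 or with zero spread get
#' `NA` with a warning.
#'
#' @param records data.frame with `tmb` and a stratum column.
#' @param stratum Name of the stratum column (default `"platform"`).
#' @return The input with `log_tmb` and `z` columns appended.
#' @export
harmonize_tmb <- function(records, stratum = "platform") {
  records <- as.data.frame(records)
  records$log_tmb <- log10(records$tmb + 1)
  records$z <- NA_real_
  for (s in unique(records[[stratum]])) {
    i <- which(records[[stratum]] == s)
    if (length(i) < 2L) {
      warning("stratum '", s, "' has fewer than 2 samples: z set to NA")
      next
    }
    sdv <- stats::sd(records$log_tmb[i])
    if (sdv == 0) {
      warning("stratum '", s, "' has zero spread: z set to NA")
      next
    }
    records$z[i] <- (records$log_tmb[i] - mean(records$log_tmb[i])) / sdv
  }
  records
}

#' The 96 single-base-substitution channels in conventional order
#'
#' Pyrimidine-centered substitution types (C>A, C>G, C>T, T>A, T>C,
#' T>G) major, flanking bases alphabetical minor — the conventional
#' COSMIC channel ordering.
#'
#' @return Character vector of 96 labels like `"A[C>A]A"`.
#' @export
sbs96_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s)
    as.vector(t(outer(bases, bases, function(f, t)
      paste0(f, "[", s, "]", t))))))
}

#' Build a 96-channel SBS spectrum from mutations at a locus
#'
#' Counts single-base substitutions by pyrimidine-centered substitution
#' type and trinucleotide context. Purine-reference mutations are
#' counted on the reverse-complement strand; indels and multi-nucleotide
#' variants are excluded (their count is reported as an attribute);
#' variants whose stated reference allele disagrees with the reference
#' sequence are skipped with a warning.
#'
#' @param mutations data.frame with `chrom`, `pos` (1-based), `ref`,
#'   `alt`.
#' @param reference Named character vector / DNAStringSet of chromosome
#'   sequences, or a FASTA path.
#' @return Named integer vector of 96 counts (class `spectrum96`), with
#'   attributes `n_snv`, `n_excluded`, `n_skipped`.
#' @export
build_spectrum96 <- function(mutations, reference) {
  if (is.character(reference) && length(reference) == 1L &&
      file.exists(reference))
    reference <- Biostrings::readDNAStringSet(reference)
  if (methods::is(reference, "DNAStringSet")) {
    nm <- sub("\\s.*", "", names(reference))
    reference <- stats::setNames(as.character(reference), nm)
  }
  # region-named records ("chrom:start-end", faidx convention) map a
  # sub-sequence to absolute coordinates
  region <- regmatches(names(reference),
                       regexec("^(.+):(\\d+)-(\\d+)$", names(reference)))
  ref_chrom <- vapply(seq_along(reference), function(i)
    if (length(region[[i]])) region[[i]][2] else names(reference)[i],
    character(1))
  ref_offset <- vapply(seq_along(reference), function(i)
    if (length(region[[i]])) as.integer(region[[i]][3]) - 1L else 0L,
    integer(1))
  channels <- sbs96_channels()
  counts <- stats::setNames(integer(96), channels)
  is_snv <- nchar(mutations$ref) == 1L & nchar(mutations$alt) == 1L &
    mutations$ref %in% c("A", "C", "G", "T") &
    mutations$alt %in% c("A", "C", "G", "T")
  n_excluded <- sum(!is_snv)
  m <- mutations[is_snv, , drop = FALSE]
  n_skipped <- 0L
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (i in seq_len(nrow(m))) {
    chrom <- as.character(m$chrom[i]); pos <- m$pos[i]
    hit <- which(ref_chrom == chrom)
    if (length(hit) > 1L)   # several regions of one chromosome
      hit <- hit[pos > ref_offset[hit] &
                 pos <= ref_offset[hit] + nchar(reference[hit])]
    if (!length(hit)) {
      warning("chromosome ", chrom, " not in reference; mutation skipped")
      n_skipped <- n_skipped + 1L; next
    }
    seq <- reference[[hit[1]]]
    pos <- pos - ref_offset[hit[1]]
    if (pos < 2L || pos > nchar(seq) - 1L) {
      warning("mutation at ", chrom, ":", pos, " outside reference; skipped")
      n_skipped <- n_skipped + 1L; next
    }
    tri <- substring(seq, pos - 1L, pos + 1L)
    ref <- m$ref[i]; alt <- m$alt[i]
    if (substring(tri, 2, 2) != ref) {
      warning("reference allele mismatch at ", chrom, ":", pos, "; skipped")
      n_skipped <- n_skipped + 1L; next
    }
    up <- substring(tri, 1, 1); down <- substring(tri, 3, 3)
    if (ref %in% c("A", "G")) {   # collapse to pyrimidine strand
      new_up <- comp[down]; new_down <- comp[up]
      ref <- comp[ref]; alt <- comp[alt]
      up <- new_up; down <- new_down
    }
    ch <- paste0(up, "[", ref, ">", alt, "]", down)
    counts[ch] <- counts[ch] + 1L
  }
  structure(counts, n_snv = sum(counts), n_excluded = n_excluded,
            n_skipped = n_skipped, class = c("spectrum96", "integer"))
}

#' Fit signature exposures by nonnegative least squares
#'
#' Estimates the contribution of each reference signature to an observed
#' 96-channel spectrum by minimizing ||C - S e||_2 subject to e >= 0,
#' using the Lawson-Hanson active-set algorithm.
#'
#' @param spectrum Numeric vector of 96 channel counts.
#' @param signatures 96 x K matrix; columns nonnegative, each summing
#'   to 1 (tolerance 1e-6).
#' @return List of class `exposure_fit`: `exposures` (named, >= 0),
#'   `residual_norm`, `fitted`.
#' @export
fit_signatures_nnls <- function(spectrum, signatures) {
  S <- as.matrix(signatures)
  if (ncol(S) == 0L) stop("no signatures supplied")
  if (nrow(S) != length(spectrum))
    stop("signature matrix rows must match spectrum length")
  if (any(S < 0)) stop("signature columns must be nonnegative")
  if (any(abs(colSums(S) - 1) > 1e-6))
    stop("signature columns must each sum to 1")
  e <- nnls_lawson_hanson(S, as.numeric(spectrum))
  names(e) <- colnames(S)
  fitted <- drop(S %*% e)
  structure(list(exposures = e,
                 residual_norm = sqrt(sum((spectrum - fitted)^2)),
                 fitted = fitted),
            class = "exposure_fit")
}

# Lawson-Hanson active-set NNLS: minimize ||A x - b|| s.t. x >= 0.
nnls_lawson_hanson <- function(A, b, tol = NULL, max_iter = 10 * ncol(A)) {
  n <- ncol(A)
  if (is.null(tol)) tol <- 1e-10 * max(1, max(abs(crossprod(A, b))))
  x <- numeric(n)
  passive <- logical(n)
  w <- drop(crossprod(A, b - A %*% x))
  iter <- 0L
  while (any(!passive) && max(w[!passive]) > tol && iter < max_iter) {
    iter <- iter + 1L
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      z <- numeric(n)
      P <- which(passive)
      z[P] <- qr.coef(qr(A[, P, drop = FALSE]), b)
      z[is.na(z)] <- 0
      if (all(z[P] > tol)) break
      neg <- P[z[P] <= tol]
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive[P[x[P] <= tol]] <- FALSE
      x[!passive] <- 0
    }
    x <- z
    w <- drop(crossprod(A, b - A %*% x))
  }
  pmax(x, 0)
}

#' Domain-enrichment test for mutation positions
#'
#' Tests whether the observed fraction of variants inside a domain
#' exceeds the fraction expected if variants occurred uniformly along
#' the gene (the domain's length fraction), via the chi-square
#' goodness-of-fit test on the in/out split.
#'
#' @param n_in_domain Variants inside the domain.
#' @param n_total Total variants (>= `n_in_domain`).
#' @param domain_length_fraction Domain length as a fraction of the gene
#'   (0 < f < 1).
#' @return A [cs_test()].
#' @export
domain_enrichment_test <- function(n_in_domain, n_total,
                                   domain_length_fraction) {
  if (domain_length_fraction <= 0 || domain_length_fraction >= 1)
    stop("domain length fraction must lie strictly between 0 and 1")
  if (n_total < n_in_domain) stop("n_total must be >= n_in_domain")
  chi_square_gof(c(n_in_domain, n_total - n_in_domain),
                 c(domain_length_fraction, 1 - domain_length_fraction))
}
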