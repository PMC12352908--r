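#' Allele and genotype specifications for simulated editing outcomes
#'
#' A diploid genotype pairs two allele outcomes with per-day growth
#' multipliers. Allele outcomes are the four editing classes produced by
#' a CRISPR-Select experiment: knock-in of the mutation of interest
#' (`allele_mut_ki()`), knock-in of the synonymous control
#' (`allele_wtstar_ki()`), no edit (`allele_unedited()`), or an InDel at
#' the cut site (`allele_indel()`, with a signed net length change).
#'
#' `base_fitness` is the per-day growth multiplier in untreated medium;
#' `cisplatin_fitness` the multiplier applied on days falling inside the
#' treatment window of a treated culture.
#'
#' @param allele1,allele2 Allele outcomes built by the `allele_*()` helpers.
#' @param base_fitness,cisplatin_fitness Per-day growth multipliers (>= 0).
#' @param position 0-based start of a deletion, or the insertion point,
#'   in amplicon coordinates.
#' @param net_length Signed net length change; negative for deletions,
#'   positive for insertions, never 0.
#' @return `genotype_spec()` returns a `genotype_spec` object; the
#'   `allele_*()` helpers return allele outcome descriptors.
#' @export
genotype_spec <- function(allele1, allele2, base_fitness = 1,
                          cisplatin_fitness = base_fitness) {
  stopifnot(is.finite(base_fitness), base_fitness >= 0,
            is.finite(cisplatin_fitness), cisplatin_fitness >= 0)
  structure(list(allele1 = allele1, allele2 = allele2,
                 base_fitness = base_fitness,
                 cisplatin_fitness = cisplatin_fitness),
            class = "genotype_spec")
}

#' @rdname genotype_spec
#' @export
allele_mut_ki <- function() list(type = "MUT_KI")

#' @rdname genotype_spec
#' @export
allele_wtstar_ki <- function() list(type = "WTSTAR_KI")

#' @rdname genotype_spec
#' @export
allele_unedited <- function() list(type = "UNEDITED")

#' @rdname genotype_spec
#' @export
allele_indel <- function(position, net_length) {
  stopifnot(net_length != 0)
  list(type = "INDEL", position = as.integer(position),
       net_length = as.integer(net_length))
}

allele_key <- function(a) {
  if (a$type == "INDEL") paste("INDEL", a$position, a$net_length, sep = ":")
  else a$type
}

#' Construct the DNA sequence of one allele of an amplicon
#'
#' Applies a knock-in substitution set or a cut-site InDel to the design
#' reference. Inserted bases duplicate the base at the insertion point
#' (templated-duplication-like), keeping the simulator deterministic.
#'
#' @param design An [amplicon_design()].
#' @param allele An allele outcome descriptor.
#' @return Character string with the allele sequence.
#' @export
allele_sequence <- function(design, allele) {
  ref <- design$reference
  switch(allele$type,
    UNEDITED = ref,
    MUT_KI = apply_substitutions(ref, design$mut_substitutions),
    WTSTAR_KI = apply_substitutions(ref, design$wtstar_substitutions),
    INDEL = {
      p <- allele$position; k <- allele$net_length
      if (k < 0) {
        if (p + abs(k) > nchar(ref)) stop("deletion runs off the amplicon")
        paste0(substring(ref, 1L, p), substring(ref, p + abs(k) + 1L))
      } else {
        ins <- strrep(substring(ref, p + 1L, p + 1L), k)
        paste0(substring(ref, 1L, p), ins, substring(ref, p + 1L))
      }
    },
    stop("unknown allele type: ", allele$type))
}

apply_substitutions <- function(ref, subs) {
  s <- strsplit(ref, "", fixed = TRUE)[[1]]
  s[subs$position + 1L] <- subs$alt
  paste(s, collapse = "")
}

#' Default genotype mixture of a CRISPR-Select experiment
#'
#' Emulates the editing-outcome composition of the assay: cells with a
#' knock-in on one allele predominantly carry a cut-site InDel on the
#' other, some cells carry biallelic InDels, and a minority remain
#' unedited. The defaults give 85% modified alleles, consistent with the
#' observed guide efficiency of more than 80% modified alleles.
#'
#' The mutation of interest is assigned `mut_cisplatin_fitness` as its
#' per-day multiplier during treatment; the synonymous control is
#' neutral. Frameshift-bearing genotypes grow with `indel_base_fitness`
#' to emulate selection against disruptive InDels in an essential gene.
#'
#' @param design An [amplicon_design()]; the InDel alleles are placed at
#'   its cut site.
#' @param mut_cisplatin_fitness Per-day multiplier of Mut-carrying cells
#'   during cisplatin treatment (1 = neutral).
#' @param mut_base_fitness Per-day multiplier of Mut-carrying cells off
#'   treatment.
#' @param indel_base_fitness Per-day multiplier of biallelic-InDel cells.
#' @param indel_net_lengths Two signed net lengths used for the InDel
#'   alleles.
#' @return List of `list(genotype = genotype_spec, freq = numeric)`
#'   entries with frequencies summing to 1.
#' @export
default_genotype_mix <- function(design, mut_cisplatin_fitness = 1,
                                 mut_base_fitness = 1,
                                 indel_base_fitness = 0.9,
                                 indel_net_lengths = c(-2L, 1L)) {
  cut <- design$cut_site
  del <- allele_indel(cut - 1L, indel_net_lengths[1])
  ins <- allele_indel(cut, indel_net_lengths[2])
  list(
    list(genotype = genotype_spec(allele_mut_ki(), del,
                                  base_fitness = mut_base_fitness,
                                  cisplatin_fitness = mut_cisplatin_fitness),
         freq = 0.32),
    list(genotype = genotype_spec(allele_wtstar_ki(), del), freq = 0.32),
    list(genotype = genotype_spec(del, ins,
                                  base_fitness = indel_base_fitness),
         freq = 0.21),
    list(genotype = genotype_spec(allele_unedited(), allele_unedited()),
         freq = 0.15))
}

# Per-day growth multiplier product from the baseline day to `day`.
genotype_mass <- function(entry, day, baseline, condition, treatment_window) {
  g <- entry$genotype
  if (day < baseline) stop("timepoint before baseline day")
  m <- entry$freq
  if (day > baseline) {
    days <- (baseline + 1L):day
    treated <- condition == "treated" &
      days > treatment_window[1] & days <= treatment_window[2]
    w <- ifelse(treated, g$cisplatin_fitness, g$base_fitness)
    m <- m * prod(w)
  }
  m
}

# Allele fractions (half-weight per genotype allele) at one timepoint.
allele_fractions <- function(mix, day, baseline, condition, treatment_window) {
  masses <- vapply(mix, genotype_mass, numeric(1), day = day,
                   baseline = baseline, condition = condition,
                   treatment_window = treatment_window)
  keys <- lapply(mix, function(e) c(allele_key(e$genotype$allele1),
                                    allele_key(e$genotype$allele2)))
  f <- numeric(0)
  for (i in seq_along(mix)) {
    for (k in keys[[i]]) {
      f[k] <- (if (k %in% names(f)) f[k] else 0) + masses[i] / 2
    }
  }
  f / sum(f)
}

#' Simulate a CRISPR-Select experiment with known ground truth
#'
#' Generates amplicon reads for every timepoint x condition x replicate
#' sample of a knock-in selection experiment. Cell growth is modeled as
#' discrete daily multiplicative updates of genotype masses; reads sample
#' alleles independently (amplicon PCR from pooled genomic DNA cannot
#' phase the two alleles of a cell); sequencing noise is uniform per-base
#' substitution error.
#'
#' The returned truth records the planted allele fractions of every
#' sample and the closed-form expectation of the baseline-normalized
#' Mut:WT* ratio R for each timepoint and condition.
#'
#' @param design An [amplicon_design()].
#' @param genotype_mix List of `list(genotype, freq)` entries (see
#'   [default_genotype_mix()]); frequencies must sum to 1 (tolerance
#'   1e-9).
#' @param timepoints Integer day numbers; must include `baseline_day`.
#' @param conditions Subset of `c("untreated", "treated")`.
#' @param treatment_window Two days `(start, end]`; cisplatin fitness
#'   applies to treated cultures on days `start+1 .. end`.
#' @param depth Reads per sample (> 0).
#' @param error_rate Per-base substitution error probability.
#' @param replicates Number of independent replicates.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @param deterministic If `TRUE`, read counts are exactly proportional
#'   to allele fractions (largest-remainder rounding) and no errors are
#'   applied regardless of `error_rate`.
#' @param baseline_day Baseline harvest day (default 2, the assay's D2).
#' @param fastq_dir If non-`NULL`, write one FASTQ file per sample there.
#' @return List with `samples` (sample sheet), `reads` (named list of
#'   character vectors), and `truth` (allele fractions, expected R,
#'   seed).
#' @export
simulate_select_experiment <- function(design, genotype_mix,
                                       timepoints = c(2L, 12L),
                                       conditions = c("untreated", "treated"),
                                       treatment_window = c(2L, 12L),
                                       depth = 5000L,
                                       error_rate = 0.005,
                                       replicates = 3L,
                                       seed = 1L,
                                       deterministic = FALSE,
                                       baseline_day = 2L,
                                       fastq_dir = NULL) {
  freqs <- vapply(genotype_mix, function(e) e$freq, numeric(1))
  if (abs(sum(freqs) - 1) > 1e-9)
    stop("genotype frequencies must sum to 1")
  if (depth <= 0) stop("depth must be positive")
  if (!baseline_day %in% timepoints)
    stop("timepoints must include the baseline day")
  conditions <- match.arg(conditions, c("untreated", "treated"),
                          several.ok = TRUE)
  set.seed(seed)

  # planted allele fractions and expected normalized ratio
  grid <- expand.grid(timepoint = sort(timepoints), condition = conditions,
                      stringsAsFactors = FALSE)
  frac <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid)))
    frac[[i]] <- allele_fractions(genotype_mix, grid$timepoint[i],
                                  baseline_day, grid$condition[i],
                                  treatment_window)
  names(frac) <- paste(grid$timepoint, grid$condition, sep = ":")
  ratio_of <- function(f) unname(f["MUT_KI"] / f["WTSTAR_KI"])
  grid$R_expected <- vapply(seq_len(nrow(grid)), function(i) {
    base <- frac[[paste(baseline_day, grid$condition[i], sep = ":")]]
    ratio_of(frac[[i]]) / ratio_of(base)
  }, numeric(1))

  # allele sequences, built once
  keys <- unique(unlist(lapply(frac, names)))
  seqs <- vapply(keys, function(k) allele_sequence(design, parse_allele_key(k)),
                 character(1))

  samples <- expand.grid(replicate = seq_len(replicates),
                         condition = conditions,
                         timepoint = sort(timepoints),
                         stringsAsFactors = FALSE)
  samples <- samples[, c("timepoint", "condition", "replicate")]
  samples$sample_id <- sprintf("D%d_%s_rep%d", samples$timepoint,
                               substr(samples$condition, 1, 4),
                               samples$replicate)
  reads <- vector("list", nrow(samples))
  names(reads) <- samples$sample_id
  truth_frac <- vector("list", nrow(samples))
  names(truth_frac) <- samples$sample_id

  for (i in seq_len(nrow(samples))) {
    f <- frac[[paste(samples$timepoint[i], samples$condition[i], sep = ":")]]
    f <- f[keys]; f[is.na(f)] <- 0; names(f) <- keys
    truth_frac[[i]] <- f / sum(f)
    counts <- if (deterministic) round_largest_remainder(depth * f / sum(f))
              else drop(stats::rmultinom(1, depth, f))
    rd <- rep(seqs, counts)
    if (!deterministic && error_rate > 0)
      rd <- apply_substitution_errors(rd, error_rate)
    truth_cat <- rep(sub(":.*", "", keys), counts)
    if (!deterministic) {
      ord <- sample.int(length(rd))
      rd <- rd[ord]; truth_cat <- truth_cat[ord]
    }
    names(rd) <- sprintf("%s:%06d:%s", samples$sample_id[i],
                         seq_along(rd), truth_cat)
    reads[[i]] <- rd
  }

  samples$fastq <- NA_character_
  if (!is.null(fastq_dir)) {
    dir.create(fastq_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(nrow(samples))) {
      path <- file.path(fastq_dir, paste0(samples$sample_id[i], ".fastq"))
      write_fastq(reads[[i]], path)
      samples$fastq[i] <- path
    }
  }

  list(design = design,
       samples = samples,
       reads = reads,
       truth = list(allele_fractions = truth_frac,
                    expected_R = grid,
                    baseline_day = baseline_day,
                    genotype_mix = genotype_mix,
                    seed = seed))
}

parse_allele_key <- function(k) {
  if (startsWith(k, "INDEL:")) {
    parts <- strsplit(k, ":", fixed = TRUE)[[1]]
    allele_indel(as.integer(parts[2]), as.integer(parts[3]))
  } else list(type = k)
}

round_largest_remainder <- function(x) {
  n <- round(sum(x))
  fl <- floor(x)
  rem <- n - sum(fl)
  if (rem > 0) {
    extra <- order(x - fl, decreasing = TRUE)[seq_len(rem)]
    fl[extra] <- fl[extra] + 1
  }
  as.integer(fl)
}

# Uniform per-base substitution errors; handles multiple errors per read
# in rounds so vectorized substr<- assignment stays well-defined.
apply_substitution_errors <- function(reads, rate) {
  lens <- nchar(reads)
  n_err <- stats::rbinom(length(reads), lens, rate)
  hit <- which(n_err > 0)
  if (!length(hit)) return(reads)
  idx <- rep(hit, n_err[hit])
  pos <- floor(stats::runif(length(idx)) * lens[idx]) + 1L
  pick <- floor(stats::runif(length(idx)) * 3) + 1L
  round <- stats::ave(seq_along(idx), idx, FUN = seq_along)
  others <- rbind(A = c("C", "G", "T"), C = c("A", "G", "T"),
                  G = c("A", "C", "T"), T = c("A", "C", "G"))
  for (r in seq_len(max(round))) {
    sel <- round == r
    ii <- idx[sel]; pp <- pos[sel]
    cur <- substr(reads[ii], pp, pp)
    repl <- others[cbind(match(cur, rownames(others)), pick[sel])]
    x <- reads[ii]
    substr(x, pp, pp) <- repl
    reads[ii] <- x
  }
  reads
}

#' Write reads as a 4-line FASTQ file
#'
#' Emits standard Phred+33 FASTQ with a constant quality (Q37 by
#' default). Read names are taken from the vector names, or generated.
#'
#' @param reads Named character vector of read sequences.
#' @param path Output file path.
#' @param quality_char Single quality character (default `"F"`, Q37).
#' @export
write_fastq <- function(reads, path, quality_char = "F") {
  if (is.null(names(reads)))
    names(reads) <- sprintf("read%06d", seq_along(reads))
  lines <- character(4L * length(reads))
  if (length(reads)) {
    lines[seq(1, by = 4, length.out = length(reads))] <- paste0("@", names(reads))
    lines[seq(2, by = 4, length.out = length(reads))] <- reads
    lines[seq(3, by = 4, length.out = length(reads))] <- "+"
    lines[seq(4, by = 4, length.out = length(reads))] <-
      strrep(quality_char, nchar(reads))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Simulate editing-outcome count tables directly
#'
#' Draws per-sample multinomial outcome counts from the same growth model
#' as [simulate_select_experiment()], skipping read emission and
#' classification. Useful for count-level statistical simulations (e.g.
#' type-I error studies of the replicate t test).
#'
#' @inheritParams simulate_select_experiment
#' @return An outcome table (one row per sample) as produced by
#'   [quantify_sample()], with InDel strata attributed from the planted
#'   alleles.
#' @export
simulate_select_counts <- function(design, genotype_mix,
                                   timepoints = c(2L, 12L),
                                   conditions = c("untreated", "treated"),
                                   treatment_window = c(2L, 12L),
                                   depth = 5000L, replicates = 3L,
                                   seed = 1L, baseline_day = 2L) {
  set.seed(seed)
  grid <- expand.grid(replicate = seq_len(replicates),
                      condition = conditions, timepoint = sort(timepoints),
                      stringsAsFactors = FALSE)
  rows <- vector("list", nrow(grid))
  frac_cache <- list()
  for (i in seq_len(nrow(grid))) {
    key <- paste(grid$timepoint[i], grid$condition[i], sep = ":")
    if (is.null(frac_cache[[key]]))
      frac_cache[[key]] <- allele_fractions(genotype_mix, grid$timepoint[i],
                                            baseline_day, grid$condition[i],
                                            treatment_window)
    f <- frac_cache[[key]]
    cnt <- drop(stats::rmultinom(1, depth, f))
    cat_of <- sub(":.*", "", names(f))
    tab <- tapply(cnt, cat_of, sum)
    getc <- function(k) if (k %in% names(tab)) unname(tab[k]) else 0L
    indel_keys <- names(f)[cat_of == "INDEL"]
    strata <- c(fs_exonic = 0L, if_exonic = 0L, fs_intronic = 0L,
                if_intronic = 0L, fs_splice = 0L, if_splice = 0L)
    for (k in indel_keys) {
      a <- parse_allele_key(k)
      lab <- indel_stratum(design, a$position, a$net_length)
      strata[lab] <- strata[lab] + cnt[k]
    }
    rows[[i]] <- data.frame(
      sample_id = sprintf("D%d_%s_rep%d", grid$timepoint[i],
                          substr(grid$condition[i], 1, 4), grid$replicate[i]),
      timepoint = grid$timepoint[i], condition = grid$condition[i],
      replicate = grid$replicate[i], n_total = depth,
      n_MUT_KI = getc("MUT_KI"), n_WTSTAR_KI = getc("WTSTAR_KI"),
      n_UNEDITED = getc("UNEDITED"), n_INDEL = getc("INDEL"),
      n_AMBIGUOUS = 0L, n_DISCARDED = 0L,
      indel_fs_exonic = unname(strata["fs_exonic"]),
      indel_if_exonic = unname(strata["if_exonic"]),
      indel_fs_intronic = unname(strata["fs_intronic"]),
      indel_if_intronic = unname(strata["if_intronic"]),
      indel_fs_splice = unname(strata["fs_splice"]),
      indel_if_splice = unname(strata["if_splice"]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$frameshift_frequency <- with(out, (indel_fs_exonic + indel_fs_intronic +
    indel_fs_splice) / pmax(n_total - n_DISCARDED, 1L))
  class(out) <- c("outcome_table", "data.frame")
  out
}

# Stratum label of a planted InDel allele: frameshift from the exonic net
# length change; region with splice > exonic > intronic precedence.
indel_stratum <- function(design, position, net_length) {
  ev <- indel_event_features(design, position, net_length)
  fs <- if (ev$frameshift) "fs" else "if"
  paste(fs, ev$region, sep = "_")
}
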