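#' Align amplicon reads to the design reference
#'
#' Global (Needleman-Wunsch) alignment with affine gap penalties via
#' Biostrings. Default scoring: match +2, mismatch -2, gap open -6, gap
#' extend -1 (a gap of length k costs `gap_open + k * gap_extend`).
#' Indel events are reported in 0-based reference coordinates and
#' left-normalized (shifted to their leftmost equivalent placement), so
#' the reported placement is independent of the aligner's internal
#' tie-breaking.
#'
#' @param reads Character vector (or DNAStringSet) of reads; A/C/G/T/N
#'   only.
#' @param reference Reference amplicon sequence (character).
#' @param match,mismatch,gap_open,gap_extend Alignment scores.
#' @return A list of per-read alignment summaries, each with `score`,
#'   `nmatch`, `columns` (alignment length including inserted bases),
#'   `mismatch_pos`/`mismatch_base` (1-based reference positions and
#'   the read base observed there) and `events` (data.frame of indels:
#'   `position` 0-based, `net_length` signed, `inserted` sequence).
#' @export
align_reads <- function(reads, reference, match = 2, mismatch = -2,
                        gap_open = 6, gap_extend = 1) {
  batch <- align_reads_batch(reads, reference, match, mismatch,
                             gap_open, gap_extend)
  lapply(seq_len(batch$n), function(i) {
    mm <- batch$mismatches[batch$mismatches$read == i, , drop = FALSE]
    ev <- batch$events[batch$events$read == i,
                       c("position", "net_length", "inserted"), drop = FALSE]
    rownames(ev) <- NULL
    list(score = batch$score[i], nmatch = batch$nmatch[i],
         columns = batch$columns[i],
         mismatch_pos = mm$pos, mismatch_base = mm$base, events = ev)
  })
}

#' @rdname align_reads
#' @param read A single read sequence.
#' @export
align_read <- function(read, reference, match = 2, mismatch = -2,
                       gap_open = 6, gap_extend = 1) {
  align_reads(read, reference, match, mismatch, gap_open, gap_extend)[[1]]
}

# Vectorized alignment: one pairwiseAlignment call, flat per-read
# summaries, flat mismatch and indel-event tables.
align_reads_batch <- function(reads, reference, match = 2, mismatch = -2,
                              gap_open = 6, gap_extend = 1) {
  reads <- as.character(reads)
  if (any(!nzchar(reads))) stop("empty read")
  if (any(grepl("[^ACGTN]", reads))) stop("non-ACGTN characters in reads")
  L <- nchar(reference)
  refc <- strsplit(reference, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T", "N")
  submat <- matrix(mismatch, 5, 5, dimnames = list(bases, bases))
  diag(submat)[1:4] <- match
  submat["N", "N"] <- mismatch   # N never matches
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(reads), Biostrings::DNAString(reference),
    substitutionMatrix = submat, gapOpening = gap_open,
    gapExtension = gap_extend, type = "global")
  ins <- Biostrings::insertion(aln)
  del <- Biostrings::deletion(aln)
  ins_n <- lengths(ins); del_n <- lengths(del)
  mt <- Biostrings::mismatchTable(aln)
  mismatches <- data.frame(read = mt$PatternId,
                           pos = as.integer(mt$SubjectStart),
                           base = as.character(mt$PatternSubstring),
                           stringsAsFactors = FALSE)
  # raw events in alignment-column frame (ref position + cumulative
  # insertion width before the event)
  ins_reads <- rep(seq_along(reads), ins_n)
  del_reads <- rep(seq_along(reads), del_n)
  raw <- rbind(
    data.frame(read = ins_reads,
               col = unlist(IRanges::start(ins), use.names = FALSE),
               w = unlist(IRanges::width(ins), use.names = FALSE),
               ins = rep(TRUE, length(ins_reads))),
    data.frame(read = del_reads,
               col = unlist(IRanges::start(del), use.names = FALSE),
               w = unlist(IRanges::width(del), use.names = FALSE),
               ins = rep(FALSE, length(del_reads))))
  events <- data.frame(read = integer(0), position = integer(0),
                       net_length = integer(0), inserted = character(0),
                       stringsAsFactors = FALSE)
  if (nrow(raw)) {
    raw <- raw[order(raw$read, raw$col), , drop = FALSE]
    out_pos <- integer(nrow(raw)); out_len <- integer(nrow(raw))
    out_seq <- character(nrow(raw))
    by_read <- split(seq_len(nrow(raw)), raw$read)
    for (rows in by_read) {
      cins <- 0L; cdel <- 0L
      rd <- reads[raw$read[rows[1]]]
      for (k in rows) {
        if (raw$ins[k]) {
          after <- raw$col[k] - 1L - cins     # 1-based ref pos preceding
          rs <- raw$col[k] - cdel             # 1-based read pos of insert
          seq <- substring(rd, rs, rs + raw$w[k] - 1L)
          norm <- left_normalize_insertion(refc, after, seq)
          out_pos[k] <- norm$after            # insert before 0-based `after`
          out_len[k] <- raw$w[k]
          out_seq[k] <- norm$seq
          cins <- cins + raw$w[k]
        } else {
          s <- raw$col[k] - cins              # 1-based ref start
          s <- left_normalize_deletion(refc, s, raw$w[k])
          out_pos[k] <- s - 1L
          out_len[k] <- -raw$w[k]
          out_seq[k] <- ""
          cdel <- cdel + raw$w[k]
        }
      }
    }
    events <- data.frame(read = raw$read, position = out_pos,
                         net_length = out_len, inserted = out_seq,
                         stringsAsFactors = FALSE)
  }
  ins_w <- integer(length(reads))
  if (nrow(raw) && any(raw$ins)) {
    tot <- tapply(raw$w[raw$ins], raw$read[raw$ins], sum)
    ins_w[as.integer(names(tot))] <- as.integer(tot)
  }
  list(n = length(reads),
       score = Biostrings::score(aln),
       nmatch = Biostrings::nmatch(aln),
       nmismatch = Biostrings::nmismatch(aln),
       columns = L + ins_w,
       mismatches = mismatches,
       events = events)
}

left_normalize_deletion <- function(refc, s, w) {
  e <- s + w - 1L
  while (s > 1L && refc[s - 1L] == refc[e]) { s <- s - 1L; e <- e - 1L }
  s
}

left_normalize_insertion <- function(refc, after, seq) {
  sq <- strsplit(seq, "", fixed = TRUE)[[1]]
  while (after >= 1L && refc[after] == sq[length(sq)]) {
    sq <- c(refc[after], sq[-length(sq)])
    after <- after - 1L
  }
  list(after = after, seq = paste(sq, collapse = ""))
}

# Region/frameshift features of one indel event.
# Deletions: exonic net change = -(overlap with exon regions);
# insertions contribute +net_length when anchored in an exon.
# Region label precedence: splice > exonic > intronic.
indel_event_features <- function(design, position, net_length) {
  reg <- design$regions
  ss <- design$splice_sites
  L <- nchar(design$reference)
  if (net_length < 0) {
    s <- position; e <- position - net_length  # [s, e), 0-based
    exon <- reg[reg$kind == "exon", , drop = FALSE]
    exonic_overlap <- sum(pmax(0, pmin(e, exon$end) - pmax(s, exon$start)))
    splice_hit <- nrow(ss) > 0 && any(pmin(e, ss$end) > pmax(s, ss$start))
    exonic_net <- -exonic_overlap
    region <- if (splice_hit) "splice"
              else if (exonic_overlap > 0) "exonic" else "intronic"
  } else {
    p <- position                               # insert before base p
    anchor <- min(max(p, 0L), L - 1L)
    kind <- reg$kind[findInterval(anchor, reg$start)]
    exonic_net <- if (kind == "exon") net_length else 0L
    splice_hit <- nrow(ss) > 0 && any(p > ss$start & p < ss$end)
    region <- if (splice_hit) "splice"
              else if (kind == "exon") "exonic" else "intronic"
  }
  list(region = region, frameshift = (exonic_net %% 3L) != 0L,
       exonic_net = exonic_net, splice_hit = splice_hit)
}

# Vectorized outcome classification of a batch of aligned reads.
# Returns a data.frame with one row per read.
classify_alignments <- function(batch, design, window = 20L,
                                min_identity = 0.8) {
  n <- batch$n
  cut <- design$cut_site
  ev <- batch$events
  # per-unique-event features (few distinct events per amplicon)
  if (nrow(ev)) {
    key <- paste(ev$position, ev$net_length)
    uk <- !duplicated(key)
    feat <- lapply(which(uk), function(i)
      indel_event_features(design, ev$position[i], ev$net_length[i]))
    names(feat) <- key[uk]
    ev$exonic_net <- vapply(feat[key], `[[`, numeric(1), "exonic_net")
    ev$splice_hit <- vapply(feat[key], `[[`, logical(1), "splice_hit")
    ev$region <- vapply(feat[key], `[[`, character(1), "region")
    ev$in_window <- ifelse(ev$net_length < 0,
                           ev$position < cut + window &
                             ev$position - ev$net_length > cut - window,
                           ev$position >= cut - window &
                             ev$position <= cut + window)
  }
  has_window_indel <- logical(n)
  frameshift <- logical(n)
  splice_dis <- logical(n)
  region <- rep(NA_character_, n)
  if (nrow(ev)) {
    agg <- function(values, f, init) {
      out <- rep(init, n)
      res <- tapply(values, ev$read, f)
      out[as.integer(names(res))] <- unname(res)
      out
    }
    has_window_indel <- agg(ev$in_window, any, FALSE)
    exonic_net <- agg(ev$exonic_net, sum, 0)
    frameshift <- (exonic_net %% 3) != 0
    splice_dis <- agg(ev$splice_hit, any, FALSE)
    # region precedence among in-window events
    evw <- ev[ev$in_window, , drop = FALSE]
    if (nrow(evw)) {
      rank <- c(splice = 3L, exonic = 2L, intronic = 1L)
      best <- tapply(rank[evw$region], evw$read, max)
      region[as.integer(names(best))] <-
        names(rank)[match(unname(best), rank)]
    }
  }

  # template presence: a substitution is present iff the read shows the
  # alt base at that reference position (a mismatch record)
  mm <- batch$mismatches
  hits_of <- function(subs) {
    all_hit <- rep(TRUE, n); any_hit <- rep(FALSE, n)
    for (i in seq_len(nrow(subs))) {
      ids <- mm$read[mm$pos == subs$position[i] + 1L &
                     mm$base == subs$alt[i]]
      h <- logical(n); h[ids] <- TRUE
      all_hit <- all_hit & h
      any_hit <- any_hit | h
    }
    list(all = all_hit, any = any_hit)
  }
  mu <- hits_of(design$mut_substitutions)
  wt <- hits_of(design$wtstar_substitutions)

  identity <- ifelse(batch$columns > 0, batch$nmatch / batch$columns, 0)
  category <- ifelse(identity < min_identity, "DISCARDED",
              ifelse(has_window_indel, "INDEL",
              ifelse(mu$all & !wt$any, "MUT_KI",
              ifelse(wt$all & !mu$any, "WTSTAR_KI",
              ifelse(mu$any | wt$any, "AMBIGUOUS", "UNEDITED")))))
  frameshift <- frameshift & category == "INDEL"
  region[category != "INDEL"] <- NA_character_

  template_pos <- unique(c(design$mut_substitutions$position,
                           design$wtstar_substitutions$position)) + 1L
  mm_out <- tabulate(mm$read[!mm$pos %in% template_pos], nbins = n)
  data.frame(category = category, frameshift = frameshift,
             indel_region = region,
             splice_disrupting = splice_dis & category == "INDEL",
             n_mismatches_outside_templates = mm_out,
             stringsAsFactors = FALSE)
}

#' Classify one aligned read into an editing-outcome category
#'
#' Decision order: DISCARDED (alignment identity below `min_identity`),
#' INDEL (any indel event within `window` bp of the cut site), MUT_KI or
#' WTSTAR_KI (full respective knock-in substitution set present, the
#' other set absent, no cut-site-window indel), AMBIGUOUS (both sets
#' present, or a partial set — e.g. template recombination), UNEDITED
#' otherwise. Indels far from the cut site with an otherwise matching
#' template are treated as background and do not veto knock-in calls.
#'
#' @param alignment One alignment summary from [align_reads()], or a
#'   raw read (character), which is aligned first.
#' @param design An [amplicon_design()].
#' @param window InDel attribution window, bp around the cut site.
#' @param min_identity Minimum fraction of matching alignment columns.
#' @return A list of class `read_outcome`: `category`, `frameshift`,
#'   `indel_region` (`NA` unless INDEL), `splice_disrupting`,
#'   `indel_events`, `n_mismatches_outside_templates`.
#' @export
classify_read <- function(alignment, design, window = 20L,
                          min_identity = 0.8) {
  if (is.character(alignment)) {
    batch <- align_reads_batch(alignment, design$reference)
  } else {
    a <- alignment
    ev <- a$events
    batch <- list(n = 1L, score = a$score, nmatch = a$nmatch,
                  columns = a$columns,
                  mismatches = data.frame(read = rep(1L, length(a$mismatch_pos)),
                                          pos = a$mismatch_pos,
                                          base = a$mismatch_base,
                                          stringsAsFactors = FALSE),
                  events = data.frame(read = rep(1L, nrow(ev)), ev,
                                      stringsAsFactors = FALSE))
  }
  row <- classify_alignments(batch, design, window, min_identity)
  structure(list(category = row$category,
                 frameshift = row$frameshift,
                 indel_region = row$indel_region,
                 splice_disrupting = row$splice_disrupting,
                 indel_events = batch$events[, c("position", "net_length",
                                                 "inserted"), drop = FALSE],
                 n_mismatches_outside_templates =
                   row$n_mismatches_outside_templates),
            class = "read_outcome")
}

#' Quantify editing outcomes of one amplicon sample
#'
#' Reads a FASTQ file (gzip-transparent) or takes reads directly,
#' classifies every read against the design, and tabulates outcome
#' counts. Identical reads are classified once. Reads of reference
#' length whose best gapless interpretation has at most 3 mismatches
#' are classified without invoking the aligner (a gapped alignment
#' cannot beat the gapless one under the default scoring until 4
#' mismatches could be absorbed), which makes deep samples fast; all
#' other reads go through full affine-gap alignment.
#'
#' @param reads FASTQ path, character vector, or DNAStringSet.
#' @param design An [amplicon_design()].
#' @param min_identity Minimum fraction of matching alignment columns;
#'   below it a read is DISCARDED.
#' @param window InDel attribution window around the cut site (bp).
#' @param sample_info Optional named list/row with `sample_id`,
#'   `timepoint`, `condition`, `replicate` copied into the output.
#' @return A one-row data.frame of class `outcome_table` with category
#'   counts, InDel counts stratified by frameshift status x region, and
#'   the frameshift frequency among classified reads.
#' @export
quantify_sample <- function(reads, design, min_identity = 0.8,
                            window = 20L, sample_info = NULL) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    reads <- read_fastq_sequences(reads)
  reads <- as.character(reads)
  n_total <- length(reads)
  if (n_total == 0L) warning("no reads in sample")

  cls <- classify_read_set(reads, design, min_identity, window)
  counts <- function(cat) sum(cls$weight[cls$category == cat])
  strata <- c(fs_exonic = 0, if_exonic = 0, fs_intronic = 0,
              if_intronic = 0, fs_splice = 0, if_splice = 0)
  ind <- cls[cls$category == "INDEL", , drop = FALSE]
  if (nrow(ind)) {
    lab <- paste(ifelse(ind$frameshift, "fs", "if"),
                 ind$indel_region, sep = "_")
    agg <- tapply(ind$weight, lab, sum)
    strata[names(agg)] <- agg
  }
  n_disc <- counts("DISCARDED")
  n_fs <- sum(cls$weight[cls$frameshift])
  out <- data.frame(
    sample_id = (sample_info$sample_id %||% NA_character_),
    timepoint = (sample_info$timepoint %||% NA_integer_),
    condition = (sample_info$condition %||% NA_character_),
    replicate = (sample_info$replicate %||% NA_integer_),
    n_total = n_total,
    n_MUT_KI = counts("MUT_KI"), n_WTSTAR_KI = counts("WTSTAR_KI"),
    n_UNEDITED = counts("UNEDITED"), n_INDEL = counts("INDEL"),
    n_AMBIGUOUS = counts("AMBIGUOUS"), n_DISCARDED = n_disc,
    indel_fs_exonic = unname(strata["fs_exonic"]),
    indel_if_exonic = unname(strata["if_exonic"]),
    indel_fs_intronic = unname(strata["fs_intronic"]),
    indel_if_intronic = unname(strata["if_intronic"]),
    indel_fs_splice = unname(strata["fs_splice"]),
    indel_if_splice = unname(strata["if_splice"]),
    frameshift_frequency = if (n_total > n_disc) n_fs / (n_total - n_disc)
                           else NA_real_,
    stringsAsFactors = FALSE)
  class(out) <- c("outcome_table", "data.frame")
  out
}

# Classify unique reads and return one row per unique read with its
# multiplicity weight.
classify_read_set <- function(reads, design, min_identity, window) {
  empty <- data.frame(category = character(0), frameshift = logical(0),
                      indel_region = character(0), weight = integer(0),
                      stringsAsFactors = FALSE)
  if (!length(reads)) return(empty)
  uq <- unique(reads)
  w <- tabulate(match(reads, uq), nbins = length(uq))
  L <- nchar(design$reference)
  refc <- strsplit(design$reference, "", fixed = TRUE)[[1]]

  category <- character(length(uq))
  frameshift <- logical(length(uq))
  region <- rep(NA_character_, length(uq))

  bad <- !nzchar(uq) | grepl("[^ACGTN]", uq)
  category[bad] <- "DISCARDED"

  # gapless fast path for reference-length, N-free reads
  todo <- which(!bad)
  eq <- todo[nchar(uq[todo]) == L & !grepl("N", uq[todo], fixed = TRUE)]
  if (length(eq)) {
    m <- matrix(unlist(strsplit(uq[eq], "", fixed = TRUE),
                       use.names = FALSE), nrow = L)
    mism <- m != refc
    nmm <- colSums(mism)
    fast <- nmm <= 3L
    if (any(fast)) {
      sub_ok <- function(subs) {
        hitmat <- m[subs$position + 1L, , drop = FALSE] ==
          matrix(subs$alt, nrow(subs), ncol(m))
        list(all = colSums(hitmat) == nrow(subs), any = colSums(hitmat) > 0)
      }
      mu <- sub_ok(design$mut_substitutions)
      wt <- sub_ok(design$wtstar_substitutions)
      cat_fast <- ifelse(mu$all & !wt$any, "MUT_KI",
                   ifelse(wt$all & !mu$any, "WTSTAR_KI",
                    ifelse(mu$any | wt$any, "AMBIGUOUS", "UNEDITED")))
      category[eq[fast]] <- cat_fast[fast]
    }
    todo <- setdiff(todo, eq[fast])
  }

  if (length(todo)) {
    batch <- align_reads_batch(uq[todo], design$reference)
    res <- classify_alignments(batch, design, window = window,
                               min_identity = min_identity)
    category[todo] <- res$category
    frameshift[todo] <- res$frameshift
    region[todo] <- res$indel_region
  }
  data.frame(category = category, frameshift = frameshift,
             indel_region = region, weight = w, stringsAsFactors = FALSE)
}

#' Quantify all samples of a simulated or real experiment
#'
#' @param experiment Result of [simulate_select_experiment()], or a
#'   sample sheet data.frame with `sample_id`, `timepoint`, `condition`,
#'   `replicate` and `fastq` columns.
#' @param design An [amplicon_design()]; taken from the experiment when
#'   omitted.
#' @inheritParams quantify_sample
#' @return An `outcome_table` with one row per sample.
#' @export
quantify_experiment <- function(experiment, design = NULL,
                                min_identity = 0.8, window = 20L) {
  if (is.data.frame(experiment)) {
    sheet <- experiment
    get_reads <- function(i) sheet$fastq[i]
    if (is.null(design)) stop("design required with a sample sheet")
  } else {
    sheet <- experiment$samples
    design <- design %||% experiment$design
    get_reads <- function(i) experiment$reads[[sheet$sample_id[i]]]
  }
  rows <- lapply(seq_len(nrow(sheet)), function(i)
    quantify_sample(get_reads(i), design, min_identity, window,
                    sample_info = sheet[i, ]))
  out <- do.call(rbind, rows)
  class(out) <- c("outcome_table", "data.frame")
  out
}

read_fastq_sequences <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) %% 4L != 0L) {
    warning("truncated FASTQ record(s) in ", path, "; trailing lines dropped")
    lines <- lines[seq_len(4L * (length(lines) %/% 4L))]
  }
  if (!length(lines)) return(character(0))
  seqs <- lines[seq(2, length(lines), by = 4L)]
  names(seqs) <- sub("^@", "", lines[seq(1, length(lines), by = 4L)])
  seqs
}

#' Write an outcome table as TSV with fixed column order
#'
#' @param table An `outcome_table`.
#' @param path Output path.
#' @export
write_outcome_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_outcome_table
#' @export
read_outcome_table <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  class(out) <- c("outcome_table", "data.frame")
  out
}
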