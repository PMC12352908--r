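#' Describe a CRISPR-Select amplicon
#'
#' An amplicon design is the coordinate frame shared by the read simulator
#' and the read classifier. It holds the reference amplicon sequence, an
#' exon/intron tiling, the Cas9 cut site, and the two knock-in templates:
#' the mutation of interest (Mut) and the synonymous internal control (WT*).
#'
#' All amplicon coordinates are 0-based, half-open. The cut site is the
#' position *between* two bases, i.e. Cas9 cuts after base `cut_site - 1`.
#' Canonical splice sites are modeled as the two intronic bases flanking
#' each exon-intron junction (GT donor / AG acceptor positions); the window
#' width is configurable via `splice_window`.
#'
#' @param name Short identifier for the design.
#' @param reference Uppercase DNA string (A/C/G/T) of the amplicon.
#' @param regions data.frame with columns `start`, `end`, `kind`
#'   (`"exon"` or `"intron"`); must tile `[0, nchar(reference))` without
#'   gaps or overlaps, in order.
#' @param cut_site Integer in `[0, nchar(reference)]`.
#' @param mut_substitutions,wtstar_substitutions data.frames with columns
#'   `position` (0-based), `ref`, `alt` describing the Mut and WT*
#'   knock-in substitution sets. The two sets must differ, each `ref`
#'   must match the reference, and all positions must lie within
#'   `arm_reach` bases of the cut site (homology-arm reach).
#' @param coding_frame_offset Frame (0-2) of the first exonic base.
#' @param splice_window Width in bp of the intronic dinucleotide treated
#'   as a canonical splice site at each junction (default 2).
#' @param arm_reach Maximum distance (bp) of a template substitution from
#'   the cut site (default 60).
#'
#' @return An object of class `amplicon_design` with derived `splice_sites`
#'   (data.frame of 0-based half-open intervals with a `type` of
#'   `"donor"` or `"acceptor"`).
#' @export
amplicon_design <- function(name, reference, regions, cut_site,
                            mut_substitutions, wtstar_substitutions,
                            coding_frame_offset = 0L, splice_window = 2L,
                            arm_reach = 60L) {
  design <- structure(
    list(name = as.character(name),
         reference = toupper(as.character(reference)),
         regions = as.data.frame(regions),
         cut_site = as.integer(cut_site),
         mut_substitutions = normalize_subs(mut_substitutions),
         wtstar_substitutions = normalize_subs(wtstar_substitutions),
         coding_frame_offset = as.integer(coding_frame_offset),
         splice_window = as.integer(splice_window),
         arm_reach = as.integer(arm_reach)),
    class = "amplicon_design")
  validate_design(design)
}

normalize_subs <- function(subs) {
  subs <- as.data.frame(subs)
  if (!all(c("position", "ref", "alt") %in% names(subs)))
    stop("substitution table needs columns position, ref, alt")
  subs$position <- as.integer(subs$position)
  subs$ref <- toupper(as.character(subs$ref))
  subs$alt <- toupper(as.character(subs$alt))
  subs[order(subs$position), , drop = FALSE]
}

#' Validate an amplicon design and derive splice sites
#'
#' Checks every structural invariant of the design (region tiling,
#' substitution/reference agreement, cut-site range, distinct Mut and WT*
#' sets, homology-arm reach) and attaches the derived splice-site
#' intervals. Called by [amplicon_design()]; exported so externally
#' deserialized designs can be re-checked.
#'
#' @param design An `amplicon_design` (possibly without `splice_sites`).
#' @return The validated design with `splice_sites` populated.
#' @export
validate_design <- function(design) {
  ref <- design$reference
  L <- nchar(ref)
  if (L == 0L) stop("empty reference")
  if (grepl("[^ACGT]", ref)) stop("reference contains non-ACGT characters")

  reg <- design$regions
  if (nrow(reg) == 0L) stop("no regions")
  reg$start <- as.integer(reg$start); reg$end <- as.integer(reg$end)
  if (!all(reg$kind %in% c("exon", "intron")))
    stop("region kind must be 'exon' or 'intron'")
  if (reg$start[1] != 0L || reg$end[nrow(reg)] != L)
    stop("regions do not tile the amplicon: must span [0, reference length)")
  if (nrow(reg) > 1L && any(reg$start[-1] != reg$end[-nrow(reg)]))
    stop("regions overlap or leave gaps")
  if (any(reg$end <= reg$start)) stop("region with nonpositive length")
  design$regions <- reg

  if (design$cut_site < 0L || design$cut_site > L)
    stop("cut site out of range")

  for (side in c("mut_substitutions", "wtstar_substitutions")) {
    subs <- design[[side]]
    if (nrow(subs) == 0L) stop(side, " is empty")
    if (any(subs$position < 0L | subs$position >= L))
      stop("substitution position out of range in ", side)
    ref_bases <- substring(ref, subs$position + 1L, subs$position + 1L)
    if (any(ref_bases != subs$ref))
      stop("ref mismatch: ", side, " ref base disagrees with reference at ",
           paste(subs$position[ref_bases != subs$ref], collapse = ","))
    if (any(subs$alt == subs$ref))
      stop("substitution alt equals ref in ", side)
    if (any(abs(subs$position - design$cut_site) > design$arm_reach))
      stop("substitution beyond homology-arm reach of cut site in ", side)
  }
  key <- function(s) paste(s$position, s$alt, sep = ":")
  if (setequal(key(design$mut_substitutions), key(design$wtstar_substitutions)))
    stop("Mut and WT* substitution sets are identical")

  design$splice_sites <- derive_splice_sites(design$regions, design$splice_window)
  design
}

# Splice sites sit on the intron side of each exon-intron junction:
# donor = first `w` intronic bases, acceptor = last `w` intronic bases.
derive_splice_sites <- function(regions, w = 2L) {
  out <- data.frame(start = integer(0), end = integer(0), type = character(0))
  if (nrow(regions) < 2L) return(out)
  for (i in seq_len(nrow(regions) - 1L)) {
    a <- regions$kind[i]; b <- regions$kind[i + 1L]
    j <- regions$end[i]
    if (a == "exon" && b == "intron")
      out <- rbind(out, data.frame(start = j, end = j + w, type = "donor"))
    if (a == "intron" && b == "exon")
      out <- rbind(out, data.frame(start = j - w, end = j, type = "acceptor"))
  }
  out
}

#' Annotate amplicon positions
#'
#' Maps 0-based amplicon positions to `"exonic"`, `"intronic"` or
#' `"splice_site"`. A position inside a junction dinucleotide is always
#' `"splice_site"`, taking precedence over the underlying region kind.
#'
#' @param design An `amplicon_design`.
#' @param pos Integer vector of 0-based positions.
#' @return Character vector of labels, one per position.
#' @export
annotate_position <- function(design, pos) {
  pos <- as.integer(pos)
  L <- nchar(design$reference)
  if (any(pos < 0L | pos >= L)) stop("position out of range")
  reg <- design$regions
  idx <- findInterval(pos, reg$start)
  lab <- ifelse(reg$kind[idx] == "exon", "exonic", "intronic")
  ss <- design$splice_sites
  if (nrow(ss) > 0L) {
    in_ss <- vapply(pos, function(p) any(p >= ss$start & p < ss$end), logical(1))
    lab[in_ss] <- "splice_site"
  }
  lab
}

#' @export
print.amplicon_design <- function(x, ...) {
  cat("Amplicon design '", x$name, "': ", nchar(x$reference), " bp, ",
      nrow(x$regions), " region(s), cut site ", x$cut_site, "\n", sep = "")
  cat("  Mut substitutions:   ",
      paste0(x$mut_substitutions$position, x$mut_substitutions$ref, ">",
             x$mut_substitutions$alt, collapse = ", "), "\n", sep = "")
  cat("  WT* substitutions:   ",
      paste0(x$wtstar_substitutions$position, x$wtstar_substitutions$ref, ">",
             x$wtstar_substitutions$alt, collapse = ", "), "\n", sep = "")
  if (nrow(x$splice_sites))
    cat("  Splice sites: ", paste0("[", x$splice_sites$start, ",",
        x$splice_sites$end, ") ", x$splice_sites$type, collapse = "; "),
        "\n", sep = "")
  invisible(x)
}

#' Read or write an amplicon design as YAML
#'
#' The YAML layout mirrors the constructor: `reference` may be given
#' inline or as a `reference_fasta` path (first record used), and the
#' region/substitution tables are lists of maps.
#'
#' @param path File path.
#' @param design An `amplicon_design` (for writing).
#' @return `read_amplicon_design` returns a validated `amplicon_design`.
#' @export
read_amplicon_design <- function(path) {
  y <- yaml::read_yaml(path)
  reference <- y$reference
  if (is.null(reference) && !is.null(y$reference_fasta)) {
    fa_path <- y$reference_fasta
    if (!file.exists(fa_path))
      fa_path <- file.path(dirname(path), y$reference_fasta)
    fa <- Biostrings::readDNAStringSet(fa_path)
    reference <- as.character(fa[[1]])
  }
  to_df <- function(lst) do.call(rbind, lapply(lst, as.data.frame))
  amplicon_design(
    name = y$name,
    reference = reference,
    regions = to_df(y$regions),
    cut_site = y$cut_site,
    mut_substitutions = to_df(y$mut_substitutions),
    wtstar_substitutions = to_df(y$wtstar_substitutions),
    coding_frame_offset = y$coding_frame_offset %||% 0L,
    splice_window = y$splice_window %||% 2L,
    arm_reach = y$arm_reach %||% 60L)
}

#' @rdname read_amplicon_design
#' @export
write_amplicon_design <- function(design, path) {
  df_to_list <- function(df) lapply(seq_len(nrow(df)), function(i) as.list(df[i, ]))
  y <- list(name = design$name,
            reference = design$reference,
            regions = df_to_list(design$regions),
            cut_site = design$cut_site,
            mut_substitutions = df_to_list(design$mut_substitutions),
            wtstar_substitutions = df_to_list(design$wtstar_substitutions),
            coding_frame_offset = design$coding_frame_offset,
            splice_window = design$splice_window,
            arm_reach = design$arm_reach)
  yaml::write_yaml(y, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
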