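# Shared in-code fixtures.

# Deterministic 200-bp reference without long repeats near the cut site.
fixture_reference <- function(n = 200L, seed = 17L) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = ""))
}

# Small single-exon design: 200 bp, cut at 100, Mut 98, WT* 95.
fixture_design_single_exon <- function() {
  ref <- fixture_reference()
  sub_at <- function(pos) {
    b <- substring(ref, pos + 1, pos + 1)
    alt <- c(A = "G", G = "A", C = "T", T = "C")[b]
    data.frame(position = pos, ref = b, alt = unname(alt))
  }
  amplicon_design("single-exon", ref,
                  regions = data.frame(start = 0L, end = 200L, kind = "exon"),
                  cut_site = 100L,
                  mut_substitutions = sub_at(98L),
                  wtstar_substitutions = sub_at(95L))
}

# Exon + intron design with the cut in the exon (like an exon guide).
fixture_design_exon_intron <- function() {
  ref <- fixture_reference()
  sub_at <- function(pos) {
    b <- substring(ref, pos + 1, pos + 1)
    alt <- c(A = "G", G = "A", C = "T", T = "C")[b]
    data.frame(position = pos, ref = b, alt = unname(alt))
  }
  amplicon_design("exon-intron", ref,
                  regions = data.frame(start = c(0L, 120L),
                                       end = c(120L, 200L),
                                       kind = c("exon", "intron")),
                  cut_site = 100L,
                  mut_substitutions = sub_at(98L),
                  wtstar_substitutions = sub_at(95L))
}

apply_subs_to <- function(ref, subs) {
  s <- strsplit(ref, "")[[1]]
  s[subs$position + 1] <- subs$alt
  paste(s, collapse = "")
}

delete_at <- function(ref, pos0, len) {
  paste0(substring(ref, 1, pos0), substring(ref, pos0 + len + 1))
}

insert_at <- function(ref, pos0, seq) {
  paste0(substring(ref, 1, pos0), seq, substring(ref, pos0 + 1))
}
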