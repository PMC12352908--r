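#' Built-in example amplicon designs
#'
#' Two designs over the same 220-bp synthetic amplicon, mirroring the
#' two guide strategies of the assay:
#'
#' * `"exon"` — exon-targeting guide: cut site inside the coding exon,
#'   so non-templated repair yields exonic (frequently frameshift)
#'   InDels on the second allele.
#' * `"intron"` — intron-targeting guide (single-allele editing): cut
#'   site inside the downstream intron, so second-allele InDels are
#'   noncoding and one full-length coding allele is preserved.
#'
#' In both designs the Mut and WT* knock-in substitutions are exonic
#' single-base changes within homology-arm reach of the cut.
#'
#' @param guide `"exon"` or `"intron"`.
#' @return An [amplicon_design()].
#' @export
example_design <- function(guide = c("exon", "intron")) {
  guide <- match.arg(guide)
  reference <- paste0(
    "CAAAAATCTTCGTCTGCTCATAAGAGGGCTGGGCGCGGATAAATGTGTTCGATGTAACC",
    "TGCTCAGCAATGCTGGAGCGGCACGGACCACATGCATTGTTAGAGCAACAGGCCAAGTT",
    "CACGCGGTAGCGATAGACGCGTCGCGTATCACGGAGTACTCGCAAATGAAGGGCATTCC",
    "CTGTATCTTCGGCAAATATATATAAGGTCGGAGGTAGAATCCT")
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  sub_at <- function(pos) {
    ref <- substring(reference, pos + 1L, pos + 1L)
    data.frame(position = pos, ref = ref, alt = unname(transition[ref]))
  }
  if (guide == "exon") {
    amplicon_design(
      name = "example-exon-guide",
      reference = reference,
      regions = data.frame(start = c(0L, 140L), end = c(140L, 220L),
                           kind = c("exon", "intron")),
      cut_site = 100L,
      mut_substitutions = sub_at(98L),
      wtstar_substitutions = sub_at(95L))
  } else {
    amplicon_design(
      name = "example-intron-guide",
      reference = reference,
      regions = data.frame(start = c(0L, 100L), end = c(100L, 220L),
                           kind = c("exon", "intron")),
      cut_site = 110L,
      mut_substitutions = sub_at(90L),
      wtstar_substitutions = sub_at(84L))
  }
}
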