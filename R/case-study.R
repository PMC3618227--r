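#' The B3 thymoma case-study tables
#'
#' Small bundled tables from a published whole-genome / transcriptome study
#' of a single B3 thymoma, used as worked examples throughout the package:
#' the twelve Sanger-confirmed tier-1 somatic mutations (ten SNVs, one
#' frameshift insertion and one in-frame deletion) with their consequence
#' classes and protein-change labels, the SIFT / PolyPhen2 predictions for
#' the nine non-synonymous SNVs, and the per-gene FPKM values with
#' mutant-allele expression percentages. The companion pileup table carries
#' synthetic read counts constructed to be consistent with the reported
#' mutant-allele percentages (the study published percentages, not raw
#' counts); it is marked `synthetic` in its filename accordingly.
#'
#' `case_rna_accounting()` reproduces the transcriptome read book-keeping of
#' the case (199.18 million reads generated, 1.15 million excluded at
#' mapping quality < 20, 188 million mapped, 36.6% duplication).
#'
#' @return Data frames mirroring the published tables; see each accessor.
#' @name case-study
NULL

case_file <- function(name) {
  system.file("extdata", name, package = "somatier", mustWork = TRUE)
}

#' @rdname case-study
#' @export
case_tier1_variants <- function() {
  df <- utils::read.delim(
    case_file("b3_thymoma_tier1_variants.tsv"),
    stringsAsFactors = FALSE, na.strings = NULL
  )
  df$label[is.na(df$label)] <- ""
  vt <- variant_table(df$chrom, df$pos, df$ref, df$alt)
  vt$gene <- df$gene
  vt$effect <- df$effect
  vt$label <- df$label
  vt
}

#' @rdname case-study
#' @export
case_predictor_scores <- function() {
  read_predictor_scores(case_file("b3_thymoma_predictor_scores.tsv"))
}

#' @rdname case-study
#' @export
case_tier1_expression <- function() {
  utils::read.delim(
    case_file("b3_thymoma_tier1_expression.tsv"), stringsAsFactors = FALSE
  )
}

#' @rdname case-study
#' @export
case_tier1_pileups <- function() {
  read_pileups(case_file("b3_thymoma_tier1_pileups_synthetic.tsv"))
}

#' @rdname case-study
#' @export
case_rna_accounting <- function() {
  rna_read_accounting(
    total = 199.18e6, low_mq = 1.15e6, mapped = 188e6,
    duplication_rate = 0.366
  )
}

#' High-confidence somatic counts of the case study
#'
#' The headline high-confidence counts of the case: 963 somatic SNVs and
#' 1101 somatic INDEL-class variants (insertions, deletions and
#' multi-nucleotide substitutions). Returned as a count table suitable for
#' aggregation; the published per-subclass split (556 + 199 + 364) sums to
#' 1119 rather than the stated 1101 - an inconsistency in the source
#' tables, which this accessor reports as-is alongside the headline totals.
#'
#' @return list with `snv`, `indel`, `indel_subclasses` (named vector) and
#'   `total`.
#' @export
case_high_confidence_counts <- function() {
  list(
    snv = 963,
    indel = 1101,
    indel_subclasses = c(insertion = 556, deletion = 199,
                         substitution = 364),
    total = 963 + 1101
  )
}
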