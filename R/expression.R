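#' FPKM from fragment counts
#'
#' Fragments per kilobase of exon per million mapped fragments:
#' `fragments / ((exon_length/1e3) * (total_mapped/1e6))`.
#'
#' @param fragments fragments assigned to the gene.
#' @param exon_length gene exon length in base pairs (> 0).
#' @param total_mapped total mapped fragments in the library (> 0).
#' @return numeric FPKM (vectorized).
#' @examples
#' fpkm(100, 1000, 1e6) # 100
#' @export
fpkm <- function(fragments, exon_length, total_mapped) {
  if (any(exon_length <= 0)) stop("exon length must be positive")
  if (any(total_mapped <= 0)) stop("library size must be positive")
  fragments / ((exon_length / 1e3) * (total_mapped / 1e6))
}

#' RNA read accounting
#'
#' Book-keeping of a transcriptome sequencing run: total reads generated,
#' reads excluded for mapping quality below 20, reads mapped, and the
#' duplication rate; the retained read count is `mapped * (1 - rate)`.
#'
#' @param total total reads generated.
#' @param low_mq reads excluded for low mapping quality.
#' @param mapped reads mapped to the reference.
#' @param duplication_rate fraction in \[0, 1\].
#' @return list of class `read_accounting`.
#' @export
rna_read_accounting <- function(total, low_mq, mapped, duplication_rate) {
  if (duplication_rate < 0 || duplication_rate > 1) {
    stop("duplication rate must lie in [0, 1]")
  }
  if (low_mq > total) stop("low-quality reads cannot exceed total reads")
  if (mapped > total) stop("mapped reads cannot exceed total reads")
  structure(
    list(
      total = total, low_mq = low_mq, mapped = mapped,
      duplication_rate = duplication_rate,
      retained = mapped * (1 - duplication_rate)
    ),
    class = "read_accounting"
  )
}

#' @export
print.read_accounting <- function(x, ...) {
  cat(sprintf(
    "RNA reads: %.4g total, %.4g low-MQ excluded, %.4g mapped, %.1f%% duplicates -> %.4g retained\n",
    x$total, x$low_mq, x$mapped, 100 * x$duplication_rate, x$retained
  ))
  invisible(x)
}

#' Mutant-allele fraction at a pileup site
#'
#' @param mutant,total mutant-supporting and total read counts at the
#'   variant site; `mutant <= total`.
#' @return fraction in \[0, 1\], or `NA` when there are no reads.
#' @export
mutant_allele_fraction <- function(mutant, total) {
  if (any(mutant > total)) stop("mutant reads cannot exceed total reads")
  if (any(mutant < 0) || any(total < 0)) stop("read counts are non-negative")
  ifelse(total > 0, mutant / total, NA_real_)
}

EXPRESSION_STATUSES <- c(
  "not_transcribed", "wild_type_only", "both_alleles", "mutant_skewed",
  "no_reads", "unknown"
)

#' Integrate expression and mutant-allele evidence for tier-1 genes
#'
#' Joins gene-level FPKM (with confidence interval) to the site-level
#' mutant-allele fraction of each tier-1 variant and assigns one status per
#' gene: `not_transcribed` when FPKM rounds to 0.00, `no_reads` when the
#' gene is transcribed but the variant site has zero coverage,
#' `wild_type_only` when covered but no mutant reads, `mutant_skewed` when
#' the mutant fraction reaches `skew_threshold`, otherwise `both_alleles`.
#' Tier-1 genes missing from the expression table get status `unknown` with
#' a warning.
#'
#' @param tier1 data frame with columns `gene` and `label` (one row per
#'   tier-1 variant).
#' @param expression data frame with `gene`, `fpkm`, `ci_low`, `ci_high`.
#' @param pileups data frame with `gene`, `mutant`, `total`.
#' @param skew_threshold mutant fraction at or above which expression is
#'   called preferentially mutant.
#' @return data frame report with one row per tier-1 gene: `gene`, `label`,
#'   `fpkm`, `ci_low`, `ci_high`, `mutant`, `total`, `mutant_fraction`,
#'   `status`.
#' @export
integrate_expression <- function(tier1, expression, pileups,
                                 skew_threshold = 0.8) {
  if (any(!is.na(expression$ci_low) &
          (expression$ci_low > expression$fpkm |
             expression$fpkm > expression$ci_high))) {
    stop("expression table violates ci_low <= fpkm <= ci_high")
  }
  rows <- lapply(seq_len(nrow(tier1)), function(i) {
    g <- tier1$gene[i]
    e <- expression[expression$gene == g, , drop = FALSE]
    p <- pileups[pileups$gene == g, , drop = FALSE]
    if (!nrow(e)) {
      warning("tier-1 gene ", g, " missing from the expression table")
      return(data.frame(
        gene = g, label = tier1$label[i], fpkm = NA_real_,
        ci_low = NA_real_, ci_high = NA_real_, mutant = NA_real_,
        total = NA_real_, mutant_fraction = NA_real_, status = "unknown",
        stringsAsFactors = FALSE
      ))
    }
    mutant <- if (nrow(p)) p$mutant[1] else NA_real_
    total <- if (nrow(p)) p$total[1] else 0
    frac <- if (!is.na(mutant)) mutant_allele_fraction(mutant, total) else
      NA_real_
    status <- if (round(e$fpkm[1], 2) == 0) {
      "not_transcribed"
    } else if (is.na(frac)) {
      "no_reads"
    } else if (frac == 0) {
      "wild_type_only"
    } else if (frac >= skew_threshold) {
      "mutant_skewed"
    } else {
      "both_alleles"
    }
    data.frame(
      gene = g, label = tier1$label[i], fpkm = e$fpkm[1],
      ci_low = e$ci_low[1], ci_high = e$ci_high[1],
      mutant = mutant, total = total, mutant_fraction = frac,
      status = status, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Read expression and pileup tables
#'
#' Expression TSV columns: `gene`, `fpkm`, `ci_low`, `ci_high`. Pileup TSV
#' columns: `gene`, `chrom`, `pos`, `mutant`, `total`.
#'
#' @param path TSV file.
#' @return data frame.
#' @export
read_expression_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "fpkm", "ci_low", "ci_high") %in% names(df)))
  df
}

#' @rdname read_expression_table
#' @export
read_pileups <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "mutant", "total") %in% names(df)))
  if (any(df$mutant > df$total)) {
    stop("pileup table has mutant > total reads")
  }
  df
}
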