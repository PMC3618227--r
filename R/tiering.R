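#' Somatic-score filter
#'
#' Keeps variants whose somatic confidence score is strictly greater than the
#' threshold (the calibrated default is 0.1). Records with a missing score
#' are never kept.
#'
#' @param variants a [variant_table()].
#' @param threshold non-negative score threshold.
#' @return the high-confidence subset (same class).
#' @export
somatic_filter <- function(variants, threshold = 0.1) {
  stopifnot(threshold >= 0)
  keep <- !is.na(variants$score) & variants$score > threshold
  variants[keep, , drop = FALSE]
}

#' Sensitivity and specificity of the somatic-score filter
#'
#' Classifies every validation record with `score > threshold` as
#' called-somatic and compares against the orthogonally confirmed truth.
#' At the calibrated threshold of 0.1 on a 104-locus Sanger truth set this
#' style of filter reaches roughly 94% sensitivity and 60% specificity.
#'
#' @param records data frame with columns `locus`, `score`, `confirmed`
#'   (logical truth).
#' @param threshold score threshold.
#' @return list of class `calibration_result` with `threshold`,
#'   `sensitivity`, `specificity` and counts `tp`, `fp`, `tn`, `fn`.
#' @export
sensitivity_specificity <- function(records, threshold = 0.1) {
  stopifnot(all(c("score", "confirmed") %in% names(records)))
  called <- records$score > threshold
  truth <- as.logical(records$confirmed)
  tp <- sum(called & truth)
  fn <- sum(!called & truth)
  fp <- sum(called & !truth)
  tn <- sum(!called & !truth)
  if (tp + fn == 0) {
    stop("sensitivity undefined: no confirmed (positive) records")
  }
  if (fp + tn == 0) {
    stop("specificity undefined: no unconfirmed (negative) records")
  }
  structure(
    list(
      threshold = threshold,
      sensitivity = tp / (tp + fn),
      specificity = tn / (tn + fp),
      tp = tp, fp = fp, tn = tn, fn = fn, n = nrow(records)
    ),
    class = "calibration_result"
  )
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "somatic-score calibration at threshold %g (n = %d)\n  sensitivity %.1f%%  specificity %.1f%%  (TP %d, FN %d, TN %d, FP %d)\n",
    x$threshold, x$n, 100 * x$sensitivity, 100 * x$specificity,
    x$tp, x$fn, x$tn, x$fp
  ))
  invisible(x)
}

#' Exclude known (population) variants
#'
#' Removes any variant whose `(chromosome, position)` appears in any of the
#' supplied known-variant position sets, regardless of population frequency.
#' Exclusion is a selection step applied before tiering: an excluded variant
#' never reaches any tier.
#'
#' @param variants a [variant_table()].
#' @param known_tracks a data frame with columns `chrom`, `pos`, or a list of
#'   such data frames (dbSNP-style position sets).
#' @return the retained subset.
#' @export
exclude_known <- function(variants, known_tracks) {
  if (is.data.frame(known_tracks)) known_tracks <- list(known_tracks)
  if (!length(known_tracks) || !nrow(variants)) return(variants)
  keys <- unlist(lapply(known_tracks, function(k) {
    if (!nrow(k)) return(character(0))
    paste(k$chrom, format_pos(k$pos), sep = ":")
  }))
  keep <- !(paste(variants$chrom, format_pos(variants$pos), sep = ":") %in% keys)
  variants[keep, , drop = FALSE]
}

TIER1_EFFECTS <- c(
  "non_synonymous", "frameshift", "inframe_indel", "splice_site",
  "miRNA_locus"
)
TIER2_EFFECTS <- c("utr5", "utr3", "ncRNA")

#' Assign functional tiers to somatic variants
#'
#' Precedence-ordered classification, first matching rule wins:
#' \describe{
#'   \item{Tier 1}{coding non-synonymous / frameshift / in-frame indel,
#'     splice site or miRNA locus, and not inside a segmental duplication.}
#'   \item{Tier 2}{UTR or ncRNA effect, or a conservation score above the
#'     cutoff (phastCons-style, default > 500 on the 0-1000 scale).}
#'   \item{Tier 3}{position not repeat-masked.}
#'   \item{Tier 4}{everything else.}
#' }
#' A tier-defining coding variant that falls inside a segmental duplication
#' is not given a special category: it simply continues down the ladder
#' (tier 3, or tier 4 when repeat-masked). Positions uncovered by the
#' conservation track count as score 0; when no conservation track is given
#' the conservation clause is skipped with a warning.
#'
#' Known-variant exclusion ([exclude_known()]) must already have been
#' applied: known SNPs never reach tiering.
#'
#' @param variants a [variant_table()].
#' @param effects character vector of consequence effects, parallel to
#'   `variants` (from [call_consequence()] or ingested annotation).
#' @param segdup,repeats interval `GRanges` tracks (may be empty).
#' @param conservation scored `GRanges` track or `NULL`.
#' @param conservation_cutoff highly-conserved cutoff (strict `>`).
#' @return data frame with columns `tier` (integer 1-4) and `reasons`
#'   (comma-joined rule identifiers that fired).
#' @export
assign_tier <- function(variants, effects, segdup, repeats,
                        conservation = NULL, conservation_cutoff = 500) {
  n <- nrow(variants)
  stopifnot(length(effects) == n)
  if (!all(effects %in% CONSEQUENCE_EFFECTS)) {
    stop(
      "unknown effect value(s): ",
      paste(setdiff(effects, CONSEQUENCE_EFFECTS), collapse = ", ")
    )
  }
  if (!n) {
    return(data.frame(tier = integer(0), reasons = character(0)))
  }
  in_segdup <- track_membership(segdup, variants$chrom, variants$pos)
  in_repeat <- track_membership(repeats, variants$chrom, variants$pos)
  if (is.null(conservation)) {
    warning("no conservation track: tier-2 conservation clause skipped")
    cons <- rep(0, n)
  } else {
    cons <- track_score(conservation, variants$chrom, variants$pos)
  }

  tier <- integer(n)
  reasons <- character(n)
  for (i in seq_len(n)) {
    r <- character(0)
    coding_class <- effects[i] %in% TIER1_EFFECTS
    if (coding_class && !in_segdup[i]) {
      tier[i] <- 1L
      reasons[i] <- paste0("coding-class:", effects[i])
      next
    }
    if (coding_class && in_segdup[i]) r <- c(r, "segdup-demoted")
    utr_nc <- effects[i] %in% TIER2_EFFECTS
    conserved <- cons[i] > conservation_cutoff
    if (utr_nc || conserved) {
      tier[i] <- 2L
      if (utr_nc) r <- c(r, paste0("utr-ncRNA:", effects[i]))
      if (conserved) r <- c(r, sprintf("conserved>%g", conservation_cutoff))
      reasons[i] <- paste(r, collapse = ",")
      next
    }
    if (!in_repeat[i]) {
      tier[i] <- 3L
      reasons[i] <- paste(c(r, "non-repeat"), collapse = ",")
      next
    }
    tier[i] <- 4L
    reasons[i] <- paste(c(r, "repeat-masked"), collapse = ",")
  }
  data.frame(tier = tier, reasons = reasons, stringsAsFactors = FALSE)
}

#' Summarize tiered variants
#'
#' Counts by variant class (SNV versus the INDEL classes insertion, deletion
#' and substitution) and by tier; the grand total always equals the number of
#' input variants.
#'
#' @param variants a [variant_table()].
#' @param tiers integer vector of tiers parallel to `variants` (optional).
#' @return list with `by_class`, `by_tier` (when tiers given), `by_class_tier`
#'   and `total`.
#' @export
summarize_counts <- function(variants, tiers = NULL) {
  classes <- factor(variants$class, levels = VARIANT_CLASSES)
  by_class <- table(class = classes)
  indel_classes <- c("insertion", "deletion", "substitution")
  out <- list(
    by_class = as.data.frame(by_class, responseName = "count"),
    snv_count = sum(classes == "SNV"),
    indel_count = sum(as.character(classes) %in% indel_classes),
    total = nrow(variants)
  )
  if (!is.null(tiers)) {
    stopifnot(length(tiers) == nrow(variants))
    tf <- factor(tiers, levels = 1:4)
    out$by_tier <- as.data.frame(table(tier = tf), responseName = "count")
    out$by_class_tier <- as.data.frame(
      table(class = classes, tier = tf), responseName = "count"
    )
  }
  out
}
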