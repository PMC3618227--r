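#' Genome build description
#'
#' A minimal description of a reference build: chromosome names, lengths and
#' centromere positions. The centromere position splits each chromosome into a
#' p arm (positions `1..centromere`) and a q arm (`centromere+1..length`),
#' which is what arm-level copy-number calls are made against.
#'
#' @param chrom character vector of unique chromosome names.
#' @param length integer vector of chromosome lengths in base pairs.
#' @param centromere integer vector of centromere positions (strictly inside
#'   each chromosome), or `NA` when unknown; chromosomes without a centromere
#'   only receive whole-chromosome copy-number calls.
#' @return A `genome_build` object (a data frame with columns `chrom`,
#'   `length`, `centromere`).
#' @examples
#' build <- genome_build(c("chr1", "chr2"), c(2e6, 1e6), c(8e5, 4e5))
#' chrom_arms(build)
#' @export
genome_build <- function(chrom, length, centromere = NA_real_) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  centromere <- rep_len(as.numeric(centromere), base::length(chrom))
  if (anyDuplicated(chrom) > 0) {
    stop("genome_build: chromosome names must be unique")
  }
  if (any(!is.finite(length)) || any(length <= 0)) {
    stop("genome_build: chromosome lengths must be positive")
  }
  bad <- !is.na(centromere) & (centromere <= 0 | centromere >= length)
  if (any(bad)) {
    stop(
      "genome_build: centromere outside (0, length) for: ",
      paste(chrom[bad], collapse = ", ")
    )
  }
  out <- data.frame(
    chrom = chrom, length = length, centromere = centromere,
    stringsAsFactors = FALSE
  )
  class(out) <- c("genome_build", "data.frame")
  out
}

#' Chromosome arms of a genome build
#'
#' @param build a [genome_build()].
#' @return Data frame with one row per arm: `chrom`, `arm` (`"p"`, `"q"`, or
#'   `"whole"` when no centromere is annotated), `start`, `end` (1-based,
#'   closed).
#' @export
chrom_arms <- function(build) {
  stopifnot(inherits(build, "genome_build"))
  rows <- lapply(seq_len(nrow(build)), function(i) {
    chrom <- build$chrom[i]
    len <- build$length[i]
    cen <- build$centromere[i]
    if (is.na(cen)) {
      data.frame(chrom = chrom, arm = "whole", start = 1, end = len)
    } else {
      data.frame(
        chrom = chrom, arm = c("p", "q"),
        start = c(1, cen + 1), end = c(cen, len)
      )
    }
  })
  do.call(rbind, rows)
}
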