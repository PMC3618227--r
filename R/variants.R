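#' Variant record tables
#'
#' Variants are carried as plain data frames with one row per call and
#' columns `chrom`, `pos` (1-based position of the first affected base; for
#' pure insertions, the base after which the sequence is inserted), `ref`,
#' `alt` (`""` encodes the empty allele), `class`, `score` (somatic
#' confidence, `NA` when not applicable) and `origin`
#' (`"germline"` or `"somatic-candidate"`).
#'
#' The variant class is always re-derived from the alleles and never trusted
#' from an input column: a mismatching single base is an SNV, an empty
#' reference is an insertion, an empty alternate is a deletion, and any other
#' combination of non-empty alleles is a multi-nucleotide substitution.
#'
#' @name variant-tables
NULL

VARIANT_CLASSES <- c("SNV", "insertion", "deletion", "substitution")

#' Infer the variant class from its alleles
#'
#' @param ref,alt character vectors of reference/alternate alleles; `""`
#'   (or `"-"`, normalised by the parsers) encodes the empty allele.
#' @return character vector over `c("SNV", "insertion", "deletion",
#'   "substitution")`.
#' @export
infer_variant_class <- function(ref, alt) {
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  if (any(ref == "" & alt == "")) {
    stop("variant with both alleles empty")
  }
  if (any(ref == alt)) {
    stop("variant with ref == alt is not a variant")
  }
  out <- character(length(ref))
  out[ref == ""] <- "insertion"
  out[alt == ""] <- "deletion"
  snv <- nchar(ref) == 1L & nchar(alt) == 1L & ref != "" & alt != ""
  out[snv] <- "SNV"
  out[out == ""] <- "substitution"
  out
}

#' Construct a validated variant table
#'
#' @param chrom,pos,ref,alt per-variant fields; `pos` is 1-based.
#' @param score somatic confidence score (non-negative; `NA` allowed).
#' @param origin `"germline"` or `"somatic-candidate"`.
#' @return data frame of class `variant_table`.
#' @export
variant_table <- function(chrom, pos, ref, alt, score = NA_real_,
                          origin = "somatic-candidate") {
  n <- length(chrom)
  ref <- normalize_allele(ref)
  alt <- normalize_allele(alt)
  pos <- as.numeric(pos)
  if (any(!is.finite(pos)) || any(pos < 1)) {
    stop("variant positions must be 1-based integers >= 1")
  }
  score <- rep_len(as.numeric(score), n)
  if (any(score[!is.na(score)] < 0)) {
    stop("somatic scores must be non-negative")
  }
  origin <- rep_len(origin, n)
  if (!all(origin %in% c("germline", "somatic-candidate"))) {
    stop("origin must be 'germline' or 'somatic-candidate'")
  }
  out <- data.frame(
    chrom = as.character(chrom), pos = pos, ref = ref, alt = alt,
    class = if (n) infer_variant_class(ref, alt) else character(0),
    score = score, origin = origin, stringsAsFactors = FALSE
  )
  class(out) <- c("variant_table", "data.frame")
  out
}

normalize_allele <- function(x) {
  x <- toupper(as.character(x))
  x[is.na(x) | x == "-" | x == "."] <- ""
  if (any(grepl("[^ACGT]", x))) {
    stop("alleles must be over the ACGT alphabet (or empty)")
  }
  x
}

#' Parse one variant row in a declared dialect
#'
#' Two minimal dialects are supported. `cgi-tsv` is a five-column
#' tab-separated row `chrom  pos  ref  alt  somatic_score` with `-` for the
#' empty allele. `vcf-min` is an eight-column VCF-style row
#' `CHROM POS ID REF ALT QUAL FILTER INFO` whose INFO field carries the
#' somatic score under key `SS`; anchored indels (REF and ALT sharing their
#' first base with unequal lengths) are stripped to the empty-allele
#' convention on read.
#'
#' @param line a single data row (no header).
#' @param dialect `"cgi-tsv"` or `"vcf-min"`.
#' @return one-row [variant_table()].
#' @examples
#' parse_variant_record("chr12\t64491096\tG\tA\t0.35", "cgi-tsv")
#' @export
parse_variant_record <- function(line, dialect = c("cgi-tsv", "vcf-min")) {
  if (length(dialect) == 1 && !dialect %in% c("cgi-tsv", "vcf-min")) {
    stop("unknown variant dialect: ", dialect)
  }
  dialect <- match.arg(dialect)
  fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (dialect == "cgi-tsv") {
    if (length(fields) < 5) {
      stop(sprintf(
        "malformed cgi-tsv row (need 5 columns, got %d): %s",
        length(fields), line
      ))
    }
    pos <- suppressWarnings(as.numeric(fields[2]))
    score <- suppressWarnings(as.numeric(fields[5]))
    if (is.na(pos)) stop("malformed cgi-tsv row, column 2 (pos): ", line)
    if (is.na(score) && !fields[5] %in% c("NA", ".", "")) {
      stop("malformed cgi-tsv row, column 5 (score): ", line)
    }
    return(variant_table(fields[1], pos, fields[3], fields[4], score))
  }
  # vcf-min
  if (length(fields) < 8) {
    stop(sprintf(
      "malformed vcf-min row (need 8 columns, got %d): %s",
      length(fields), line
    ))
  }
  pos <- suppressWarnings(as.numeric(fields[2]))
  if (is.na(pos)) stop("malformed vcf-min row, column 2 (POS): ", line)
  ref <- toupper(fields[4])
  alt <- toupper(fields[5])
  # canonical anchored indel only: single-base REF prefixing a longer ALT,
  # or vice versa (substitutions sharing a first base are left alone)
  anchored <- (nchar(ref) == 1 && nchar(alt) > 1) ||
    (nchar(alt) == 1 && nchar(ref) > 1)
  if (anchored && substr(ref, 1, 1) == substr(alt, 1, 1) &&
      !ref %in% c(".", "-") && !alt %in% c(".", "-")) {
    # anchored indel: drop the shared anchor base, position moves past it
    ref <- substr(ref, 2, nchar(ref))
    alt <- substr(alt, 2, nchar(alt))
    pos <- pos + ifelse(ref == "", 0, 1)
  }
  info <- fields[8]
  score <- NA_real_
  m <- regmatches(info, regexec("(?:^|;)SS=([0-9.eE+-]+)", info))[[1]]
  if (length(m) == 2) score <- as.numeric(m[2])
  variant_table(fields[1], pos, ref, alt, score)
}

#' Read / write variant tables
#'
#' `read_variants()` reads a whole file in one dialect (header lines starting
#' with `#` are skipped); `write_variants()` writes one, so that
#' read-write round trips preserve every field.
#'
#' @param path file path.
#' @param dialect `"cgi-tsv"` or `"vcf-min"`.
#' @param variants a [variant_table()].
#' @param origin origin assigned to all records read.
#' @return `read_variants()`: a [variant_table()].
#' @export
read_variants <- function(path, dialect = c("cgi-tsv", "vcf-min"),
                          origin = "somatic-candidate") {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) {
    return(variant_table(character(0), numeric(0), character(0), character(0)))
  }
  rows <- lapply(lines, parse_variant_record, dialect = dialect)
  out <- do.call(rbind, rows)
  out$origin <- origin
  class(out) <- c("variant_table", "data.frame")
  out
}

#' @rdname read_variants
#' @export
write_variants <- function(variants, path, dialect = c("cgi-tsv", "vcf-min")) {
  dialect <- match.arg(dialect)
  fmt_allele <- function(x) ifelse(x == "", "-", x)
  if (dialect == "cgi-tsv") {
    lines <- sprintf(
      "%s\t%s\t%s\t%s\t%s",
      variants$chrom, format_pos(variants$pos),
      fmt_allele(variants$ref), fmt_allele(variants$alt),
      ifelse(is.na(variants$score), "NA", format(variants$score, digits = 15))
    )
    writeLines(c("#chrom\tpos\tref\talt\tsomatic_score", lines), path)
  } else {
    # vcf-min writes the empty allele as "-" (no anchor base is available
    # without a genome); anchored indels are still accepted on read
    info <- ifelse(is.na(variants$score), ".",
      sprintf("SS=%s", format(variants$score, digits = 15))
    )
    lines <- sprintf(
      "%s\t%s\t.\t%s\t%s\t.\t.\t%s",
      variants$chrom, format_pos(variants$pos),
      fmt_allele(variants$ref), fmt_allele(variants$alt), info
    )
    header <- c(
      "##fileformat=VCFv4.1-min",
      "##INFO=<ID=SS,Number=1,Type=Float,Description=\"Somatic score\">",
      "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
    )
    writeLines(c(header, lines), path)
  }
  invisible(path)
}

format_pos <- function(pos) {
  format(pos, scientific = FALSE, trim = TRUE)
}
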