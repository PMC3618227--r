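#' Standard genetic code as a lookup table
#'
#' @keywords internal
CODON_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

STOP_CODONS <- c("TAA", "TAG", "TGA")

CONSEQUENCE_EFFECTS <- c(
  "non_synonymous", "synonymous", "frameshift", "inframe_indel",
  "splice_site", "utr5", "utr3", "ncRNA", "miRNA_locus", "intronic",
  "intergenic"
)

#' Translate a coding sequence
#'
#' Standard-code translation of an ACGT sequence whose length is a multiple
#' of 3. Translation terminates at the first stop codon (the stop itself is
#' not included in the returned protein).
#'
#' @param sequence DNA string, length a multiple of 3.
#' @return protein string.
#' @examples
#' translate_cds("ATGCGTCAT") # "MRH"
#' @export
translate_cds <- function(sequence) {
  sequence <- toupper(as.character(sequence))
  if (nchar(sequence) %% 3 != 0) {
    stop("CDS length ", nchar(sequence), " is not a multiple of 3")
  }
  bad <- regexpr("[^ACGT]", sequence)
  if (bad > 0) {
    stop("ambiguous or invalid base at offset ", as.integer(bad))
  }
  if (!nchar(sequence)) return("")
  codons <- substring(
    sequence,
    seq(1, nchar(sequence), by = 3),
    seq(3, nchar(sequence), by = 3)
  )
  aas <- CODON_TABLE[codons]
  stop_at <- which(aas == "*")
  if (length(stop_at)) aas <- aas[seq_len(stop_at[1] - 1)]
  paste(aas, collapse = "")
}

#' Splice-site test
#'
#' A variant is at a splice site when its position lies in the first two or
#' last two bases of any intron (the canonical donor and acceptor
#' dinucleotides).
#'
#' @param variant one-row [variant_table()] (or list with `chrom`, `pos`).
#' @param model a [gene_model()].
#' @return logical flag.
#' @export
is_splice_site <- function(variant, model) {
  if (variant$chrom != model$chrom) return(FALSE)
  intr <- introns(model)
  if (!nrow(intr)) return(FALSE)
  pos <- variant$pos
  any(
    (pos >= intr$start & pos <= pmin(intr$start + 1, intr$end)) |
      (pos <= intr$end & pos >= pmax(intr$end - 1, intr$start))
  )
}

#' Classify the transcript effect of a variant
#'
#' Determines the position class of a variant against one gene model and, for
#' coding SNVs, retranslates the affected codon to decide synonymous versus
#' non-synonymous and to emit a protein-change label in the conventional
#' old-AA/position/new-AA style ("R585H"). CDS indels are labelled frameshift
#' ("L1067fs") when the inserted-minus-deleted length is not a multiple of 3
#' and in-frame ("S1756del", "K12ins") otherwise.
#'
#' @param variant one-row [variant_table()].
#' @param model a [gene_model()] or `NULL` (no overlapping gene, gives
#'   `intergenic`).
#' @param genome named `DNAStringSet` (or character vector of chromosome
#'   sequences); required to retranslate codons for coding SNVs.
#' @return data frame with `effect`, `label`, `gene`.
#' @export
call_consequence <- function(variant, model, genome = NULL) {
  out <- function(effect, label = "", gene = "") {
    data.frame(
      effect = effect, label = label, gene = gene, stringsAsFactors = FALSE
    )
  }
  if (is.null(model)) return(out("intergenic"))
  if (variant$chrom != model$chrom) return(out("intergenic"))
  span <- gene_span(model)
  pos <- variant$pos
  if (pos < span[1] || pos > span[2]) return(out("intergenic"))

  if (model$biotype == "miRNA") return(out("miRNA_locus", gene = model$gene))
  if (model$biotype == "ncRNA") return(out("ncRNA", gene = model$gene))

  cp <- cds_positions(model)
  del_span <- if (variant$class %in% c("deletion", "substitution")) {
    seq(pos, pos + max(nchar(variant$ref) - 1, 0))
  } else {
    pos
  }
  touches_cds <- length(cp) && any(del_span %in% cp)

  if (touches_cds) {
    if (variant$class == "SNV") {
      return(classify_cds_snv(variant, model, genome, cp))
    }
    shift <- nchar(variant$alt) - nchar(variant$ref)
    idx <- match(del_span[del_span %in% cp][1], cp)
    codon_idx <- ceiling(idx / 3)
    ref_aa <- cds_codon_aa(model, genome, codon_idx)
    if (shift %% 3 != 0) {
      return(out(
        "frameshift", paste0(ref_aa, codon_idx, "fs"), model$gene
      ))
    }
    suffix <- switch(variant$class,
      deletion = "del", insertion = "ins", "delins"
    )
    return(out(
      "inframe_indel", paste0(ref_aa, codon_idx, suffix), model$gene
    ))
  }

  if (is_splice_site(variant, model)) {
    return(out("splice_site", gene = model$gene))
  }

  ex_pos <- exonic_positions(model)
  if (pos %in% ex_pos) {
    if (!length(cp)) return(out("ncRNA", gene = model$gene))
    # exonic but outside the CDS: 5' or 3' UTR by transcript orientation
    before_cds <- if (model$strand == "+") {
      pos < model$cds_start
    } else {
      pos > model$cds_end
    }
    return(out(if (before_cds) "utr5" else "utr3", gene = model$gene))
  }
  out("intronic", gene = model$gene)
}

classify_cds_snv <- function(variant, model, genome, cp) {
  if (is.null(genome)) {
    stop("a genome sequence is required to classify coding SNVs")
  }
  idx <- match(variant$pos, cp)
  codon_idx <- ceiling(idx / 3)
  codon_pos <- cp[(codon_idx - 1) * 3 + 1:3] # genomic, transcript order
  bases <- chrom_bases(genome, model$chrom, codon_pos)
  ref_base <- chrom_bases(genome, model$chrom, variant$pos)
  if (!identical(unname(ref_base), variant$ref)) {
    stop(sprintf(
      "reference allele mismatch for %s:%s (genome has %s, variant says %s)",
      variant$chrom, format_pos(variant$pos), ref_base, variant$ref
    ))
  }
  if (model$strand == "-") bases <- dna_complement(bases)
  old_codon <- paste(bases, collapse = "")
  within <- ((idx - 1) %% 3) + 1
  new_base <- if (model$strand == "-") {
    dna_complement(variant$alt)
  } else {
    variant$alt
  }
  new_bases <- bases
  new_bases[within] <- new_base
  new_codon <- paste(new_bases, collapse = "")
  old_aa <- unname(CODON_TABLE[old_codon])
  new_aa <- unname(CODON_TABLE[new_codon])
  effect <- if (old_aa == new_aa) "synonymous" else "non_synonymous"
  data.frame(
    effect = effect,
    label = paste0(old_aa, codon_idx, new_aa),
    gene = model$gene, stringsAsFactors = FALSE
  )
}

cds_codon_aa <- function(model, genome, codon_idx) {
  if (is.null(genome)) return("X")
  cp <- cds_positions(model)
  codon_pos <- cp[(codon_idx - 1) * 3 + 1:3]
  if (anyNA(codon_pos)) return("X")
  bases <- chrom_bases(genome, model$chrom, codon_pos)
  if (model$strand == "-") bases <- dna_complement(bases)
  unname(CODON_TABLE[paste(bases, collapse = "")])
}

chrom_bases <- function(genome, chrom, pos) {
  seqs <- if (methods::is(genome, "DNAStringSet")) {
    as.character(genome[[chrom]])
  } else {
    genome[[chrom]]
  }
  if (any(pos < 1 | pos > nchar(seqs))) {
    stop("position outside chromosome ", chrom, " bounds")
  }
  vapply(pos, function(p) substr(seqs, p, p), character(1))
}

dna_complement <- function(bases) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  out <- comp[bases]
  if (anyNA(out)) stop("cannot complement non-ACGT base")
  unname(out)
}

#' Deleteriousness by either predictor
#'
#' A variant counts as damaging when SIFT or PolyPhen2 predicts "Damaging";
#' the predictions are ingested as data (the predictors themselves are not
#' implemented here). With both predictions absent the result is undefined.
#'
#' @param sift_pred,polyphen_pred `"Damaging"`, `"Tolerated"` or `NA`.
#' @return logical vector.
#' @export
damaging_by_any <- function(sift_pred, polyphen_pred) {
  sift_pred <- as.character(sift_pred)
  polyphen_pred <- as.character(polyphen_pred)
  both_absent <- is.na(sift_pred) & is.na(polyphen_pred)
  if (any(both_absent)) {
    stop("damaging_by_any is undefined when both predictions are absent")
  }
  (!is.na(sift_pred) & sift_pred == "Damaging") |
    (!is.na(polyphen_pred) & polyphen_pred == "Damaging")
}

#' Read a predictor-score table
#'
#' TSV with columns `gene`, `sift_pred`, `sift_score`, `polyphen_pred`,
#' `polyphen_score`; `-` or empty cells mean absent. A score must be present
#' exactly when its prediction is.
#'
#' @param path TSV file.
#' @return data frame.
#' @export
read_predictor_scores <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", "-", ""))
  needed <- c("gene", "sift_pred", "sift_score", "polyphen_pred",
              "polyphen_score")
  if (!all(needed %in% names(df))) {
    stop("predictor table must have columns: ", paste(needed, collapse = ", "))
  }
  mism <- xor(is.na(df$sift_pred), is.na(df$sift_score)) |
    xor(is.na(df$polyphen_pred), is.na(df$polyphen_score))
  if (any(mism)) {
    stop(
      "predictor score present without prediction (or vice versa) for: ",
      paste(df$gene[mism], collapse = ", ")
    )
  }
  df
}

#' Annotate a variant table against a gene-model set
#'
#' For each variant, finds the gene model whose span contains it (genes are
#' assumed non-overlapping; the first match wins) and calls
#' [call_consequence()]; variants outside every gene are intergenic.
#'
#' @param variants a [variant_table()].
#' @param models list of [gene_model()]s.
#' @param genome named `DNAStringSet` or list of chromosome sequences.
#' @return data frame with columns `effect`, `label`, `gene`, one row per
#'   variant.
#' @export
annotate_consequences <- function(variants, models, genome = NULL) {
  spans <- data.frame(
    gene = vapply(models, function(m) m$gene, character(1)),
    chrom = vapply(models, function(m) m$chrom, character(1)),
    start = vapply(models, function(m) gene_span(m)[1], numeric(1)),
    end = vapply(models, function(m) gene_span(m)[2], numeric(1)),
    stringsAsFactors = FALSE
  )
  rows <- lapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, , drop = FALSE]
    hit <- which(
      spans$chrom == v$chrom & spans$start <= v$pos & spans$end >= v$pos
    )
    model <- if (length(hit)) models[[hit[1]]] else NULL
    call_consequence(v, model, genome)
  })
  do.call(rbind, rows)
}
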