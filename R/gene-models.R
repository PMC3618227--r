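#' Gene models
#'
#' One transcript per gene: exons, an optional CDS, a strand and a biotype
#' (`protein_coding`, `ncRNA` or `miRNA`). Coordinates are 1-based closed.
#' The spliced CDS of a protein-coding model must be a multiple of 3 so that
#' codon arithmetic (consequence labels such as "R585H") is well defined.
#'
#' @param gene gene name.
#' @param chrom chromosome.
#' @param strand `"+"` or `"-"`.
#' @param exons data frame with `start`, `end` (sorted, non-overlapping).
#' @param cds_start,cds_end genomic bounds of the CDS (`NA` for non-coding).
#' @param biotype one of `"protein_coding"`, `"ncRNA"`, `"miRNA"`.
#' @return a `gene_model` object.
#' @export
gene_model <- function(gene, chrom, strand, exons,
                       cds_start = NA_real_, cds_end = NA_real_,
                       biotype = "protein_coding") {
  stopifnot(strand %in% c("+", "-"))
  if (!biotype %in% c("protein_coding", "ncRNA", "miRNA")) {
    stop("gene ", gene, ": unknown biotype '", biotype, "'")
  }
  exons <- as.data.frame(exons)[, c("start", "end")]
  exons <- exons[order(exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  if (any(exons$end < exons$start)) {
    stop("gene ", gene, ": exon with end < start")
  }
  if (nrow(exons) > 1 &&
      any(exons$start[-1] <= exons$end[-nrow(exons)])) {
    stop("gene ", gene, ": exons overlap or touch")
  }
  model <- structure(
    list(
      gene = gene, chrom = chrom, strand = strand, exons = exons,
      cds_start = as.numeric(cds_start), cds_end = as.numeric(cds_end),
      biotype = biotype
    ),
    class = "gene_model"
  )
  if (biotype == "protein_coding") {
    if (is.na(cds_start) || is.na(cds_end) || cds_end < cds_start) {
      stop("gene ", gene, ": protein_coding model needs a valid CDS")
    }
    cp <- cds_positions(model)
    if (!length(cp)) {
      stop("gene ", gene, ": CDS does not intersect the exon union")
    }
    in_exon <- exonic_positions(model)
    if (cds_start < min(exons$start) || cds_end > max(exons$end)) {
      stop("gene ", gene, ": CDS outside the exon span")
    }
    if (!(cds_start %in% in_exon) || !(cds_end %in% in_exon)) {
      stop("gene ", gene, ": CDS bounds fall outside exons")
    }
    if (length(cp) %% 3 != 0) {
      stop(
        "gene ", gene, ": spliced CDS length ", length(cp),
        " is not a multiple of 3"
      )
    }
  }
  model
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf(
    "<gene_model> %s %s:%d-%d (%s) %s, %d exon(s)\n",
    x$gene, x$chrom, min(x$exons$start), max(x$exons$end),
    x$strand, x$biotype, nrow(x$exons)
  ))
  invisible(x)
}

gene_span <- function(model) c(min(model$exons$start), max(model$exons$end))

#' Exonic / CDS genomic positions of a model
#'
#' `exonic_positions()` returns all exonic genomic positions in ascending
#' order; `cds_positions()` returns the genomic positions of the spliced CDS
#' ordered 5' to 3' along the transcript (descending coordinates on the minus
#' strand).
#'
#' @param model a [gene_model()].
#' @return numeric vector of genomic positions.
#' @export
exonic_positions <- function(model) {
  unlist(lapply(seq_len(nrow(model$exons)), function(i) {
    seq(model$exons$start[i], model$exons$end[i])
  }), use.names = FALSE)
}

#' @rdname exonic_positions
#' @export
cds_positions <- function(model) {
  if (is.na(model$cds_start)) return(numeric(0))
  pos <- exonic_positions(model)
  pos <- pos[pos >= model$cds_start & pos <= model$cds_end]
  if (model$strand == "-") rev(pos) else pos
}

#' Introns of a model
#'
#' @param model a [gene_model()].
#' @return data frame with `start`, `end` (1-based closed, possibly empty).
#' @export
introns <- function(model) {
  ex <- model$exons
  if (nrow(ex) < 2) {
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  data.frame(
    start = ex$end[-nrow(ex)] + 1,
    end = ex$start[-1] - 1
  )
}

#' Read gene models from a GTF-like file
#'
#' Expects `exon` and (for coding genes) `CDS` features carrying `gene_id`
#' and optionally `gene_biotype` attributes; one transcript per gene.
#'
#' @param path GTF file.
#' @return named list of [gene_model()] objects.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "GTF")
  if (!"gene_id" %in% names(S4Vectors::mcols(gr))) {
    stop("GTF has no gene_id attribute")
  }
  df <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    gene = gr$gene_id,
    biotype = if ("gene_biotype" %in% names(S4Vectors::mcols(gr))) {
      gr$gene_biotype
    } else {
      "protein_coding"
    },
    stringsAsFactors = FALSE
  )
  models <- lapply(split(df, df$gene), function(g) {
    ex <- g[g$type == "exon", ]
    cds <- g[g$type == "CDS", ]
    if (!nrow(ex)) stop("gene ", g$gene[1], ": no exon features")
    biotype <- ex$biotype[1]
    gene_model(
      gene = g$gene[1], chrom = ex$chrom[1], strand = ex$strand[1],
      exons = ex[, c("start", "end")],
      cds_start = if (nrow(cds)) min(cds$start) else NA_real_,
      cds_end = if (nrow(cds)) max(cds$end) else NA_real_,
      biotype = biotype
    )
  })
  models[order(names(models))]
}

#' Write gene models to a GTF file
#'
#' @param models list of [gene_model()] objects.
#' @param path output file.
#' @export
write_gene_models <- function(models, path) {
  rows <- lapply(models, function(m) {
    ex <- m$exons
    feat <- data.frame(
      chrom = m$chrom, source = "somatier", type = "exon",
      start = ex$start, end = ex$end, strand = m$strand,
      gene = m$gene, biotype = m$biotype, stringsAsFactors = FALSE
    )
    if (!is.na(m$cds_start)) {
      cp <- sort(cds_positions(m))
      # contiguous runs of CDS positions -> CDS features per exon
      brk <- c(0, which(diff(cp) != 1), length(cp))
      cds <- data.frame(
        chrom = m$chrom, source = "somatier", type = "CDS",
        start = cp[brk[-length(brk)] + 1], end = cp[brk[-1]],
        strand = m$strand, gene = m$gene, biotype = m$biotype,
        stringsAsFactors = FALSE
      )
      feat <- rbind(feat, cds)
    }
    feat
  })
  df <- do.call(rbind, rows)
  lines <- sprintf(
    "%s\t%s\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s.t1\"; gene_biotype \"%s\";",
    df$chrom, df$source, df$type, df$start, df$end, df$strand,
    df$gene, df$gene, df$biotype
  )
  writeLines(lines, path)
  invisible(path)
}
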