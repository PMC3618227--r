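#' Structural-variant cluster tables
#'
#' A cluster is a candidate junction supported by discordant read pairs:
#' two breakends (chromosome, 1-based position, retained-side direction),
#' a supporting-pair count and a span. The direction encodes which side of
#' the breakend survives on the derivative chromosome: `"+"` retains the
#' lower coordinates, `"-"` the higher.
#'
#' @param path TSV with columns `left_chrom`, `left_pos`, `left_dir`,
#'   `right_chrom`, `right_pos`, `right_dir`, `n_pairs`, `span`.
#' @return data frame of class `sv_clusters`.
#' @export
read_sv_clusters <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  sv_clusters(df)
}

#' @param df data frame with the cluster columns.
#' @rdname read_sv_clusters
#' @export
sv_clusters <- function(df) {
  needed <- c(
    "left_chrom", "left_pos", "left_dir", "right_chrom", "right_pos",
    "right_dir", "n_pairs", "span"
  )
  if (!all(needed %in% names(df))) {
    stop("cluster table must have columns: ", paste(needed, collapse = ", "))
  }
  if (!all(df$left_dir %in% c("+", "-")) ||
      !all(df$right_dir %in% c("+", "-"))) {
    stop("breakend directions must be '+' or '-'")
  }
  if (any(df$n_pairs < 0) || any(df$span < 0)) {
    stop("supporting pairs and span must be non-negative")
  }
  class(df) <- c("sv_clusters", "data.frame")
  df
}

#' @param clusters an `sv_clusters` table.
#' @rdname read_sv_clusters
#' @export
write_sv_clusters <- function(clusters, path) {
  utils::write.table(clusters, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Filter SV candidates by read support and span
#'
#' Keeps clusters supported by strictly more than `min_pairs` discordant
#' pairs AND spanning strictly more than `min_span` base pairs (the
#' "more than 20 pairs, larger than 5 kb" rule).
#'
#' @param clusters an [sv_clusters()] table.
#' @param min_pairs,min_span strict lower bounds.
#' @return the surviving subset.
#' @export
filter_sv_candidates <- function(clusters, min_pairs = 20, min_span = 5000) {
  keep <- clusters$n_pairs > min_pairs & clusters$span > min_span
  clusters[keep, , drop = FALSE]
}

#' Fusion orientation of a two-gene junction
#'
#' Each breakend retains one side of its chromosome (`"+"` keeps the lower
#' coordinates, `"-"` the higher). For each partner gene we ask which
#' transcriptional direction faces the junction: a retained fragment that
#' contains the gene's 5' end (promoter) is transcribed *toward* the
#' junction, so its 3' direction faces the junction; a fragment containing
#' the 3' end faces the junction with its 5' direction. The pair of
#' junction-facing directions names the orientation:
#' 5'+3' is `head_to_tail` (a conventional promoter-to-poly-A chimera),
#' 3'+3' is `tail_to_tail` (both poly-A tails are lost),
#' 5'+5' is `head_to_head` (both promoters are lost).
#'
#' @param cluster one-row [sv_clusters()] table.
#' @param gene_a,gene_b [gene_model()]s containing the left and right
#'   breakends respectively.
#' @return `"head_to_tail"`, `"tail_to_tail"` or `"head_to_head"`.
#' @export
classify_orientation <- function(cluster, gene_a, gene_b) {
  ends <- c(
    junction_facing_end(cluster$left_chrom, cluster$left_pos,
                        cluster$left_dir, gene_a),
    junction_facing_end(cluster$right_chrom, cluster$right_pos,
                        cluster$right_dir, gene_b)
  )
  if (all(ends == "3prime")) return("tail_to_tail")
  if (all(ends == "5prime")) return("head_to_head")
  "head_to_tail"
}

# Which transcriptional direction of the gene faces the junction.
# Retained side contains the 5' end -> the gene reads toward the junction
# -> "3prime" faces it; retained 3' end -> "5prime" faces it.
junction_facing_end <- function(chrom, pos, dir, model) {
  if (chrom != model$chrom) {
    stop("breakend ", chrom, ":", pos, " not on gene ", model$gene,
         "'s chromosome")
  }
  span <- gene_span(model)
  if (pos < span[1] || pos > span[2]) {
    stop("breakend ", chrom, ":", pos, " outside gene ", model$gene)
  }
  retains_lower <- dir == "+"
  retains_5prime <- retains_lower == (model$strand == "+")
  if (retains_5prime) "3prime" else "5prime"
}

#' First in-frame stop codon of a sequence
#'
#' Scans the given reading frame (0, 1 or 2 skipped bases) for the first
#' stop codon (TAA, TAG, TGA) and returns its 1-based codon index, counted
#' from the start of the scanned sequence; `NA` when the frame contains no
#' stop.
#'
#' @param sequence DNA string (ACGT).
#' @param frame 0, 1 or 2.
#' @return integer codon index or `NA`.
#' @examples
#' scan_premature_stop("AAACCCGGGTTTTAA", 0) # 5
#' @export
scan_premature_stop <- function(sequence, frame = 0) {
  stopifnot(frame %in% 0:2)
  sequence <- toupper(as.character(sequence))
  if (grepl("[^ACGT]", sequence)) {
    stop("scan_premature_stop expects an ACGT sequence")
  }
  usable <- nchar(sequence) - frame
  if (usable < 3) return(NA_integer_)
  starts <- seq(frame + 1, frame + 3 * (usable %/% 3), by = 3)
  codons <- substring(sequence, starts, starts + 2)
  hit <- which(codons %in% STOP_CODONS)
  if (!length(hit)) NA_integer_ else hit[1]
}

#' Predict the fusion transcript of a filtered junction
#'
#' Assembles the junction-spanning transcript and reasons about its fate.
#' The transcribed ("driver") partner is the one whose retained fragment
#' contains its own promoter (5' end); when both do (tail-to-tail) the left
#' partner is taken as driver. The transcript consists of the driver's
#' spliced exons up to the breakend, plus - when the breakend lies in an
#' intron - the retained intronic sequence up to the junction
#' (`retained_intron = TRUE`), then continues across the junction into the
#' other partner's retained genomic sequence, read in the direction imposed
#' by the derivative chromosome.
#'
#' Reading frame continues from the driver's CDS: the sequence downstream of
#' the driver's last complete codon is scanned for the first stop codon, and
#' the reported premature-stop offset counts codons downstream of that last
#' exon-encoded codon. Nonsense-mediated decay is predicted when a premature
#' stop sits more than `nmd_window` nucleotides upstream of the transcript's
#' final junction (the breakpoint junction, which lies downstream of all the
#' driver's exon-exon junctions). Detectability by poly-A-capture RNA
#' sequencing follows from orientation alone: only a head-to-tail fusion
#' keeps a poly-A tail.
#'
#' @param cluster one-row [sv_clusters()] table.
#' @param gene_a,gene_b [gene_model()]s for the left / right breakends.
#' @param genome named `DNAStringSet` or list of chromosome sequences.
#' @param nmd_window distance rule for NMD (default 50 nt).
#' @param max_acceptor_bases cap on how much of the non-driver partner's
#'   retained sequence is assembled.
#' @return list of class `fusion_prediction`: `gene_a`, `gene_b`,
#'   `orientation`, `driver`, `retained_intron`, `premature_stop_offset`,
#'   `polya_detectable`, `nmd_predicted`, `frame_ok`, `junction_sequence`,
#'   `transcript`.
#' @export
predict_fusion_transcript <- function(cluster, gene_a, gene_b, genome,
                                      nmd_window = 50,
                                      max_acceptor_bases = 10000) {
  orientation <- classify_orientation(cluster, gene_a, gene_b)
  sides <- list(
    list(model = gene_a, chrom = cluster$left_chrom,
         pos = cluster$left_pos, dir = cluster$left_dir),
    list(model = gene_b, chrom = cluster$right_chrom,
         pos = cluster$right_pos, dir = cluster$right_dir)
  )
  facing <- vapply(
    sides,
    function(s) junction_facing_end(s$chrom, s$pos, s$dir, s$model),
    character(1)
  )
  polya <- orientation == "head_to_tail"
  if (!any(facing == "3prime")) {
    # head-to-head: no retained promoter, no transcript to predict
    return(structure(
      list(
        gene_a = gene_a$gene, gene_b = gene_b$gene,
        orientation = orientation, driver = NA_character_,
        retained_intron = FALSE, premature_stop_offset = NA_integer_,
        polya_detectable = polya, nmd_predicted = FALSE,
        frame_ok = FALSE, junction_sequence = "", transcript = ""
      ),
      class = "fusion_prediction"
    ))
  }
  driver_i <- which(facing == "3prime")[1]
  drv <- sides[[driver_i]]
  acc <- sides[[if (driver_i == 1) 2 else 1]]

  a_part <- driver_transcript_part(drv$model, drv$pos, genome)
  b_seq <- acceptor_sequence(acc, genome, max_acceptor_bases)

  transcript <- paste0(a_part$seq, b_seq)
  junction_at <- nchar(a_part$seq) # transcript coordinate of the junction
  jseq <- paste0(
    substr(a_part$seq, max(1, junction_at - 19), junction_at),
    substr(b_seq, 1, 20)
  )

  frame_ok <- a_part$coding_nt > 0
  stop_offset <- NA_integer_
  nmd <- FALSE
  if (frame_ok) {
    complete <- 3 * (a_part$coding_nt %/% 3)
    scan_start <- a_part$cds_offset + complete + 1
    downstream <- substr(transcript, scan_start, nchar(transcript))
    stop_offset <- scan_premature_stop(downstream, 0)
    if (!is.na(stop_offset)) {
      stop_end_nt <- scan_start - 1 + 3 * stop_offset
      if (is_natural_terminator(stop_end_nt, junction_at, acc)) {
        # the scan ran into the acceptor gene's own terminator: the fusion
        # reads through cleanly, there is no premature stop
        stop_offset <- NA_integer_
      } else {
        nmd <- (junction_at - stop_end_nt) > nmd_window
      }
    }
  }
  structure(
    list(
      gene_a = gene_a$gene, gene_b = gene_b$gene,
      orientation = orientation, driver = drv$model$gene,
      retained_intron = a_part$retained_intron,
      premature_stop_offset = stop_offset,
      polya_detectable = polya, nmd_predicted = nmd,
      frame_ok = frame_ok, junction_sequence = jseq,
      transcript = transcript
    ),
    class = "fusion_prediction"
  )
}

#' @export
print.fusion_prediction <- function(x, ...) {
  cat(sprintf(
    "<fusion_prediction> %s-%s %s (driver %s)\n  retained intron: %s; premature stop: %s; NMD: %s; poly-A detectable: %s\n",
    x$gene_a, x$gene_b, x$orientation, x$driver,
    x$retained_intron,
    if (is.na(x$premature_stop_offset)) "none" else
      paste0("codon +", x$premature_stop_offset),
    x$nmd_predicted, x$polya_detectable
  ))
  invisible(x)
}

# Driver-side transcript: spliced exon sequence transcribed before the
# breakend, plus retained intron sequence up to the junction when the
# breakend is intronic. Returns the sequence in transcript (sense)
# orientation, the number of CDS nucleotides transcribed before the
# junction, and the transcript offset at which the CDS starts.
driver_transcript_part <- function(model, pos, genome) {
  ex <- exonic_positions(model)
  tx_order <- if (model$strand == "-") rev(ex) else ex
  # exonic positions transcribed before reaching the breakend
  before <- if (model$strand == "+") tx_order[tx_order <= pos] else
    tx_order[tx_order >= pos]
  retained_intron <- FALSE
  intron_part <- numeric(0)
  if (!(pos %in% ex)) {
    intr <- introns(model)
    hit <- which(pos >= intr$start & pos <= intr$end)
    if (!length(hit)) {
      stop("breakend at ", pos, " is outside gene ", model$gene)
    }
    retained_intron <- TRUE
    intron_part <- if (model$strand == "+") {
      seq(intr$start[hit], pos)
    } else {
      seq(intr$end[hit], pos) # descending read on minus strand
    }
  }
  all_pos <- c(before, intron_part)
  bases <- chrom_bases(genome, model$chrom, all_pos)
  if (model$strand == "-") bases <- dna_complement(bases)
  cp <- cds_positions(model)
  coding_before <- if (length(cp)) sum(cp %in% before) else 0
  cds_offset <- if (length(cp)) match(cp[1], c(before, intron_part)) - 1 else 0
  if (length(cp) && is.na(cds_offset)) {
    # CDS starts downstream of the breakend: no reading frame available
    coding_before <- 0
    cds_offset <- 0
  }
  list(
    seq = paste(bases, collapse = ""),
    coding_nt = coding_before,
    cds_offset = cds_offset,
    retained_intron = retained_intron
  )
}

# A stop codon ending at transcript position stop_end_nt is the acceptor
# gene's own terminator when its three genomic positions coincide with the
# final codon of the acceptor's CDS.
is_natural_terminator <- function(stop_end_nt, junction_at, acc) {
  cp <- cds_positions(acc$model)
  if (length(cp) < 3) return(FALSE)
  nt <- (stop_end_nt - 2):stop_end_nt
  if (any(nt <= junction_at)) return(FALSE)
  i <- nt - junction_at # 1-based index into the acceptor-side sequence
  gpos <- if (acc$dir == "-") acc$pos + i - 1 else acc$pos - i + 1
  setequal(gpos, utils::tail(cp, 3))
}

# Non-driver retained sequence, read away from the junction along the
# derivative chromosome: a retained lower side ("+") is read descending
# (reverse complement), a retained higher side ("-") ascending (as-is).
acceptor_sequence <- function(side, genome, max_bases) {
  span <- gene_span(side$model)
  if (side$dir == "-") {
    to <- min(span[2], side$pos + max_bases - 1)
    bases <- chrom_bases(genome, side$chrom, seq(side$pos, to))
  } else {
    from <- max(span[1], side$pos - max_bases + 1)
    bases <- rev(dna_complement(
      chrom_bases(genome, side$chrom, seq(from, side$pos))
    ))
  }
  paste(bases, collapse = "")
}

#' Serialize a fusion prediction to JSON
#'
#' @param prediction a `fusion_prediction`.
#' @param path output file.
#' @export
write_fusion_json <- function(prediction, path) {
  x <- unclass(prediction)
  x$transcript <- NULL # the full transcript goes to FASTA, not the report
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                       na = "null")
  invisible(path)
}
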