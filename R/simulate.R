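#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generator. The defaults
#' describe the study conditions the analysis targets: a mostly diploid
#' tumor with high purity (0.8, matching a specimen with >80% cancer
#' cells), a typical human heterozygous fraction of 0.6 among germline
#' SNPs, arm-level copy-number events (gains of 1q, 5 and 7; losses of 3p,
#' 6, 13 and the terminal part of 11q) at log2 levels of +/-0.4 with probe
#' noise sd 0.1, a tier-1 somatic burden of 9 non-synonymous SNVs, one
#' splice-site SNV and two coding indels, and a 104-locus validation set
#' whose score distributions encode 94% sensitivity and 60% specificity at
#' the 0.1 somatic-score threshold. The genome itself is desk-scale (13
#' chromosomes of 400 kb) so that the full pipeline runs in seconds.
#'
#' @param seed integer seed; with a fixed seed every generator output is
#'   byte-identical across runs.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param centromere_fraction centromere position as a fraction of length.
#' @param n_genes,n_ncrna,n_mirna gene counts (`n_genes` total, of which
#'   `n_ncrna` ncRNA and `n_mirna` miRNA).
#' @param exon_count_range,exon_length_range,intron_length_range gene
#'   structure ranges (exon lengths are rounded to codon multiples).
#' @param germline_snps total germline SNP count.
#' @param het_fraction fraction of germline SNPs that are heterozygous.
#' @param purity tumor purity in \[0, 1\].
#' @param snp_call_dropout per-SNP no-call probability applied
#'   independently to the tumor and normal call sets (sampling noise of the
#'   tumor/normal comparison).
#' @param somatic_counts named vector of true somatic variants per feature
#'   class: `tier1_coding`, `tier1_splice`, `tier1_indel`, `tier2_utr`,
#'   `tier2_conserved`, `tier3`, `tier4`.
#' @param somatic_score_range,artifact_score_range score draws for true
#'   somatic variants (all above threshold) and artifacts (all at or below).
#' @param artifact_count low-score artifact candidates.
#' @param known_leak_count germline variants leaking into the somatic
#'   candidate list (removed by known-SNP exclusion).
#' @param known_decoys extra known-SNP positions carrying no variant.
#' @param cn_events data frame `chrom`, `arm` (`"p"`, `"q"`, `"whole"`),
#'   `state` (`"gain"`/`"loss"`), `fraction` (of the arm, anchored at the
#'   telomere).
#' @param gain_level,loss_level,probe_sd,probe_spacing aCGH probe model.
#' @param sv_cluster_spec data frame `n_pairs`, `span` of discordant-pair
#'   clusters to emit (defaults include three real candidates and seven
#'   decoys).
#' @param pileup_depth_mean mean RNA depth at variant sites.
#' @param library_fragments RNA library size used for FPKM.
#' @param validation_n,validation_positive_fraction,validation_sensitivity,validation_specificity
#'   validation truth-set size and operating characteristics encoded at
#'   `validation_threshold`.
#' @param validation_threshold score threshold the validation set is
#'   calibrated around.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(
    seed = 1L,
    chrom_lengths = stats::setNames(
      rep(4e5, 13), paste0("chr", 1:13)
    ),
    centromere_fraction = 0.4,
    n_genes = 20, n_ncrna = 2, n_mirna = 1,
    exon_count_range = c(2, 4),
    exon_length_range = c(90, 240),
    intron_length_range = c(60, 200),
    germline_snps = 10000,
    het_fraction = 0.6,
    purity = 0.8,
    snp_call_dropout = 0.01,
    somatic_counts = c(
      tier1_coding = 9, tier1_splice = 1, tier1_indel = 2,
      tier2_utr = 3, tier2_conserved = 7, tier3 = 40, tier4 = 40
    ),
    somatic_score_range = c(0.12, 0.95),
    artifact_score_range = c(0, 0.1),
    artifact_count = 30,
    known_leak_count = 10,
    known_decoys = 200,
    cn_events = data.frame(
      chrom = c("chr1", "chr5", "chr7", "chr3", "chr6", "chr13", "chr11"),
      arm = c("q", "whole", "whole", "p", "whole", "whole", "q"),
      state = c("gain", "gain", "gain", "loss", "loss", "loss", "loss"),
      fraction = c(1, 1, 1, 1, 1, 1, 0.55),
      stringsAsFactors = FALSE
    ),
    gain_level = 0.4, loss_level = -0.4,
    probe_sd = 0.1, probe_spacing = 2000,
    sv_cluster_spec = data.frame(
      n_pairs = c(25, 30, 40, 20, 21, 15, 10, 5, 18, 22),
      span = c(12, 8, 100, 50, 5, 20, 2, 9, 4, 3) * 1000
    ),
    pileup_depth_mean = 40,
    library_fragments = 2e6,
    validation_n = 104,
    validation_positive_fraction = 0.5,
    validation_sensitivity = 0.94,
    validation_specificity = 0.60,
    validation_threshold = 0.1) {
  cfg <- as.list(environment())
  stopifnot(
    all(cfg$chrom_lengths > 0),
    cfg$het_fraction >= 0, cfg$het_fraction <= 1,
    cfg$purity >= 0, cfg$purity <= 1,
    cfg$gain_level > 0, cfg$loss_level < 0,
    cfg$validation_sensitivity >= 0, cfg$validation_sensitivity <= 1,
    cfg$validation_specificity >= 0, cfg$validation_specificity <= 1
  )
  if (cfg$n_ncrna + cfg$n_mirna >= cfg$n_genes) {
    stop("config error: need at least one protein-coding gene")
  }
  class(cfg) <- "simulation_config"
  cfg
}

SENSE_CODONS <- setdiff(names(CODON_TABLE), STOP_CODONS)
DNA_BASES <- c("A", "C", "G", "T")

#' Generate a synthetic genome with gene models
#'
#' Random chromosome sequence, with protein-coding genes whose CDS is
#' written into the sequence as ATG + sense codons + TAA (so every CDS
#' translates to a protein starting with M and free of internal stops),
#' plus ncRNA and miRNA genes. Deterministic under the config seed.
#'
#' @param config a [simulation_config()].
#' @return list with `genome` (named list of chromosome strings), `build`
#'   (a [genome_build()]) and `models` (list of [gene_model()]s).
#' @export
generate_genome <- function(config) {
  with_local_seed(config$seed, generate_genome_impl(config))
}

generate_genome_impl <- function(config) {
  lens <- config$chrom_lengths
  chroms <- names(lens)
  genome <- lapply(lens, function(n) sample(DNA_BASES, n, replace = TRUE))
  build <- genome_build(
    chroms, lens, floor(lens * config$centromere_fraction)
  )
  n_pc <- config$n_genes - config$n_ncrna - config$n_mirna
  biotypes <- c(
    rep("protein_coding", n_pc), rep("ncRNA", config$n_ncrna),
    rep("miRNA", config$n_mirna)
  )
  cursors <- stats::setNames(rep(3000, length(chroms)), chroms)
  models <- list()
  for (i in seq_len(config$n_genes)) {
    biotype <- biotypes[i]
    gene <- sprintf("SYN%03d", i)
    placed <- FALSE
    for (chrom in sample(chroms)) {
      g <- random_gene_structure(config, gene, chrom, cursors[chrom], biotype)
      if (g$end_cursor + 3000 <= lens[chrom]) {
        cursors[chrom] <- g$end_cursor + sample(2000:6000, 1)
        models[[gene]] <- g$model
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("config error: could not place gene ", gene,
           " (genome too small for requested genes)")
    }
  }
  # write CDS codons into the genome so coding models translate cleanly
  for (m in models) {
    if (m$biotype != "protein_coding") next
    cp <- cds_positions(m)
    n_codons <- length(cp) / 3
    codons <- c(
      "ATG", sample(SENSE_CODONS, n_codons - 2, replace = TRUE), "TAA"
    )
    tx_bases <- strsplit(paste(codons, collapse = ""), "")[[1]]
    genomic_bases <- if (m$strand == "-") dna_complement(tx_bases) else
      tx_bases
    genome[[m$chrom]][cp] <- genomic_bases
  }
  genome <- lapply(genome, paste, collapse = "")
  list(genome = genome, build = build, models = models)
}

random_gene_structure <- function(config, gene, chrom, at, biotype) {
  if (biotype == "miRNA") {
    start <- at
    exons <- data.frame(start = start, end = start + 89)
    model <- gene_model(gene, chrom, sample(c("+", "-"), 1), exons,
                        biotype = "miRNA")
    return(list(model = model, end_cursor = exons$end))
  }
  n_ex <- sample(seq(config$exon_count_range[1], config$exon_count_range[2]),
                 1)
  ex_lens <- 3 * sample(
    seq(ceiling(config$exon_length_range[1] / 3),
        floor(config$exon_length_range[2] / 3)),
    n_ex, replace = TRUE
  )
  in_lens <- if (n_ex > 1) {
    sample(seq(config$intron_length_range[1], config$intron_length_range[2]),
           n_ex - 1, replace = TRUE)
  } else {
    integer(0)
  }
  starts <- at + cumsum(c(0, utils::head(ex_lens, -1) + in_lens))
  exons <- data.frame(start = starts, end = starts + ex_lens - 1)
  strand <- sample(c("+", "-"), 1)
  if (biotype == "ncRNA") {
    model <- gene_model(gene, chrom, strand, exons, biotype = "ncRNA")
    return(list(model = model, end_cursor = max(exons$end)))
  }
  total <- sum(ex_lens)
  utr_low <- sample(15:45, 1)
  utr_high <- sample(15:45, 1)
  utr_high <- utr_high + (total - utr_low - utr_high) %% 3
  model <- gene_model(
    gene, chrom, strand, exons,
    cds_start = exons$start[1] + utr_low,
    cds_end = exons$end[n_ex] - utr_high,
    biotype = "protein_coding"
  )
  list(model = model, end_cursor = max(exons$end))
}

#' Generate germline and somatic variant sets with tier-feature tracks
#'
#' Places germline SNPs (heterozygous with the configured fraction, each
#' het SNP carrying a haplotype label), true somatic variants realizing the
#' configured per-feature-class counts (coding non-synonymous SNVs,
#' splice-site SNVs, coding indels, UTR, conserved, plain non-repeat and
#' repeat-masked positions), plus germline leak-through and low-score
#' artifact candidates; builds the segmental-duplication, repeat-mask and
#' conservation tracks the tier rules consult, and a known-SNP position set
#' containing every germline position plus decoys.
#'
#' @param config a [simulation_config()].
#' @param gen output of [generate_genome()].
#' @return list with `germline`, `somatic` (a [variant_table()] with truth
#'   columns), `known` (data frame `chrom`, `pos`), `segdup`, `repeats`,
#'   `conservation` (tracks).
#' @export
generate_variant_sets <- function(config, gen) {
  with_local_seed(config$seed + 1L, generate_variant_sets_impl(config, gen))
}

generate_variant_sets_impl <- function(config, gen) {
  genome <- gen$genome
  models <- gen$models
  blocks <- label_intergenic_blocks(config, gen)
  used <- new.env(parent = emptyenv())
  mark_used <- function(chrom, pos) {
    assign(paste0(chrom, ":", pos), TRUE, envir = used)
  }
  is_used <- function(chrom, pos) {
    exists(paste0(chrom, ":", pos), envir = used)
  }
  pick_block_positions <- function(label, n) {
    b <- blocks[blocks$label == label, , drop = FALSE]
    if (!nrow(b)) stop("config error: no blocks of class ", label)
    out <- data.frame(chrom = character(0), pos = numeric(0))
    guard <- 0
    while (nrow(out) < n) {
      guard <- guard + 1
      if (guard > 50 * n + 100) {
        stop("config error: cannot place ", n, " variants in ", label,
             " blocks")
      }
      i <- sample(nrow(b), 1)
      pos <- sample(b$start[i]:b$end[i], 1)
      if (is_used(b$chrom[i], pos)) next
      mark_used(b$chrom[i], pos)
      out <- rbind(out, data.frame(chrom = b$chrom[i], pos = pos))
    }
    out
  }
  snv_at <- function(chrom, pos) {
    ref <- chrom_bases(genome, chrom, pos)
    alt <- sample(setdiff(DNA_BASES, ref), 1)
    data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
               stringsAsFactors = FALSE)
  }

  sc <- config$somatic_counts
  pc_models <- Filter(function(m) m$biotype == "protein_coding", models)
  spliced <- Filter(function(m) nrow(m$exons) >= 2, pc_models)
  if (sc["tier1_coding"] + sc["tier1_indel"] > length(pc_models)) {
    stop("config error: more coding somatic variants than coding genes")
  }

  somatic <- list()
  truth <- character(0)
  genes_used <- sample(names(pc_models))
  take_gene <- function() {
    g <- genes_used[1]
    genes_used <<- genes_used[-1]
    pc_models[[g]]
  }

  # tier 1: coding non-synonymous SNVs
  for (i in seq_len(sc["tier1_coding"])) {
    m <- take_gene()
    v <- nonsynonymous_snv(m, genome)
    mark_used(v$chrom, v$pos)
    somatic[[length(somatic) + 1]] <- v
    truth <- c(truth, "tier1_coding")
  }
  # tier 1: splice-site SNVs (intron donor base)
  for (i in seq_len(sc["tier1_splice"])) {
    m <- spliced[[sample(length(spliced), 1)]]
    intr <- introns(m)
    pos <- intr$start[sample(nrow(intr), 1)]
    somatic[[length(somatic) + 1]] <- snv_at(m$chrom, pos)
    mark_used(m$chrom, pos)
    truth <- c(truth, "tier1_splice")
  }
  # tier 1: coding indels (alternating frameshift insertion / in-frame del)
  for (i in seq_len(sc["tier1_indel"])) {
    m <- take_gene()
    v <- coding_indel(m, genome, inframe = (i %% 2 == 0))
    mark_used(v$chrom, v$pos)
    somatic[[length(somatic) + 1]] <- v
    truth <- c(truth, "tier1_indel")
  }
  # tier 2: UTR SNVs
  for (i in seq_len(sc["tier2_utr"])) {
    m <- take_gene()
    ex <- exonic_positions(m)
    utr <- ex[ex < m$cds_start | ex > m$cds_end]
    pos <- utr[sample(length(utr), 1)]
    somatic[[length(somatic) + 1]] <- snv_at(m$chrom, pos)
    mark_used(m$chrom, pos)
    truth <- c(truth, "tier2_utr")
  }
  # tier 2 (conserved), tier 3 (plain non-repeat), tier 4 (repeat-masked)
  for (spec in list(
    c("conserved", "tier2_conserved"), c("plain", "tier3"),
    c("repeat", "tier4")
  )) {
    picks <- pick_block_positions(spec[1], sc[spec[2]])
    for (j in seq_len(nrow(picks))) {
      somatic[[length(somatic) + 1]] <- snv_at(picks$chrom[j], picks$pos[j])
    }
    truth <- c(truth, rep(spec[2], nrow(picks)))
  }
  somatic <- do.call(rbind, somatic)
  somatic$score <- stats::runif(
    nrow(somatic), config$somatic_score_range[1],
    config$somatic_score_range[2]
  )
  somatic$truth <- "somatic"
  somatic$truth_class <- truth

  # germline SNPs everywhere else
  germline <- sample_germline(config, gen, is_used, mark_used)

  # germline leak-through candidates (same position, above-threshold score)
  leaks <- germline[sample(nrow(germline), config$known_leak_count), ]
  leak_rows <- data.frame(
    chrom = leaks$chrom, pos = leaks$pos, ref = leaks$ref, alt = leaks$alt,
    score = stats::runif(nrow(leaks), config$somatic_score_range[1],
                         config$somatic_score_range[2]),
    truth = "germline-leak", truth_class = NA_character_,
    stringsAsFactors = FALSE
  )
  # low-score artifacts at plain positions
  art_pos <- pick_block_positions("plain", config$artifact_count)
  art_rows <- do.call(rbind, lapply(seq_len(nrow(art_pos)), function(j) {
    snv_at(art_pos$chrom[j], art_pos$pos[j])
  }))
  art_rows$score <- stats::runif(
    nrow(art_rows), config$artifact_score_range[1],
    config$artifact_score_range[2]
  )
  art_rows$truth <- "artifact"
  art_rows$truth_class <- NA_character_

  candidates <- rbind(somatic, leak_rows, art_rows)
  vt <- variant_table(candidates$chrom, candidates$pos, candidates$ref,
                      candidates$alt, candidates$score)
  vt$truth <- candidates$truth
  vt$truth_class <- candidates$truth_class

  # known-SNP set: all germline positions plus decoys
  decoys <- pick_block_positions("plain", config$known_decoys)
  known <- rbind(
    germline[, c("chrom", "pos")],
    decoys
  )

  list(
    germline = germline,
    somatic = vt,
    known = known,
    segdup = blocks_to_track(blocks, "segdup"),
    repeats = blocks_to_track(blocks, "repeat"),
    conservation = conservation_track(blocks)
  )
}

label_intergenic_blocks <- function(config, gen) {
  spans <- lapply(gen$models, function(m) {
    c(chrom = m$chrom, gene_span(m))
  })
  out <- list()
  for (chrom in names(config$chrom_lengths)) {
    len <- config$chrom_lengths[[chrom]]
    gs <- Filter(function(s) s[["chrom"]] == chrom, spans)
    occupied <- if (length(gs)) {
      do.call(rbind, lapply(gs, function(s) {
        c(as.numeric(s[2]) - 200, as.numeric(s[3]) + 200)
      }))
    } else {
      matrix(numeric(0), ncol = 2)
    }
    occupied <- occupied[order(occupied[, 1]), , drop = FALSE]
    gaps <- list()
    cursor <- 1
    for (i in seq_len(nrow(occupied))) {
      if (occupied[i, 1] > cursor) {
        gaps[[length(gaps) + 1]] <- c(cursor, occupied[i, 1] - 1)
      }
      cursor <- max(cursor, occupied[i, 2] + 1)
    }
    if (cursor < len) gaps[[length(gaps) + 1]] <- c(cursor, len)
    for (g in gaps) {
      n_blocks <- (g[2] - g[1] + 1) %/% 1000
      if (n_blocks < 1) next
      starts <- g[1] + 1000 * (seq_len(n_blocks) - 1)
      out[[length(out) + 1]] <- data.frame(
        chrom = chrom, start = starts, end = starts + 999,
        stringsAsFactors = FALSE
      )
    }
  }
  blocks <- do.call(rbind, out)
  blocks$label <- sample(
    c("plain", "repeat", "conserved", "segdup"),
    nrow(blocks), replace = TRUE, prob = c(0.5, 0.3, 0.15, 0.05)
  )
  blocks
}

blocks_to_track <- function(blocks, label) {
  b <- blocks[blocks$label == label, , drop = FALSE]
  if (!nrow(b)) {
    return(GenomicRanges::GRanges())
  }
  GenomicRanges::reduce(interval_track(b$chrom, b$start, b$end, name = label))
}

conservation_track <- function(blocks) {
  b <- blocks[blocks$label == "conserved", , drop = FALSE]
  if (!nrow(b)) return(GenomicRanges::GRanges())
  gr <- GenomicRanges::reduce(
    interval_track(b$chrom, b$start, b$end, name = "conservation")
  )
  gr$score <- round(stats::runif(length(gr), 600, 950))
  gr
}

nonsynonymous_snv <- function(model, genome) {
  cp <- cds_positions(model)
  n_codons <- length(cp) / 3
  for (try in seq_len(50)) {
    ci <- sample(2:(n_codons - 1), 1)
    pos <- cp[(ci - 1) * 3 + 2] # middle base, transcript order
    ref <- chrom_bases(genome, model$chrom, pos)
    codon_pos <- cp[(ci - 1) * 3 + 1:3]
    bases <- chrom_bases(genome, model$chrom, codon_pos)
    if (model$strand == "-") bases <- dna_complement(bases)
    old_aa <- CODON_TABLE[paste(bases, collapse = "")]
    for (alt in sample(setdiff(DNA_BASES, ref))) {
      nb <- bases
      nb[2] <- if (model$strand == "-") dna_complement(alt) else alt
      new_aa <- CODON_TABLE[paste(nb, collapse = "")]
      if (new_aa != old_aa && new_aa != "*") {
        return(data.frame(
          chrom = model$chrom, pos = pos, ref = ref, alt = alt,
          stringsAsFactors = FALSE
        ))
      }
    }
  }
  stop("could not construct a non-synonymous SNV in gene ", model$gene)
}

coding_indel <- function(model, genome, inframe) {
  cp <- cds_positions(model)
  n_codons <- length(cp) / 3
  if (inframe) {
    # whole-codon deletion: needs a codon contiguous in genomic space
    for (try in seq_len(100)) {
      ci <- sample(2:(n_codons - 1), 1)
      codon_pos <- sort(cp[(ci - 1) * 3 + 1:3])
      if (!all(diff(codon_pos) == 1)) next
      ref <- paste(
        chrom_bases(genome, model$chrom, seq(codon_pos[1], codon_pos[3])),
        collapse = ""
      )
      return(data.frame(
        chrom = model$chrom, pos = codon_pos[1], ref = ref, alt = "",
        stringsAsFactors = FALSE
      ))
    }
    stop("could not place an in-frame deletion in gene ", model$gene)
  }
  # 2-bp frameshift insertion after a CDS base
  pos <- sort(cp)[sample(3:(length(cp) - 3), 1)]
  data.frame(
    chrom = model$chrom, pos = pos, ref = "",
    alt = paste(sample(DNA_BASES, 2, replace = TRUE), collapse = ""),
    stringsAsFactors = FALSE
  )
}

sample_germline <- function(config, gen, is_used, mark_used) {
  lens <- config$chrom_lengths
  n_per <- round(config$germline_snps * lens / sum(lens))
  rows <- list()
  for (chrom in names(lens)) {
    pos <- sample(lens[[chrom]], n_per[[chrom]] + 50)
    pos <- pos[!vapply(pos, function(p) is_used(chrom, p), logical(1))]
    pos <- sort(pos[seq_len(min(n_per[[chrom]], length(pos)))])
    for (p in pos) mark_used(chrom, p)
    ref <- vapply(pos, function(p) chrom_bases(gen$genome, chrom, p),
                  character(1))
    alt <- vapply(ref, function(r) sample(setdiff(DNA_BASES, r), 1),
                  character(1))
    rows[[chrom]] <- data.frame(
      chrom = chrom, pos = pos, ref = unname(ref), alt = unname(alt),
      stringsAsFactors = FALSE
    )
  }
  germ <- do.call(rbind, rows)
  rownames(germ) <- NULL
  n <- nrow(germ)
  het <- stats::runif(n) < config$het_fraction
  germ$zygosity <- ifelse(het, "het", "hom")
  germ$haplotype <- ifelse(het, sample(1:2, n, replace = TRUE), NA_integer_)
  germ
}

#' Loss regions implied by a config's copy-number events
#'
#' Partial arm events are anchored at the telomere (a fraction f of a q arm
#' means the terminal f of that arm).
#'
#' @param config a [simulation_config()].
#' @param build a [genome_build()].
#' @param state `"loss"` or `"gain"`.
#' @return data frame `chrom`, `start`, `end`.
#' @export
cn_event_regions <- function(config, build, state = c("loss", "gain")) {
  state <- match.arg(state)
  ev <- config$cn_events[config$cn_events$state == state, , drop = FALSE]
  if (!nrow(ev)) return(data.frame(chrom = character(0), start = numeric(0),
                                   end = numeric(0)))
  arms <- chrom_arms(build)
  rows <- lapply(seq_len(nrow(ev)), function(i) {
    chrom <- ev$chrom[i]
    if (ev$arm[i] == "whole") {
      rng <- c(1, build$length[build$chrom == chrom])
    } else {
      a <- arms[arms$chrom == chrom & arms$arm == ev$arm[i], ]
      if (!nrow(a)) stop("no centromere for ", chrom, ": cannot place arm event")
      rng <- c(a$start, a$end)
    }
    f <- ev$fraction[i]
    len <- rng[2] - rng[1] + 1
    if (f < 1) {
      # telomere-anchored partial event
      if (ev$arm[i] == "p") {
        rng[2] <- rng[1] + round(f * len) - 1
      } else {
        rng[1] <- rng[2] - round(f * len) + 1
      }
    }
    data.frame(chrom = chrom, start = rng[1], end = rng[2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-chromosome SNP counts in normal and tumor DNA
#'
#' In a hemizygous copy-number loss one haplotype disappears from the tumor
#' cells: a heterozygous germline SNP whose variant allele sits on the lost
#' haplotype (probability 1/2 via the haplotype labels) vanishes from the
#' tumor calls, attenuated by purity - the admixed normal cells still carry
#' it, so a lost SNP remains observed with probability `1 - purity`.
#' Homozygous SNPs survive on the retained haplotype. At purity 1 and
#' heterozygous fraction h, the expected percent excess of normal over
#' tumor on a lost chromosome is `100 * (h/2) / (1 - h/2)`.
#'
#' @param config a [simulation_config()].
#' @param germline germline table from [generate_variant_sets()].
#' @param build a [genome_build()].
#' @return data frame `chrom`, `normal`, `tumor`, `loss`.
#' @export
generate_tumor_normal_snp_counts <- function(config, germline, build) {
  with_local_seed(
    config$seed + 2L,
    generate_tumor_normal_snp_counts_impl(config, germline, build)
  )
}

generate_tumor_normal_snp_counts_impl <- function(config, germline, build) {
  loss <- cn_event_regions(config, build, "loss")
  chroms <- build$chrom
  n <- nrow(germline)
  in_loss <- rep(FALSE, n)
  for (i in seq_len(nrow(loss))) {
    in_loss <- in_loss | (
      germline$chrom == loss$chrom[i] &
        germline$pos >= loss$start[i] & germline$pos <= loss$end[i]
    )
  }
  lost_hap <- stats::setNames(
    sample(1:2, length(chroms), replace = TRUE), chroms
  )
  on_lost <- in_loss & germline$zygosity == "het" &
    germline$haplotype == lost_hap[germline$chrom]
  on_lost[is.na(on_lost)] <- FALSE
  dropped <- on_lost & (stats::runif(n) < config$purity)
  # independent no-call noise in each sample
  miss_n <- stats::runif(n) < config$snp_call_dropout
  miss_t <- stats::runif(n) < config$snp_call_dropout
  normal <- table(factor(germline$chrom[!miss_n], levels = chroms))
  tumor <- table(factor(germline$chrom[!(dropped | miss_t)], levels = chroms))
  data.frame(
    chrom = chroms,
    normal = as.numeric(normal),
    tumor = as.numeric(tumor),
    loss = chroms %in% loss$chrom,
    stringsAsFactors = FALSE
  )
}

#' Generate probe, SV-cluster, pileup, expression and validation tables
#'
#' Probes are drawn around the event-implied segment means with Gaussian
#' noise; SV clusters follow the configured support/span list with random
#' breakend placement; pileups are binomial with the allele fraction implied
#' by purity and local copy-number state; expression values are computed
#' through the FPKM formula from Poisson fragment counts; the validation set
#' encodes the configured sensitivity/specificity at the configured
#' threshold.
#'
#' @param config a [simulation_config()].
#' @param gen output of [generate_genome()].
#' @param varsets output of [generate_variant_sets()].
#' @return list with `probes`, `clusters`, `pileups`, `expression`,
#'   `validation`.
#' @export
generate_probes_clusters_pileups <- function(config, gen, varsets) {
  with_local_seed(
    config$seed + 3L,
    generate_probes_clusters_pileups_impl(config, gen, varsets)
  )
}

#' Generate an aCGH probe table for a config's copy-number events
#'
#' Probes are laid out at the configured spacing; each probe's log2 ratio is
#' the sum of the event levels covering it plus Gaussian noise. Called as
#' part of [generate_probes_clusters_pileups()] but also useful on its own.
#' Not seeded internally - call within a seeded context or rely on the
#' caller.
#'
#' @param config a [simulation_config()].
#' @param build a [genome_build()].
#' @return probe data frame (`chrom`, `start`, `end`, `log2`).
#' @export
generate_probes <- function(config, build) {
  gain <- cn_event_regions(config, build, "gain")
  loss <- cn_event_regions(config, build, "loss")
  level_at <- function(chrom, pos) {
    lv <- numeric(length(pos))
    for (i in seq_len(nrow(gain))) {
      hit <- chrom == gain$chrom[i] & pos >= gain$start[i] &
        pos <= gain$end[i]
      lv[hit] <- lv[hit] + config$gain_level
    }
    for (i in seq_len(nrow(loss))) {
      hit <- chrom == loss$chrom[i] & pos >= loss$start[i] &
        pos <= loss$end[i]
      lv[hit] <- lv[hit] + config$loss_level
    }
    lv
  }
  do.call(rbind, lapply(build$chrom, function(chrom) {
    len <- build$length[build$chrom == chrom]
    pos <- seq(config$probe_spacing %/% 2, len, by = config$probe_spacing)
    data.frame(
      chrom = chrom, start = pos, end = pos,
      log2 = level_at(rep(chrom, length(pos)), pos) +
        stats::rnorm(length(pos), 0, config$probe_sd),
      stringsAsFactors = FALSE
    )
  }))
}

generate_probes_clusters_pileups_impl <- function(config, gen, varsets) {
  build <- gen$build
  gain <- cn_event_regions(config, build, "gain")
  loss <- cn_event_regions(config, build, "loss")
  probes <- generate_probes(config, build)

  # SV clusters: configured support and span, random breakends
  spec <- config$sv_cluster_spec
  n_cl <- nrow(spec)
  lens <- config$chrom_lengths
  lc <- sample(names(lens), n_cl, replace = TRUE)
  rc <- sample(names(lens), n_cl, replace = TRUE)
  clusters <- sv_clusters(data.frame(
    left_chrom = lc,
    left_pos = vapply(lc, function(ch) sample(lens[[ch]], 1), numeric(1)),
    left_dir = sample(c("+", "-"), n_cl, replace = TRUE),
    right_chrom = rc,
    right_pos = vapply(rc, function(ch) sample(lens[[ch]], 1), numeric(1)),
    right_dir = sample(c("+", "-"), n_cl, replace = TRUE),
    n_pairs = spec$n_pairs,
    span = spec$span,
    stringsAsFactors = FALSE
  ))

  # pileups + expression for tier-1 somatic variants
  tier1 <- varsets$somatic[
    !is.na(varsets$somatic$truth_class) &
      startsWith(varsets$somatic$truth_class, "tier1"),
  ]
  eff <- annotate_consequences(tier1, gen$models, gen$genome)
  p <- config$purity
  in_region <- function(regions, chrom, pos) {
    any(regions$chrom == chrom & regions$start <= pos & regions$end >= pos)
  }
  pileups <- do.call(rbind, lapply(seq_len(nrow(tier1)), function(i) {
    af <- if (in_region(loss, tier1$chrom[i], tier1$pos[i])) {
      p / (2 - p)
    } else if (in_region(gain, tier1$chrom[i], tier1$pos[i])) {
      p / (2 + p)
    } else {
      p / 2
    }
    depth <- stats::rpois(1, config$pileup_depth_mean)
    data.frame(
      gene = eff$gene[i], chrom = tier1$chrom[i], pos = tier1$pos[i],
      mutant = stats::rbinom(1, depth, af), total = depth,
      allele_fraction_true = af, stringsAsFactors = FALSE
    )
  }))
  genes <- unique(eff$gene)
  expression <- do.call(rbind, lapply(genes, function(g) {
    m <- gen$models[[g]]
    exon_len <- sum(m$exons$end - m$exons$start + 1)
    frags <- stats::rpois(1, 150)
    f <- fpkm(frags, exon_len, config$library_fragments)
    data.frame(
      gene = g, fpkm = round(f, 2),
      ci_low = round(0.8 * f, 2), ci_high = round(1.2 * f, 2),
      stringsAsFactors = FALSE
    )
  }))

  validation <- generate_validation(config)
  list(
    probes = probes, clusters = clusters, pileups = pileups,
    expression = expression, validation = validation
  )
}

generate_validation <- function(config) {
  n <- config$validation_n
  t <- config$validation_threshold
  confirmed <- stats::runif(n) < config$validation_positive_fraction
  above <- ifelse(
    confirmed,
    stats::runif(n) < config$validation_sensitivity,
    stats::runif(n) < (1 - config$validation_specificity)
  )
  score <- ifelse(above, stats::runif(n, t, 1), stats::runif(n, 0, t))
  data.frame(
    locus = sprintf("locus%03d", seq_len(n)),
    score = score, confirmed = confirmed, stringsAsFactors = FALSE
  )
}

#' Run the full generator and (optionally) write every pipeline input
#'
#' Executes the generators in a fixed order under the config seed and, when
#' `out_dir` is given, writes: `genome.fa`, `build.tsv`, `genes.gtf`,
#' `germline.tsv`, `somatic.vcf` (vcf-min dialect), `known.tsv`,
#' `segdup.bed`, `repeats.bed`, `conservation.bedgraph`, `probes.tsv`,
#' `sv_clusters.tsv`, `pileups.tsv`, `expression.tsv`, `validation.tsv`,
#' `snp_counts.tsv`. Identical seeds give byte-identical files.
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory (created), or `NULL` for in-memory only.
#' @return (invisibly) list with all generated objects.
#' @export
simulate_run <- function(config, out_dir = NULL) {
  gen <- generate_genome(config)
  varsets <- generate_variant_sets(config, gen)
  counts <- generate_tumor_normal_snp_counts(config, varsets$germline,
                                             gen$build)
  aux <- generate_probes_clusters_pileups(config, gen, varsets)
  sim <- c(list(config = config), gen, varsets,
           list(snp_counts = counts), aux)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(x) file.path(out_dir, x)
    dna <- Biostrings::DNAStringSet(unlist(gen$genome))
    Biostrings::writeXStringSet(dna, fp("genome.fa"))
    utils::write.table(as.data.frame(gen$build), fp("build.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_gene_models(gen$models, fp("genes.gtf"))
    utils::write.table(varsets$germline, fp("germline.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_variants(varsets$somatic, fp("somatic.vcf"), dialect = "vcf-min")
    utils::write.table(varsets$known, fp("known.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_track_bed(varsets$segdup, fp("segdup.bed"))
    write_track_bed(varsets$repeats, fp("repeats.bed"))
    write_track_bedgraph(varsets$conservation, fp("conservation.bedgraph"))
    write_probes(aux$probes, fp("probes.tsv"))
    write_sv_clusters(aux$clusters, fp("sv_clusters.tsv"))
    utils::write.table(aux$pileups, fp("pileups.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(aux$expression, fp("expression.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(aux$validation, fp("validation.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(counts, fp("snp_counts.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(sim)
}

#' A constructed two-gene fusion example
#'
#' A small deterministic genome with two spliced protein-coding genes and a
#' junction joining them tail-to-tail: the driver gene's breakend lies in
#' its second intron, and the retained intron carries an in-frame TAA four
#' codons downstream of the last exon-encoded codon, far enough upstream of
#' the breakpoint junction to trigger the nonsense-mediated-decay rule.
#' Useful as a worked example and as a fixture for the fusion logic.
#'
#' @return list with `genome`, `models` (driver `GENEA`, partner `GENEB`)
#'   and `cluster` (one-row [sv_clusters()]).
#' @export
fusion_toy <- function() {
  with_local_seed(7L, {
    fa <- sample(DNA_BASES, 700, replace = TRUE)
    fb <- sample(DNA_BASES, 700, replace = TRUE)
    gene_a <- gene_model(
      "GENEA", "chr_fA", "+",
      exons = data.frame(start = c(101, 201, 521), end = c(160, 260, 580)),
      cds_start = 101, cds_end = 580
    )
    # CDS: ATG + sense codons + TAA written into the sequence
    cp <- cds_positions(gene_a)
    codons <- c("ATG", sample(SENSE_CODONS, length(cp) / 3 - 2,
                              replace = TRUE), "TAA")
    fa[cp] <- strsplit(paste(codons, collapse = ""), "")[[1]]
    # retained intron 2 (261..520): no stop for 3 codons, TAA at codon 4
    intron <- 261:520
    fa[intron[1:9]] <- "C"
    fa[intron[10:12]] <- c("T", "A", "A")
    fa[intron[13:200]] <- "C"
    gene_b <- gene_model(
      "GENEB", "chr_fB", "-",
      exons = data.frame(start = c(101, 301), end = c(220, 420)),
      cds_start = 101, cds_end = 420
    )
    cpb <- cds_positions(gene_b)
    codons_b <- c("ATG", sample(SENSE_CODONS, length(cpb) / 3 - 2,
                                replace = TRUE), "TAA")
    fb[cpb] <- dna_complement(strsplit(paste(codons_b, collapse = ""),
                                       "")[[1]])
    cluster <- sv_clusters(data.frame(
      left_chrom = "chr_fA", left_pos = 400, left_dir = "+",
      right_chrom = "chr_fB", right_pos = 350, right_dir = "-",
      n_pairs = 30, span = 50000, stringsAsFactors = FALSE
    ))
    list(
      genome = list(
        chr_fA = paste(fa, collapse = ""),
        chr_fB = paste(fb, collapse = "")
      ),
      models = list(GENEA = gene_a, GENEB = gene_b),
      cluster = cluster
    )
  })
}
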