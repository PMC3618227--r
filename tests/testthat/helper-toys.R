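# Small deterministic fixtures built in code.

# A three-exon plus-strand toy gene whose CDS is written into the sequence
# (ATG + sense codons + TAA), with the second codon forced to `codon2`.
make_toy_gene <- function(codon2 = "CGT", strand = "+") {
  set.seed(11)
  seq <- sample(c("A", "C", "G", "T"), 2000, replace = TRUE)
  model <- gene_model(
    "TOY1", "chrT", strand,
    exons = data.frame(start = c(101, 201, 321), end = c(160, 260, 380)),
    cds_start = 101, cds_end = 380
  )
  cp <- cds_positions(model)
  n_codons <- length(cp) / 3
  sense <- setdiff(names(somatier:::CODON_TABLE), c("TAA", "TAG", "TGA"))
  codons <- c("ATG", codon2, sample(sense, n_codons - 3, replace = TRUE),
              "TAA")
  bases <- strsplit(paste(codons, collapse = ""), "")[[1]]
  if (strand == "-") bases <- somatier:::dna_complement(bases)
  seq[cp] <- bases
  list(genome = list(chrT = paste(seq, collapse = "")), model = model)
}

# Random variant tables for round-trip properties.
random_variant_table <- function(n, seed = 1) {
  set.seed(seed)
  kind <- sample(c("snv", "ins", "del", "sub"), n, replace = TRUE,
                 prob = c(0.6, 0.15, 0.15, 0.1))
  rand_seq <- function(len) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }
  ref <- character(n)
  alt <- character(n)
  for (i in seq_len(n)) {
    if (kind[i] == "snv") {
      ref[i] <- rand_seq(1)
      alt[i] <- sample(setdiff(c("A", "C", "G", "T"), ref[i]), 1)
    } else if (kind[i] == "ins") {
      ref[i] <- ""
      alt[i] <- rand_seq(sample(1:4, 1))
    } else if (kind[i] == "del") {
      ref[i] <- rand_seq(sample(1:4, 1))
      alt[i] <- ""
    } else {
      ref[i] <- rand_seq(sample(2:4, 1))
      repeat {
        alt[i] <- rand_seq(sample(2:4, 1))
        if (alt[i] != ref[i]) break
      }
    }
  }
  variant_table(
    chrom = sample(paste0("chr", 1:5), n, replace = TRUE),
    pos = sample(1e6, n),
    ref = ref, alt = alt,
    score = round(stats::runif(n), 4)
  )
}

# Fast config for generator-backed tests; `...` overrides any default.
small_sim_config <- function(seed = 5L, ...) {
  args <- list(
    seed = seed,
    chrom_lengths = stats::setNames(rep(2e5, 8), paste0("chr", 1:8)),
    n_genes = 14, n_ncrna = 1, n_mirna = 1,
    germline_snps = 2000,
    somatic_counts = c(
      tier1_coding = 5, tier1_splice = 1, tier1_indel = 2,
      tier2_utr = 2, tier2_conserved = 4, tier3 = 10, tier4 = 10
    ),
    artifact_count = 10, known_leak_count = 5, known_decoys = 50,
    cn_events = data.frame(
      chrom = c("chr1", "chr3", "chr5", "chr6"),
      arm = c("q", "p", "whole", "whole"),
      state = c("gain", "loss", "gain", "loss"),
      fraction = 1,
      stringsAsFactors = FALSE
    )
  )
  args <- utils::modifyList(args, list(...))
  do.call(simulation_config, args)
}

empty_track <- function() GenomicRanges::GRanges()
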