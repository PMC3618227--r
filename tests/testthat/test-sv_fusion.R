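ten_clusters <- function() {
  sv_clusters(data.frame(
    left_chrom = "chr1", left_pos = 1000 * (1:10), left_dir = "+",
    right_chrom = "chr2", right_pos = 2000 * (1:10), right_dir = "-",
    n_pairs = c(25, 30, 40, 20, 21, 15, 10, 5, 18, 22),
    span = c(12, 8, 100, 50, 5, 20, 2, 9, 4, 3) * 1000
  ))
}

test_that("the SV filter applies both strict thresholds", {
  cl <- ten_clusters()
  kept <- filter_sv_candidates(cl, 20, 5000)
  expect_equal(nrow(kept), 3)
  expect_true(all(kept$n_pairs > 20 & kept$span > 5000))
  # boundary strictness
  expect_equal(nrow(filter_sv_candidates(cl[cl$n_pairs == 20, ], 20, 5000)),
               0) # 20 pairs, 50 kb
  expect_equal(nrow(filter_sv_candidates(cl[cl$n_pairs == 21, ], 20, 5000)),
               0) # 21 pairs, exactly 5000 bp
})

test_that("the SV filter output is a monotone subset of its input", {
  cl <- ten_clusters()
  base <- filter_sv_candidates(cl, 20, 5000)
  for (mp in c(0, 10, 20, 30, 50)) {
    for (ms in c(0, 2000, 5000, 20000)) {
      out <- filter_sv_candidates(cl, mp, ms)
      expect_true(all(rownames(out) %in% rownames(cl)))
      if (mp >= 20 && ms >= 5000) {
        expect_true(all(rownames(out) %in% rownames(base)))
      }
    }
  }
})

test_that("orientation matches a hand-enumerated 16-case truth table", {
  mk_gene <- function(name, chrom, strand) {
    gene_model(name, chrom, strand,
               exons = data.frame(start = 100, end = 399),
               cds_start = 100, cds_end = 399)
  }
  for (sa in c("+", "-")) {
    for (sb in c("+", "-")) {
      for (da in c("+", "-")) {
        for (db in c("+", "-")) {
          ga <- mk_gene("GA", "c1", sa)
          gb <- mk_gene("GB", "c2", sb)
          cl <- sv_clusters(data.frame(
            left_chrom = "c1", left_pos = 250, left_dir = da,
            right_chrom = "c2", right_pos = 250, right_dir = db,
            n_pairs = 30, span = 10000
          ))
          # oracle: literal retained-side reasoning. dir "+" keeps the
          # lower-coordinate side; the 5' terminus sits at the low end on
          # "+" genes and the high end on "-" genes. A fragment holding
          # the 5' terminus reads toward the junction (3' faces it).
          keeps_5prime <- function(dir, strand) {
            five_at_low <- strand == "+"
            (dir == "+" && five_at_low) || (dir == "-" && !five_at_low)
          }
          facing <- function(dir, strand) {
            if (keeps_5prime(dir, strand)) "3" else "5"
          }
          pair <- paste0(sort(c(facing(da, sa), facing(db, sb))),
                         collapse = "")
          want <- switch(pair, "33" = "tail_to_tail",
                         "55" = "head_to_head", "head_to_tail")
          expect_equal(classify_orientation(cl, ga, gb), want,
                       info = paste(sa, sb, da, db))
          # symmetry under swapping partners
          cl_sw <- sv_clusters(data.frame(
            left_chrom = "c2", left_pos = 250, left_dir = db,
            right_chrom = "c1", right_pos = 250, right_dir = da,
            n_pairs = 30, span = 10000
          ))
          expect_equal(classify_orientation(cl_sw, gb, ga), want)
        }
      }
    }
  }
})

test_that("breakends outside the gene are rejected", {
  ga <- gene_model("GA", "c1", "+",
                   exons = data.frame(start = 100, end = 399),
                   cds_start = 100, cds_end = 399)
  cl <- sv_clusters(data.frame(
    left_chrom = "c1", left_pos = 50, left_dir = "+",
    right_chrom = "c1", right_pos = 250, right_dir = "-",
    n_pairs = 30, span = 10000
  ))
  expect_error(classify_orientation(cl, ga, ga), "outside gene")
})

test_that("stop-codon scanning matches a sliding-window oracle", {
  expect_equal(scan_premature_stop("AAACCCGGGTTTTAA", 0), 5)
  expect_true(is.na(scan_premature_stop("AAACCCGGG", 0)))
  expect_error(scan_premature_stop("AAN", 0), "ACGT")

  set.seed(17)
  stops <- c("TAA", "TAG", "TGA")
  for (i in 1:200) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(3:60, 1),
                      replace = TRUE), collapse = "")
    for (frame in 0:2) {
      oracle <- NA_integer_
      k <- 0
      if (nchar(s) - frame >= 3) {
        for (start in seq(frame + 1, nchar(s) - 2, by = 3)) {
          if (start + 2 > nchar(s)) break
          k <- k + 1
          if (substr(s, start, start + 2) %in% stops) {
            oracle <- k
            break
          }
        }
      }
      expect_equal(scan_premature_stop(s, frame), oracle,
                   info = paste(s, frame))
    }
  }
})

test_that("the constructed tail-to-tail fusion behaves as designed", {
  toy <- fusion_toy()
  pred <- predict_fusion_transcript(
    toy$cluster, toy$models$GENEA, toy$models$GENEB, toy$genome
  )
  expect_equal(pred$orientation, "tail_to_tail")
  expect_true(pred$retained_intron)
  expect_equal(pred$premature_stop_offset, 4)
  expect_true(pred$nmd_predicted)
  expect_false(pred$polya_detectable)
  expect_equal(pred$driver, "GENEA")
  # the premature stop sits in the retained intron, upstream of the
  # breakpoint junction by more than the 50-nt window
  expect_gt(nchar(pred$transcript), 0)
})

test_that("a clean in-frame head-to-tail fusion has no premature stop", {
  toy <- fusion_toy()
  set.seed(23)
  # single-exon plus-strand acceptor whose CDS ends in its own TAA
  fb2 <- sample(c("A", "C", "G", "T"), 700, replace = TRUE)
  gene_c <- gene_model("GENEC", "chr_fC", "+",
                       exons = data.frame(start = 101, end = 460),
                       cds_start = 101, cds_end = 400)
  cp <- cds_positions(gene_c)
  sense <- setdiff(names(somatier:::CODON_TABLE), c("TAA", "TAG", "TGA"))
  codons <- c("ATG", sample(sense, length(cp) / 3 - 2, replace = TRUE),
              "TAA")
  fb2[cp] <- strsplit(paste(codons, collapse = ""), "")[[1]]
  genome <- c(toy$genome, list(chr_fC = paste(fb2, collapse = "")))

  # driver breakend at the end of exon 2 (codon-aligned, exonic);
  # acceptor breakend at a codon boundary so frames align
  cl <- sv_clusters(data.frame(
    left_chrom = "chr_fA", left_pos = 260, left_dir = "+",
    right_chrom = "chr_fC", right_pos = 200, right_dir = "-",
    n_pairs = 30, span = 10000
  ))
  pred <- predict_fusion_transcript(cl, toy$models$GENEA, gene_c, genome)
  expect_equal(pred$orientation, "head_to_tail")
  expect_true(pred$polya_detectable)
  expect_false(pred$retained_intron)
  expect_true(is.na(pred$premature_stop_offset)) # only GENEC's terminator
  expect_false(pred$nmd_predicted)
})

test_that("a frame-shifting junction finds the stop of the shifted frame", {
  toy <- fusion_toy()
  set.seed(23)
  fb2 <- sample(c("A", "C", "G", "T"), 700, replace = TRUE)
  gene_c <- gene_model("GENEC", "chr_fC", "+",
                       exons = data.frame(start = 101, end = 460),
                       cds_start = 101, cds_end = 400)
  cp <- cds_positions(gene_c)
  sense <- setdiff(names(somatier:::CODON_TABLE), c("TAA", "TAG", "TGA"))
  codons <- c("ATG", sample(sense, length(cp) / 3 - 2, replace = TRUE),
              "TAA")
  fb2[cp] <- strsplit(paste(codons, collapse = ""), "")[[1]]
  genome <- c(toy$genome, list(chr_fC = paste(fb2, collapse = "")))
  cl <- sv_clusters(data.frame(
    left_chrom = "chr_fA", left_pos = 260, left_dir = "+",
    right_chrom = "chr_fC", right_pos = 201, right_dir = "-",
    n_pairs = 30, span = 10000
  ))
  pred <- predict_fusion_transcript(cl, toy$models$GENEA, gene_c, genome)
  # oracle: scan the assembled transcript downstream of the driver's last
  # complete codon with an independent window scan
  downstream <- substr(pred$transcript, 121, nchar(pred$transcript))
  oracle <- NA_integer_
  k <- 0
  for (start in seq(1, nchar(downstream) - 2, by = 3)) {
    k <- k + 1
    if (substr(downstream, start, start + 2) %in%
          c("TAA", "TAG", "TGA")) {
      oracle <- k
      break
    }
  }
  expect_equal(pred$premature_stop_offset, oracle)
})

test_that("retained-intron transcripts with an early in-frame stop get NMD", {
  # property: stop before the final junction by more than 50 nt
  toy <- fusion_toy()
  pred <- predict_fusion_transcript(
    toy$cluster, toy$models$GENEA, toy$models$GENEB, toy$genome
  )
  stop_end <- 120 + 3 * pred$premature_stop_offset
  junction <- regexpr(pred$junction_sequence, pred$transcript, fixed = TRUE)
  expect_true(pred$retained_intron)
  expect_true(pred$nmd_predicted)
  expect_gt(260 - stop_end, 50) # breakpoint junction at transcript nt 260
})

test_that("cluster tables round-trip and validate", {
  cl <- ten_clusters()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sv_clusters(cl, path)
  back <- read_sv_clusters(path)
  expect_equal(as.data.frame(back), as.data.frame(cl))
  bad <- as.data.frame(cl)
  bad$left_dir[1] <- "x"
  expect_error(sv_clusters(bad), "directions")
})
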