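test_that("variant class is inferred from alleles alone", {
  expect_equal(infer_variant_class("G", "A"), "SNV")
  expect_equal(infer_variant_class("", "TC"), "insertion")
  expect_equal(infer_variant_class("CTG", ""), "deletion")
  expect_equal(infer_variant_class("AT", "GC"), "substitution")
  expect_equal(infer_variant_class("A", "GC"), "substitution")
  expect_error(infer_variant_class("A", "A"), "ref == alt")
})

test_that("cgi-tsv rows parse with positions, alleles and score preserved", {
  v <- parse_variant_record("chr12\t64491096\tG\tA\t0.35", "cgi-tsv")
  expect_equal(v$chrom, "chr12")
  expect_equal(v$pos, 64491096)
  expect_equal(v$ref, "G")
  expect_equal(v$alt, "A")
  expect_equal(v$class, "SNV")
  expect_equal(v$score, 0.35)

  del <- parse_variant_record("chr19\t8162193\tCTG\t-\t0.5", "cgi-tsv")
  expect_equal(del$class, "deletion")
  expect_equal(nchar(del$ref), 3)

  expect_error(parse_variant_record("chr1\t10\tA\tA\t0.2", "cgi-tsv"),
               "ref == alt")
  expect_error(parse_variant_record("chr1\t10\tA", "cgi-tsv"), "column")
  expect_error(parse_variant_record("chr1\tx\tA\tC\t0.2", "cgi-tsv"),
               "column 2")
  expect_error(parse_variant_record("chr1\t10\tA\tC\t0.2", "made-up"),
               "unknown variant dialect")
})

test_that("vcf-min rows parse, including anchored indels and SS scores", {
  v <- parse_variant_record(
    "chr1\t100\t.\tG\tT\t.\t.\tSS=0.42", "vcf-min"
  )
  expect_equal(v$class, "SNV")
  expect_equal(v$score, 0.42)

  ins <- parse_variant_record(
    "chr1\t100\t.\tA\tATC\t.\t.\tSS=0.9", "vcf-min"
  )
  expect_equal(ins$class, "insertion")
  expect_equal(ins$pos, 100) # insertion after the anchor base
  expect_equal(ins$alt, "TC")

  del <- parse_variant_record(
    "chr1\t100\t.\tACTG\tA\t.\t.\tSS=0.9", "vcf-min"
  )
  expect_equal(del$class, "deletion")
  expect_equal(del$pos, 101) # first deleted base
  expect_equal(del$ref, "CTG")
})

test_that("variant tables round-trip through both dialects", {
  vt <- random_variant_table(300, seed = 42)
  for (dialect in c("cgi-tsv", "vcf-min")) {
    path <- withr::local_tempfile(fileext = ".txt")
    write_variants(vt, path, dialect)
    back <- read_variants(path, dialect)
    expect_equal(back$chrom, vt$chrom)
    expect_equal(back$pos, vt$pos)
    expect_equal(back$ref, vt$ref)
    expect_equal(back$alt, vt$alt)
    expect_equal(back$class, vt$class)
    expect_equal(back$score, vt$score)
  }
})

test_that("genome build validates lengths, centromeres and names", {
  b <- genome_build(c("chr1", "chr2"), c(100, 200), c(40, 80))
  arms <- chrom_arms(b)
  expect_equal(nrow(arms), 4)
  expect_equal(arms$end[arms$chrom == "chr1" & arms$arm == "p"], 40)
  expect_error(genome_build(c("chr1", "chr1"), c(100, 100)), "unique")
  expect_error(genome_build("chr1", -5), "positive")
  expect_error(genome_build("chr1", 100, 100), "centromere")
  expect_equal(chrom_arms(genome_build("chr1", 100))$arm, "whole")
})

test_that("BED interval membership follows the 1-based point convention", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t10\t20", bed) # 0-based half-open on disk
  track <- read_track_bed(bed)
  expect_true(track_membership(track, "chr1", 11))
  expect_false(track_membership(track, "chr1", 10))
  expect_true(track_membership(track, "chr1", 20))
  expect_false(track_membership(track, "chr1", 21))
  expect_message(
    expect_false(track_membership(track, "chrZ", 5)),
    "absent from track"
  )
  expect_error(track_membership(track, "chr1", 0), "1-based")
})

test_that("membership and score lookups agree with a linear-scan oracle", {
  set.seed(7)
  n_iv <- 60
  chrom <- sample(paste0("chr", 1:3), n_iv, replace = TRUE)
  start <- sample(1e4, n_iv)
  end <- start + sample(0:500, n_iv, replace = TRUE)
  track <- interval_track(chrom, start, end)
  scored <- local({
    # non-overlapping scored intervals on a grid
    s <- seq(1, 9000, by = 300)
    keep <- sample(c(TRUE, FALSE), length(s), replace = TRUE)
    interval_track(
      rep("chr1", sum(keep)), s[keep], s[keep] + 99,
      score = sample(0:1000, sum(keep))
    )
  })
  q_chrom <- sample(paste0("chr", 1:3), 1000, replace = TRUE)
  q_pos <- sample(11000, 1000, replace = TRUE)

  oracle_member <- vapply(seq_along(q_pos), function(i) {
    any(chrom == q_chrom[i] & start <= q_pos[i] & end >= q_pos[i])
  }, logical(1))
  expect_equal(track_membership(track, q_chrom, q_pos), oracle_member)

  q1 <- sample(11000, 1000, replace = TRUE)
  oracle_score <- vapply(q1, function(p) {
    hit <- which(GenomicRanges::start(scored) <= p &
                   GenomicRanges::end(scored) >= p)
    if (length(hit)) scored$score[hit[1]] else 0
  }, numeric(1))
  expect_equal(track_score(scored, rep("chr1", 1000), q1), oracle_score)
})

test_that("scored tracks reject overlaps and out-of-range scores", {
  bg <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines(c("chr1\t0\t100\t600", "chr1\t50\t150\t700"), bg)
  expect_error(read_track_bedgraph(bg), "overlap")
  bg2 <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines("chr1\t0\t100\t2000", bg2)
  expect_error(read_track_bedgraph(bg2), "\\[0, 1000\\]")
})

test_that("gene models enforce their structural invariants", {
  expect_error(
    gene_model("G", "chr1", "+",
               exons = data.frame(start = c(1, 50), end = c(60, 100)),
               cds_start = 1, cds_end = 100),
    "overlap"
  )
  expect_error(
    gene_model("G", "chr1", "+",
               exons = data.frame(start = 1, end = 100),
               cds_start = 1, cds_end = 100),
    "multiple of 3"
  )
  m <- gene_model("G", "chr1", "+",
                  exons = data.frame(start = c(1, 200), end = c(30, 229)),
                  cds_start = 1, cds_end = 229)
  expect_equal(length(cds_positions(m)), 60)
  expect_equal(nrow(introns(m)), 1)
})

test_that("gene model sets round-trip through GTF", {
  gen <- generate_genome(small_sim_config(seed = 9L))
  path <- withr::local_tempfile(fileext = ".gtf")
  write_gene_models(gen$models, path)
  back <- read_gene_models(path)
  expect_setequal(names(back), names(gen$models))
  for (g in names(gen$models)) {
    expect_equal(back[[g]]$exons, gen$models[[g]]$exons, info = g)
    expect_equal(back[[g]]$strand, gen$models[[g]]$strand, info = g)
    expect_equal(back[[g]]$biotype, gen$models[[g]]$biotype, info = g)
    if (gen$models[[g]]$biotype == "protein_coding") {
      expect_equal(back[[g]]$cds_start, gen$models[[g]]$cds_start, info = g)
      expect_equal(back[[g]]$cds_end, gen$models[[g]]$cds_end, info = g)
    }
  }
})
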