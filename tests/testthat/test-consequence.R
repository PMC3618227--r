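test_that("translate_cds follows the standard code and stops at stops", {
  expect_equal(translate_cds("ATGCGTCAT"), "MRH")
  expect_equal(translate_cds("ATGTAA"), "M")
  expect_equal(translate_cds("ATGTAACGT"), "M")
  expect_error(translate_cds("ATGC"), "multiple of 3")
  expect_error(translate_cds("ATGNNN"), "offset 4")
})

test_that("translate_cds matches Biostrings on random 300-mers", {
  set.seed(21)
  for (i in 1:100) {
    s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
               collapse = "")
    oracle <- as.character(
      Biostrings::translate(Biostrings::DNAString(s), no.init.codon = TRUE)
    )
    oracle <- sub("\\*.*$", "", oracle) # terminate at first stop
    expect_equal(translate_cds(s), oracle, info = s)
  }
})

test_that("coding SNVs are labelled by codon retranslation", {
  toy <- make_toy_gene(codon2 = "CGT") # R at codon 2
  cp <- cds_positions(toy$model)
  codon2_pos <- cp[4:6]
  # every single-base change of codon 2, vs the codon table directly
  for (within in 1:3) {
    pos <- codon2_pos[within]
    ref <- substr(toy$genome$chrT, pos, pos)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      v <- variant_table("chrT", pos, ref, alt)
      call <- call_consequence(v, toy$model, toy$genome)
      codon <- strsplit("CGT", "")[[1]]
      codon[within] <- alt
      new_aa <- somatier:::CODON_TABLE[paste(codon, collapse = "")]
      if (new_aa == "R") {
        expect_equal(call$effect, "synonymous")
      } else {
        expect_equal(call$effect, "non_synonymous")
        expect_equal(call$label, paste0("R2", new_aa))
      }
    }
  }
  # the worked middle-base example: CGT -> CAT is R2H
  pos <- codon2_pos[2]
  v <- variant_table("chrT", pos, "G", "A")
  expect_equal(call_consequence(v, toy$model, toy$genome)$label, "R2H")
})

test_that("minus-strand coding SNVs complement correctly", {
  toy <- make_toy_gene(codon2 = "CGT", strand = "-")
  cp <- cds_positions(toy$model) # descending genomic order
  pos <- cp[5] # middle base of codon 2
  ref <- substr(toy$genome$chrT, pos, pos)
  expect_equal(ref, "C") # complement of G
  v <- variant_table("chrT", pos, ref, "T") # tx base G -> A
  call <- call_consequence(v, toy$model, toy$genome)
  expect_equal(call$label, "R2H")
})

test_that("silent substitutions are never called non-synonymous", {
  # property over all 64 codons x all silent single-base substitutions
  tbl <- somatier:::CODON_TABLE
  for (codon in names(tbl)) {
    if (tbl[codon] == "*") next
    toy <- make_toy_gene(codon2 = codon)
    cp <- cds_positions(toy$model)
    for (within in 1:3) {
      pos <- cp[3 + within]
      ref <- substr(toy$genome$chrT, pos, pos)
      for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
        mutated <- strsplit(codon, "")[[1]]
        mutated[within] <- alt
        if (tbl[paste(mutated, collapse = "")] != tbl[codon]) next
        v <- variant_table("chrT", pos, ref, alt)
        call <- call_consequence(v, toy$model, toy$genome)
        expect_equal(
          call$effect, "synonymous",
          info = paste(codon, within, alt)
        )
      }
    }
  }
})

test_that("CDS indels split into frameshift and in-frame by length", {
  toy <- make_toy_gene()
  cp <- cds_positions(toy$model)
  codon3 <- cp[7:9] # contiguous within exon 1
  ref3 <- substr(toy$genome$chrT, codon3[1], codon3[3])
  del <- variant_table("chrT", codon3[1], ref3, "")
  call <- call_consequence(del, toy$model, toy$genome)
  expect_equal(call$effect, "inframe_indel")
  expect_match(call$label, "del$")

  ins <- variant_table("chrT", cp[10], "", "TC")
  call <- call_consequence(ins, toy$model, toy$genome)
  expect_equal(call$effect, "frameshift")
  expect_match(call$label, "fs$")

  far <- variant_table("chrT", 1500, "A", "C")
  expect_equal(call_consequence(far, toy$model, toy$genome)$effect,
               "intergenic")
})

test_that("UTR, intronic and splice classes fall out of position", {
  toy <- make_toy_gene()
  m <- gene_model(
    "UTRG", "chrT", "+",
    exons = data.frame(start = c(101, 201), end = c(160, 260)),
    cds_start = 121, cds_end = 241
  )
  utr5 <- variant_table("chrT", 110, substr(toy$genome$chrT, 110, 110),
                        setdiff(c("A", "C", "G", "T"),
                                substr(toy$genome$chrT, 110, 110))[1])
  expect_equal(call_consequence(utr5, m, toy$genome)$effect, "utr5")
  utr3 <- variant_table("chrT", 250, "A", "C")
  utr3$ref <- substr(toy$genome$chrT, 250, 250)
  utr3$alt <- setdiff(c("A", "C", "G", "T"), utr3$ref)[1]
  expect_equal(call_consequence(utr3, m, toy$genome)$effect, "utr3")
  mid_intron <- variant_table("chrT", 180, "A", "C")
  expect_equal(call_consequence(mid_intron, m, toy$genome)$effect,
               "intronic")
})

test_that("splice-site flag matches an exhaustive position sweep", {
  toy <- make_toy_gene()
  m <- toy$model # introns 161-200 and 261-320
  splice_set <- c(161, 162, 199, 200, 261, 262, 319, 320)
  for (pos in 100:400) {
    v <- list(chrom = "chrT", pos = pos)
    expect_equal(
      is_splice_site(v, m), pos %in% splice_set,
      info = paste("pos", pos)
    )
  }
})

test_that("damaging-by-either-predictor follows the published calls", {
  expect_true(damaging_by_any("Tolerated", "Damaging"))
  expect_false(damaging_by_any("Tolerated", "Tolerated"))
  expect_true(damaging_by_any(NA, "Damaging"))
  expect_error(damaging_by_any(NA, NA), "undefined")

  scores <- case_predictor_scores()
  dmg <- damaging_by_any(scores$sift_pred, scores$polyphen_pred)
  expect_equal(sum(dmg), 8)
  expect_equal(scores$gene[!dmg], "PPP1R3A")
})

test_that("predictor tables require score/prediction consistency", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "gene\tsift_pred\tsift_score\tpolyphen_pred\tpolyphen_score",
    "G1\tDamaging\t-\tDamaging\t0.9"
  ), path)
  expect_error(read_predictor_scores(path), "G1")
})
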