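test_that("somatic-score filtering is strictly greater-than", {
  vt <- variant_table(
    rep("chr1", 3), 1:3, rep("A", 3), rep("C", 3),
    score = c(0.11, 0.10, NA)
  )
  kept <- somatic_filter(vt, 0.1)
  expect_equal(kept$pos, 1)

  # a constructed set with 963 scores above and 5542 at/below the threshold
  n_hi <- 963
  n_lo <- 5542
  big <- variant_table(
    rep("chr1", n_hi + n_lo), seq_len(n_hi + n_lo),
    rep("A", n_hi + n_lo), rep("G", n_hi + n_lo),
    score = c(rep(0.2, n_hi), rep(0.1, n_lo))
  )
  expect_equal(nrow(somatic_filter(big, 0.1)), 963)
})

test_that("sensitivity and specificity come out of the confusion counts", {
  records <- data.frame(
    locus = letters[1:10],
    score = c(0.5, 0.3, 0.2, 0.15, 0.05, 0.4, 0.3, 0.05, 0.02, 0.01),
    confirmed = rep(c(TRUE, FALSE), each = 5)
  )
  cal <- sensitivity_specificity(records, 0.1)
  expect_equal(cal$sensitivity, 0.8)
  expect_equal(cal$specificity, 0.6)
  expect_equal(cal$tp + cal$fp + cal$tn + cal$fn, 10)

  all_pos <- data.frame(locus = "x", score = 0.5, confirmed = TRUE)
  expect_error(sensitivity_specificity(all_pos, 0.1),
               "specificity undefined")
  all_neg <- data.frame(locus = "x", score = 0.5, confirmed = FALSE)
  expect_error(sensitivity_specificity(all_neg, 0.1),
               "sensitivity undefined")
})

test_that("threshold sweeps match a brute-force ROC oracle and are monotone", {
  set.seed(31)
  records <- data.frame(
    locus = sprintf("l%03d", 1:150),
    score = round(runif(150), 3),
    confirmed = runif(150) < 0.5
  )
  thresholds <- seq(0, 0.95, by = 0.05)
  prev_sens <- Inf
  prev_spec <- -Inf
  for (t in thresholds) {
    cal <- sensitivity_specificity(records, t)
    oracle_sens <- mean(records$score[records$confirmed] > t)
    oracle_spec <- mean(records$score[!records$confirmed] <= t)
    expect_equal(cal$sensitivity, oracle_sens)
    expect_equal(cal$specificity, oracle_spec)
    expect_lte(cal$sensitivity, prev_sens)
    expect_gte(cal$specificity, prev_spec)
    prev_sens <- cal$sensitivity
    prev_spec <- cal$specificity
  }
})

test_that("known-variant exclusion removes listed positions only", {
  vt <- variant_table(c("chr1", "chr1", "chr2"), c(10, 20, 10),
                      c("A", "C", "G"), c("C", "A", "T"))
  known <- data.frame(chrom = c("chr1", "chr3"), pos = c(10, 10))
  kept <- exclude_known(vt, known)
  expect_equal(nrow(kept), 2)
  expect_false(any(kept$chrom == "chr1" & kept$pos == 10))

  # 500 random variants against the union of two tracks, vs a set oracle
  set.seed(13)
  vt2 <- random_variant_table(500, seed = 13)
  k1 <- data.frame(chrom = sample(paste0("chr", 1:5), 300, replace = TRUE),
                   pos = sample(1e6, 300))
  k2 <- data.frame(chrom = sample(paste0("chr", 1:5), 300, replace = TRUE),
                   pos = sample(1e6, 300))
  kept2 <- exclude_known(vt2, list(k1, k2))
  keys <- union(paste(k1$chrom, k1$pos), paste(k2$chrom, k2$pos))
  oracle <- vt2[!(paste(vt2$chrom, vt2$pos) %in% keys), ]
  expect_equal(kept2$pos, oracle$pos)
  expect_equal(kept2$chrom, oracle$chrom)
})

test_that("tier assignment follows the precedence ladder", {
  segdup <- interval_track("chr1", 1000, 2000)
  repeats <- interval_track(c("chr1", "chr1"), c(1800, 3000),
                            c(2500, 4000))
  cons <- interval_track("chr1", 5000, 6000, score = 600)

  v <- function(pos) variant_table("chr1", pos, "A", "C", score = 0.5)
  t_of <- function(pos, effect) {
    assign_tier(v(pos), effect, segdup, repeats, cons)$tier
  }
  expect_equal(t_of(100, "non_synonymous"), 1L)
  # segmental duplication disqualifies tier 1 only: the variant continues
  # down the ladder to tier 3 (non-repeat) or tier 4 (repeat-masked)
  expect_equal(t_of(1500, "non_synonymous"), 3L)
  expect_equal(t_of(1900, "non_synonymous"), 4L)
  expect_equal(t_of(3500, "non_synonymous"), 1L) # repeat alone is no bar
  expect_equal(t_of(5500, "intronic"), 2L) # conserved > 500
  expect_equal(t_of(3500, "intronic"), 4L) # repeat-masked
  expect_equal(t_of(100, "utr5"), 2L)
  expect_equal(t_of(100, "intergenic"), 3L)
  expect_equal(t_of(100, "miRNA_locus"), 1L)
})

test_that("tier assignment agrees with a truth-table oracle", {
  # all 2^4 feature combinations x every effect class
  tier_oracle <- function(effect, segdup, conserved, repeatm) {
    t1 <- effect %in% c("non_synonymous", "frameshift", "inframe_indel",
                        "splice_site", "miRNA_locus")
    t2 <- effect %in% c("utr5", "utr3", "ncRNA")
    if (t1 && !segdup) return(1L)
    if (t2 || conserved) return(2L)
    if (!repeatm) return(3L)
    4L
  }
  effects <- c("non_synonymous", "frameshift", "inframe_indel",
               "splice_site", "miRNA_locus", "utr5", "utr3", "ncRNA",
               "intronic", "intergenic", "synonymous")
  grid <- expand.grid(
    segdup = c(FALSE, TRUE), conserved = c(FALSE, TRUE),
    repeatm = c(FALSE, TRUE), effect = effects,
    stringsAsFactors = FALSE
  )
  # one position per combination; tracks built to realize the features
  pos <- 1000 * seq_len(nrow(grid))
  segdup_track <- interval_track("chr1", pos[grid$segdup] - 1,
                                 pos[grid$segdup] + 1)
  repeat_track <- interval_track("chr1", pos[grid$repeatm] - 1,
                                 pos[grid$repeatm] + 1)
  cons_track <- interval_track("chr1", pos[grid$conserved] - 1,
                               pos[grid$conserved] + 1, score = 700)
  vt <- variant_table(rep("chr1", nrow(grid)), pos,
                      rep("A", nrow(grid)), rep("C", nrow(grid)),
                      score = 0.5)
  got <- assign_tier(vt, grid$effect, segdup_track, repeat_track,
                     cons_track)
  want <- mapply(tier_oracle, grid$effect, grid$segdup, grid$conserved,
                 grid$repeatm)
  expect_equal(got$tier, unname(want))
  # partition: every variant gets exactly one tier in 1..4
  expect_true(all(got$tier %in% 1:4))
  expect_true(all(nzchar(got$reasons)))
})

test_that("a missing conservation track skips the clause with a warning", {
  vt <- variant_table("chr1", 5500, "A", "C", score = 0.5)
  expect_warning(
    res <- assign_tier(vt, "intronic", empty_track(), empty_track(), NULL),
    "conservation"
  )
  expect_equal(res$tier, 3L) # would be tier 2 with the conserved track
})

test_that("count summaries are internally consistent", {
  vt <- case_tier1_variants()
  s <- summarize_counts(vt, rep(1L, nrow(vt)))
  expect_equal(s$total, 12)
  expect_equal(s$snv_count, 10)
  expect_equal(s$indel_count, 2)
  t1 <- s$by_class_tier[s$by_class_tier$tier == 1, ]
  expect_equal(t1$count[t1$class == "SNV"], 10)
  expect_equal(sum(t1$count[t1$class != "SNV"]), 2)

  empty <- summarize_counts(variant_table(character(0), numeric(0),
                                          character(0), character(0)))
  expect_equal(empty$total, 0)
  expect_true(all(empty$by_class$count == 0))

  set.seed(3)
  vt2 <- random_variant_table(400, seed = 3)
  tiers <- sample(1:4, 400, replace = TRUE)
  s2 <- summarize_counts(vt2, tiers)
  expect_equal(s2$total, 400)
  expect_equal(sum(s2$by_tier$count), 400)
  for (cl in unique(vt2$class)) {
    expect_equal(
      s2$by_class$count[s2$by_class$class == cl],
      sum(vt2$class == cl)
    )
  }
})
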