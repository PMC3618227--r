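#' Pipeline configuration
#'
#' Paths to every input plus all analysis thresholds. Defaults are the
#' calibrated operating points of the analysis: somatic-score cutoff 0.1,
#' phastCons-style conservation cutoff 500 (of 1000), SV support > 20 pairs
#' and span > 5 kb, copy-number gain/loss at +/-0.2 log2, arm coverage
#' fraction 0.5 and mutant-skew threshold 0.8.
#'
#' @param input_dir directory holding the input files (the layout written
#'   by [simulate_run()]).
#' @param out_dir directory for reports.
#' @param ... overrides for any config field (thresholds, file names, seed).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir, out_dir, ...) {
  cfg <- list(
    input_dir = input_dir,
    out_dir = out_dir,
    variants_file = "somatic.vcf",
    variant_dialect = "vcf-min",
    known_file = "known.tsv",
    segdup_file = "segdup.bed",
    repeats_file = "repeats.bed",
    conservation_file = "conservation.bedgraph",
    genes_file = "genes.gtf",
    genome_file = "genome.fa",
    build_file = "build.tsv",
    probes_file = "probes.tsv",
    clusters_file = "sv_clusters.tsv",
    pileups_file = "pileups.tsv",
    expression_file = "expression.tsv",
    validation_file = "validation.tsv",
    snp_counts_file = "snp_counts.tsv",
    somatic_threshold = 0.1,
    conservation_cutoff = 500,
    sv_min_pairs = 20,
    sv_min_span = 5000,
    cn_gain_threshold = 0.2,
    cn_loss_threshold = -0.2,
    cn_min_probes = 5,
    cn_alpha = 0.01,
    cn_permutations = 1000,
    arm_fraction = 0.5,
    skew_threshold = 0.8,
    seed = 1L
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) {
    stop("unknown pipeline config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(overrides)] <- overrides
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' YAML keys override the defaults of [pipeline_config()]; `input_dir` and
#' `out_dir` must be present in the file or supplied as arguments.
#'
#' @param path YAML file.
#' @param ... further overrides (win over the file).
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  args <- utils::modifyList(vals, list(...))
  if (is.null(args$input_dir) || is.null(args$out_dir)) {
    stop("pipeline config needs input_dir and out_dir")
  }
  do.call(pipeline_config, args)
}

#' Run the full downstream analysis
#'
#' Executes, in order: known-variant exclusion, somatic-score filtering,
#' consequence annotation, tier assignment and summary; copy-number
#' segmentation, segment classification, arm-level event calling and (when
#' tumor/normal SNP counts are available) the SNP-depletion comparison;
#' SV filtering with fusion prediction for survivors whose breakends both
#' fall inside annotated genes; somatic-score calibration against the
#' validation truth set; and tier-1 expression integration. Reports are
#' written as TSV plus a JSON twin, together with a run log recording every
#' effective parameter, so two runs with the same config and seed produce
#' byte-identical reports.
#'
#' Optional inputs degrade gracefully: a missing conservation track skips
#' the tier-2 conservation clause (with a warning), and missing
#' validation / SNP-count / expression tables skip their stages.
#'
#' @param config a `pipeline_config` (or path to a YAML config).
#' @return (invisibly) list with every stage result.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  ip <- function(f) file.path(config$input_dir, config[[f]])
  have <- function(f) file.exists(ip(f))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  op <- function(x) file.path(config$out_dir, x)
  results <- list(config = config)

  # --- variant tiering -------------------------------------------------
  variants <- read_variants(ip("variants_file"), config$variant_dialect)
  known <- utils::read.delim(ip("known_file"), stringsAsFactors = FALSE)
  segdup <- read_track_bed(ip("segdup_file"))
  repeats <- read_track_bed(ip("repeats_file"))
  conservation <- if (have("conservation_file")) {
    read_track_bedgraph(ip("conservation_file"))
  } else {
    NULL
  }
  models <- read_gene_models(ip("genes_file"))
  genome <- if (have("genome_file")) {
    Biostrings::readDNAStringSet(ip("genome_file"))
  } else {
    NULL
  }
  if (!is.null(genome)) names(genome) <- sub(" .*", "", names(genome))

  retained <- exclude_known(variants, known)
  high_conf <- somatic_filter(retained, config$somatic_threshold)
  cons <- annotate_consequences(high_conf, models, genome)
  tiers <- assign_tier(
    high_conf, cons$effect, segdup, repeats, conservation,
    config$conservation_cutoff
  )
  tiered <- cbind(high_conf, cons, tiers)
  summary <- summarize_counts(high_conf, tiers$tier)
  utils::write.table(tiered, op("tiers.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(
      excluded_known = nrow(variants) - nrow(retained),
      below_threshold = nrow(retained) - nrow(high_conf),
      high_confidence = summary$total,
      snv = summary$snv_count, indel = summary$indel_count,
      by_tier = if (!is.null(summary$by_tier)) summary$by_tier else NULL
    ),
    op("tier_summary.json"), auto_unbox = TRUE, pretty = TRUE
  )
  utils::write.table(summary$by_class_tier, op("tier_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  results$tiered <- tiered
  results$summary <- summary

  # --- calibration -----------------------------------------------------
  if (have("validation_file")) {
    val <- utils::read.delim(ip("validation_file"), stringsAsFactors = FALSE)
    calib <- sensitivity_specificity(val, config$somatic_threshold)
    jsonlite::write_json(
      unclass(calib), op("calibration.json"), auto_unbox = TRUE,
      pretty = TRUE
    )
    results$calibration <- calib
  }

  # --- copy number -----------------------------------------------------
  build_df <- utils::read.delim(ip("build_file"), stringsAsFactors = FALSE)
  build <- genome_build(build_df$chrom, build_df$length, build_df$centromere)
  probes <- read_probes(ip("probes_file"))
  segments <- segment_profile(
    probes, min_probes = config$cn_min_probes, alpha = config$cn_alpha,
    permutations = config$cn_permutations, seed = config$seed
  )
  segments <- classify_segments(
    segments, config$cn_gain_threshold, config$cn_loss_threshold
  )
  arms <- arm_events(segments, build, config$arm_fraction)
  write_segments(segments, op("segments.seg"))
  utils::write.table(arms, op("arm_events.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  results$segments <- segments
  results$arm_events <- arms

  if (have("snp_counts_file")) {
    counts <- utils::read.delim(ip("snp_counts_file"),
                                stringsAsFactors = FALSE)
    loss_chroms <- unique(arms$chrom[arms$state == "loss"])
    depl <- snp_depletion(
      stats::setNames(counts$normal, counts$chrom),
      stats::setNames(counts$tumor, counts$chrom),
      loss_chroms
    )
    jsonlite::write_json(
      unclass(depl)[c("loss_mean", "loss_sd", "neutral_mean", "neutral_sd",
                      "p_value")],
      op("snp_depletion.json"), auto_unbox = TRUE, pretty = TRUE
    )
    results$depletion <- depl
  }

  # --- structural variants ---------------------------------------------
  clusters <- read_sv_clusters(ip("clusters_file"))
  survivors <- filter_sv_candidates(
    clusters, config$sv_min_pairs, config$sv_min_span
  )
  write_sv_clusters(survivors, op("sv_survivors.tsv"))
  results$sv_survivors <- survivors
  if (!is.null(genome)) {
    preds <- list()
    for (i in seq_len(nrow(survivors))) {
      cl <- survivors[i, , drop = FALSE]
      ga <- model_containing(models, cl$left_chrom, cl$left_pos)
      gb <- model_containing(models, cl$right_chrom, cl$right_pos)
      if (is.null(ga) || is.null(gb)) next
      preds[[length(preds) + 1]] <- tryCatch(
        predict_fusion_transcript(cl, ga, gb, genome),
        error = function(e) {
          warning("fusion prediction skipped for cluster ", i, ": ",
                  conditionMessage(e))
          NULL
        }
      )
    }
    preds <- Filter(Negate(is.null), preds)
    if (length(preds)) {
      jsonlite::write_json(
        lapply(preds, function(p) {
          x <- unclass(p)
          x$transcript <- NULL
          x
        }),
        op("fusions.json"), auto_unbox = TRUE, pretty = TRUE, na = "null"
      )
    }
    results$fusions <- preds
  }

  # --- expression integration ------------------------------------------
  if (have("expression_file") && have("pileups_file")) {
    expr <- read_expression_table(ip("expression_file"))
    pile <- read_pileups(ip("pileups_file"))
    t1 <- tiered[tiered$tier == 1, , drop = FALSE]
    t1 <- t1[t1$gene != "", c("gene", "label")]
    t1 <- t1[!duplicated(t1$gene), , drop = FALSE]
    report <- integrate_expression(t1, expr, pile, config$skew_threshold)
    utils::write.table(report, op("expression_report.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report, op("expression_report.json"),
                         auto_unbox = TRUE, pretty = TRUE, na = "null")
    results$expression_report <- report
  }

  # --- run log ---------------------------------------------------------
  log_cfg <- unclass(config)
  yaml::write_yaml(log_cfg, op("run_log.yaml"))
  invisible(results)
}

model_containing <- function(models, chrom, pos) {
  for (m in models) {
    sp <- gene_span(m)
    if (m$chrom == chrom && pos >= sp[1] && pos <= sp[2]) return(m)
  }
  NULL
}
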