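#!/usr/bin/env Rscript
# Structural variation: the discordant-pair support/span filter, and the
# fusion-transcript worked example - a tail-to-tail junction whose retained
# intron carries an in-frame stop four codons past the last exon, predicted
# to trigger nonsense-mediated decay and to be invisible to poly-A-capture
# RNA sequencing.

suppressPackageStartupMessages(library(somatier))
dir.create("results/sv_fusion", recursive = TRUE, showWarnings = FALSE)

clusters <- sv_clusters(data.frame(
  left_chrom = "chr1", left_pos = 1000 * (1:10), left_dir = "+",
  right_chrom = "chr2", right_pos = 2000 * (1:10), right_dir = "-",
  n_pairs = c(25, 30, 40, 20, 21, 15, 10, 5, 18, 22),
  span = c(12, 8, 100, 50, 5, 20, 2, 9, 4, 3) * 1000
))
kept <- filter_sv_candidates(clusters, min_pairs = 20, min_span = 5000)
message(nrow(kept), " of ", nrow(clusters),
        " clusters pass the strict >20-pair and >5-kb filter")
write_sv_clusters(kept, "results/sv_fusion/survivors.tsv")

toy <- fusion_toy()
pred <- predict_fusion_transcript(toy$cluster, toy$models$GENEA,
                                  toy$models$GENEB, toy$genome)
print(pred)
write_fusion_json(pred, "results/sv_fusion/fusion_prediction.json")
writeLines(
  c(">fusion_junction", pred$junction_sequence),
  "results/sv_fusion/junction.fa"
)
message("wrote results/sv_fusion/")
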