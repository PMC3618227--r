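#!/usr/bin/env Rscript
# Generate the synthetic study dataset: a desk-scale tumor/normal genome
# with germline SNPs, tiered somatic variants, feature tracks, aCGH probes,
# SV clusters, RNA pileups and a 104-locus validation set. Every downstream
# driver reads from results/sim/.

suppressPackageStartupMessages(library(somatier))

cfg <- simulation_config(seed = 20130405 %% 1000L)
message("simulating with seed ", cfg$seed, ": ",
        length(cfg$chrom_lengths), " chromosomes, ",
        cfg$n_genes, " genes, ", cfg$germline_snps, " germline SNPs, ",
        sum(cfg$somatic_counts), " true somatic variants")

sim <- simulate_run(cfg, out_dir = "results/sim")

message("wrote ", length(list.files("results/sim")), " input files")
message("somatic candidate classes:")
print(table(sim$somatic$truth))
message("configured copy-number events:")
print(cfg$cn_events)
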