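#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study data.
#
# Emulates an around-the-clock liver profiling design: 12 Zeitgeber times
# every 2 h, 2 replicate series, paired RPF and RNA count matrices with
# planted rhythms (10% mRNA-level, 10% TE-level, 10% both), NB dispersion
# 0.05, plus a small FASTQ fixture of adapter-tagged reads with contaminant
# spike-ins for the preprocessing stage.

library(clocktide)

out <- "results/synthetic"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20160305L

design <- ts_design()
params <- sim_params(n_genes = 2000, seed = seed)
sim <- simulate_counts(design, params)

write.table(data.frame(gene_id = rownames(sim$rna), unclass(sim$rna),
                       check.names = FALSE),
            file.path(out, "counts_rna.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(gene_id = rownames(sim$rpf), unclass(sim$rpf),
                       check.names = FALSE),
            file.path(out, "counts_rpf.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(sim$truth, file.path(out, "truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(design, file.path(out, "samples.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

fq <- simulate_fastq(
  n_clean = 400,
  n_contaminant = c(rRNA_mouse = 300, rRNA_human = 80, mt_tRNA = 60,
                    tRNA = 60),
  adapter = "AGATCGGAAGAGCACACGTCT", seed = seed,
  fastq_path = file.path(out, "reads_rpf.fastq"),
  manifest_path = file.path(out, "reads_manifest.tsv"))

message(sprintf("simulated %d genes x %d samples per assay",
                nrow(sim$rna), ncol(sim$rna)))
print(table(sim$truth$true_class))
message(sprintf("FASTQ fixture: %d reads (%s)", nrow(fq$manifest),
                paste(names(table(fq$manifest$origin)), collapse = ", ")))
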