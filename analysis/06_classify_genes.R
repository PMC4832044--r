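#!/usr/bin/env Rscript
# Stage 6: classification of rhythm origin and evaluation against truth.
#
# Genes rhythmic in mRNA abundance and footprints are "both"; rhythmic
# footprints on flat mRNA are "translation_only" — rhythms generated at the
# level of protein synthesis; the TE call is carried as supporting evidence.

library(clocktide)

out <- "results/synthetic"
read_calls <- function(l)
  read.delim(file.path(out, sprintf("rhythm_%s.tsv", l)))
cl <- classify_genes(read_calls("rna"), read_calls("rpf"), read_calls("te"))
write.table(cl, file.path(out, "classification.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
print(table(cl$category))

truth <- read.delim(file.path(out, "truth.tsv"))
ev <- evaluate_against_truth(cl, truth)
message(sprintf("detected genes: %d; rhythmic RNA %.1f%%, rhythmic RPF %.1f%%",
                ev$n_detected_genes, 100 * ev$fraction_rhythmic_rna,
                100 * ev$fraction_rhythmic_rpf))
message("confusion matrix (truth x called):")
print(ev$confusion)
print(ev$per_category, row.names = FALSE)
write.table(ev$per_category, file.path(out, "evaluation.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
jsonlite::write_json(
  list(n_detected_genes = ev$n_detected_genes,
       n_per_category = as.list(ev$n_per_category),
       fraction_rhythmic_rna = ev$fraction_rhythmic_rna,
       fraction_rhythmic_rpf = ev$fraction_rhythmic_rpf),
  file.path(out, "summary.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
message("wrote classification, evaluation and summary under ", out)
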