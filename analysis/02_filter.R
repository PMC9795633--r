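#!/usr/bin/env Rscript
# Filter the candidate-mutation tables with the three-stage cascade
# (Poisson LRT + BH at 1% FDR, ubiquity, persistence) and report how many
# candidates each stage removes and how the survivors relate to the truth.

suppressPackageStartupMessages(library(evotraj))
dir.create("results", showWarnings = FALSE)

for (run in c("mouse", "fly")) {
  variants <- read_variant_table(sprintf("results/data/%s_variants.tsv", run))
  sheet <- read_sample_sheet(sprintf("results/data/%s_samples.tsv", run))
  res <- filter_pipeline(variants, sheet)
  write_variant_table(res$filtered, sprintf("results/%s_filtered.tsv", run))
  write.table(res$report$per_mutation,
              sprintf("results/%s_filter_report.tsv", run),
              sep = "\t", quote = FALSE, row.names = FALSE)

  truth <- read.delim(sprintf("results/data/%s_truth_mutations.tsv", run))
  fp <- truth$mutation_id[truth$is_false_positive]
  kept <- res$filtered$mutation_id
  cat(sprintf("[%s] cascade: %s\n", run,
              paste(sprintf("%s %d->%d", res$report$stages$stage,
                            res$report$stages$n_in, res$report$stages$n_out),
                    collapse = ", ")))
  cat(sprintf("[%s] false positives kept: %d of %d; true mutations kept: %d of %d\n",
              run, sum(kept %in% fp), length(fp),
              sum(!(kept %in% fp)), sum(!truth$is_false_positive)))
}
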