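#!/usr/bin/env Rscript
# Reconstruct genotype nesting for the fly arms (where sweeps define a small
# number of genotypes) and export ggmuller-compatible edge/population tables.
# The mouse-host hypermutator arm is dominated by hundreds of co-travelling
# hitchhikers whose trajectories are not separately orderable; genotype
# reconstruction there uses one representative per distinct trajectory.

suppressPackageStartupMessages(library(evotraj))
dir.create("results", showWarnings = FALSE)

export_for <- function(freqs, sheet, gene_of, label) {
  sel <- select_muller_mutations(freqs, thr = 0.10)
  tree <- infer_genotype_nesting(sel, gene_of = gene_of, epsilon = 0.05)
  corr <- correct_genotype_frequencies(tree)
  tabs <- export_muller_tables(corr$tree, sheet)
  write.csv(tabs$edges, sprintf("results/muller_%s_edges.csv", label),
            row.names = FALSE, quote = FALSE)
  write.csv(tabs$population, sprintf("results/muller_%s_pops.csv", label),
            row.names = FALSE, quote = FALSE)
  cat(sprintf("[%s] %d genotypes, max frequency correction %.3f\n",
              label, nrow(tabs$edges), corr$report$max_adjustment))
}

fly <- read_variant_table("results/fly_filtered.tsv")
fly_sheet <- read_sample_sheet("results/data/fly_samples.tsv")
fly_freqs <- compute_frequencies(fly)
gene_of <- setNames(fly$gene, fly$mutation_id)
for (trt in unique(fly_sheet$treatment)) {
  cols <- fly_sheet$sample_id[fly_sheet$treatment == trt]
  export_for(fly_freqs[, cols, drop = FALSE], fly_sheet, gene_of, trt)
}

# mouse host: hypermutator hitchhikers travel at their lineage's frequency,
# so hundreds of trajectories are indistinguishable and cannot be ordered.
# Keep one representative per distinct trajectory (greedy dedup by total
# Manhattan distance, highest peaks first) before reconstructing genotypes.
mouse <- read_variant_table("results/mouse_filtered.tsv")
mouse_sheet <- read_sample_sheet("results/data/mouse_samples.tsv")
host_cols <- mouse_sheet$sample_id[mouse_sheet$treatment == "mouse_host"]
mf <- compute_frequencies(mouse)[, host_cols, drop = FALSE]
peak <- apply(mf, 1, max, na.rm = TRUE)
reps <- character(0)
for (id in rownames(mf)[order(-peak)]) {
  d <- vapply(reps, function(r) manhattan_distance(mf[id, ], mf[r, ]),
              numeric(1))
  if (!length(d) || min(d) >= 0.4) reps <- c(reps, id)
}
cat(sprintf("[mouse_host] %d distinct trajectories among %d mutations\n",
            length(reps), nrow(mf)))
mf_rep <- mf[reps, , drop = FALSE]
export_for(mf_rep, mouse_sheet,
           setNames(mouse$gene, mouse$mutation_id)[reps], "mouse_host")
cat(paste0("note: large corrections are expected in the hypermutator arm -\n",
           "within-lineage mutation waves share trajectories up to noise, so\n",
           "containment cannot order them; unorderable waves become root\n",
           "siblings and are rescaled rather than silently guessed.\n"))
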