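#!/usr/bin/env Rscript
# Generate the synthetic evolve-and-resequence experiments analysed by the
# rest of the workflow: a mouse-like run (two competing mutS hypermutator
# lineages plus a quiet diet arm) and a fly-like run (slow parallel
# accumulation in host and diet arms). Writes variant tables, sample sheets
# and ground truth under results/data/.

suppressPackageStartupMessages(library(evotraj))
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

mut_w <- c(0.9, 0.02, 0.02, 0.02, 0.02, 0.02)  # A:T>G:C-biased mutator spectrum
g <- mouse_host_generations()
sch <- mouse_host_fraction_schedule()

mouse_cfg <- sim_config(list(
  treatment_spec("mouse_host", g, lineages = list(
    lineage_spec("A41T", 0.5, sch[, "A41T"], marker = TRUE,
                 spectrum_weights = mut_w),
    lineage_spec("D1303", 0.2, sch[, "D1303"], marker = TRUE,
                 marker_class = "indel", spectrum_weights = mut_w),
    lineage_spec("ancestral", 0.005, 1 - rowSums(sch))),
    depth_mean = 150, n_false_positives = 30, fp_freq_mean = 0.04),
  treatment_spec("mouse_diet", rep(mouse_diet_generations(), each = 3),
                 sample_ids = paste0("diet_T", rep(c(2, 14), each = 3), "_",
                                     rep(c(1, 2, 4), 2)),
                 lineages = list(lineage_spec("diet", 0.0076, rep(1, 6))),
                 depth_mean = 150, n_false_positives = 30,
                 fp_freq_mean = 0.04)),
  seed = 20230101)

mouse <- simulate_experiment(mouse_cfg)
write_variant_table(mouse$variants, file.path(out, "mouse_variants.tsv"))
write_sample_sheet(mouse$samples, file.path(out, "mouse_samples.tsv"))
write_truth(mouse$truth, file.path(out, "mouse_truth"))
cat(sprintf("mouse run: %d candidate mutations over %d samples\n",
            nrow(mouse$variants), nrow(mouse$samples)))

# fly-like run: one slowly sweeping lineage per arm, C:G-biased spectrum
g_fly <- fly_generations()
fly_w <- c(0.05, 0.05, 0.05, 0.40, 0.40, 0.05)
fly_cfg <- sim_config(list(
  treatment_spec("fly_host", g_fly, lineages = list(
    lineage_spec("host_sweep", 0.00177, c(0.2, 0.6, 0.9, 1.0),
                 spectrum_weights = fly_w)),
    depth_mean = 150, n_false_positives = 20, fp_freq_mean = 0.04),
  treatment_spec("fly_diet", g_fly, lineages = list(
    lineage_spec("diet_sweep", 0.00150, c(0.3, 0.7, 0.95, 1.0),
                 spectrum_weights = fly_w)),
    depth_mean = 150, n_false_positives = 20, fp_freq_mean = 0.04)),
  seed = 20230102)

fly <- simulate_experiment(fly_cfg)
write_variant_table(fly$variants, file.path(out, "fly_variants.tsv"))
write_sample_sheet(fly$samples, file.path(out, "fly_samples.tsv"))
write_truth(fly$truth, file.path(out, "fly_truth"))
cat(sprintf("fly run: %d candidate mutations over %d samples\n",
            nrow(fly$variants), nrow(fly$samples)))
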