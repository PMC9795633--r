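# Builders shared across the suite. Everything is generated in code; no
# fixture files.

# variant table whose counts encode the given frequency matrix exactly
# (choose freqs representable at the given depth, e.g. hundredths at 100x)
counts_table <- function(freqs, depth = 100, genes = NULL, ref = "A", alt = "G",
                         class = "snv") {
  n <- nrow(freqs)
  ids <- rownames(freqs)
  if (is.null(ids)) ids <- sprintf("m%03d", seq_len(n))
  info <- data.frame(
    mutation_id = ids, contig = "contig_1", position = seq_len(n) * 10L,
    ref_allele = rep_len(ref, n), alt_allele = rep_len(alt, n),
    gene = if (is.null(genes)) sprintf("gene_%03d", seq_len(n)) else genes,
    mutation_class = rep_len(class, n), stringsAsFactors = FALSE)
  total <- matrix(as.integer(depth), n, ncol(freqs),
                  dimnames = list(NULL, colnames(freqs)))
  total[is.na(freqs)] <- 0L
  mutant <- total
  mutant[!is.na(freqs)] <- as.integer(round(freqs[!is.na(freqs)] * depth))
  variant_table(info, mutant, total)
}

simple_sheet <- function(sample_ids, generations, treatment = "trt",
                         f_A41T = NULL, f_D1303 = NULL) {
  sheet <- data.frame(sample_id = sample_ids, treatment = treatment,
                      replicate = "1", generations = generations,
                      stringsAsFactors = FALSE)
  if (!is.null(f_A41T)) sheet$f_A41T <- f_A41T
  if (!is.null(f_D1303)) sheet$f_D1303 <- f_D1303
  sheet
}

# study-like two-treatment configuration (hypermutator host + quiet diet)
mouse_like_config <- function(seed = 1, r_A41T = 0.5, r_D1303 = 0.2,
                              r_anc = 0.005, depth = 150,
                              n_false_positives = 30) {
  g <- mouse_host_generations()
  sch <- mouse_host_fraction_schedule()
  mut_w <- c(0.9, 0.02, 0.02, 0.02, 0.02, 0.02)
  sim_config(list(
    treatment_spec("mouse_host", g, lineages = list(
      lineage_spec("A41T", r_A41T, sch[, "A41T"], marker = TRUE,
                   spectrum_weights = mut_w),
      lineage_spec("D1303", r_D1303, sch[, "D1303"], marker = TRUE,
                   marker_class = "indel", spectrum_weights = mut_w),
      lineage_spec("ancestral", r_anc, 1 - sch[, "A41T"] - sch[, "D1303"])),
      depth_mean = depth, n_false_positives = n_false_positives,
      fp_freq_mean = 0.04),
    treatment_spec("mouse_diet", rep(mouse_diet_generations(), each = 3),
                   sample_ids = paste0("diet_s", 1:6),
                   lineages = list(lineage_spec("diet", 0.0076, rep(1, 6))),
                   depth_mean = depth,
                   n_false_positives = n_false_positives,
                   fp_freq_mean = 0.04)),
    seed = seed)
}

# nested genotype trajectories with known parent structure and comfortable
# frequency gaps (all values representable at depth 100)
nested_muller_freqs <- function() {
  f <- rbind(
    A = c(0.30, 0.80, 0.95, 0.95),
    B = c(0.10, 0.55, 0.75, 0.80),  # child of A
    C = c(0.00, 0.20, 0.40, 0.60),  # child of B
    D = c(0.50, 0.15, 0.05, 0.00))  # independent root, declining
  colnames(f) <- paste0("s", 1:4)
  f
}

nested_muller_parents <- c(A = "ancestor", B = "A", C = "B", D = "ancestor")
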