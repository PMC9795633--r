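#' Run the full trajectory-analysis pipeline on one experiment
#'
#' Drives simulate (optional) -> filter -> rates -> lineage assignment ->
#' spectra -> Muller export, writing every artifact under `out_dir`. All
#' outputs are functions of the inputs, the parameters and the seed; two runs
#' with identical arguments produce identical files.
#'
#' @param variants variant table, or a path to one; ignored when `config` is
#'   given.
#' @param samples sample sheet, or a path; ignored when `config` is given.
#' @param config optional [sim_config()]; when supplied the experiment is
#'   simulated first and the synthetic tables are written alongside the
#'   results.
#' @param out_dir output directory (created if needed).
#' @param fdr_q,ubiquity_thr,range_thr,peak_thr filtering thresholds (defaults
#'   are the study values 0.01, 0.05, 0.20, 0.10).
#' @param muller_thr Muller inclusion threshold (default 0.10).
#' @param lineage_cutoff Manhattan assignment cutoff (default 0.4).
#' @param exclusions mutation ids excluded from Muller reconstruction.
#' @param verbose print a line per stage.
#' @return invisibly, a list with the filtered table, filter report, per-
#'   treatment rate fits, lineage assignments, spectra and Muller tables.
#' @export
run_pipeline <- function(variants = NULL, samples = NULL, config = NULL,
                         out_dir = ".", fdr_q = 0.01, ubiquity_thr = 0.05,
                         range_thr = 0.20, peak_thr = 0.10, muller_thr = 0.10,
                         lineage_cutoff = 0.4, exclusions = character(),
                         verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config)) {
    say("simulate: seed %d, %d treatment(s)", config$seed, length(config$treatments))
    sim <- simulate_experiment(config)
    variants <- sim$variants
    samples <- sim$samples
    write_variant_table(variants, file.path(out_dir, "variants.tsv"))
    write_sample_sheet(samples, file.path(out_dir, "samples.tsv"))
    write_truth(sim$truth, file.path(out_dir, "truth"))
  } else {
    if (is.character(variants)) variants <- read_variant_table(variants)
    if (is.character(samples)) samples <- read_sample_sheet(samples)
    validate_variant_table(variants)
    samples <- validate_sample_sheet(samples)
  }

  say("filter: %d candidates, FDR %g", nrow(variants), fdr_q)
  flt <- filter_pipeline(variants, samples, fdr_q = fdr_q,
                         ubiquity_thr = ubiquity_thr, range_thr = range_thr,
                         peak_thr = peak_thr)
  write_variant_table(flt$filtered, file.path(out_dir, "filtered.tsv"))
  utils::write.table(flt$report$per_mutation,
                     file.path(out_dir, "filter_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  say("filter: %d mutations kept", nrow(flt$filtered))

  pts_all <- rate_points(flt$filtered, samples)
  fits <- list()
  for (trt in unique(samples$treatment)) {
    pts <- pts_all[pts_all$treatment == trt, , drop = FALSE]
    if (!nrow(pts) || all(pts$generations == 0)) next
    has_markers <- all(c("f_A41T", "f_D1303") %in% colnames(pts)) &&
      !anyNA(pts$f_A41T) && !anyNA(pts$f_D1303)
    fit <- if (has_markers) {
      fr <- as.matrix(pts[, c("f_anc", "f_A41T", "f_D1303")])
      colnames(fr) <- c("ancestral", "A41T", "D1303")
      ok <- tryCatch(fit_multirate(pts$generations, fr, pts$M),
                     error = function(e) NULL)
      if (is.null(ok)) fit_single_rate(pts$generations, pts$M) else ok
    } else {
      fit_single_rate(pts$generations, pts$M)
    }
    fits[[trt]] <- fit
    say("rates[%s]: %s", trt,
        paste(sprintf("%s=%.4g", names(fit$rates), fit$rates), collapse = ", "))
  }
  rate_tab <- do.call(rbind, lapply(names(fits), function(trt) {
    data.frame(treatment = trt, lineage = names(fits[[trt]]$rates),
               rate = unname(fits[[trt]]$rates), se = unname(fits[[trt]]$se),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(rate_tab)) {
    utils::write.table(rate_tab, file.path(out_dir, "rates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  freqs <- compute_frequencies(flt$filtered)
  assignments <- NULL
  spectra <- NULL
  markers <- sheet_markers(samples)
  if (length(markers) && nrow(freqs)) {
    # restrict to the samples where every marker trajectory is defined
    # (the hypermutator experiment's own samples)
    defined <- rowSums(is.na(as.matrix(samples[, markers, drop = FALSE]))) == 0
    cols <- intersect(samples$sample_id[defined], colnames(freqs))
    marker_trajs <- lapply(markers, function(col) {
      stats::setNames(samples[[col]], samples$sample_id)[cols]
    })
    names(marker_trajs) <- sub("^f_", "", markers)
    if (length(cols) >= 2) {
      assignments <- assign_lineages(freqs[, cols, drop = FALSE], marker_trajs,
                                     cutoff = lineage_cutoff)
      utils::write.table(assignments, file.path(out_dir, "assignments.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      spectra <- spectrum_counts(flt$filtered, assignments$label)
      say("lineages: %s", paste(sprintf("%s=%d", names(spectra$N), spectra$N),
                                collapse = ", "))
    }
  }
  if (is.null(spectra) && nrow(flt$filtered)) {
    trt_of <- samples$treatment[match(variant_samples(flt$filtered),
                                      samples$sample_id)]
    # group each mutation by the treatment where it peaks
    peak_trt <- apply(freqs, 1, function(x) {
      if (all(is.na(x)) || max(x, na.rm = TRUE) == 0) NA_character_
      else trt_of[which.max(x)]
    })
    spectra <- spectrum_counts(flt$filtered, peak_trt)
  }
  if (!is.null(spectra)) {
    spec_tab <- cbind(data.frame(group = rownames(spectra$counts),
                                 N = spectra$N), as.data.frame(spectra$counts))
    utils::write.table(spec_tab, file.path(out_dir, "spectra.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  muller <- list()
  for (trt in unique(samples$treatment)) {
    cols <- intersect(samples$sample_id[samples$treatment == trt], colnames(freqs))
    if (length(cols) < 2 || !nrow(freqs)) next
    sel <- select_muller_mutations(freqs[, cols, drop = FALSE], thr = muller_thr,
                                   exclusions = exclusions)
    gene_of <- stats::setNames(flt$filtered$gene, flt$filtered$mutation_id)
    tree <- infer_genotype_nesting(sel, gene_of = gene_of)
    corr <- correct_genotype_frequencies(tree)
    tabs <- export_muller_tables(corr$tree, samples)
    utils::write.csv(tabs$edges, file.path(out_dir, sprintf("muller_%s_edges.csv", trt)),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(tabs$population,
                     file.path(out_dir, sprintf("muller_%s_pops.csv", trt)),
                     row.names = FALSE, quote = FALSE)
    muller[[trt]] <- c(tabs, list(max_adjustment = corr$report$max_adjustment))
    say("muller[%s]: %d genotypes, max correction %.3g", trt,
        nrow(tabs$edges), corr$report$max_adjustment)
  }

  invisible(list(filtered = flt$filtered, report = flt$report, fits = fits,
                 assignments = assignments, spectra = spectra, muller = muller))
}
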