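#' Poisson likelihood-ratio test for a sample effect on mutant read counts
#'
#' Tests, for one candidate mutation, whether the per-sample rates of reads
#' supporting the mutant allele differ across samples, against the null of one
#' common rate with the total read counts as an offset. The null MLE is
#' lambda = sum(m) / sum(t); the alternative is the saturated per-sample model
#' (one rate per sample, i.e. sample as a fixed factor with one observation
#' per sample). The deviance is 2 * sum(m * log(m / (lambda * t))) with the
#' 0 * log 0 = 0 convention, referred to a chi-square with S_eff - 1 degrees
#' of freedom, where S_eff counts samples with nonzero total reads.
#'
#' @param mutant_counts,total_counts integer vectors of equal length;
#'   `0 <= m <= t`; samples with `t = 0` are excluded from the fit.
#' @return list with `statistic`, `df` and `p_value`. With fewer than two
#'   usable samples the test is degenerate: statistic 0, p = 1.
#' @export
poisson_lrt <- function(mutant_counts, total_counts) {
  m <- mutant_counts; t <- total_counts
  if (length(m) != length(t)) stop("count vectors differ in length")
  if (any(m < 0) || any(t < 0) || any(m > t)) {
    stop("counts must satisfy 0 <= mutant <= total")
  }
  use <- t > 0
  if (!any(use)) stop("all samples have zero total reads")
  m <- m[use]; t <- t[use]
  df <- length(m) - 1L
  if (df == 0L || sum(m) == 0) {
    return(list(statistic = 0, df = df, p_value = 1))
  }
  lambda <- sum(m) / sum(t)
  terms <- ifelse(m > 0, m * log(m / (lambda * t)), 0)
  stat <- max(0, 2 * sum(terms))
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  list(statistic = stat, df = df,
       p_value = max(p, .Machine$double.xmin))  # never report exactly 0
}

#' Poisson LRT applied to every row of a variant table
#'
#' @param table a variant table.
#' @return `data.frame` with `mutation_id`, `statistic`, `df`, `p_value`.
#' @export
poisson_lrt_table <- function(table) {
  samples <- variant_samples(table)
  mut <- as.matrix(table[, paste0(samples, ":mut"), drop = FALSE])
  tot <- as.matrix(table[, paste0(samples, ":tot"), drop = FALSE])
  res <- lapply(seq_len(nrow(table)), function(i) poisson_lrt(mut[i, ], tot[i, ]))
  data.frame(mutation_id = table$mutation_id,
             statistic = vapply(res, `[[`, numeric(1), "statistic"),
             df = vapply(res, `[[`, numeric(1), "df"),
             p_value = vapply(res, `[[`, numeric(1), "p_value"),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg significance at a target false-discovery rate
#'
#' Standard step-up rule over the pooled p-values; ties are kept together
#' (equal p-values share a decision).
#'
#' @param p_values vector of p-values in \[0, 1\].
#' @param fdr_q target FDR (default 0.01).
#' @return list with logical `significant` and numeric `adjusted` (BH-adjusted
#'   p-values).
#' @export
bh_adjust <- function(p_values, fdr_q = 0.01) {
  if (fdr_q <= 0 || fdr_q >= 1) stop("fdr_q must lie in (0, 1)")
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  adjusted <- stats::p.adjust(p_values, method = "BH")
  list(significant = adjusted <= fdr_q, adjusted = adjusted)
}

#' Ubiquity filter: remove candidates common across the whole run
#'
#' Removes candidate mutations whose frequency is at least `freq_thr` in at
#' least `sample_fraction` of all samples pooled over treatments — the
#' signature of systematic false-positive calls that persist everywhere at a
#' low, roughly constant frequency. Masked cells are not counted. The "at
#' least half" boundary with an even number of samples triggers removal at
#' exactly half.
#'
#' @param freqs frequency matrix (all treatments pooled).
#' @param freq_thr frequency threshold (default 0.05).
#' @param sample_fraction fraction of samples (default 0.5).
#' @return logical removal mask (TRUE = removed), named by mutation.
#' @export
ubiquity_filter <- function(freqs, freq_thr = 0.05, sample_fraction = 0.5) {
  if (ncol(freqs) == 0) stop("frequency matrix has no samples")
  n_hit <- rowSums(freqs >= freq_thr, na.rm = TRUE)
  stats::setNames(n_hit >= ceiling(sample_fraction * ncol(freqs)),
                  rownames(freqs))
}

#' Persistence filter: keep candidates with real trajectory signal
#'
#' Within one treatment, keeps a mutation iff its unmasked predicted
#' frequencies span a range greater than `range_thr`, or it both peaks above
#' `peak_thr` and appears (frequency above `presence_thr`) in at most
#' `sample_fraction` of the treatment's samples ("less than or equal to
#' half", i.e. `floor(sample_fraction * S)`).
#'
#' @param freqs frequency matrix restricted to one treatment's samples.
#' @param range_thr minimum exceeded frequency range (default 0.20).
#' @param peak_thr minimum exceeded peak frequency (default 0.10).
#' @param presence_thr a sample counts as an appearance when the frequency
#'   exceeds this value (default 0: any nonzero unmasked frequency).
#' @param sample_fraction appearance bound as a fraction of samples
#'   (default 0.5).
#' @return logical keep mask, named by mutation.
#' @export
persistence_filter <- function(freqs, range_thr = 0.20, peak_thr = 0.10,
                               presence_thr = 0, sample_fraction = 0.5) {
  if (ncol(freqs) == 0) stop("frequency matrix has no samples")
  fmax <- apply(freqs, 1, function(x) if (all(is.na(x))) 0 else max(x, na.rm = TRUE))
  fmin <- apply(freqs, 1, function(x) if (all(is.na(x))) 0 else min(x, na.rm = TRUE))
  n_present <- rowSums(freqs > presence_thr, na.rm = TRUE)
  keep <- (fmax - fmin > range_thr) |
    (fmax > peak_thr & n_present <= floor(sample_fraction * ncol(freqs)))
  stats::setNames(keep, rownames(freqs))
}

#' Candidate-mutation filtering cascade
#'
#' Applies, in order: (1) the Poisson likelihood-ratio test for a sample
#' effect with Benjamini-Hochberg control over the pooled candidate list;
#' (2) the ubiquity filter over all samples pooled across treatments; (3) the
#' persistence filter evaluated per treatment (a survivor must pass in at
#' least one treatment).
#'
#' @param table a variant table.
#' @param sheet the matching sample sheet.
#' @param fdr_q FDR for the BH step (default 0.01).
#' @param ubiquity_thr,ubiquity_fraction ubiquity-filter parameters.
#' @param range_thr,peak_thr,presence_thr,persistence_fraction
#'   persistence-filter parameters.
#' @param treatments treatments whose samples enter the persistence stage
#'   (default: all in the sheet).
#' @return list with `filtered` (surviving variant table) and `report`
#'   (per-mutation stage flags plus per-stage in/out counts that telescope).
#' @export
filter_pipeline <- function(table, sheet, fdr_q = 0.01,
                            ubiquity_thr = 0.05, ubiquity_fraction = 0.5,
                            range_thr = 0.20, peak_thr = 0.10,
                            presence_thr = 0, persistence_fraction = 0.5,
                            treatments = unique(sheet$treatment)) {
  sheet <- validate_sample_sheet(sheet)
  samples <- variant_samples(table)
  if (!all(samples %in% sheet$sample_id)) {
    stop("variant table samples missing from sample sheet: ",
         paste(setdiff(samples, sheet$sample_id), collapse = ", "))
  }
  n0 <- nrow(table)
  if (n0 == 0) {
    report <- list(per_mutation = data.frame(), stages = data.frame(
      stage = c("input", "lrt_bh", "ubiquity", "persistence"),
      n_in = 0L, n_out = 0L))
    return(list(filtered = table, report = report))
  }
  freqs <- compute_frequencies(table)

  lrt <- poisson_lrt_table(table)
  bh <- bh_adjust(lrt$p_value, fdr_q)
  bh_significant <- bh$significant

  ubiq_removed <- ubiquity_filter(freqs, ubiquity_thr, ubiquity_fraction)

  persist_kept <- rep(FALSE, n0)
  for (trt in treatments) {
    cols <- sheet$sample_id[sheet$treatment == trt]
    cols <- intersect(cols, colnames(freqs))
    if (!length(cols)) next
    persist_kept <- persist_kept |
      persistence_filter(freqs[, cols, drop = FALSE], range_thr, peak_thr,
                         presence_thr, persistence_fraction)
  }

  final <- bh_significant & !ubiq_removed & persist_kept
  per_mutation <- data.frame(
    mutation_id = table$mutation_id,
    p_value = lrt$p_value, p_adjusted = bh$adjusted,
    bh_significant = bh_significant,
    removed_by_ubiquity = unname(ubiq_removed),
    kept_by_persistence = unname(persist_kept),
    final_kept = unname(final), stringsAsFactors = FALSE)
  n1 <- sum(bh_significant)
  n2 <- sum(bh_significant & !ubiq_removed)
  n3 <- sum(final)
  stages <- data.frame(
    stage = c("input", "lrt_bh", "ubiquity", "persistence"),
    n_in = c(n0, n0, n1, n2), n_out = c(n0, n1, n2, n3))
  list(filtered = table[final, , drop = FALSE],
       report = list(per_mutation = per_mutation, stages = stages))
}
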