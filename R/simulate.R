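#' Lineage specification for the synthetic-experiment generator
#'
#' Describes one lineage of an evolving population: a constant per-generation
#' mutation accumulation rate and a fraction-of-population schedule across the
#' sequenced samples. Mutations arising inside a lineage hitchhike at the
#' lineage's fraction (neutral hitchhiking; no sub-lineage structure is
#' modelled).
#'
#' @param label lineage name (e.g. `"A41T"`, `"D1303"`, `"ancestral"`).
#' @param rate_per_generation nonnegative accumulation rate r_k (new mutations
#'   per generation carried by the whole lineage).
#' @param fraction_schedule per-sample lineage fraction f_k,s in \[0, 1\]; one
#'   entry per sample time.
#' @param marker if `TRUE`, the lineage's defining allele is emitted as an
#'   ordinary variant row whose true frequency equals the lineage fraction.
#' @param marker_class `"snv"` or `"indel"` for the marker row.
#' @param spectrum_weights 6 nonnegative weights (summing to 1) over the
#'   substitution classes of [substitution_classes()] used to draw this
#'   lineage's SNV alleles. Mismatch-repair-deficient lineages put most weight
#'   on the first class (A:T>G:C).
#' @return a `lineage_spec` list.
#' @export
lineage_spec <- function(label, rate_per_generation, fraction_schedule,
                         marker = FALSE, marker_class = "snv",
                         spectrum_weights = rep(1 / 6, 6)) {
  if (rate_per_generation < 0) stop("rate_per_generation must be >= 0")
  if (any(fraction_schedule < 0 | fraction_schedule > 1)) {
    stop("fraction_schedule entries must lie in [0, 1]")
  }
  if (length(spectrum_weights) != 6 || any(spectrum_weights < 0)) {
    stop("spectrum_weights must be 6 nonnegative values")
  }
  if (abs(sum(spectrum_weights) - 1) > 1e-8) {
    stop("spectrum_weights must sum to 1")
  }
  structure(list(label = label, rate_per_generation = rate_per_generation,
                 fraction_schedule = fraction_schedule, marker = marker,
                 marker_class = match.arg(marker_class, c("snv", "indel")),
                 spectrum_weights = spectrum_weights),
            class = "lineage_spec")
}

#' Treatment specification for the synthetic-experiment generator
#'
#' @param name treatment name (e.g. `"mouse_host"`).
#' @param sample_times strictly increasing elapsed generations at each
#'   sequenced sample.
#' @param lineages list of [lineage_spec()] objects; at every sample the
#'   lineage fractions must sum to at most 1 (the remainder is the nonmutator
#'   background).
#' @param depth_mean mean sequencing depth per site (reads; the study's mean
#'   coverage per population was 124-193).
#' @param depth_dispersion negative-binomial dispersion of per-cell depth
#'   (variance = mu + dispersion * mu^2); 0 gives constant depth.
#' @param seq_error_rate per-base sequencing error probability.
#' @param n_false_positives number of sequencing-noise false-positive sites,
#'   each with one latent frequency (roughly constant across samples).
#' @param fp_freq_mean mean latent frequency of false positives.
#' @param sample_ids optional sample ids (default `<name>_s<i>`).
#' @param replicate replicate label for the sample sheet.
#' @return a `treatment_spec` list.
#' @export
treatment_spec <- function(name, sample_times, lineages = list(),
                           depth_mean = 150, depth_dispersion = 0,
                           seq_error_rate = 0, n_false_positives = 0,
                           fp_freq_mean = 0.02, sample_ids = NULL,
                           replicate = "1") {
  if (any(diff(sample_times) < 0)) {
    stop("sample_times must be non-decreasing")
  }
  if (any(sample_times < 0)) stop("sample_times must be nonnegative")
  if (depth_mean <= 0) stop("depth_mean must be positive")
  if (depth_dispersion < 0) stop("depth_dispersion must be nonnegative")
  if (seq_error_rate < 0 || seq_error_rate > 1) {
    stop("seq_error_rate must lie in [0, 1]")
  }
  if (fp_freq_mean < 0 || fp_freq_mean > 1) stop("fp_freq_mean must lie in [0, 1]")
  for (lin in lineages) {
    if (!inherits(lin, "lineage_spec")) stop("lineages must be lineage_spec objects")
    if (length(lin$fraction_schedule) != length(sample_times)) {
      stop(sprintf("lineage '%s': fraction_schedule length differs from sample_times",
                   lin$label))
    }
  }
  if (length(lineages)) {
    tot <- Reduce(`+`, lapply(lineages, `[[`, "fraction_schedule"))
    if (any(tot > 1 + 1e-9)) {
      stop(sprintf("lineage fractions sum to %.3f > 1 at sample %d",
                   max(tot), which.max(tot)))
    }
  }
  if (is.null(sample_ids)) {
    sample_ids <- sprintf("%s_s%02d", name, seq_along(sample_times))
  }
  structure(list(name = name, sample_times = sample_times, lineages = lineages,
                 depth_mean = depth_mean, depth_dispersion = depth_dispersion,
                 seq_error_rate = seq_error_rate,
                 n_false_positives = n_false_positives,
                 fp_freq_mean = fp_freq_mean, sample_ids = sample_ids,
                 replicate = replicate),
            class = "treatment_spec")
}

#' Full configuration of a synthetic evolve-and-resequence experiment
#'
#' @param treatments list of [treatment_spec()] objects.
#' @param genome_length length of the single circular synthetic contig
#'   (sites are drawn uniformly without replacement).
#' @param seed integer RNG seed; identical configs produce identical output.
#' @return a `sim_config` list.
#' @export
sim_config <- function(treatments, genome_length = 3.3e6, seed = 1L) {
  if (inherits(treatments, "treatment_spec")) treatments <- list(treatments)
  for (tr in treatments) {
    if (!inherits(tr, "treatment_spec")) stop("treatments must be treatment_spec objects")
  }
  structure(list(treatments = treatments, genome_length = genome_length,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Binomial read sampling of an allele frequency
#'
#' Observation model for metagenomic allele frequencies: at a site of true
#' population frequency f sequenced to a given depth, the mutant read count is
#' Binomial(depth, f(1-e) + (1-f)e) where e is the per-base error rate.
#'
#' @param true_freq true allele frequency in \[0, 1\] (vectorised).
#' @param depth positive integer read depth (vectorised).
#' @param seq_error_rate per-base error probability.
#' @return list with integer vectors `mutant_reads` and `total_reads`.
#' @export
sample_read_counts <- function(true_freq, depth, seq_error_rate = 0) {
  if (any(depth <= 0)) stop("depth must be positive")
  if (any(true_freq < 0 | true_freq > 1)) stop("true_freq must lie in [0, 1]")
  p <- true_freq * (1 - seq_error_rate) + (1 - true_freq) * seq_error_rate
  n <- max(length(true_freq), length(depth))
  depth <- as.integer(rep_len(depth, n))
  m <- stats::rbinom(n, size = depth, prob = rep_len(p, n))
  list(mutant_reads = m, total_reads = depth)
}

#' Draw ordered base substitutions from six-class weights
#'
#' Draws a substitution class from the given weights and then one of the two
#' ordered (ref, alt) representations of that class with equal probability.
#'
#' @param weights 6 nonnegative class weights summing to 1 (order of
#'   [substitution_classes()]).
#' @param n number of draws.
#' @return a `data.frame` with columns `ref` and `alt` (`n` rows).
#' @export
draw_substitution <- function(weights, n = 1) {
  if (length(weights) != 6 || any(weights < 0)) {
    stop("weights must be 6 nonnegative values")
  }
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  cls <- sample.int(6, n, replace = TRUE, prob = weights)
  strand <- sample.int(2, n, replace = TRUE)
  ref <- character(n); alt <- character(n)
  for (i in seq_len(n)) {
    pair <- .class_pairs[[SUBSTITUTION_CLASSES[cls[i]]]][strand[i], ]
    ref[i] <- pair[1]; alt[i] <- pair[2]
  }
  data.frame(ref = ref, alt = alt, stringsAsFactors = FALSE)
}

# per-lineage true-frequency matrix of hitchhiking mutations.
# deterministic mode: mutation j carries within-lineage weight
# min(1, max(0, r*g_s - (j-1))), so the lineage's summed true frequency is
# exactly r * f_s * g_s; stochastic mode: Poisson arrivals between samples,
# whole hitchhikers thereafter.
.lineage_true_freqs <- function(lin, g, deterministic) {
  r <- lin$rate_per_generation
  f <- lin$fraction_schedule
  S <- length(g)
  if (r == 0) return(matrix(numeric(0), 0, S))
  if (deterministic) {
    n_mut <- ceiling(r * g[S])
    if (n_mut == 0) return(matrix(numeric(0), 0, S))
    w <- outer(seq_len(n_mut), r * g, function(j, mass) pmin(1, pmax(0, mass - (j - 1))))
  } else {
    arrivals <- stats::rpois(S, r * diff(c(0, g)))
    n_mut <- sum(arrivals)
    if (n_mut == 0) return(matrix(numeric(0), 0, S))
    arrival_sample <- rep(seq_len(S), arrivals)
    w <- outer(arrival_sample, seq_len(S), `<=`) * 1
  }
  sweep(w, 2, f, `*`)
}

#' Simulate a complete evolve-and-resequence experiment
#'
#' Generates a variant table, a sample sheet and a ground-truth record with
#' the statistical structure the downstream analysis assumes: per-lineage
#' mutation accumulation at constant per-generation rates, neutral hitchhiking
#' at the lineage fraction, marker alleles tracking lineage fractions,
#' constant-frequency sequencing-noise false positives, negative-binomial
#' depth and binomial read sampling.
#'
#' In `deterministic = TRUE` mode all random choices that affect frequencies
#' are replaced by their expectations: cumulative mutation mass r*g_s is
#' spread over ceiling(r*g_max) mutation rows via within-lineage weights so
#' that each lineage's summed true frequency equals r * f_s * g_s exactly,
#' depth is constant at `round(depth_mean)`, and read counts are rounded
#' expectations. Site coordinates and alleles are still drawn from the seeded
#' RNG.
#'
#' @param config a [sim_config()].
#' @param deterministic use deterministic (expectation-valued) counts.
#' @return list with `variants` (variant table over all treatments' samples),
#'   `samples` (sample sheet) and `truth` (list: `mutations` data.frame,
#'   `true_freq` matrix, `rates` data.frame).
#' @export
simulate_experiment <- function(config, deterministic = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)

  all_ids <- unlist(lapply(config$treatments, `[[`, "sample_ids"))
  if (anyDuplicated(all_ids)) stop("duplicate sample ids across treatments")

  info_rows <- list(); truth_rows <- list(); freq_blocks <- list()
  rate_rows <- list(); sheet_rows <- list()

  for (tr in config$treatments) {
    S <- length(tr$sample_times)
    lin_freqs <- list(); lin_meta <- list()
    for (lin in tr$lineages) {
      fr <- .lineage_true_freqs(lin, tr$sample_times, deterministic)
      if (nrow(fr)) {
        lin_freqs[[length(lin_freqs) + 1L]] <- fr
        lin_meta[[length(lin_meta) + 1L]] <-
          data.frame(lineage = lin$label, is_false_positive = FALSE,
                     is_marker = FALSE, n = nrow(fr), stringsAsFactors = FALSE)
      }
      if (isTRUE(lin$marker)) {
        lin_freqs[[length(lin_freqs) + 1L]] <- matrix(lin$fraction_schedule, 1, S)
        lin_meta[[length(lin_meta) + 1L]] <-
          data.frame(lineage = lin$label, is_false_positive = FALSE,
                     is_marker = TRUE, n = 1L, stringsAsFactors = FALSE)
      }
    }
    if (tr$n_false_positives > 0) {
      latent <- if (deterministic) {
        rep(tr$fp_freq_mean, tr$n_false_positives)
      } else if (tr$fp_freq_mean %in% c(0, 1)) {
        rep(tr$fp_freq_mean, tr$n_false_positives)
      } else {
        conc <- 200
        stats::rbeta(tr$n_false_positives, tr$fp_freq_mean * conc,
                     (1 - tr$fp_freq_mean) * conc)
      }
      lin_freqs[[length(lin_freqs) + 1L]] <- matrix(latent, ncol = S,
                                                    nrow = tr$n_false_positives)
      lin_meta[[length(lin_meta) + 1L]] <-
        data.frame(lineage = NA_character_, is_false_positive = TRUE,
                   is_marker = FALSE, n = tr$n_false_positives,
                   stringsAsFactors = FALSE)
    }
    n_rows <- sum(vapply(lin_meta, function(x) as.integer(x$n[1]), integer(1)))
    if (n_rows == 0) {
      sheet_rows[[length(sheet_rows) + 1L]] <- .treatment_sheet(tr)
      for (lin in tr$lineages) {
        rate_rows[[length(rate_rows) + 1L]] <-
          data.frame(treatment = tr$name, lineage = lin$label,
                     rate = lin$rate_per_generation, stringsAsFactors = FALSE)
      }
      next
    }
    freqs <- do.call(rbind, lin_freqs)
    meta <- do.call(rbind, lapply(lin_meta, function(x)
      x[rep(1L, x$n), c("lineage", "is_false_positive", "is_marker")]))

    # synthetic coordinates and alleles on one circular contig
    pos <- sort(sample.int(config$genome_length, n_rows))
    ord <- sample.int(n_rows)  # detach position order from lineage blocks
    meta <- meta[ord, , drop = FALSE]
    freqs <- freqs[ord, , drop = FALSE]
    cls_weights <- lapply(tr$lineages, `[[`, "spectrum_weights")
    names(cls_weights) <- vapply(tr$lineages, `[[`, character(1), "label")
    ref <- character(n_rows); alt <- character(n_rows)
    mclass <- rep("snv", n_rows)
    for (i in seq_len(n_rows)) {
      if (meta$is_marker[i]) {
        lin <- tr$lineages[[match(meta$lineage[i],
                                  vapply(tr$lineages, `[[`, character(1), "label"))]]
        if (lin$marker_class == "indel") {
          ref[i] <- "A"; alt[i] <- "del1"; mclass[i] <- "indel"
        } else {
          d <- draw_substitution(lin$spectrum_weights)
          ref[i] <- d$ref; alt[i] <- d$alt
        }
      } else {
        w <- if (!is.na(meta$lineage[i])) cls_weights[[meta$lineage[i]]] else rep(1 / 6, 6)
        d <- draw_substitution(w)
        ref[i] <- d$ref; alt[i] <- d$alt
      }
    }
    id <- ifelse(meta$is_marker,
                 sprintf("%s_marker_%s", tr$name, meta$lineage),
                 sprintf("%s_m%04d", tr$name, seq_len(n_rows)))
    info_rows[[length(info_rows) + 1L]] <- data.frame(
      mutation_id = id, contig = "contig_1", position = pos,
      ref_allele = ref, alt_allele = alt,
      gene = sprintf("gene_%04d", pos %% 997L + 1L),
      mutation_class = mclass, stringsAsFactors = FALSE)
    rownames(freqs) <- id
    colnames(freqs) <- tr$sample_ids
    freq_blocks[[length(freq_blocks) + 1L]] <- freqs
    truth_rows[[length(truth_rows) + 1L]] <- data.frame(
      mutation_id = id, treatment = tr$name, lineage = meta$lineage,
      is_false_positive = meta$is_false_positive, is_marker = meta$is_marker,
      stringsAsFactors = FALSE)
    sheet_rows[[length(sheet_rows) + 1L]] <- .treatment_sheet(tr)
    for (lin in tr$lineages) {
      rate_rows[[length(rate_rows) + 1L]] <-
        data.frame(treatment = tr$name, lineage = lin$label,
                   rate = lin$rate_per_generation, stringsAsFactors = FALSE)
    }
  }

  sheet <- do.call(rbind, sheet_rows)
  rownames(sheet) <- NULL
  if (!length(info_rows)) {
    empty_info <- data.frame(mutation_id = character(0), contig = character(0),
                             position = integer(0), ref_allele = character(0),
                             alt_allele = character(0), gene = character(0),
                             mutation_class = character(0), stringsAsFactors = FALSE)
    mk <- matrix(integer(0), 0, length(all_ids), dimnames = list(NULL, all_ids))
    variants <- variant_table(empty_info, mk, mk)
    truth <- list(mutations = data.frame(), true_freq = mk,
                  rates = if (length(rate_rows)) do.call(rbind, rate_rows) else data.frame())
    return(list(variants = variants, samples = sheet, truth = truth))
  }

  info <- do.call(rbind, info_rows)
  # expand each treatment block to the full sample set (true freq 0 elsewhere)
  true_freq <- matrix(0, nrow(info), length(all_ids),
                      dimnames = list(info$mutation_id, all_ids))
  for (blk in freq_blocks) true_freq[rownames(blk), colnames(blk)] <- blk

  mutant <- matrix(0L, nrow(info), length(all_ids),
                   dimnames = list(info$mutation_id, all_ids))
  total <- mutant
  for (tr in config$treatments) {
    n_cells <- nrow(info) * length(tr$sample_ids)
    depth <- if (deterministic || tr$depth_dispersion == 0) {
      rep(as.integer(round(tr$depth_mean)), n_cells)
    } else {
      pmax(1L, stats::rnbinom(n_cells, mu = tr$depth_mean,
                              size = 1 / tr$depth_dispersion))
    }
    f <- as.vector(true_freq[, tr$sample_ids, drop = FALSE])
    if (deterministic) {
      e <- tr$seq_error_rate
      m <- as.integer(round((f * (1 - e) + (1 - f) * e) * depth))
    } else {
      m <- sample_read_counts(f, depth, tr$seq_error_rate)$mutant_reads
    }
    mutant[, tr$sample_ids] <- m
    total[, tr$sample_ids] <- depth
  }

  variants <- variant_table(info, mutant, total)
  truth <- list(mutations = do.call(rbind, truth_rows),
                true_freq = true_freq,
                rates = do.call(rbind, rate_rows))
  rownames(truth$mutations) <- NULL
  list(variants = variants, samples = sheet, truth = truth)
}

.treatment_sheet <- function(tr) {
  sheet <- data.frame(sample_id = tr$sample_ids, treatment = tr$name,
                      replicate = tr$replicate, generations = tr$sample_times,
                      f_A41T = NA_real_, f_D1303 = NA_real_,
                      stringsAsFactors = FALSE)
  for (lin in tr$lineages) {
    if (!isTRUE(lin$marker)) next
    col <- if (grepl("A41T", lin$label)) "f_A41T"
           else if (grepl("D1303", lin$label)) "f_D1303"
           else next
    sheet[[col]] <- lin$fraction_schedule
  }
  sheet
}

#' Write simulation ground truth as TSV files
#'
#' @param truth the `truth` component of [simulate_experiment()] output.
#' @param prefix path prefix; writes `<prefix>_mutations.tsv` (per-mutation
#'   lineage labels and true per-sample frequencies) and `<prefix>_rates.tsv`
#'   (true per-lineage rates).
#' @return the two paths, invisibly.
#' @export
write_truth <- function(truth, prefix) {
  mut_path <- paste0(prefix, "_mutations.tsv")
  rate_path <- paste0(prefix, "_rates.tsv")
  mut <- truth$mutations
  if (nrow(mut)) {
    tf <- as.data.frame(truth$true_freq[mut$mutation_id, , drop = FALSE])
    colnames(tf) <- paste0("freq:", colnames(tf))
    mut <- cbind(mut, tf)
  }
  utils::write.table(mut, mut_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(truth$rates, rate_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(mut_path, rate_path))
}
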