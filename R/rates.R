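#' Normalize mutS lineage fractions against the nonmutator background
#'
#' Marker-allele frequency estimates occasionally sum to slightly more than 1
#' because each is estimated independently from sequencing reads; in that case
#' both are rescaled proportionally to sum to 1 (ancestral fraction 0).
#' Otherwise the ancestral nonmutator fraction is the remainder.
#'
#' @param f_A41T,f_D1303 marker-allele frequencies in \[0, 1\] (vectorised).
#' @return `data.frame` with columns `f_A41T`, `f_D1303`, `f_anc` summing to 1
#'   per row.
#' @export
normalize_lineage_fractions <- function(f_A41T, f_D1303) {
  if (any(f_A41T < 0 | f_D1303 < 0)) stop("lineage fractions must be nonnegative")
  if (any(f_A41T > 1 | f_D1303 > 1)) stop("lineage fractions must be <= 1")
  tot <- f_A41T + f_D1303
  over <- tot > 1
  fa <- ifelse(over, f_A41T / tot, f_A41T)
  fd <- ifelse(over, f_D1303 / tot, f_D1303)
  data.frame(f_A41T = fa, f_D1303 = fd, f_anc = pmax(0, 1 - fa - fd))
}

.new_rate_fit <- function(rates, se, fitted, residuals, rss, n, p, cov) {
  structure(list(rates = rates, se = se, fitted = fitted,
                 residuals = residuals, rss = rss, n = n, p = p,
                 cov = cov),
            class = "rate_fit")
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf("Zero-intercept mutation-accumulation fit (%d points, %d rate%s)\n",
              x$n, x$p, if (x$p > 1) "s" else ""))
  se <- if (all(is.na(x$se))) rep(NA_real_, x$p) else x$se
  for (k in seq_len(x$p)) {
    cat(sprintf("  %-10s %.6g per generation (SE %.3g)\n",
                names(x$rates)[k], x$rates[k], se[k]))
  }
  cat(sprintf("  RSS %.4g\n", x$rss))
  invisible(x)
}

#' Through-origin fit of one mutation-accumulation rate
#'
#' Least squares for M_s = r * g_s with no intercept (no initial mutations):
#' r = sum(M g) / sum(g^2), SE = sqrt((RSS / (n - 1)) / sum(g^2)). Noise-free
#' consistent data is recovered exactly (RSS 0).
#'
#' @param g elapsed generations per sample (at least one positive).
#' @param M summed mutation frequencies per sample.
#' @return a `rate_fit` object; `se` is `NA` when n = 1.
#' @export
fit_single_rate <- function(g, M) {
  stopifnot(length(g) == length(M))
  if (all(g == 0)) stop("all samples have zero elapsed generations")
  if (any(g < 0) || any(M < 0)) stop("g and M must be nonnegative")
  r <- sum(M * g) / sum(g^2)
  fitted <- r * g
  resid <- M - fitted
  rss <- sum(resid^2)
  n <- length(g)
  se <- if (n > 1) sqrt(rss / (n - 1) / sum(g^2)) else NA_real_
  .new_rate_fit(rates = c(rate = r), se = c(rate = se), fitted = fitted,
                residuals = resid, rss = rss, n = n, p = 1L,
                cov = matrix(if (n > 1) rss / (n - 1) / sum(g^2) else NA_real_,
                             1, 1, dimnames = list("rate", "rate")))
}

#' Multi-lineage zero-intercept mutation-accumulation fit
#'
#' Models the summed mutation frequency of a sample as the sum over lineages
#' of rate_k * fraction_k,s * generations_s, i.e. least squares with no
#' intercept over design columns X_{s,k} = f_k,s * g_s. With one lineage at
#' fraction 1 everywhere this reduces exactly to [fit_single_rate()].
#'
#' @param g elapsed generations per sample.
#' @param fractions samples x lineages matrix of population fractions (named
#'   columns).
#' @param M summed mutation frequencies per sample.
#' @return a `rate_fit` with one rate per lineage; covariance
#'   (RSS / (n - p)) * (X'X)^-1.
#' @export
fit_multirate <- function(g, fractions, M) {
  fractions <- as.matrix(fractions)
  stopifnot(nrow(fractions) == length(g), length(M) == length(g))
  if (is.null(colnames(fractions))) {
    colnames(fractions) <- paste0("lineage", seq_len(ncol(fractions)))
  }
  X <- fractions * g
  p <- ncol(X); n <- nrow(X)
  if (n < p) stop("need at least as many samples as lineages")
  qrX <- qr(X)
  if (qrX$rank < p) {
    absent <- colnames(X)[colSums(abs(X)) == 0]
    if (length(absent)) {
      stop("lineage never observed (all-zero design column): ",
           paste(absent, collapse = ", "))
    }
    dropped <- colnames(X)[-qrX$pivot[seq_len(qrX$rank)]]
    stop("rank-deficient design; collinear lineage column(s): ",
         paste(dropped, collapse = ", "))
  }
  xtx <- crossprod(X)
  beta <- drop(solve(xtx, crossprod(X, M)))
  fitted <- drop(X %*% beta)
  resid <- M - fitted
  rss <- sum(resid^2)
  cov <- if (n > p) rss / (n - p) * solve(xtx) else matrix(NA_real_, p, p)
  dimnames(cov) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(cov))
  .new_rate_fit(rates = stats::setNames(beta, colnames(X)),
                se = stats::setNames(se, colnames(X)),
                fitted = fitted, residuals = resid, rss = rss,
                n = n, p = p, cov = cov)
}

#' Model-implied summed mutation frequency
#'
#' Convenience for constructing noise-free data under the accumulation model:
#' M_s = sum_k r_k * f_k,s * g_s.
#'
#' @param g elapsed generations per sample.
#' @param fractions samples x lineages fraction matrix.
#' @param rates per-lineage rates (recycled against the columns).
#' @return numeric vector of M_s.
#' @export
model_summed_frequency <- function(g, fractions, rates) {
  fractions <- as.matrix(fractions)
  drop((fractions * g) %*% rates)
}

#' F-test for equality of two lineage rates
#'
#' Compares the full multi-lineage fit with a constrained fit in which the two
#' named lineages share one rate (their design columns summed):
#' F = ((RSS0 - RSS1) / (p1 - p0)) / (RSS1 / (n - p1)).
#'
#' @inheritParams fit_multirate
#' @param lineages character vector of the two lineage (column) names
#'   constrained to be equal.
#' @return list with `F`, `df1`, `df2`, `p_value`, `constraint`, and the two
#'   fits. A saturated full fit (RSS1 = 0) yields infinite F with a clamped
#'   p-value and a warning.
#' @export
compare_rates_ftest <- function(g, fractions, M, lineages) {
  fractions <- as.matrix(fractions)
  if (ncol(fractions) < 2) stop("need at least two lineages to compare")
  if (length(lineages) != 2 || !all(lineages %in% colnames(fractions))) {
    stop("lineages must name two columns of the fraction matrix")
  }
  full <- fit_multirate(g, fractions, M)
  merged <- fractions[, lineages[1]] + fractions[, lineages[2]]
  keep <- setdiff(colnames(fractions), lineages)
  constrained_fr <- cbind(fractions[, keep, drop = FALSE], merged = merged)
  reduced <- fit_multirate(g, constrained_fr, M)
  df1 <- full$p - reduced$p
  df2 <- full$n - full$p
  if (df2 < 1) stop("no residual degrees of freedom in the full model")
  if (full$rss <= 1e-12 * max(1, sum(M^2))) {  # numerically saturated fit
    warning("degenerate fit: full model has zero residual sum of squares")
    return(list(F = Inf, df1 = df1, df2 = df2,
                p_value = .Machine$double.xmin,
                constraint = sprintf("equal(%s, %s)", lineages[1], lineages[2]),
                full = full, reduced = reduced))
  }
  Fstat <- ((reduced$rss - full$rss) / df1) / (full$rss / df2)
  list(F = Fstat, df1 = df1, df2 = df2,
       p_value = stats::pf(Fstat, df1, df2, lower.tail = FALSE),
       constraint = sprintf("equal(%s, %s)", lineages[1], lineages[2]),
       full = full, reduced = reduced)
}

#' Fold change between two rates
#'
#' @param r_num,r_den numerator and (positive) denominator rates.
#' @param round_to_integer round the ratio to the nearest integer for
#'   reporting.
#' @return the ratio.
#' @export
fold_change <- function(r_num, r_den, round_to_integer = FALSE) {
  if (any(r_den <= 0)) stop("denominator rate must be positive")
  ratio <- r_num / r_den
  if (round_to_integer) round(ratio) else ratio
}

#' Doubling (generation) time from two population sizes
#'
#' gt = log10(2) * (t2 - t1) / (log10(X2) - log10(X1)): the time per doubling
#' of a population growing exponentially from X1 at t1 to X2 at t2.
#'
#' @param t1,t2 times (t2 > t1), any unit.
#' @param X1,X2 positive population sizes (e.g. CFU/mL) at t1 and t2.
#' @return generation time in the units of t; negative (with a warning) for a
#'   declining population.
#' @export
generation_time <- function(t1, t2, X1, X2) {
  if (t2 <= t1) stop("t2 must exceed t1")
  if (X1 <= 0 || X2 <= 0) stop("population sizes must be positive")
  if (X2 == X1) stop("zero growth: X2 equals X1")
  gt <- log10(2) * (t2 - t1) / (log10(X2) - log10(X1))
  if (X2 < X1) warning("population declined; returning negative generation time")
  gt
}

#' Assemble per-sample rate points from filtered variants and a sample sheet
#'
#' Computes the summed mutation frequency of each sample and, when marker
#' columns are present, the normalized three-way lineage fractions. By default
#' the marker rows themselves are part of the sum (all observed mutations are
#' summed); set `include_markers = FALSE` to drop rows whose mutation_id
#' matches `marker_pattern`.
#'
#' @param table filtered variant table.
#' @param sheet sample sheet.
#' @param include_markers include marker alleles in the summed frequency.
#' @param marker_pattern regular expression identifying marker rows.
#' @return `data.frame` with `sample_id`, `treatment`, `generations`, `M` and,
#'   when markers are present, `f_A41T`, `f_D1303`, `f_anc`.
#' @export
rate_points <- function(table, sheet, include_markers = TRUE,
                        marker_pattern = "marker") {
  sheet <- validate_sample_sheet(sheet)
  freqs <- compute_frequencies(table)
  if (!include_markers && nrow(freqs)) {
    freqs <- freqs[!grepl(marker_pattern, rownames(freqs)), , drop = FALSE]
  }
  samples <- intersect(sheet$sample_id, colnames(freqs))
  pts <- sheet[match(samples, sheet$sample_id),
               c("sample_id", "treatment", "generations")]
  pts$M <- unname(summed_frequency(freqs, samples))
  markers <- sheet_markers(sheet)
  if (all(c("f_A41T", "f_D1303") %in% markers)) {
    idx <- match(samples, sheet$sample_id)
    fa <- sheet$f_A41T[idx]; fd <- sheet$f_D1303[idx]
    ok <- !is.na(fa) & !is.na(fd)
    norm <- data.frame(f_A41T = NA_real_, f_D1303 = NA_real_, f_anc = NA_real_)
    norm <- norm[rep(1, length(samples)), ]
    if (any(ok)) norm[ok, ] <- normalize_lineage_fractions(fa[ok], fd[ok])
    pts <- cbind(pts, norm)
  }
  rownames(pts) <- NULL
  pts
}
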