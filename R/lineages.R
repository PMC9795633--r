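# Six strand-symmetric base-substitution classes; the first is the
# mismatch-repair-deficiency signature (A:T -> G:C transitions).
SUBSTITUTION_CLASSES <- c("A:T>G:C", "A:T>C:G", "A:T>T:A",
                          "C:G>T:A", "C:G>A:T", "C:G>G:C")

# ordered (ref, alt) pairs belonging to each class; two per class
.class_pairs <- list(
  "A:T>G:C" = rbind(c("A", "G"), c("T", "C")),
  "A:T>C:G" = rbind(c("A", "C"), c("T", "G")),
  "A:T>T:A" = rbind(c("A", "T"), c("T", "A")),
  "C:G>T:A" = rbind(c("C", "T"), c("G", "A")),
  "C:G>A:T" = rbind(c("C", "A"), c("G", "T")),
  "C:G>G:C" = rbind(c("C", "G"), c("G", "C")))

#' Six-class label of a base substitution
#'
#' Folds an ordered single-base substitution into one of the six
#' strand-symmetric classes (e.g. both A>G and T>C are `"A:T>G:C"`).
#'
#' @param ref,alt reference and alternate bases (character vectors over
#'   A, C, G, T; `ref != alt` elementwise).
#' @return character vector of class labels (levels in
#'   [substitution_classes()]).
#' @export
substitution_class <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  bases <- c("A", "C", "G", "T")
  if (any(!ref %in% bases) || any(!alt %in% bases)) {
    stop("ref and alt must be single bases (A/C/G/T)")
  }
  if (any(ref == alt)) stop("ref and alt must differ")
  key <- paste0(ref, alt)
  lut <- character(0)
  for (cls in names(.class_pairs)) {
    p <- .class_pairs[[cls]]
    lut[paste0(p[, 1], p[, 2])] <- cls
  }
  unname(lut[key])
}

#' @rdname substitution_class
#' @export
substitution_classes <- function() SUBSTITUTION_CLASSES

#' Manhattan distance between two frequency trajectories
#'
#' Total Manhattan distance `sum |a_s - b_s|` over the samples where both
#' trajectories are unmasked (masked samples are dropped pairwise, not
#' imputed).
#'
#' @param a,b numeric trajectories of equal length; `NA` marks masked samples.
#' @return nonnegative scalar distance.
#' @export
manhattan_distance <- function(a, b) {
  if (length(a) != length(b)) stop("trajectories differ in length")
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) stop("no common unmasked samples between trajectories")
  sum(abs(a[ok] - b[ok]))
}

#' Assign a mutation to a hypermutator lineage by trajectory distance
#'
#' Computes the Manhattan distance from the mutation's frequency trajectory to
#' each marker-allele trajectory and assigns the mutation to the nearest
#' lineage provided that distance is below `cutoff`; otherwise (or on an exact
#' tie below the cutoff) the mutation is left unassigned.
#'
#' @param traj mutation frequency trajectory.
#' @param marker_trajs named list (or matrix with named columns) of marker
#'   trajectories, one per lineage.
#' @param cutoff assignment cutoff on the total Manhattan distance
#'   (default 0.4).
#' @return list with `distances` (named), `label` (lineage name or
#'   `"unassigned"`), `tie` flag and the `cutoff` used.
#' @export
assign_lineage <- function(traj, marker_trajs, cutoff = 0.4) {
  if (is.matrix(marker_trajs)) {
    marker_trajs <- stats::setNames(
      lapply(seq_len(ncol(marker_trajs)), function(j) marker_trajs[, j]),
      colnames(marker_trajs))
  }
  if (!length(marker_trajs)) stop("at least one marker trajectory is required")
  d <- vapply(marker_trajs, manhattan_distance, numeric(1), a = traj)
  best <- which(d - min(d) < 1e-12)  # numerically equal distances tie
  tie <- length(best) > 1 && min(d) < cutoff
  label <- if (min(d) < cutoff && !tie) names(d)[best[1]] else "unassigned"
  list(distances = d, label = label, tie = tie, cutoff = cutoff)
}

#' Lineage assignment for every mutation of a frequency matrix
#'
#' @param freqs frequency matrix (mutations x samples).
#' @param marker_trajs as in [assign_lineage()]; trajectories over the same
#'   samples (columns) as `freqs`.
#' @inheritParams assign_lineage
#' @return `data.frame` with one row per mutation: distances `D_<lineage>`,
#'   `label`, `tie`.
#' @export
assign_lineages <- function(freqs, marker_trajs, cutoff = 0.4) {
  rows <- lapply(rownames(freqs), function(id) {
    a <- assign_lineage(freqs[id, ], marker_trajs, cutoff)
    out <- data.frame(mutation_id = id, label = a$label, tie = a$tie,
                      stringsAsFactors = FALSE)
    for (k in names(a$distances)) out[[paste0("D_", k)]] <- a$distances[[k]]
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Base-substitution spectrum counts per group
#'
#' Counts SNV rows of a variant table in the six strand-symmetric substitution
#' classes, per group (e.g. treatment or assigned lineage). Non-SNV rows are
#' excluded and their number reported.
#'
#' @param table a variant table.
#' @param group factor/character vector of length `nrow(table)` assigning each
#'   mutation to a group; `NA` rows are dropped.
#' @return list with `counts` (groups x 6 matrix), `proportions` (same shape;
#'   `NA` rows for empty groups), `N` (per group), and `n_excluded` (non-SNV
#'   rows).
#' @export
spectrum_counts <- function(table, group) {
  stopifnot(length(group) == nrow(table))
  is_snv <- table$mutation_class == "snv"
  n_excluded <- sum(!is_snv)
  keep <- is_snv & !is.na(group)
  cls <- factor(substitution_class(table$ref_allele[keep], table$alt_allele[keep]),
                levels = SUBSTITUTION_CLASSES)
  grp <- factor(as.character(group[keep]),
                levels = unique(stats::na.omit(as.character(group))))
  counts <- table(grp, cls)
  counts <- matrix(counts, nrow = nlevels(grp), ncol = 6,
                   dimnames = list(levels(grp), SUBSTITUTION_CLASSES))
  N <- rowSums(counts)
  props <- counts / ifelse(N > 0, N, NA_real_)
  list(counts = counts, proportions = props, N = N, n_excluded = n_excluded)
}
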