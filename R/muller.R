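#' Select mutations for Muller-plot reconstruction
#'
#' Keeps mutations whose maximum unmasked frequency reaches at least `thr`
#' (boundary inclusive), minus an explicit exclusion list (e.g. calls known to
#' stem from unresolved structural variants).
#'
#' @param freqs frequency matrix.
#' @param thr inclusion threshold on the peak frequency (default 0.10).
#' @param exclusions mutation ids to drop regardless of frequency.
#' @return the row-subset frequency matrix.
#' @export
select_muller_mutations <- function(freqs, thr = 0.10, exclusions = character()) {
  if (nrow(freqs) == 0) return(freqs)
  peak <- apply(freqs, 1, function(x) if (all(is.na(x))) 0 else max(x, na.rm = TRUE))
  keep <- peak >= thr & !(rownames(freqs) %in% exclusions)
  freqs[keep, , drop = FALSE]
}

#' Infer genotype nesting from frequency trajectories
#'
#' Greedy containment reconstruction of genotype structure under purely
#' asexual reproduction: each selected mutation defines a genotype; mutations
#' are taken in order of descending peak frequency (ties: earlier first
#' appearance, then mutation id) and each is nested under the deepest existing
#' genotype whose corrected-for-tolerance frequency dominates it at every
#' sample (`freq_child <= freq_parent + epsilon`), provided no mutation along
#' that genotype's path hits the same gene (one mutation per gene in a
#' lineage). A mutation with no admissible parent starts a new root-level
#' genotype. Masked frequencies are treated as 0.
#'
#' @param freqs frequency matrix (typically [select_muller_mutations()]
#'   output).
#' @param gene_of named character vector mapping mutation_id to gene (empty
#'   string = unknown, never conflicts).
#' @param epsilon containment tolerance (default 0.02).
#' @param lineage_of optional named vector of lineage labels; when supplied,
#'   nesting is only attempted within the same lineage label.
#' @return a `genotype_tree`: list with `nodes` (`data.frame`: `genotype`,
#'   `parent` (`"ancestor"` for roots), `mutation_id`, `gene`, `depth`) and
#'   `raw` (genotype x sample frequency matrix); `corrected` is `NULL` until
#'   [correct_genotype_frequencies()].
#' @export
infer_genotype_nesting <- function(freqs, gene_of = NULL, epsilon = 0.02,
                                   lineage_of = NULL) {
  if (nrow(freqs) == 0) {
    nodes <- data.frame(genotype = character(0), parent = character(0),
                        mutation_id = character(0), gene = character(0),
                        depth = integer(0), stringsAsFactors = FALSE)
    return(structure(list(nodes = nodes,
                          raw = freqs, corrected = NULL),
                     class = "genotype_tree"))
  }
  f <- freqs
  f[is.na(f)] <- 0
  ids <- rownames(f)
  peak <- apply(f, 1, max)
  first_seen <- apply(f, 1, function(x) {
    w <- which(x > 0)
    if (length(w)) w[1] else ncol(f) + 1L
  })
  ord <- order(-peak, first_seen, ids)
  gene <- if (is.null(gene_of)) stats::setNames(rep("", length(ids)), ids) else gene_of
  lin <- if (is.null(lineage_of)) NULL else lineage_of

  nodes <- data.frame(genotype = character(0), parent = character(0),
                      mutation_id = character(0), gene = character(0),
                      depth = integer(0), stringsAsFactors = FALSE)
  path_genes <- list()   # genotype -> genes along its path (incl. own)
  path_lineage <- list()

  for (i in ord) {
    id <- ids[i]
    traj <- f[i, ]
    best <- NA_character_; best_depth <- -1L
    for (j in seq_len(nrow(nodes))) {
      gt <- nodes$genotype[j]
      if (!is.null(lin) && !identical(lin[[id]], path_lineage[[gt]])) next
      if (nzchar(gene[[id]]) && gene[[id]] %in% path_genes[[gt]]) next
      if (all(traj <= f[nodes$mutation_id[j], ] + epsilon) &&
          nodes$depth[j] > best_depth) {
        best <- gt; best_depth <- nodes$depth[j]
      }
    }
    parent <- if (is.na(best)) "ancestor" else best
    depth <- if (is.na(best)) 1L else best_depth + 1L
    nodes <- rbind(nodes, data.frame(
      genotype = id, parent = parent, mutation_id = id,
      gene = gene[[id]], depth = depth, stringsAsFactors = FALSE))
    own_gene <- if (nzchar(gene[[id]])) gene[[id]] else character(0)
    path_genes[[id]] <- if (is.na(best)) own_gene else c(path_genes[[best]], own_gene)
    path_lineage[[id]] <- if (!is.null(lin)) lin[[id]] else NULL
  }
  rownames(nodes) <- NULL
  raw <- f[nodes$genotype, , drop = FALSE]
  structure(list(nodes = nodes, raw = raw, corrected = NULL),
            class = "genotype_tree")
}

#' @export
print.genotype_tree <- function(x, ...) {
  cat(sprintf("genotype_tree: %d genotypes over %d samples%s\n",
              nrow(x$nodes), ncol(x$raw),
              if (is.null(x$corrected)) " (uncorrected)" else " (corrected)"))
  invisible(x)
}

#' Correct inferred genotype frequencies for read-estimation errors
#'
#' Because each mutation's frequency is estimated independently from the reads
#' covering its own site, raw genotype frequencies can be mutually
#' inconsistent. Two corrections are applied top-down by depth: (1) a
#' genotype's frequency is capped at its (already corrected) parent's
#' frequency; (2) if sibling genotypes jointly exceed their parent's frequency
#' (root-level siblings: exceed 1) at a sample, they are rescaled
#' proportionally. A warning is raised when any single adjustment reaches
#' 0.10, since corrections of that size suggest the nesting is wrong.
#'
#' @param tree a `genotype_tree` with raw frequencies.
#' @return list with `tree` (corrected frequencies attached) and `report`
#'   (`data.frame` of every nonzero adjustment plus `max_adjustment`).
#' @export
correct_genotype_frequencies <- function(tree) {
  stopifnot(inherits(tree, "genotype_tree"))
  f <- tree$raw
  adj <- list()
  if (nrow(f)) {
    nodes <- tree$nodes
    for (d in sort(unique(nodes$depth))) {
      at_level <- nodes[nodes$depth == d, , drop = FALSE]
      # pass 1: cap at the corrected parent frequency
      for (j in seq_len(nrow(at_level))) {
        g <- at_level$genotype[j]; par <- at_level$parent[j]
        cap <- if (par == "ancestor") rep(1, ncol(f)) else f[par, ]
        over <- f[g, ] > cap
        if (any(over)) {
          adj[[length(adj) + 1L]] <- data.frame(
            genotype = g, sample = colnames(f)[over], type = "cap",
            raw = f[g, over], corrected = cap[over], stringsAsFactors = FALSE)
          f[g, over] <- cap[over]
        }
      }
      # pass 2: proportional normalization of sibling totals
      for (par in unique(at_level$parent)) {
        sibs <- at_level$genotype[at_level$parent == par]
        cap <- if (par == "ancestor") rep(1, ncol(f)) else f[par, ]
        tot <- colSums(f[sibs, , drop = FALSE])
        over <- which(tot > cap & tot > 0)
        for (s in over) {
          scale <- cap[s] / tot[s]
          before <- f[sibs, s]
          f[sibs, s] <- before * scale
          changed <- before > 0
          adj[[length(adj) + 1L]] <- data.frame(
            genotype = sibs[changed], sample = colnames(f)[s],
            type = "normalize", raw = before[changed],
            corrected = f[sibs, s][changed], stringsAsFactors = FALSE)
        }
      }
    }
  }
  report <- if (length(adj)) do.call(rbind, adj) else
    data.frame(genotype = character(0), sample = character(0),
               type = character(0), raw = numeric(0), corrected = numeric(0),
               stringsAsFactors = FALSE)
  report$adjustment <- abs(report$raw - report$corrected)
  max_adj <- if (nrow(report)) max(report$adjustment) else 0
  if (max_adj >= 0.10) {
    warning(sprintf("a genotype frequency was corrected by %.3f (>= 0.10)", max_adj))
  }
  tree$corrected <- f
  list(tree = tree, report = list(adjustments = report, max_adjustment = max_adj))
}

#' Export ggmuller-compatible edge and population tables
#'
#' Converts a corrected genotype tree into the two tables the ggmuller R
#' package consumes: an edges table (`Parent`, `Identity`) and a population
#' table (`Generation`, `Identity`, `Population`) where `Population` is the
#' genotype's exclusive frequency (its corrected frequency minus its
#' children's) and the ancestor carries the remainder, so per-generation
#' populations sum to exactly 1.
#'
#' @param tree a corrected `genotype_tree`.
#' @param sheet sample sheet supplying `generations` for the tree's sample
#'   columns.
#' @return list with `edges` and `population` data.frames.
#' @export
export_muller_tables <- function(tree, sheet) {
  stopifnot(inherits(tree, "genotype_tree"))
  if (is.null(tree$corrected) && nrow(tree$nodes) > 0) {
    stop("tree has no corrected frequencies; run correct_genotype_frequencies()")
  }
  sheet <- validate_sample_sheet(sheet)
  samples <- colnames(tree$raw)
  gen <- sheet$generations[match(samples, sheet$sample_id)]
  if (length(samples) && any(is.na(gen))) {
    stop("sample sheet lacks generations for: ",
         paste(samples[is.na(gen)], collapse = ", "))
  }
  nodes <- tree$nodes
  edges <- data.frame(Parent = nodes$parent, Identity = nodes$genotype,
                      stringsAsFactors = FALSE)
  f <- tree$corrected
  pop_rows <- list()
  for (s in seq_along(samples)) {
    child_sum <- stats::setNames(rep(0, nrow(nodes) + 1L),
                                 c("ancestor", nodes$genotype))
    if (nrow(nodes)) {
      sums <- tapply(f[nodes$genotype, s], nodes$parent, sum)
      child_sum[names(sums)] <- sums
    }
    excl <- if (nrow(nodes)) f[nodes$genotype, s] - child_sum[nodes$genotype] else numeric(0)
    anc <- 1 - child_sum[["ancestor"]]
    vals <- c(anc, excl)
    if (any(vals < -1e-9)) {
      stop("negative exclusive frequency after correction (internal inconsistency)")
    }
    vals <- pmax(vals, 0)
    pop_rows[[s]] <- data.frame(
      Generation = gen[s], Identity = c("ancestor", nodes$genotype),
      Population = unname(vals), stringsAsFactors = FALSE)
  }
  population <- if (length(pop_rows)) do.call(rbind, pop_rows) else
    data.frame(Generation = numeric(0), Identity = character(0),
               Population = numeric(0), stringsAsFactors = FALSE)
  rownames(population) <- NULL
  list(edges = edges, population = population)
}
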