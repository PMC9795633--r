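test_that("Manhattan distance is a metric computed over unmasked samples", {
  expect_equal(manhattan_distance(c(0.1, 0.5, 0.9), c(0.2, 0.2, 0.8)), 0.5)
  expect_equal(manhattan_distance(c(0.3, 0.3), c(0.3, 0.3)), 0)
  expect_equal(manhattan_distance(c(0.1, NA, 0.9), c(0.2, 0.5, NA)), 0.1)
  expect_error(manhattan_distance(c(NA, 1), c(1, NA)), "unmasked")
  expect_error(manhattan_distance(c(1, 2), c(1, 2, 3)), "length")

  set.seed(6)
  for (i in 1:25) {
    a <- runif(5); b <- runif(5); c <- runif(5)
    expect_equal(manhattan_distance(a, b), manhattan_distance(b, a))
    expect_lte(manhattan_distance(a, c),
               manhattan_distance(a, b) + manhattan_distance(b, c) + 1e-12)
  }
})

test_that("assignment picks the nearest marker under the cutoff", {
  markers <- list(A41T = c(0.1, 0.6, 0.9), D1303 = c(0.0, 0.1, 0.05))
  same <- assign_lineage(markers$A41T, markers)
  expect_equal(same$label, "A41T")
  expect_equal(unname(same$distances["A41T"]), 0)

  # constant-zero trajectory against sweeping markers: distances >= cutoff
  sweeps <- list(A41T = c(0.2, 0.6, 1.0), D1303 = c(0.1, 0.5, 0.9))
  far <- assign_lineage(c(0, 0, 0), sweeps)
  expect_equal(far$label, "unassigned")
  expect_true(all(far$distances >= 0.4))

  tie <- assign_lineage(c(0.15, 0.55, 0.95), sweeps)  # equidistant at 0.15
  expect_true(tie$tie)
  expect_equal(tie$label, "unassigned")

  expect_error(assign_lineage(c(0.1), list()), "marker")
})

test_that("substitution classes fold strand complements together", {
  expect_equal(substitution_class("A", "G"), "A:T>G:C")
  expect_equal(substitution_class("T", "C"), "A:T>G:C")
  expect_equal(substitution_class("G", "T"), "C:G>A:T")
  expect_error(substitution_class("A", "A"), "differ")
  expect_error(substitution_class("N", "A"), "single bases")

  comp <- c(A = "T", C = "G", G = "C", T = "A")
  bases <- names(comp)
  pairs <- expand.grid(ref = bases, alt = bases, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  expect_equal(nrow(pairs), 12)
  cls <- substitution_class(pairs$ref, pairs$alt)
  cls_comp <- substitution_class(comp[pairs$ref], comp[pairs$alt])
  expect_equal(cls, cls_comp)
  expect_setequal(unique(cls), substitution_classes())
  expect_true(all(table(cls) == 2))
})

test_that("spectrum counts group SNVs and report indel exclusions", {
  f <- matrix(0.5, 12, 2, dimnames = list(sprintf("m%02d", 1:12), c("s1", "s2")))
  tab <- counts_table(f, ref = c(rep("A", 10), "C", "A"),
                      alt = c(rep("G", 10), "T", "del3"),
                      class = c(rep("snv", 11), "indel"))
  res <- spectrum_counts(tab, rep("grp", 12))
  expect_equal(res$n_excluded, 1)
  expect_equal(unname(res$N["grp"]), 11)
  expect_equal(unname(res$counts["grp", "A:T>G:C"]), 10)
  expect_equal(unname(res$proportions["grp", "A:T>G:C"]), 10 / 11)
  expect_equal(sum(res$proportions["grp", ]), 1)

  # strand relabeling (complementing ref/alt of every row) leaves the
  # spectrum unchanged
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  flipped <- tab
  snv <- flipped$mutation_class == "snv"
  flipped$ref_allele[snv] <- comp[flipped$ref_allele[snv]]
  flipped$alt_allele[snv] <- comp[flipped$alt_allele[snv]]
  res2 <- spectrum_counts(flipped, rep("grp", 12))
  expect_identical(res2$counts, res$counts)

  empty <- spectrum_counts(tab[0, ], character(0))
  expect_equal(sum(empty$counts), 0)
})

test_that("assignment recovers simulated lineage labels when markers separate", {
  # lineages established well before the first sequenced sample, so nearly
  # all hitchhikers track their lineage fraction over the whole window
  g <- c(500, 510, 520, 530, 540, 550)
  fa <- c(0.75, 0.70, 0.72, 0.68, 0.74, 0.70)
  fd <- c(0.20, 0.25, 0.22, 0.26, 0.20, 0.24)
  expect_gte(sum(abs(fa - fd)), 1)  # marker separation precondition
  cfg <- sim_config(treatment_spec(
    "host", g, depth_mean = 150, lineages = list(
      lineage_spec("A41T", 0.3, fa, marker = TRUE),
      lineage_spec("D1303", 0.15, fd, marker = TRUE))), seed = 8)
  sim <- simulate_experiment(cfg)
  freqs <- compute_frequencies(sim$variants)
  truth <- sim$truth$mutations
  asg <- assign_lineages(freqs, list(A41T = fa, D1303 = fd))
  # classification targets mutations tracked over the whole window; those
  # arising between later samples sit far from both markers by construction
  present <- sim$truth$true_freq[, 1] > 0
  real <- !truth$is_false_positive & !truth$is_marker &
    present[truth$mutation_id]
  agree <- asg$label[match(truth$mutation_id[real], asg$mutation_id)] ==
    truth$lineage[real]
  expect_gt(sum(real), 150)
  expect_gte(mean(agree), 0.95)
})

test_that("simulator spectrum weights are recovered in assigned spectra", {
  g <- c(500, 510, 520, 530, 540, 550)
  fa <- c(0.75, 0.70, 0.72, 0.68, 0.74, 0.70)
  w <- c(0.9, 0.02, 0.02, 0.02, 0.02, 0.02)
  cfg <- sim_config(treatment_spec(
    "host", g, depth_mean = 150, lineages = list(
      lineage_spec("A41T", 0.6, fa, marker = TRUE, spectrum_weights = w))),
    seed = 9)
  sim <- simulate_experiment(cfg)
  freqs <- compute_frequencies(sim$variants)
  asg <- assign_lineages(freqs, list(A41T = fa))
  grp <- asg$label[match(sim$variants$mutation_id, asg$mutation_id)]
  spec <- spectrum_counts(sim$variants, grp)
  expect_gt(spec$N[["A41T"]], 100)
  expect_lt(abs(spec$proportions["A41T", "A:T>G:C"] - 0.9), 0.06)
})
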