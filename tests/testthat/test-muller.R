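test_that("peak threshold and exclusions select Muller mutations", {
  f <- rbind(low = c(0.05, 0.09), edge = c(0.10, 0.02),
             high = c(0.6, 0.9), excluded = c(0.8, 0.8))
  colnames(f) <- c("s1", "s2")
  sel <- select_muller_mutations(f, exclusions = "excluded")
  expect_setequal(rownames(sel), c("edge", "high"))  # 0.10 boundary inclusive
})

test_that("greedy containment nests trajectories under the one-per-gene rule", {
  f <- rbind(first = c(0.2, 0.8, 1.0), second = c(0.0, 0.3, 0.9))
  colnames(f) <- paste0("s", 1:3)
  tree <- infer_genotype_nesting(f)
  expect_equal(tree$nodes$parent[tree$nodes$genotype == "second"], "first")
  expect_equal(tree$nodes$parent[tree$nodes$genotype == "first"], "ancestor")

  # same gene blocks nesting even when containment holds
  gene_of <- c(first = "mutS", second = "mutS")
  sib <- infer_genotype_nesting(f, gene_of = gene_of)
  expect_equal(sort(unique(sib$nodes$parent)), "ancestor")

  single <- infer_genotype_nesting(f[1, , drop = FALSE])
  expect_equal(single$nodes$parent, "ancestor")
  expect_equal(nrow(single$nodes), 1)
})

test_that("corrections cap children and normalize sibling totals", {
  # child exceeds its parent at s1 by 0.15 (wide tolerance to force nesting)
  f <- rbind(parent = c(0.5, 0.9), child = c(0.65, 0.4))
  colnames(f) <- c("s1", "s2")
  tree <- infer_genotype_nesting(f, epsilon = 0.2)
  expect_equal(tree$nodes$parent[tree$nodes$genotype == "child"], "parent")
  expect_warning(res <- correct_genotype_frequencies(tree), ">= 0.10")
  expect_equal(unname(res$tree$corrected["child", "s1"]), 0.5)
  expect_equal(res$report$max_adjustment, 0.15, tolerance = 1e-12)

  # root siblings summing to 1.3 rescale proportionally
  roots <- rbind(a = c(0.7, 0.3), b = c(0.6, 0.5))
  colnames(roots) <- c("s1", "s2")
  rtree <- infer_genotype_nesting(roots)
  expect_equal(unique(rtree$nodes$parent), "ancestor")
  expect_warning(rres <- correct_genotype_frequencies(rtree))
  expect_equal(unname(rres$tree$corrected[c("a", "b"), "s1"]),
               c(0.7, 0.6) / 1.3)
  expect_equal(unname(rres$tree$corrected[c("a", "b"), "s2"]), c(0.3, 0.5))

  # an already-consistent tree is a fixed point
  ok <- infer_genotype_nesting(nested_muller_freqs())
  first <- correct_genotype_frequencies(ok)
  expect_equal(nrow(first$report$adjustments), 0)
  expect_identical(first$tree$corrected, first$tree$raw)

  # idempotence: re-correcting corrected frequencies changes nothing
  recor <- res$tree
  recor$raw <- recor$corrected
  expect_silent(again <- correct_genotype_frequencies(recor))
  expect_identical(again$tree$corrected, res$tree$corrected)
  expect_equal(nrow(again$report$adjustments), 0)
})

test_that("export produces conserving ggmuller tables", {
  f <- rbind(A = 0.8, B = 0.3)
  colnames(f) <- "s1"
  tree <- infer_genotype_nesting(f)
  corr <- correct_genotype_frequencies(tree)
  sheet <- simple_sheet("s1", 100)
  tabs <- export_muller_tables(corr$tree, sheet)
  expect_equal(tabs$edges$Parent[tabs$edges$Identity == "B"], "A")
  pop <- tabs$population
  expect_equal(pop$Population[pop$Identity == "A"], 0.5)
  expect_equal(pop$Population[pop$Identity == "B"], 0.3)
  expect_equal(pop$Population[pop$Identity == "ancestor"], 0.2)
  expect_equal(pop$Generation, rep(100, 3))

  # empty tree exports the ancestor alone at 1.0
  empty <- infer_genotype_nesting(f[0, , drop = FALSE])
  etabs <- export_muller_tables(empty, sheet)
  expect_equal(etabs$population$Identity, "ancestor")
  expect_equal(etabs$population$Population, 1.0)

  # per-generation conservation on a deeper tree
  deep <- correct_genotype_frequencies(
    infer_genotype_nesting(nested_muller_freqs()))
  sheet4 <- simple_sheet(paste0("s", 1:4), c(10, 20, 30, 40))
  dt <- export_muller_tables(deep$tree, sheet4)
  sums <- tapply(dt$population$Population, dt$population$Generation, sum)
  expect_equal(as.vector(sums), rep(1, 4))
})

test_that("noise-free nesting reconstructs known genotype structure exactly", {
  # known-nesting trajectories observed noise-free through exact read counts
  f <- nested_muller_freqs()
  tab <- counts_table(f, depth = 100,
                      genes = c("geneA", "geneB", "geneC", "geneD"))
  freqs <- compute_frequencies(tab)
  expect_equal(unname(freqs), unname(f))  # representable: observation = truth
  tree <- infer_genotype_nesting(select_muller_mutations(freqs))
  got <- setNames(tree$nodes$parent, tree$nodes$genotype)
  expect_equal(got[names(nested_muller_parents)], nested_muller_parents)
  corr <- correct_genotype_frequencies(tree)
  expect_equal(corr$report$max_adjustment, 0)
})

test_that("corrections stay small under read-depth noise on nested genotypes", {
  f <- nested_muller_freqs()
  set.seed(10)
  depth <- 150
  noisy <- f
  noisy[] <- rbinom(length(f), depth, as.vector(f)) / depth
  tab <- counts_table(noisy, depth = depth)
  tree <- infer_genotype_nesting(compute_frequencies(tab), epsilon = 0.05)
  corr <- correct_genotype_frequencies(tree)
  expect_lt(corr$report$max_adjustment, 0.10)
  # invariants hold exactly after correction
  cf <- corr$tree$corrected
  for (i in seq_len(nrow(corr$tree$nodes))) {
    par <- corr$tree$nodes$parent[i]
    cap <- if (par == "ancestor") rep(1, ncol(cf)) else cf[par, ]
    expect_true(all(cf[corr$tree$nodes$genotype[i], ] <= cap + 1e-12))
  }
})
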