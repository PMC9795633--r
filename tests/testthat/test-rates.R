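test_that("lineage fractions normalize onto the closed simplex", {
  over <- normalize_lineage_fractions(0.6, 0.5)
  expect_equal(unlist(over), c(f_A41T = 6 / 11, f_D1303 = 5 / 11, f_anc = 0))
  under <- normalize_lineage_fractions(0.2, 0.3)
  expect_equal(under$f_anc, 0.5)
  pure <- normalize_lineage_fractions(0, 0)
  expect_equal(pure$f_anc, 1)
  expect_error(normalize_lineage_fractions(-0.1, 0.2), "nonnegative")
  v <- normalize_lineage_fractions(c(0.6, 0.2), c(0.5, 0.3))
  expect_equal(rowSums(v), c(1, 1))
})

test_that("through-origin single-rate fit matches closed form and lm", {
  fit <- fit_single_rate(c(10, 20), c(1.0, 2.2))
  expect_equal(unname(fit$rates), 0.108)
  expect_equal(unname(fit$se), 0.004)

  # exact recovery on consistent data at the fly cycle generations
  g <- fly_generations()
  exact <- fit_single_rate(g, 0.00177 * g)
  expect_equal(unname(exact$rates), 0.00177, tolerance = 1e-12)
  expect_equal(exact$rss, 0, tolerance = 1e-20)

  expect_equal(unname(fit_single_rate(c(5, 10), c(0, 0))$rates), 0)
  expect_error(fit_single_rate(c(0, 0), c(1, 2)), "zero elapsed")
  expect_true(is.na(fit_single_rate(7, 0.5)$se))

  set.seed(1)
  gg <- runif(8, 10, 300); MM <- 0.02 * gg + rnorm(8, sd = 0.1)
  MM <- pmax(MM, 0)
  ours <- fit_single_rate(gg, MM)
  lmfit <- lm(MM ~ 0 + gg)
  expect_equal(unname(ours$rates), unname(coef(lmfit)), tolerance = 1e-10)
  expect_equal(unname(ours$se), unname(sqrt(diag(vcov(lmfit)))),
               tolerance = 1e-10)
})

test_that("multi-lineage fit recovers generating rates and reduces properly", {
  g <- mouse_host_generations()
  sch <- mouse_host_fraction_schedule()
  fr <- cbind(ancestral = 1 - rowSums(sch), sch)
  truth <- c(ancestral = 0.0076, A41T = 2.453, D1303 = 0.310)
  M <- model_summed_frequency(g, fr, truth)
  fit <- fit_multirate(g, fr, M)
  expect_equal(fit$rates, truth, tolerance = 1e-10)
  expect_lt(fit$rss, 1e-18)

  # one-hot fractions: rates equal per-lineage single fits
  oh <- cbind(a = c(1, 1, 0, 0), b = c(0, 0, 1, 1))
  g4 <- c(10, 20, 30, 40); M4 <- c(1, 2.2, 0.6, 0.7)
  both <- fit_multirate(g4, oh, M4)
  expect_equal(unname(both$rates["a"]),
               unname(fit_single_rate(g4[1:2], M4[1:2])$rates))
  expect_equal(unname(both$rates["b"]),
               unname(fit_single_rate(g4[3:4], M4[3:4])$rates))

  # single lineage at fraction 1 is numerically the single-rate fit
  one <- fit_multirate(g4, cbind(only = rep(1, 4)), M4)
  single <- fit_single_rate(g4, M4)
  expect_equal(unname(one$rates), unname(single$rates), tolerance = 1e-12)
  expect_equal(unname(one$se), unname(single$se), tolerance = 1e-12)

  expect_error(fit_multirate(g4, cbind(a = oh[, 1], a2 = oh[, 1]), M4),
               "collinear")
  expect_error(fit_multirate(g4, cbind(a = oh[, 1], z = rep(0, 4)), M4),
               "never observed.*z")

  # lm oracle on a noisy three-lineage design
  set.seed(2)
  Mn <- M + rnorm(length(M), sd = 5)
  ours <- fit_multirate(g, fr, Mn)
  X <- fr * g
  lmfit <- lm(Mn ~ 0 + X)
  expect_equal(unname(ours$rates), unname(coef(lmfit)), tolerance = 1e-8)
  expect_equal(unname(ours$se), unname(sqrt(diag(vcov(lmfit)))),
               tolerance = 1e-8)
})

test_that("rate equality F-test matches anova and flags degenerate fits", {
  g <- mouse_host_generations()
  sch <- mouse_host_fraction_schedule()
  fr <- cbind(ancestral = 1 - rowSums(sch), sch)
  set.seed(3)
  M <- model_summed_frequency(g, fr, c(0.01, 1.2, 0.4)) + abs(rnorm(15, sd = 3))
  res <- compare_rates_ftest(g, fr, M, c("A41T", "D1303"))

  X <- fr * g
  Xr <- cbind(X[, "ancestral"], X[, "A41T"] + X[, "D1303"])
  an <- anova(lm(M ~ 0 + Xr), lm(M ~ 0 + X))
  expect_equal(res$F, an$F[2], tolerance = 1e-10)
  expect_equal(res$p_value, an$`Pr(>F)`[2], tolerance = 1e-10)
  expect_equal(res$df1, 1)
  expect_equal(res$df2, 12)

  # noise-free unequal rates: saturated full model, degenerate path
  M0 <- model_summed_frequency(g, fr, c(0.01, 1.2, 0.4))
  expect_warning(deg <- compare_rates_ftest(g, fr, M0, c("A41T", "D1303")),
                 "degenerate")
  expect_identical(deg$F, Inf)
  expect_lt(deg$p_value, 1e-300)

  expect_error(compare_rates_ftest(g, fr[, "A41T", drop = FALSE], M0,
                                   c("A41T", "D1303")), "two lineages")
})

test_that("equal-rate null produces uniform F-test p-values", {
  g <- mouse_host_generations()
  sch <- mouse_host_fraction_schedule()
  fr <- cbind(ancestral = 1 - rowSums(sch), sch)
  set.seed(4)
  pvals <- replicate(300, {
    M <- model_summed_frequency(g, fr, c(0.05, 0.8, 0.8)) + rnorm(15, sd = 2)
    compare_rates_ftest(g, fr, M, c("A41T", "D1303"))$p_value
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 1e-3)
})

test_that("fold change and generation time follow their closed forms", {
  expect_equal(fold_change(2.453, 0.0076, round_to_integer = TRUE), 323)
  expect_equal(fold_change(0.310, 0.0076, round_to_integer = TRUE), 41)
  expect_equal(fold_change(0.5, 0.5), 1)
  expect_error(fold_change(1, 0), "positive")

  expect_equal(generation_time(0, 24, 1e3, 2e3), 24)
  expect_equal(generation_time(0, 24, 1e3, 4e3), 12)
  expect_equal(generation_time(0, 3, 1e3, 1e6), 3 * log10(2) / 3)
  expect_error(generation_time(0, 3, 1e3, 1e3), "zero growth")
  expect_warning(gt <- generation_time(0, 3, 1e6, 1e3), "declined")
  expect_lt(gt, 0)
})

test_that("rates are equivariant under rescaling of the generation axis", {
  g <- fly_generations()
  set.seed(5)
  M <- 0.002 * g + abs(rnorm(4, sd = 0.05))
  base <- fit_single_rate(g, M)
  scaled <- fit_single_rate(3 * g, M)
  expect_equal(unname(scaled$rates) * 3, unname(base$rates), tolerance = 1e-12)
})

test_that("rate points assemble summed frequencies with normalized fractions", {
  f <- rbind(m1 = c(0.5, 0.2), m2 = c(0.1, 0.4))
  colnames(f) <- c("s1", "s2")
  tab <- counts_table(f, depth = 100)
  sheet <- simple_sheet(c("s1", "s2"), c(30, 60), "mouse_host",
                        f_A41T = c(0.6, 0.2), f_D1303 = c(0.5, 0.3))
  pts <- rate_points(tab, sheet)
  expect_equal(pts$M, c(0.6, 0.6))
  expect_equal(pts$f_A41T, c(6 / 11, 0.2))
  expect_equal(pts$f_anc, c(0, 0.5))
  expect_equal(pts$f_A41T + pts$f_D1303 + pts$f_anc, c(1, 1))
})
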