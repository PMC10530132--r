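test_that("trial means and SDs follow the replicate conventions", {
  tm <- trial_means(data.frame(trial = 1:3,
                               r1 = c(4.40, 2, 1), r2 = c(3.90, 2, 2),
                               r3 = c(4.06, 2, 3)))
  expect_equal(round(tm$mean[1], 2), 4.12)
  expect_equal(tm$mean[2], 2)
  expect_equal(tm$sd[2], 0)
  expect_equal(tm$mean[3], 2)
  expect_equal(tm$sd[3], 1) # sample SD, n - 1 denominator
  # single replicate: SD 0, not NA
  one <- trial_means(data.frame(trial = 1, r1 = 5))
  expect_equal(one$sd, 0)
  expect_error(trial_means(data.frame(trial = 1, r1 = NA_real_)),
               class = "pelletr_validation_error")
  expect_error(trial_means(data.frame(trial = 1, r1 = -1)),
               class = "pelletr_validation_error")
})

test_that("screening effects reproduce the published effect row", {
  eff <- pb_effects(pb12_design(), table3_means())
  printed <- table3_printed()
  printed_eff <- as.numeric(printed[printed$statistic == "effect", -1])
  # the published values were computed from unrounded replicates; printed
  # means agree to +/- 0.005 on every column
  expect_true(all(abs(eff$effect - printed_eff) <= 0.005))
  expect_equal(round(eff$effect[eff$factor == "X4"], 3), 1.313)
  expect_equal(round(eff$effect[eff$factor == "X5"], 2), 1.06)
})

test_that("constant responses give zero effects and an undefined dummy test", {
  eff <- pb_effects(pb12_design(), rep(1, 12))
  expect_true(all(eff$effect == 0))
  expect_error(anova_vs_dummy(eff, 12), class = "pelletr_domain_error")
})

test_that("dummy-factor ANOVA matches the published sums of squares", {
  eff <- pb_effects(pb12_design(), table3_means())
  an <- anova_vs_dummy(eff, 12)
  expect_equal(an$ss[an$factor == "X4"], 5.173, tolerance = 0.01 / 5.173)
  expect_true(all(abs(an$ss - an$ms) < 1e-12)) # df = 1
  # the dummy tested against itself
  expect_equal(an$f[an$is_dummy], 1)
  expect_equal(an$p[an$is_dummy], 0.5)
})

test_that("a zero effect yields SS = 0, F = 0, p = 1", {
  eff <- tibble::tibble(factor = c("X1", "X11"), effect = c(0, 0.1))
  an <- anova_vs_dummy(eff, 12)
  expect_equal(an$ss[1], 0)
  expect_equal(an$f[1], 0)
  expect_equal(an$p[1], 1)
})

test_that("critical F values agree with an independent quadrature oracle", {
  expect_equal(round(critical_f(0.05, 1, 1)), 161)
  expect_equal(critical_f(0.5, 1, 1), 1) # median of F(1,1)
  # independent check: integrate the F density above the returned quantile
  cf <- critical_f(0.05, 1, 10)
  tail_mass <- stats::integrate(function(x) stats::df(x, 1, 10), cf, Inf,
                                rel.tol = 1e-10)$value
  expect_equal(tail_mass, 0.05, tolerance = 1e-4)
  expect_error(critical_f(0, 1, 1), class = "pelletr_validation_error")
  expect_error(critical_f(0.05, 0, 1), class = "pelletr_validation_error")
})

test_that("exactly CaCO3, olive oil and Tween 80 clear the critical value", {
  fit <- pb_screen(pb12_design(), table3_means())
  expect_setequal(fit$significant, c("X4", "X5", "X8"))
  an <- anova_vs_dummy(pb_effects(pb12_design(), table3_means()), 12)
  expect_setequal(flag_significant(an, 0.05), c("X4", "X5", "X8"))
})

test_that("a planted effect far above noise is always flagged and top-ranked", {
  # with a single error df every null factor still has a 5% chance of
  # crossing F = 161, so what is guaranteed is that the planted factor is
  # flagged and carries the largest F, not that it is the only flag
  for (seed in 1:20) {
    sim <- simulate_doe(pb12_design(), baseline = 8,
                        effects = c(X4 = 1.0), # (+)-(-) difference 2.0
                        noise_sd = 0.05, replicates = 3, seed = seed)
    fit <- pb_screen(pb12_design(), sim$responses)
    expect_true("X4" %in% fit$significant)
    expect_equal(fit$table$factor[which.max(fit$table$f)], "X4")
  }
})

test_that("effect shares reproduce the published ranking percentages", {
  eff <- pb_effects(pb12_design(), table3_means())
  sh <- effect_shares(eff)
  expect_equal(nrow(sh), 10) # dummy excluded
  expect_equal(round(sh$share[sh$factor == "X4"]), 24)
  expect_equal(round(sh$share[sh$factor == "X5"]), 20)
  expect_equal(round(sh$share[sh$factor == "X8"]), 19)
  expect_equal(round(sh$share[sh$factor == "X9"]), 13)
  expect_equal(sum(sh$share), 100)

  equal <- tibble::tibble(factor = c(paste0("X", 1:10), "X11"),
                          effect = c(rep(0.5, 10), 0.01))
  expect_true(all(effect_shares(equal)$share == 10))
  zero <- tibble::tibble(factor = c("X1", "X11"), effect = c(0, 0.1))
  expect_error(effect_shares(zero), class = "pelletr_domain_error")
})

test_that("column sums of squares decompose the total response variation", {
  set.seed(42)
  y <- rnorm(12, 2, 1)
  eff <- pb_effects(pb12_design(), y)
  ss <- 12 * eff$effect^2 / 4
  expect_equal(sum(ss), sum((y - mean(y))^2), tolerance = 1e-9)
})

test_that("effects are shift-invariant and scale-equivariant", {
  set.seed(7)
  y <- rnorm(12, 2, 0.5)
  base <- pb_effects(pb12_design(), y)$effect
  expect_equal(pb_effects(pb12_design(), y + 5)$effect, base)
  expect_equal(pb_effects(pb12_design(), 3 * y)$effect, 3 * base)
})

test_that("the dummy-referenced F test has a plausible null type-I rate", {
  n_sim <- 2000
  hits <- matrix(FALSE, n_sim, 10)
  fcrit <- critical_f(0.05, 1, 1)
  d <- pb12_design()
  codes <- design_codes(d)
  set.seed(2024)
  for (s in seq_len(n_sim)) {
    y <- rnorm(12, 2, 0.3)
    eff <- crossprod(codes, y) / 6 # (+) mean minus (-) mean
    ms <- 12 * eff^2 / 4
    f <- ms / ms["X11", ]
    hits[s, ] <- f[paste0("X", 1:10), ] > fcrit
  }
  rates <- colMeans(hits)
  # with a single error df the test is noisy; a wide sanity band
  expect_true(all(rates >= 0.005 & rates <= 0.15))
})

test_that("planted effects are recovered with negligible bias", {
  est <- vapply(1:200, function(seed) {
    sim <- simulate_doe(pb12_design(), baseline = 3, effects = c(X4 = 0.65),
                        noise_sd = 0.1, replicates = 3, seed = seed)
    eff <- pb_effects(pb12_design(), trial_means(sim$responses))
    eff$effect[eff$factor == "X4"]
  }, numeric(1))
  expect_lt(abs(mean(est) - 1.3), 0.1 / sqrt(3))
  expect_lt(abs(mean(est) - 1.3), 0.02) # Monte-Carlo precision at 200 seeds
})

test_that("tidy and glance views expose the screening results", {
  fit <- pb_screen(pb12_design(), table3_means())
  tab <- tidy(fit)
  expect_s3_class(tab, "tbl_df")
  expect_true(all(c("factor", "effect", "ss", "f", "p", "share", "significant")
                  %in% names(tab)))
  g <- glance(fit)
  expect_equal(g$n_significant, 3L)
  expect_equal(g$n_factors, 10L)
  expect_s3_class(autoplot(fit), "ggplot")
})
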