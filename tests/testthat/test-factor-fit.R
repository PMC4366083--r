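test_that("minres recovers an exact 1-factor structure", {
  C <- equicor(5, 0.49)  # loadings 0.7, uniqueness 0.51
  fm <- minres_efa(C, 1)
  expect_true(fm$converged)
  expect_false(fm$heywood)
  expect_equal(as.numeric(fm$loadings), rep(0.7, 5), tolerance = 1e-4)
  expect_equal(fm$uniquenesses, rep(0.51, 5), tolerance = 1e-4)
  expect_lt(fm$objective, 1e-10)
})

test_that("minres on an identity matrix finds nothing to explain", {
  fm <- minres_efa(diag(5), 1)
  expect_lt(fm$objective, 1e-8)
  # off-diagonal implied correlations vanish (a lone nonzero loading is
  # unidentified by the off-diagonal objective and may remain)
  expect_lt(max(abs(fm$implied[upper.tri(fm$implied)])), 1e-4)
})

test_that("adding a factor never worsens the minres objective", {
  set.seed(21)
  for (i in 1:5) {
    m <- matrix(sample(1:5, 300 * 6, replace = TRUE), 300, 6)
    C <- cor(m)
    expect_lte(minres_efa(C, 2)$objective,
               minres_efa(C, 1)$objective + 1e-10)
  }
})

test_that("ML discrepancy has its closed-form values and symmetries", {
  S <- equicor(2, 0.5)
  expect_equal(ml_discrepancy(S, S), 0, tolerance = 1e-12)
  # S vs identity: -log(1 - 0.25) + 2 - 2
  expect_equal(ml_discrepancy(S, diag(2)), -log(0.75), tolerance = 1e-12)
  # invariant under joint permutation
  set.seed(6)
  m <- matrix(sample(1:5, 200 * 4, replace = TRUE), 200, 4)
  S4 <- cor(m)
  Sig <- equicor(4, 0.3)
  perm <- c(3, 1, 4, 2)
  expect_equal(ml_discrepancy(S4, Sig),
               ml_discrepancy(S4[perm, perm], Sig[perm, perm]))
  expect_gte(ml_discrepancy(S4, Sig), 0)
  expect_error(ml_discrepancy(S, matrix(0, 2, 2)))
})

test_that("EFA chi-square applies the Bartlett correction and df rule", {
  z <- efa_chi2(0, 1000, 5, 1)
  expect_equal(z$chi2, 0)
  expect_equal(z$p_value, 1)
  expect_equal(z$df, 5)  # ((5-1)^2 - 6) / 2
  z2 <- efa_chi2(0.01, 2000, 5, 1)
  expect_equal(z2$chi2, (2000 - 1 - 15 / 6 - 2 / 3) * 0.01)
  expect_equal(z2$chi2, 19.958, tolerance = 1e-4)
  expect_equal(efa_chi2(0.1, 2000, 5, 2)$df, 1)
  expect_error(efa_chi2(0.1, 2000, 4, 3))
})

test_that("difference test rejects only overwhelming improvements", {
  f1 <- list(chi2 = 100, df = 5)
  f2 <- list(chi2 = 100, df = 1)
  expect_false(delta_chi2_test(f1, f2)$reject_1factor)
  expect_equal(delta_chi2_test(f1, f2)$delta_df, 4)
  f3 <- list(chi2 = 600, df = 5)
  dt <- delta_chi2_test(f3, f2, alpha = 1e-5)
  expect_true(dt$reject_1factor)
  expect_equal(dt$delta_chi2, 500)
  # chi2 improvement below zero is clamped, never rejected
  f4 <- list(chi2 = 90, df = 5)
  expect_equal(delta_chi2_test(f4, list(chi2 = 95, df = 1))$delta_chi2, 0)
})

test_that("RMSEA follows its formula and monotonicity", {
  expect_equal(rmsea(5, 5, 2000), 0)
  expect_equal(rmsea(10, 5, 2000), sqrt(5 / (5 * 1999)))
  expect_equal(rmsea(10, 5, 2000), 0.02237, tolerance = 1e-3)
  chis <- seq(6, 60, by = 2)
  expect_true(all(diff(vapply(chis, rmsea, 0, df = 5, n = 2000)) > 0))
  expect_error(rmsea(10, 0, 2000))
})

test_that("GFI and AGFI match hand-computed values", {
  S <- equicor(2, 0.5)
  g <- gfi_agfi(S, S, df = 1, p = 2)
  expect_equal(g$gfi, 1)
  expect_equal(g$agfi, 1)
  g2 <- gfi_agfi(S, diag(2), df = 1, p = 2)
  expect_equal(g2$gfi, 0.8)        # 1 - 0.5 / 2.5
  expect_equal(g2$agfi, 0.4)       # 1 - 3 * 0.2
  expect_lte(g2$agfi, g2$gfi)
})

test_that("1-factor CFA is exact on an exact 1-factor matrix", {
  C <- equicor(5, 0.49)
  cf <- cfa_1factor(C, 2000)
  expect_true(cf$converged)
  expect_equal(cf$F, 0, tolerance = 1e-8)
  expect_equal(cf$df, 5)  # p(p+1)/2 - 2p
  expect_equal(cf$gfi, 1, tolerance = 1e-6)
  expect_equal(cf$rmsea, 0)
  expect_false(cf$reject_chi2)
  expect_false(cf$reject_agfi)
  expect_false(cf$reject_rmsea)
  expect_equal(as.numeric(cf$model$loadings), rep(0.7, 5), tolerance = 1e-4)
})

test_that("CFA is calibrated for continuous 1-factor data", {
  # data truly from a linear 1-factor model: rejection at alpha .001 is rare
  set.seed(55)
  rejections <- vapply(1:30, function(i) {
    f <- rnorm(2000)
    x <- sapply(1:5, function(j) 0.7 * f + sqrt(1 - 0.49) * rnorm(2000))
    cfa_1factor(cor(x), 2000)$reject_chi2
  }, TRUE)
  expect_lte(mean(rejections), 0.1)
})

test_that("EFA and CFA agree on the 1-factor discrepancy", {
  cond <- simulation_condition(dist_normal(), 6, "large",
                               n_respondents = 1000, seed = 13)
  C <- pearson_matrix(generate_dataset(cond))$matrix
  efa_ml <- efa_fit(C, 1, 1000, refit_ml = TRUE)
  cfa <- cfa_1factor(C, 1000)
  expect_equal(efa_ml$F, cfa$F, tolerance = 1e-6)
  # the minres-evaluated discrepancy sits close above the ML minimum
  efa_mr <- efa_fit(C, 1, 1000)
  expect_gte(efa_mr$F, cfa$F - 1e-8)
  expect_lt((efa_mr$F - cfa$F) / cfa$F, 0.1)
})

test_that("2-factor EFA never fits worse than 1-factor in chi-square", {
  set.seed(77)
  for (i in 1:5) {
    cond <- simulation_condition(dist_uniform(), 6, "small",
                                 n_respondents = 800,
                                 seed = sample.int(1e6, 1))
    C <- pearson_matrix(generate_dataset(cond))$matrix
    f1 <- efa_fit(C, 1, 800)
    f2 <- efa_fit(C, 2, 800)
    expect_lte(f2$chi2, f1$chi2 + 1e-6)
  }
})
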