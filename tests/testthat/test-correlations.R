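test_that("bivariate normal CDF matches closed forms and the reference", {
  # P(X<=0, Y<=0) = 1/4 + asin(rho) / (2 pi)
  for (r in c(-0.95, -0.5, 0, 0.3, 0.8, 0.99)) {
    expect_equal(pbvnorm(0, 0, r), 0.25 + asin(r) / (2 * pi),
                 tolerance = 1e-12)
  }
  expect_equal(pbvnorm(Inf, 1.3, 0.5), pnorm(1.3), tolerance = 1e-12)
  expect_equal(pbvnorm(-Inf, 1.3, 0.5), 0)
  expect_equal(pbvnorm(2, Inf, -0.7), pnorm(2), tolerance = 1e-12)
  skip_if_not_installed("mvtnorm")
  set.seed(1)
  h <- c(-3, -1.2, -0.4, 0, 0.7, 1.9, 3.5, runif(10, -3, 3))
  g <- expand.grid(x = h, y = h)
  for (r in c(-0.999, -0.95, -0.6, 0.2, 0.8, 0.924, 0.926, 0.99)) {
    ref <- mapply(function(a, b) {
      mvtnorm::pmvnorm(upper = c(a, b),
                       corr = matrix(c(1, r, r, 1), 2),
                       algorithm = mvtnorm::TVPACK())[1]
    }, g$x, g$y)
    expect_equal(pbvnorm(g$x, g$y, r), ref, tolerance = 1e-7)
  }
})

test_that("Pearson matrices are exact on toy data and flagged correctly", {
  m <- cbind(a = c(1, 2, 3, 4), b = c(2, 1, 4, 3), c = c(1, 2, 3, 4))
  ce <- pearson_matrix(m)
  expect_s3_class(ce, "cor_estimate")
  expect_equal(diag(ce$matrix), c(a = 1, b = 1, c = 1))
  expect_equal(ce$matrix["a", "c"], 1)
  # hand-computed product-moment value for (1,2,3,4) vs (2,1,4,3)
  x <- c(1, 2, 3, 4); y <- c(2, 1, 4, 3)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(ce$matrix["a", "b"], r_hand)
  expect_true(ce$converged)

  bad <- cbind(a = c(1, 1, 1, 1), b = c(1, 2, 3, 4))
  ceb <- pearson_matrix(bad)
  expect_false(ceb$converged)
  expect_match(ceb$pairwise_flags, "zero variance")
})

test_that("Pearson correlation matrices are positive semi-definite", {
  set.seed(99)
  for (i in 1:20) {
    m <- matrix(sample(1:5, 50 * 6, replace = TRUE), 50, 6)
    ev <- eigen(cor(m), symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-10)
  }
})

test_that("threshold estimation inverts cumulative proportions", {
  tau <- estimate_thresholds(c(400, 400, 400, 400, 400))
  expect_equal(tau, qnorm(c(0.2, 0.4, 0.6, 0.8)), ignore_attr = TRUE)
  tau2 <- estimate_thresholds(c(1000, 0, 1000, 0, 0))
  expect_equal(as.numeric(tau2), 0)  # empty categories collapse
  tau3 <- estimate_thresholds(c(2000, 0, 0, 0, 0))
  expect_length(tau3, 0)
  expect_true(attr(tau3, "degenerate"))
})

test_that("polychoric rho handles independence, concordance, degeneracy", {
  ind <- outer(c(300, 500, 200), c(400, 400, 200)) / 1000
  est <- polychoric_rho(ind)
  expect_true(est$converged)
  expect_equal(est$rho, 0, tolerance = 0.01)

  conc <- diag(c(500, 500, 500))  # perfectly concordant
  expect_equal(polychoric_rho(conc)$rho, 0.999, tolerance = 1e-3)

  degen <- matrix(c(10, 20, 0, 0), 2, 2)  # single-category margin
  expect_false(polychoric_rho(degen)$converged)
})

test_that("two-step estimator recovers the latent correlation", {
  pool <- likert_pool()
  # spec-pinned oracle: items 1 and 12 under the normal population
  ta <- item_tau(pool[1, ], 50, 20)
  tb <- item_tau(pool[12, ], 50, 20)
  codes <- rbvn_codes(1e5, 0.6, ta, tb, seed = 8)
  tab <- table(factor(codes[, 1], 1:5), factor(codes[, 2], 1:5))
  est <- polychoric_rho(tab)
  expect_lt(abs(est$rho - 0.6), 0.015)

  # recovery within +/- 0.02 at n = 2000 across rho and threshold sets
  cases <- expand.grid(rho = c(-0.9, -0.4, 0.3, 0.7, 0.9),
                       item = c(3, 17))
  for (i in seq_len(nrow(cases))) {
    tj <- item_tau(pool[cases$item[i], ], 50, 20)
    codes <- rbvn_codes(2000, cases$rho[i], tj, tj, seed = 100 + i)
    tab <- table(factor(codes[, 1], 1:5), factor(codes[, 2], 1:5))
    est <- polychoric_rho(tab)
    # single-draw sampling error at n = 2000 is ~0.02 sd; allow 3 sd
    expect_lt(abs(est$rho - cases$rho[i]), 0.06,
              label = sprintf("rho=%.1f item=%d error", cases$rho[i],
                              cases$item[i]))
  }
  # and tightly (within 0.02 on average) over replications at n = 2000
  errs <- vapply(1:20, function(rep) {
    tj <- item_tau(pool[3, ], 50, 20)
    codes <- rbvn_codes(2000, 0.6, tj, tj, seed = 500 + rep)
    tab <- table(factor(codes[, 1], 1:5), factor(codes[, 2], 1:5))
    polychoric_rho(tab)$rho - 0.6
  }, 0)
  expect_lt(abs(mean(errs)), 0.02)
})

test_that("polychoric rho is antisymmetric under category reversal", {
  codes <- rbvn_codes(5000, 0.55, c(-1, 0, 1), c(-0.8, 0.2, 1.1), seed = 12)
  tab <- table(factor(codes[, 1], 1:4), factor(codes[, 2], 1:4))
  rev_tab <- tab[, 4:1]
  expect_equal(polychoric_rho(tab)$rho, -polychoric_rho(rev_tab)$rho,
               tolerance = 1e-4)
})

test_that("categorisation attenuates Pearson but not polychoric", {
  diffs <- vapply(1:10, function(rep) {
    codes <- rbvn_codes(2000, 0.6, c(-0.5, 0.3, 1.2), c(-1.2, 0, 0.8),
                        seed = 900 + rep)
    pe <- cor(codes[, 1], codes[, 2])
    tab <- table(factor(codes[, 1], 1:4), factor(codes[, 2], 1:4))
    polychoric_rho(tab)$rho - pe
  }, 0)
  expect_gt(mean(diffs), 0)
})

test_that("polychoric matrices are symmetric with unit diagonal", {
  cond <- simulation_condition(dist_normal(), 5, "large",
                               n_respondents = 500, seed = 77)
  ds <- generate_dataset(cond)
  ce <- polychoric_matrix(ds)
  expect_equal(ce$matrix, t(ce$matrix))
  expect_equal(unname(diag(ce$matrix)), rep(1, 5))
  expect_true(all(abs(ce$matrix) <= 1))
  expect_true(ce$converged)
})

test_that("correlation estimates round-trip through the CSV writer", {
  ce <- pearson_matrix(cbind(a = c(1, 2, 3, 4, 2), b = c(2, 1, 4, 3, 5),
                             c = c(5, 4, 3, 2, 1)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cor_estimate(ce, path, condition_id = "toy")
  back <- as.matrix(utils::read.csv(path))
  expect_equal(unname(back), unname(ce$matrix))
  side <- jsonlite::read_json(sub("\\.csv$", ".json", path))
  expect_equal(side$kind, "pearson")
  expect_equal(side$condition_id, "toy")
})
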