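test_that("item pool matches its published specification", {
  pool <- likert_pool()
  expect_equal(nrow(pool), 27)
  expect_equal(pool$item_id, 1:27)
  b <- as.matrix(pool[, c("b1", "b2", "b3", "b4")])
  expect_true(all(t(apply(b, 1, diff)) > 0))
  expect_equal(as.numeric(pool[pool$item_id == 1, -1]), c(13, 21, 29, 36))
  expect_equal(as.numeric(pool[pool$item_id == 26, -1]), c(19, 26, 53, 82))
  expect_error(validate_pool(data.frame(item_id = 1, b1 = 2, b2 = 1,
                                        b3 = 3, b4 = 4)))
})

test_that("true_score follows the boundary convention", {
  pool <- likert_pool()
  expect_equal(true_score(33, pool[1, ]), 4)   # worked example, item 1
  expect_equal(true_score(33, pool[12, ]), 1)  # worked example, item 12
  expect_equal(true_score(-100, pool[1, ]), 1)
  # category 5 begins exactly at the fourth boundary
  expect_equal(true_score(36, pool[1, ]), 5)
  expect_equal(true_score(13, pool[1, ]), 2)  # lower boundary included
  # monotone non-decreasing in position, every item
  grid <- seq(-10, 110, by = 0.5)
  for (j in seq_len(nrow(pool))) {
    expect_true(all(diff(true_score(grid, pool[j, ])) >= 0))
  }
})

test_that("perturb shifts by the discretised |z| and truncates", {
  lg <- error_model("large")
  sm <- error_model("small")
  expect_equal(perturb(3, 0.5, lg), 3)
  expect_equal(perturb(3, 1.5, lg), 4)
  expect_equal(perturb(3, -2.5, lg), 1)
  expect_equal(perturb(5, 2.5, lg), 5)   # truncation at the top
  expect_equal(perturb(1, -3.5, lg), 1)  # and at the bottom
  expect_equal(perturb(3, 1.1, sm), 3)   # small-error cutoff at 1.2
  expect_equal(perturb(3, 1.0, lg), 3)   # boundary |z| = c1 gives no shift
  # symmetry around the true category before clamping
  z <- seq(0.05, 4, by = 0.05)
  up <- perturb(rep(3, length(z)), z, lg)
  dn <- perturb(rep(3, length(z)), -z, lg)
  expect_equal(up - 3, 3 - dn)
})

test_that("error rates match the normal-tail probabilities", {
  set.seed(42)
  z <- rnorm(2e5)
  lg_shift <- perturb(rep(3L, length(z)), z, error_model("large")) != 3
  # category 3 can move freely both ways, so no truncation interferes
  expect_equal(mean(lg_shift), 2 * (1 - pnorm(1)), tolerance = 0.02)
  sm_shift <- perturb(rep(3L, length(z)), z, error_model("small")) != 3
  expect_equal(mean(sm_shift), 2 * (1 - pnorm(1.2)), tolerance = 0.02)
})

test_that("latent samples have the distribution-specific moments", {
  x <- sample_latent(dist_normal(), 1e5, seed = 1)
  expect_equal(mean(x), 50, tolerance = 0.01)
  expect_equal(sd(x), 20, tolerance = 0.02)

  u <- sample_latent(dist_uniform(), 1000, seed = 2)
  expect_true(all(u >= 0 & u <= 100))

  # closed-form skew-normal skewness with delta = 5 / sqrt(26)
  delta <- 5 / sqrt(26)
  g1 <- (4 - pi) / 2 * (delta * sqrt(2 / pi))^3 /
    (1 - 2 * delta^2 / pi)^1.5
  s <- sample_latent(dist_skew_normal(), 1e6, seed = 3)
  expect_equal(item_skewness(s), g1, tolerance = 0.02)

  b <- sample_latent(dist_bimodal(), 1e5, seed = 4)
  expect_equal(mean(b), 50, tolerance = 0.05)
  expect_equal(sd(b), sqrt(10^2 + 25^2), tolerance = 0.02)

  expect_error(sample_latent(structure(list(family = "cauchy"),
                                       class = "dist_spec"), 10))
})

test_that("datasets are well-formed, reproducible, and leave latents intact", {
  cond <- simulation_condition(dist_normal(), 8, "large",
                               n_respondents = 400, seed = 11)
  d1 <- generate_dataset(cond)
  expect_equal(dim(d1$responses), c(400, 8))
  expect_true(all(d1$responses %in% 1:5))
  expect_equal(anyDuplicated(d1$items$item_id), 0)
  d2 <- generate_dataset(cond)
  expect_identical(d1$responses, d2$responses)
  expect_identical(d1$items, d2$items)

  # regenerating responses from a fixed latent sample only changes responses
  pos <- sample_latent(dist_normal(), 300, seed = 5)
  before <- as.numeric(pos)
  invisible(generate_responses(pos, likert_pool()[1:4, ],
                               error_model("large")))
  expect_identical(as.numeric(pos), before)

  expect_error(generate_dataset(
    simulation_condition(dist_normal(), 30, "large", seed = 1)),
    "pool size")
})

test_that("grid construction is deterministic and correctly sized", {
  g <- build_grid(replicates = 1, master_seed = 7)
  expect_length(g, 24)  # 4 distributions x 3 sizes x 2 error levels
  g2 <- build_grid(replicates = 1, master_seed = 7)
  expect_identical(vapply(g, `[[`, 0L, "seed"), vapply(g2, `[[`, 0L, "seed"))
  g3 <- build_grid(replicates = 1, master_seed = 8)
  expect_false(identical(vapply(g, `[[`, 0L, "seed"),
                         vapply(g3, `[[`, 0L, "seed")))
  full <- build_grid(replicates = 100)
  expect_length(full, 2400)
})

test_that("item 7 marginals shift with the population distribution", {
  pool <- likert_pool()
  marg <- function(spec, seed) {
    pos <- sample_latent(spec, 2000, seed = seed)
    tabulate(generate_responses(pos, pool[7, , drop = FALSE],
                                error_model("large")), 5)
  }
  sn <- marg(dist_skew_normal(), 21)
  expect_equal(which.max(sn), 1)  # skewed population piles into category 1
  un <- marg(dist_uniform(), 22)
  # uniform population spreads responses: extreme categories dominate
  expect_gt(min(un[c(1, 5)]), max(un[2:4]) * 0.5)
  bi <- marg(dist_bimodal(), 23)
  expect_gt(min(bi[c(1, 5)]), max(bi[2:4]))  # bimodal empties the middle
})

test_that("test-retest reliability behaves like a reliability", {
  tr <- test_retest(spec = dist_normal(), error = "large",
                    n_respondents = 500, seed = 31)
  expect_equal(nrow(tr$items), 27)
  expect_true(all(tr$items$pearson > 0.3 & tr$items$pearson < 1,
                  na.rm = TRUE))
  expect_equal(tr$summary$pearson[4],
               tr$summary$pearson[3] - tr$summary$pearson[2])
  # polychoric disattenuates: item-wise at least as large on average
  expect_gt(mean(tr$items$polychoric - tr$items$pearson, na.rm = TRUE), 0)
})
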