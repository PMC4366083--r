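#' Discretised ordinal response-error model
#'
#' The error process perturbs the deterministic 'true' category of each
#' response by 0--3 categories, driven by a single standard-normal draw `z`
#' per respondent-item cell: no deviation for `|z| <= c1`, one category for
#' `c1 < |z| <= c2`, two for `c2 < |z| <= c3`, three beyond `c3`, always in
#' the direction of `sign(z)` and truncated to the 1..5 range. The `large`
#' level uses cutoffs (1, 2, 3), so roughly 2(1 - pnorm(1)) = 31.7% of
#' responses deviate before truncation; the `small` level uses
#' (1.2, 2.2, 3), roughly 23%.
#'
#' @param level `"large"` or `"small"`.
#' @param cutoffs Optional custom cutoffs: 3 ascending positive reals on |z|.
#' @return An object of class `error_model`.
#' @examples
#' perturb(3, 1.5, error_model("large"))   # 4
#' perturb(3, -2.5, error_model("large"))  # 1
#' @export
error_model <- function(level = c("large", "small"), cutoffs = NULL) {
  level <- match.arg(level)
  if (is.null(cutoffs)) {
    cutoffs <- if (level == "large") c(1, 2, 3) else c(1.2, 2.2, 3)
  }
  stopifnot(length(cutoffs) == 3, all(cutoffs > 0), all(diff(cutoffs) > 0))
  structure(list(level = level, cutoffs = cutoffs), class = "error_model")
}

#' @rdname error_model
#' @param true_category Integer vector of categories in 1..5.
#' @param z Standard-normal draws, same length as `true_category` (or
#'   recyclable).
#' @param error An `error_model`.
#' @export
perturb <- function(true_category, z, error = error_model("large")) {
  stopifnot(inherits(error, "error_model"),
            all(true_category %in% 1:5))
  shift <- findInterval(abs(z), error$cutoffs, left.open = TRUE)
  pmin(pmax(true_category + sign(z) * shift, 1), 5)
}

#' One cell of the simulation design grid
#'
#' Bundles everything needed to generate one simulated dataset: the latent
#' population distribution, the number of items to sample from the pool, the
#' error level, a replicate index and the seed that makes the dataset
#' reproducible.
#'
#' @param distribution A `dist_spec`.
#' @param n_items Number of items to draw from the pool (study grid: 5, 8, 10).
#' @param error An `error_model` or a level string.
#' @param replicate Replicate index within the cell.
#' @param n_respondents Sample size per dataset (study value: 2000).
#' @param seed Integer seed for this dataset.
#' @return An object of class `sim_condition`.
#' @export
simulation_condition <- function(distribution, n_items, error,
                                 replicate = 1L, n_respondents = 2000L,
                                 seed = 1L) {
  if (is.character(error)) error <- error_model(error)
  stopifnot(inherits(distribution, "dist_spec"),
            inherits(error, "error_model"),
            n_items >= 1, n_respondents >= 2)
  structure(list(distribution = distribution,
                 n_items = as.integer(n_items),
                 error = error,
                 replicate = as.integer(replicate),
                 n_respondents = as.integer(n_respondents),
                 seed = as.integer(seed)),
            class = "sim_condition")
}

#' @export
print.sim_condition <- function(x, ...) {
  cat(sprintf("<sim_condition> %s, %d items, %s error, rep %d, n=%d, seed=%d\n",
              x$distribution$family, x$n_items, x$error$level, x$replicate,
              x$n_respondents, x$seed))
  invisible(x)
}

#' Generate ordinal responses for fixed latent positions
#'
#' Applies the deterministic categorisation and the discretised error process
#' to an already-drawn latent sample, for a given set of items. The latent
#' positions are left untouched; only the responses carry error.
#'
#' @param positions Numeric vector of latent positions.
#' @param items Data frame of item definitions (rows of [likert_pool()]).
#' @param error An `error_model`.
#' @return Integer matrix `length(positions)` x `nrow(items)` with entries in
#'   1..5 and item ids as column names.
#' @export
generate_responses <- function(positions, items, error) {
  validate_pool(items)
  n <- length(positions)
  p <- nrow(items)
  resp <- matrix(0L, n, p, dimnames = list(NULL, paste0("it", items$item_id)))
  for (j in seq_len(p)) {
    ts <- true_score(positions, items[j, ])
    resp[, j] <- as.integer(perturb(ts, stats::rnorm(n), error))
  }
  resp
}

#' Simulate one dataset of unidimensional Likert responses
#'
#' Draws a fresh latent sample from the condition's population distribution,
#' samples `n_items` items from the pool without replacement, and generates
#' error-perturbed responses. Everything is driven by the condition seed, so
#' the same condition reproduces the same dataset bitwise.
#'
#' @param condition A `sim_condition`.
#' @param pool Item pool (default the 27-item study pool).
#' @return An object of class `likert_responses`: a list with `responses`
#'   (n x p integer matrix in 1..5), `items` (the sampled item definitions,
#'   in sampling order) and `condition`.
#' @export
generate_dataset <- function(condition, pool = likert_pool()) {
  stopifnot(inherits(condition, "sim_condition"))
  validate_pool(pool)
  if (condition$n_items > nrow(pool)) {
    stop("n_items exceeds the pool size (", nrow(pool), ")")
  }
  set.seed(condition$seed)
  idx <- sample.int(nrow(pool), condition$n_items)
  items <- pool[idx, , drop = FALSE]
  positions <- sample_latent(condition$distribution, condition$n_respondents)
  resp <- generate_responses(positions, items, condition$error)
  structure(list(responses = resp, items = items, condition = condition),
            class = "likert_responses")
}

#' @export
print.likert_responses <- function(x, ...) {
  cat(sprintf("<likert_responses> %d x %d (items %s)\n",
              nrow(x$responses), ncol(x$responses),
              paste(x$items$item_id, collapse = ",")))
  invisible(x)
}

#' Build the simulation design grid
#'
#' Expands distributions x item counts x error levels x replicates into a
#' list of reproducible conditions. Per-condition seeds are drawn once from
#' the master seed, so the grid (including every dataset it generates) is a
#' pure function of `master_seed`. The study default is 4 distributions x
#' {5, 8, 10} items x 2 error levels x 100 replicates = 2400 datasets.
#'
#' @param distributions Named list of `dist_spec`s.
#' @param n_items Integer vector of item-set sizes.
#' @param error_levels Character vector of error levels.
#' @param replicates Replicates per cell.
#' @param n_respondents Sample size per dataset.
#' @param master_seed Master seed from which all condition seeds derive.
#' @return List of `sim_condition` objects, ordered by distribution, item
#'   count, error level, replicate.
#' @examples
#' length(build_grid(replicates = 1))  # 24
#' @export
build_grid <- function(distributions = study_distributions(),
                       n_items = c(5L, 8L, 10L),
                       error_levels = c("large", "small"),
                       replicates = 100L,
                       n_respondents = 2000L,
                       master_seed = 20150319L) {
  stopifnot(length(distributions) >= 1, length(n_items) >= 1,
            length(error_levels) >= 1, replicates >= 1)
  cells <- expand.grid(replicate = seq_len(replicates),
                       error = error_levels,
                       items = n_items,
                       dist = names(distributions),
                       stringsAsFactors = FALSE)
  # fixed ordering: distribution slowest, replicate fastest
  cells <- cells[order(match(cells$dist, names(distributions)),
                       cells$items, cells$error, cells$replicate), ]
  set.seed(master_seed)
  seeds <- sample.int(.Machine$integer.max - 1L, nrow(cells))
  Map(function(d, it, e, r, s) {
    simulation_condition(distributions[[d]], it, e, replicate = r,
                         n_respondents = n_respondents, seed = s)
  }, cells$dist, cells$items, cells$error, cells$replicate, seeds)
}

#' Test-retest reliability of the item pool
#'
#' Generates, for a single latent sample, two independently error-perturbed
#' response sets to every item in the pool, and computes the per-item
#' test-retest correlation (Pearson and polychoric). This quantifies the
#' reliability induced by the error model: the latent positions are identical
#' in both sets, so any departure from 1 comes from the discretised error.
#'
#' @param pool Item pool.
#' @param spec Latent population distribution (`dist_spec`).
#' @param error An `error_model` or level string.
#' @param n_respondents Size of the single latent sample.
#' @param seed Seed for the latent sample and both error draws.
#' @return A list with `items` (data frame: `item_id`, `pearson`,
#'   `polychoric`; degenerate items are `NA`) and `summary` (data frame with
#'   rows mean, min, max, spread = max - min for each correlation type).
#' @export
test_retest <- function(pool = likert_pool(), spec = dist_normal(),
                        error = error_model("large"),
                        n_respondents = 2000L, seed = 1L) {
  if (is.character(error)) error <- error_model(error)
  set.seed(seed)
  positions <- sample_latent(spec, n_respondents)
  r1 <- generate_responses(positions, pool, error)
  r2 <- generate_responses(positions, pool, error)
  k <- nrow(pool)
  pe <- po <- rep(NA_real_, k)
  for (j in seq_len(k)) {
    x <- r1[, j]; y <- r2[, j]
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next  # degenerate
    pe[j] <- stats::cor(x, y)
    tab <- table(factor(x, 1:5), factor(y, 1:5))
    est <- polychoric_rho(tab)
    if (isTRUE(est$converged)) po[j] <- est$rho
  }
  items <- data.frame(item_id = pool$item_id, pearson = pe, polychoric = po)
  smry <- function(v) c(mean = mean(v, na.rm = TRUE),
                        min = min(v, na.rm = TRUE),
                        max = max(v, na.rm = TRUE),
                        spread = diff(range(v, na.rm = TRUE)))
  structure(list(items = items,
                 summary = data.frame(statistic = c("mean", "min", "max",
                                                    "spread"),
                                      pearson = unname(smry(pe)),
                                      polychoric = unname(smry(po))),
                 spec = spec, error = error, n = n_respondents, seed = seed),
            class = "test_retest")
}

#' @export
print.test_retest <- function(x, ...) {
  cat(sprintf("<test_retest> %s population, %s error, n=%d\n",
              x$spec$family, x$error$level, x$n))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write a simulated dataset to CSV with a JSON sidecar
#'
#' Writes the response matrix as plain CSV (one column per item, integer
#' codes 1--5) and, when `jsonlite` is available, a `.json` sidecar recording
#' the condition (distribution, items, error level, seed).
#'
#' @param dataset A `likert_responses`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_response_matrix <- function(dataset, path) {
  stopifnot(inherits(dataset, "likert_responses"))
  utils::write.csv(as.data.frame(dataset$responses), path, row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    cond <- dataset$condition
    side <- list(distribution = cond$distribution$family,
                 n_items = cond$n_items,
                 items = dataset$items$item_id,
                 error = cond$error$level,
                 replicate = cond$replicate,
                 n_respondents = cond$n_respondents,
                 seed = cond$seed)
    jsonlite::write_json(side, sub("\\.csv$", ".json", path),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}
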