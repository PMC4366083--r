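pa_subseed <- function(seed) {
  s <- bitwXor(as.integer(seed), 228158747L)
  if (s < 0L) s <- -s
  s
}

empty_branch <- function(prefix, p_max = 10L) {
  cols <- c(paste0("eig", seq_len(p_max)),
            "nf_k1", "nf_pa", "nf_af",
            "efa1_chi2", "efa1_df", "efa1_p", "efa1_rmsea",
            "efa1_rmsea_reject", "efa1_heywood",
            "efa2_chi2", "efa2_df", "delta_chi2", "delta_reject",
            "cfa_chi2", "cfa_df", "cfa_p", "cfa_gfi", "cfa_agfi",
            "cfa_rmsea", "cfa_reject_chi2", "cfa_reject_agfi",
            "cfa_reject_rmsea", "cfa_heywood", "cfa_converged", "ok")
  out <- as.list(rep(NA_real_, length(cols)))
  names(out) <- paste0(prefix, cols)
  out[[paste0(prefix, "ok")]] <- FALSE
  out
}

branch_record <- function(ce, n, rules, pa_cent, prefix, p_max = 10L) {
  rec <- empty_branch(prefix, p_max)
  g <- function(nm) paste0(prefix, nm)
  if (!isTRUE(ce$converged) ||
      (ce$kind == "polychoric" && !isTRUE(ce$positive_definite))) {
    return(rec)
  }
  p <- ncol(ce$matrix)
  eigs <- cor_eigenvalues(ce)
  for (j in seq_len(min(p, p_max))) rec[[g(paste0("eig", j))]] <- eigs[j]
  rec[[g("nf_k1")]] <- k1(eigs)
  rec[[g("nf_pa")]] <- pa_count(eigs, pa_cent)
  rec[[g("nf_af")]] <- acceleration_factor(eigs)
  if (!isTRUE(ce$positive_definite)) {
    rec[[g("ok")]] <- FALSE
    return(rec)
  }
  f1 <- efa_fit(ce$matrix, 1, n)
  f2 <- efa_fit(ce$matrix, 2, n)
  if (is.finite(f1$chi2)) {
    rec[[g("efa1_chi2")]] <- f1$chi2
    rec[[g("efa1_df")]] <- f1$df
    rec[[g("efa1_p")]] <- f1$p_value
    rec[[g("efa1_rmsea")]] <- f1$rmsea
    rec[[g("efa1_rmsea_reject")]] <- as.numeric(f1$rmsea > rules$rmsea_cutoff)
    rec[[g("efa1_heywood")]] <- as.numeric(f1$heywood)
  }
  if (is.finite(f1$chi2) && is.finite(f2$chi2)) {
    rec[[g("efa2_chi2")]] <- f2$chi2
    rec[[g("efa2_df")]] <- f2$df
    dt <- delta_chi2_test(f1, f2, rules$efa_delta_alpha)
    rec[[g("delta_chi2")]] <- dt$delta_chi2
    rec[[g("delta_reject")]] <- as.numeric(dt$reject_1factor)
  }
  cf <- cfa_1factor(ce$matrix, n, rules)
  rec[[g("cfa_converged")]] <- as.numeric(cf$converged)
  if (isTRUE(cf$converged)) {
    rec[[g("cfa_chi2")]] <- cf$chi2
    rec[[g("cfa_df")]] <- cf$df
    rec[[g("cfa_p")]] <- cf$p_value
    rec[[g("cfa_gfi")]] <- cf$gfi
    rec[[g("cfa_agfi")]] <- cf$agfi
    rec[[g("cfa_rmsea")]] <- cf$rmsea
    rec[[g("cfa_reject_chi2")]] <- as.numeric(cf$reject_chi2)
    rec[[g("cfa_reject_agfi")]] <- as.numeric(cf$reject_agfi)
    rec[[g("cfa_reject_rmsea")]] <- as.numeric(cf$reject_rmsea)
    rec[[g("cfa_heywood")]] <- as.numeric(cf$heywood)
  }
  rec[[g("ok")]] <- TRUE
  rec
}

#' Analyse one simulated dataset with the full criterion battery
#'
#' Runs both correlation branches (Pearson, polychoric) through the
#' eigenvalue-based retention criteria, the 1- and 2-factor minres EFA with
#' its fit statistics and difference test, and the 1-factor ML CFA, and
#' collects everything -- together with the item-set predictors -- into a
#' one-row harvest record. A failure in one branch (e.g. a non-positive
#' definite polychoric matrix) leaves that branch's fields missing and never
#' aborts: the other branch is still recorded.
#'
#' @param dataset A `likert_responses`.
#' @param rules A `decision_rules`.
#' @param pa_nrep,pa_centile Parallel-analysis settings.
#' @param pa_seed Seed for the parallel-analysis reference simulations
#'   (default: derived from the dataset's condition seed).
#' @return One-row data frame. Columns are prefixed `pe_` (Pearson branch)
#'   and `po_` (polychoric branch); `pe_ok`/`po_ok` flag whether the branch's
#'   fit analyses are usable.
#' @export
analyze_dataset <- function(dataset, rules = decision_rules(),
                            pa_nrep = 100, pa_centile = 95, pa_seed = NULL) {
  stopifnot(inherits(dataset, "likert_responses"))
  cond <- dataset$condition
  n <- cond$n_respondents
  if (is.null(pa_seed)) pa_seed <- pa_subseed(cond$seed)
  # one set of reference centiles per dataset, shared by both branches
  pa_cent <- pa_reference(n, cond$n_items, pa_nrep, pa_centile, pa_seed)
  pred <- dataset_predictors(dataset)
  pe <- pearson_matrix(dataset)
  po <- polychoric_matrix(dataset)
  meta <- list(distribution = cond$distribution$family,
               n_items = cond$n_items,
               error = cond$error$level,
               replicate = cond$replicate,
               n_respondents = n,
               seed = cond$seed,
               items = paste(dataset$items$item_id, collapse = ","),
               iqr_im = pred$iqr_interpolated_medians,
               skew_range = pred$skew_range)
  rec <- c(meta,
           branch_record(pe, n, rules, pa_cent, "pe_"),
           branch_record(po, n, rules, pa_cent, "po_"))
  as.data.frame(rec, stringsAsFactors = FALSE)
}

#' Run a simulation grid and harvest all results
#'
#' Generates and analyses every dataset of a condition grid, returning the
#' harvest: one row per dataset with every criterion verdict and fit
#' statistic for both correlation branches. Datasets are independent, so the
#' harvest is a pure function of the grid (and thereby of the master seed).
#'
#' @param conditions List of `sim_condition`s from [build_grid()].
#' @param pool Item pool.
#' @param rules Decision rules.
#' @param pa_nrep,pa_centile Parallel-analysis settings.
#' @param progress Print a progress line every `progress` datasets (0 = off).
#' @param out_dir Optional directory; when given, writes `harvest.csv` and a
#'   `manifest.json` (seeds and settings) there.
#' @return The harvest data frame.
#' @export
run_grid <- function(conditions, pool = likert_pool(),
                     rules = decision_rules(), pa_nrep = 100,
                     pa_centile = 95, progress = 0, out_dir = NULL) {
  stopifnot(length(conditions) >= 1)
  rows <- vector("list", length(conditions))
  for (i in seq_along(conditions)) {
    ds <- generate_dataset(conditions[[i]], pool)
    rows[[i]] <- analyze_dataset(ds, rules, pa_nrep, pa_centile)
    if (progress > 0 && i %% progress == 0) {
      message(sprintf("[likertdim] %d/%d datasets analysed",
                      i, length(conditions)))
    }
  }
  harvest <- do.call(rbind, rows)
  rownames(harvest) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(harvest, file.path(out_dir, "harvest.csv"),
                     row.names = FALSE)
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      manifest <- list(n_datasets = length(conditions),
                       seeds = vapply(conditions, `[[`, 0L, "seed"),
                       pa_nrep = pa_nrep, pa_centile = pa_centile,
                       rules = unclass(rules),
                       timestamp = format(Sys.time(), tz = "UTC"))
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE)
    }
  }
  harvest
}

overdim_indicator <- function(records, criterion, branch) {
  pre <- if (branch == "pearson") "pe_" else "po_"
  switch(criterion,
         k1 = records[[paste0(pre, "nf_k1")]] >= 2,
         pa = records[[paste0(pre, "nf_pa")]] >= 2,
         af = records[[paste0(pre, "nf_af")]] >= 2,
         efa_delta = records[[paste0(pre, "delta_reject")]] > 0,
         efa_rmsea = records[[paste0(pre, "efa1_rmsea_reject")]] > 0,
         cfa_chi2 = records[[paste0(pre, "cfa_reject_chi2")]] > 0,
         cfa_agfi = records[[paste0(pre, "cfa_reject_agfi")]] > 0,
         cfa_rmsea = records[[paste0(pre, "cfa_reject_rmsea")]] > 0,
         stop("unknown criterion: ", criterion))
}

#' Risk table: percentage of over-dimensionalised verdicts per cell
#'
#' Tabulates, for each population distribution x item count cell (pooled
#' over the two error levels), the percentage of datasets that a criterion
#' diagnoses as multi-factor: retained factors >= 2 for the retention
#' criteria (`k1`, `pa`, `af`), or rejection of the 1-factor model for the
#' fit criteria (`efa_delta`, `efa_rmsea`, `cfa_chi2`, `cfa_agfi`,
#' `cfa_rmsea`). Records whose branch is missing are excluded from that
#' cell's denominator; the denominators are attached as attribute
#' `denominators`.
#'
#' @param records Harvest data frame.
#' @param criteria Character vector of criterion names.
#' @param branches `"pearson"`, `"polychoric"` or both.
#' @return Data frame with `distribution`, `n_items` and one
#'   `<criterion>_<branch>` percentage column per combination; attribute
#'   `denominators` holds the same layout with cell denominators.
#' @export
risk_table <- function(records,
                       criteria = c("k1", "pa", "af"),
                       branches = c("pearson", "polychoric")) {
  stopifnot(nrow(records) >= 1)
  dists <- unique(records$distribution)
  sizes <- sort(unique(records$n_items))
  cells <- expand.grid(n_items = sizes, distribution = dists,
                       stringsAsFactors = FALSE)[, 2:1]
  out <- nn <- cells
  for (crit in criteria) {
    for (br in branches) {
      col <- paste0(crit, "_", br)
      ind <- overdim_indicator(records, crit, br)
      pct <- den <- numeric(nrow(cells))
      for (r in seq_len(nrow(cells))) {
        sel <- records$distribution == cells$distribution[r] &
          records$n_items == cells$n_items[r]
        v <- ind[sel]
        den[r] <- sum(!is.na(v))
        pct[r] <- if (den[r] > 0) 100 * mean(v, na.rm = TRUE) else NA_real_
      }
      out[[col]] <- pct
      nn[[col]] <- den
    }
  }
  attr(out, "denominators") <- nn
  out
}

#' Test-retest summary table across distributions
#'
#' Builds the reliability table of the item pool: mean, minimum, maximum and
#' spread of the 27 per-item test-retest correlations (Pearson and
#' polychoric), for each population distribution at a given error level.
#'
#' @param distributions Named list of `dist_spec`s.
#' @param error Error level (string or `error_model`).
#' @param pool Item pool.
#' @param n_respondents Latent sample size.
#' @param seed Master seed (one sub-seed per distribution).
#' @return Data frame with `statistic`, then `<distribution>_pearson` and
#'   `<distribution>_polychoric` columns.
#' @export
retest_table <- function(distributions = study_distributions(),
                         error = "large", pool = likert_pool(),
                         n_respondents = 2000L, seed = 1L) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, length(distributions))
  out <- data.frame(statistic = c("mean", "min", "max", "spread"))
  for (i in seq_along(distributions)) {
    tr <- test_retest(pool, distributions[[i]], error,
                      n_respondents = n_respondents, seed = seeds[i])
    nm <- names(distributions)[i]
    out[[paste0(nm, "_pearson")]] <- tr$summary$pearson
    out[[paste0(nm, "_polychoric")]] <- tr$summary$polychoric
  }
  out
}
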