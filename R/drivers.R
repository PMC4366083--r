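#' Interpolated median of a grouped ordinal distribution
#'
#' Grouped-data median with category `k` treated as the interval
#' `[k - 0.5, k + 0.5)`: `IM = m - 0.5 + (n/2 - F_(m-1)) / f_m`, where `m` is
#' the lowest category whose cumulative count reaches half the sample. Used
#' as the item-location ('popularity') measure.
#'
#' @param counts Vector of 5 category counts (total >= 1).
#' @return Scalar interpolated median.
#' @examples
#' interpolated_median(c(0, 0, 2000, 0, 0))     # 3
#' interpolated_median(c(500, 500, 500, 500, 0))  # 2.5
#' @export
interpolated_median <- function(counts) {
  n <- sum(counts)
  stopifnot(n >= 1, all(counts >= 0))
  cum <- cumsum(counts)
  m <- which(cum >= n / 2)[1]
  below <- if (m > 1) cum[m - 1] else 0
  m - 0.5 + (n / 2 - below) / counts[m]
}

#' Moment-based sample skewness
#'
#' `g1 = m3 / m2^(3/2)` on the response codes, without small-sample
#' correction (negligible at n = 2000).
#'
#' @param x Numeric vector (response codes 1..5).
#' @return Scalar skewness; `NA` for zero variance.
#' @export
item_skewness <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(NA_real_)
  mean((x - m)^3) / m2^1.5
}

#' Item-set predictors of model fit
#'
#' Per-dataset predictors used in the driver regressions: the spread of item
#' locations (inter-quartile range, linear-interpolation quantiles, of the p
#' interpolated medians) and the range (max - min) of the item skewnesses.
#' Both are invariant to respondent order. A degenerate (zero-variance) item
#' yields `NA` predictors with a flag.
#'
#' @param x A `likert_responses` or an n x p matrix of codes in 1..5.
#' @return List with `iqr_interpolated_medians`, `skew_range`,
#'   `interpolated_medians`, `skewnesses`, `degenerate`.
#' @export
dataset_predictors <- function(x) {
  m <- response_codes(x)
  ims <- apply(m, 2, function(col) interpolated_median(tabulate(col, 5)))
  sk <- apply(m, 2, item_skewness)
  degenerate <- anyNA(sk)
  list(iqr_interpolated_medians =
         if (degenerate) NA_real_ else
           unname(diff(stats::quantile(ims, c(0.25, 0.75), type = 7))),
       skew_range = if (degenerate) NA_real_ else diff(range(sk)),
       interpolated_medians = ims,
       skewnesses = sk,
       degenerate = degenerate)
}

driver_model_specs <- function() {
  data.frame(
    model_id = LETTERS[1:10],
    response = rep(c("efa_delta_chi2", "efa1_rmsea", "cfa_chi2", "cfa_agfi",
                     "cfa_rmsea"), each = 2),
    branch = rep(c("pearson", "polychoric"), 5),
    cube_root = rep(c(TRUE, FALSE, TRUE, FALSE, FALSE), each = 2),
    stringsAsFactors = FALSE)
}

harvest_driver_frame <- function(records, branch) {
  pre <- if (branch == "pearson") "pe_" else "po_"
  g <- function(col) records[[paste0(pre, col)]]
  data.frame(
    efa_delta_chi2 = g("efa1_chi2") - g("efa2_chi2"),
    efa1_rmsea = g("efa1_rmsea"),
    cfa_chi2 = g("cfa_chi2"),
    cfa_agfi = g("cfa_agfi"),
    cfa_rmsea = g("cfa_rmsea"),
    iqr = records$iqr_im,
    skew_range = records$skew_range,
    error_high = as.integer(records$error == "large"),
    distribution = factor(records$distribution,
                          levels = c("normal", "bimodal", "uniform",
                                     "skew_normal")),
    items = factor(records$n_items,
                   levels = sort(unique(records$n_items))))
}

#' OLS driver regressions of the fit statistics
#'
#' Fits the ten OLS models explaining (possibly cube-root-transformed) fit
#' statistics of the 1-factor models from the harvest: the EFA 1- vs
#' 2-factor chi-square difference (cube root; models A/B), the EFA 1-factor
#' RMSEA (C/D), the CFA chi-square (cube root; E/F), the CFA AGFI (G/H) and
#' the CFA RMSEA (I/J), alternating Pearson/polychoric branches. Predictors:
#' error-level dummy (1 = large), IQR of interpolated medians, range of item
#' skews, population-distribution dummies (reference: normal) and item-count
#' dummies (reference: smallest set). Records with a missing branch are
#' dropped listwise per model. The cube-root transform tames the
#' heteroskedasticity of chi-square-distributed outcomes.
#'
#' @param records Harvest data frame from [run_grid()].
#' @return List of class `driver_models`; each element has `model_id`,
#'   `response`, `branch`, `cube_root`, `coefficients` (matrix with
#'   estimates, standard errors, t and p), `adj_r_squared`, `n`, and the
#'   fitted `lm` object.
#' @export
fit_driver_models <- function(records) {
  stopifnot(nrow(records) >= 50)
  specs <- driver_model_specs()
  out <- vector("list", nrow(specs))
  names(out) <- specs$model_id
  for (i in seq_len(nrow(specs))) {
    sp <- specs[i, ]
    d <- harvest_driver_frame(records, sp$branch)
    y <- d[[sp$response]]
    if (sp$cube_root) y <- pmax(y, 0)^(1 / 3)
    d$y <- y
    d <- d[stats::complete.cases(d[c("y", "iqr", "skew_range")]), ]
    fit <- stats::lm(y ~ error_high + iqr + skew_range + distribution + items,
                     data = d)
    if (any(is.na(stats::coef(fit)))) {
      stop("rank-deficient design in model ", sp$model_id, ": collinear ",
           paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                 collapse = ", "))
    }
    sm <- summary(fit)
    out[[i]] <- structure(list(model_id = sp$model_id,
                               response = sp$response,
                               branch = sp$branch,
                               cube_root = sp$cube_root,
                               coefficients = sm$coefficients,
                               adj_r_squared = sm$adj.r.squared,
                               n = nrow(d),
                               fit = fit),
                          class = "driver_model")
  }
  structure(out, class = "driver_models")
}

#' @export
print.driver_model <- function(x, ...) {
  cat(sprintf("<driver_model %s> %s (%s)%s, n=%d, adj R^2=%.3f\n",
              x$model_id, x$response, x$branch,
              if (x$cube_root) ", cube-root dependent" else "", x$n,
              x$adj_r_squared))
  stats::printCoefmat(x$coefficients)
  invisible(x)
}

#' @export
print.driver_models <- function(x, ...) {
  for (m in x) {
    cat(sprintf("Model %s: %s (%s)%s  adj R^2 = %.3f  n = %d\n",
                m$model_id, m$response, m$branch,
                if (m$cube_root) " [cube root]" else "", m$adj_r_squared, m$n))
  }
  invisible(x)
}

#' Predict a fit statistic for a hypothetical item set
#'
#' Linear prediction from a fitted driver model for a scenario described by
#' the predictors; chi-square models are cubed back to the original scale.
#' Useful to gauge what a fit statistic would look like for *truly
#' unidimensional* items with given characteristics. A warning is issued
#' when the scenario leaves the predictor range seen during fitting.
#'
#' @param model A `driver_model` from [fit_driver_models()].
#' @param n_items Item count (one of the grid sizes).
#' @param distribution Population distribution family name.
#' @param iqr IQR of the interpolated medians.
#' @param skew_range Range of item skews.
#' @param error_high 1 for the large-error condition, 0 for small.
#' @return Predicted value of the model's dependent fit statistic.
#' @export
predict_fit <- function(model, n_items, distribution = "normal",
                        iqr = 1, skew_range = 1.8, error_high = 0) {
  stopifnot(inherits(model, "driver_model"))
  mf <- model$fit$model
  if (iqr < min(mf$iqr) || iqr > max(mf$iqr) ||
      skew_range < min(mf$skew_range) || skew_range > max(mf$skew_range)) {
    warning("scenario outside the fitted predictor range; extrapolating")
  }
  nd <- data.frame(error_high = error_high, iqr = iqr,
                   skew_range = skew_range,
                   distribution = factor(distribution,
                                         levels = levels(mf$distribution)),
                   items = factor(n_items, levels = levels(mf$items)))
  pred <- as.numeric(stats::predict(model$fit, newdata = nd))
  if (model$cube_root) pred^3 else pred
}

#' Table of driver-regression coefficients
#'
#' Arranges the ten fitted models into a coefficients-by-models table
#' (one column per model, plus an adjusted R-squared row).
#'
#' @param models A `driver_models` object.
#' @return Data frame: rows are predictors plus `adj_r_squared`, columns the
#'   model ids.
#' @export
driver_table <- function(models) {
  stopifnot(inherits(models, "driver_models"))
  terms <- rownames(models[[1]]$coefficients)
  out <- data.frame(term = c(terms, "adj_r_squared"))
  for (m in models) {
    out[[m$model_id]] <- c(m$coefficients[terms, "Estimate"],
                           m$adj_r_squared)
  }
  out
}
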