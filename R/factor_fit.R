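#' Decision rules for rejecting a 1-factor model
#'
#' The study's accept/reject thresholds: the EFA 1- vs 2-factor chi-square
#' difference test at alpha 1e-5 (guarding against the overpowering effect of
#' n = 2000), the CFA chi-square at alpha 0.001, RMSEA above 0.10 ('poor
#' fit'), and AGFI below 0.90.
#'
#' @param efa_delta_alpha Alpha for the EFA difference test.
#' @param cfa_chi2_alpha Alpha for the CFA chi-square test.
#' @param rmsea_cutoff RMSEA rejection cutoff.
#' @param agfi_cutoff AGFI rejection cutoff.
#' @return A list of class `decision_rules`.
#' @export
decision_rules <- function(efa_delta_alpha = 1e-5, cfa_chi2_alpha = 1e-3,
                           rmsea_cutoff = 0.10, agfi_cutoff = 0.90) {
  stopifnot(efa_delta_alpha > 0, efa_delta_alpha < 1,
            cfa_chi2_alpha > 0, cfa_chi2_alpha < 1,
            rmsea_cutoff > 0, agfi_cutoff > 0, agfi_cutoff < 1)
  structure(list(efa_delta_alpha = efa_delta_alpha,
                 cfa_chi2_alpha = cfa_chi2_alpha,
                 rmsea_cutoff = rmsea_cutoff,
                 agfi_cutoff = agfi_cutoff),
            class = "decision_rules")
}

# PORT reports benign stopping states ("singular convergence") as code 1;
# treat any convergence-type message as converged, limits as failure.
nlminb_converged <- function(fit) {
  fit$convergence == 0 || grepl("convergence", fit$message, fixed = FALSE)
}

# sign convention: each factor's loading sum nonnegative
orient_loadings <- function(L) {
  flip <- colSums(L) < 0
  L[, flip] <- -L[, flip, drop = FALSE]
  L
}

smc_start <- function(C) {
  p <- ncol(C)
  inv <- tryCatch(solve(C), error = function(e) NULL)
  if (is.null(inv)) return(rep(0.5, p))
  pmin(pmax(1 - 1 / diag(inv), 0.05), 0.95)
}

#' Minimum-residual (minres) exploratory factor analysis
#'
#' Extracts `k` factors by minimising the sum of squared off-diagonal
#' residuals of `C - Lambda Lambda'`. The loadings for given uniquenesses are
#' the scaled leading eigenvectors of the reduced matrix `C - diag(psi)`;
#' the uniquenesses are optimised over `[lower, 1]`. A uniqueness at its
#' lower bound marks a Heywood case (communality at 1); the case is flagged
#' but retained.
#'
#' @param C Correlation matrix or `cor_estimate`.
#' @param k Number of factors (study models use 1 or 2).
#' @param lower Lower bound for uniquenesses.
#' @return A `factor_model`: list with `loadings` (p x k), `uniquenesses`,
#'   `implied` (model matrix `Lambda Lambda' + Psi`), `k`,
#'   `method = "minres"`, `objective` (residual sum of squares), `converged`,
#'   `heywood`.
#' @examples
#' C <- matrix(0.49, 5, 5); diag(C) <- 1
#' fm <- minres_efa(C, 1)
#' round(fm$loadings, 3)  # all 0.7
#' @export
minres_efa <- function(C, k, lower = 1e-4) {
  C <- cor_mat(C)
  p <- ncol(C)
  df <- ((p - k)^2 - (p + k)) / 2
  if (df < 0) stop("model has negative degrees of freedom")
  off <- upper.tri(C)
  loadings_for <- function(psi) {
    e <- eigen(C - diag(psi, p), symmetric = TRUE)
    ev <- pmax(e$values[seq_len(k)], 0)
    e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(ev), k)
  }
  obj <- function(psi) {
    L <- loadings_for(psi)
    sum((C - tcrossprod(L))[off]^2)
  }
  fit <- stats::nlminb(1 - smc_start(C), obj,
                       lower = lower, upper = 1,
                       control = list(iter.max = 1000, eval.max = 2000))
  psi <- fit$par
  L <- orient_loadings(loadings_for(psi))
  structure(list(loadings = L,
                 uniquenesses = psi,
                 implied = tcrossprod(L) + diag(psi, p),
                 k = k, method = "minres",
                 objective = fit$objective,
                 converged = nlminb_converged(fit),
                 heywood = any(psi <= lower * 1.01)),
            class = "factor_model")
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf("<factor_model> %s, k=%d, converged=%s, heywood=%s\n",
              x$method, x$k, x$converged, x$heywood))
  invisible(x)
}

#' Maximum-likelihood discrepancy between two covariance matrices
#'
#' The ML fit function `F = log|Sigma| - log|S| + tr(S Sigma^-1) - p`,
#' nonnegative and zero iff `S = Sigma`.
#'
#' @param S Observed correlation/covariance matrix.
#' @param Sigma Model-implied matrix (must be invertible).
#' @return Scalar discrepancy.
#' @export
ml_discrepancy <- function(S, Sigma) {
  S <- cor_mat(S)
  p <- ncol(S)
  ld_sigma <- determinant(Sigma, logarithm = TRUE)
  ld_s <- determinant(S, logarithm = TRUE)
  if (ld_sigma$sign <= 0) stop("implied matrix is not positive definite")
  inv <- solve(Sigma)
  as.numeric(ld_sigma$modulus - ld_s$modulus + sum(S * inv) - p)
}

#' Bartlett-corrected chi-square for an EFA model
#'
#' Converts an ML discrepancy into the large-sample chi-square with
#' Bartlett's correction factor `n - 1 - (2p + 5)/6 - 2k/3`, with
#' `df = ((p - k)^2 - (p + k)) / 2`.
#'
#' @param F ML discrepancy at the fitted model.
#' @param n Sample size.
#' @param p Number of items.
#' @param k Number of factors.
#' @return List with `chi2`, `df`, `p_value`.
#' @export
efa_chi2 <- function(F, n, p, k) {
  df <- ((p - k)^2 - (p + k)) / 2
  if (df < 0) stop("negative degrees of freedom")
  chi2 <- max((n - 1 - (2 * p + 5) / 6 - 2 * k / 3) * F, 0)
  list(chi2 = chi2, df = df,
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Chi-square difference test between nested factor models
#'
#' Tests whether the 2-factor model fits significantly better than the
#' 1-factor model: `delta = chi2_1 - chi2_2` (clamped at zero) referred to
#' `chi2(df1 - df2)`. Rejecting means the 1-factor model is abandoned --
#' over-dimensionalisation when the data are truly unidimensional.
#'
#' @param fit1,fit2 Fit lists with `chi2` and `df` (1- and 2-factor models).
#' @param alpha Test level (study value 1e-5).
#' @return List with `delta_chi2`, `delta_df`, `p_value`,
#'   `reject_1factor`.
#' @export
delta_chi2_test <- function(fit1, fit2, alpha = 1e-5) {
  ddf <- fit1$df - fit2$df
  if (ddf <= 0) stop("models are not nested in the expected order")
  delta <- max(fit1$chi2 - fit2$chi2, 0)
  pv <- stats::pchisq(delta, ddf, lower.tail = FALSE)
  list(delta_chi2 = delta, delta_df = ddf, p_value = pv,
       reject_1factor = pv < alpha)
}

#' Root mean square error of approximation
#'
#' `sqrt(max(chi2 - df, 0) / (df (n - 1)))`: approximation error per degree
#' of freedom, zero whenever the chi-square does not exceed its expectation.
#'
#' @param chi2 Chi-square statistic.
#' @param df Degrees of freedom (>= 1).
#' @param n Sample size.
#' @return Scalar RMSEA.
#' @export
rmsea <- function(chi2, df, n) {
  if (df < 1) stop("RMSEA undefined for df < 1")
  sqrt(max(chi2 - df, 0) / (df * (n - 1)))
}

#' GFI and AGFI of a fitted covariance-structure model
#'
#' `GFI = 1 - tr[(Sigma^-1 S - I)^2] / tr[(Sigma^-1 S)^2]`, and AGFI adjusts
#' for the model's parameter count:
#' `AGFI = 1 - [p(p + 1) / (2 df)] (1 - GFI)`.
#'
#' @param S Observed matrix.
#' @param Sigma Implied matrix.
#' @param df Model degrees of freedom.
#' @param p Number of items.
#' @return List with `gfi`, `agfi` (`agfi` is `NA` when `df = 0`).
#' @export
gfi_agfi <- function(S, Sigma, df, p) {
  S <- cor_mat(S)
  A <- solve(Sigma, S)
  M <- A - diag(p)
  gfi <- 1 - sum(M * t(M)) / sum(A * t(A))
  agfi <- if (df > 0) 1 - (p * (p + 1) / (2 * df)) * (1 - gfi) else NA_real_
  list(gfi = gfi, agfi = agfi)
}

#' Fit statistics for a minres EFA model
#'
#' Fits a `k`-factor minres model and evaluates the ML discrepancy at the
#' minres solution, converted to a Bartlett-corrected chi-square, p-value and
#' RMSEA. Mirrors the common EFA-software behaviour of reporting ML-based
#' fit statistics for an OLS extraction. Optionally the model can be refit by
#' direct minimisation of the ML discrepancy before computing statistics.
#'
#' @inheritParams minres_efa
#' @param n Sample size behind `C`.
#' @param refit_ml If `TRUE`, re-minimise the ML discrepancy starting from
#'   the minres solution.
#' @return List with `model` (`factor_model`), `F`, `chi2`, `df`, `p_value`,
#'   `rmsea`, `converged`, `heywood`.
#' @export
efa_fit <- function(C, k, n, refit_ml = FALSE) {
  C <- cor_mat(C)
  model <- minres_efa(C, k)
  if (refit_ml) model <- refit_ml_efa(C, model)
  ok <- model$converged
  F <- tryCatch(ml_discrepancy(C, model$implied), error = function(e) NA_real_)
  if (!is.finite(F)) {
    return(list(model = model, F = NA_real_, chi2 = NA_real_, df = NA_real_,
                p_value = NA_real_, rmsea = NA_real_, converged = FALSE,
                heywood = model$heywood))
  }
  ch <- efa_chi2(F, n, ncol(C), k)
  list(model = model, F = F, chi2 = ch$chi2, df = ch$df,
       p_value = ch$p_value, rmsea = rmsea(ch$chi2, ch$df, n),
       converged = ok, heywood = model$heywood)
}

refit_ml_efa <- function(C, model) {
  p <- nrow(C)
  k <- model$k
  par0 <- c(model$loadings, pmin(pmax(model$uniquenesses, 1e-4), 1))
  obj <- function(par) {
    L <- matrix(par[seq_len(p * k)], p, k)
    psi <- par[p * k + seq_len(p)]
    tryCatch(ml_discrepancy(C, tcrossprod(L) + diag(psi, p)),
             error = function(e) 1e6)
  }
  fit <- stats::nlminb(par0, obj,
                       lower = c(rep(-2, p * k), rep(1e-4, p)),
                       upper = c(rep(2, p * k), rep(2, p)),
                       control = list(iter.max = 2000, eval.max = 10000))
  L <- orient_loadings(matrix(fit$par[seq_len(p * k)], p, k))
  psi <- fit$par[p * k + seq_len(p)]
  structure(list(loadings = L, uniquenesses = psi,
                 implied = tcrossprod(L) + diag(psi, p), k = k,
                 method = "ml", objective = fit$objective,
                 converged = nlminb_converged(fit),
                 heywood = any(psi <= 1e-4 * 1.01)),
            class = "factor_model")
}

#' One-factor maximum-likelihood confirmatory factor analysis
#'
#' Fits the congeneric 1-factor model `Sigma = lambda lambda' + Psi` with the
#' latent variance fixed at 1 (p free loadings, p free uniquenesses) by
#' minimising the ML discrepancy, treating the correlation matrix as the
#' analysed covariance matrix. The chi-square is `(n - 1) F` on
#' `df = p(p + 1)/2 - 2p`; GFI/AGFI and RMSEA are computed from the fitted
#' solution, and each rejection rule of [decision_rules()] is recorded
#' separately.
#'
#' @param C Correlation matrix or `cor_estimate` (must be positive definite).
#' @param n Sample size.
#' @param rules A `decision_rules` object.
#' @return List with `model` (`factor_model`), `F`, `chi2`, `df`, `p_value`,
#'   `gfi`, `agfi`, `rmsea`, `converged`, `heywood`, and logical
#'   `reject_chi2`, `reject_agfi`, `reject_rmsea`.
#' @export
cfa_1factor <- function(C, n, rules = decision_rules()) {
  C <- cor_mat(C)
  p <- ncol(C)
  df <- p * (p + 1) / 2 - 2 * p
  start <- minres_efa(C, 1)
  par0 <- c(start$loadings, pmin(pmax(start$uniquenesses, 1e-4), 1))
  obj <- function(par) {
    lam <- par[seq_len(p)]
    psi <- par[p + seq_len(p)]
    tryCatch(ml_discrepancy(C, tcrossprod(lam) + diag(psi, p)),
             error = function(e) 1e6)
  }
  fit <- stats::nlminb(par0, obj,
                       lower = c(rep(-2, p), rep(1e-4, p)),
                       upper = c(rep(2, p), rep(2, p)),
                       control = list(iter.max = 2000, eval.max = 10000))
  lam <- fit$par[seq_len(p)]
  if (sum(lam) < 0) lam <- -lam
  psi <- fit$par[p + seq_len(p)]
  implied <- tcrossprod(lam) + diag(psi, p)
  model <- structure(list(loadings = matrix(lam, p, 1), uniquenesses = psi,
                          implied = implied, k = 1L, method = "ml",
                          objective = fit$objective,
                          converged = nlminb_converged(fit),
                          heywood = any(psi <= 1e-4 * 1.01)),
                     class = "factor_model")
  F <- fit$objective
  converged <- model$converged && F < 1e6
  if (!converged) {
    return(list(model = model, F = NA_real_, chi2 = NA_real_, df = df,
                p_value = NA_real_, gfi = NA_real_, agfi = NA_real_,
                rmsea = NA_real_, converged = FALSE, heywood = model$heywood,
                reject_chi2 = NA, reject_agfi = NA, reject_rmsea = NA))
  }
  chi2 <- (n - 1) * F
  pv <- stats::pchisq(chi2, df, lower.tail = FALSE)
  ga <- gfi_agfi(C, implied, df, p)
  rm <- rmsea(chi2, df, n)
  list(model = model, F = F, chi2 = chi2, df = df, p_value = pv,
       gfi = ga$gfi, agfi = ga$agfi, rmsea = rm,
       converged = TRUE, heywood = model$heywood,
       reject_chi2 = pv < rules$cfa_chi2_alpha,
       reject_agfi = ga$agfi < rules$agfi_cutoff,
       reject_rmsea = rm > rules$rmsea_cutoff)
}
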