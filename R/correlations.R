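#' Pearson correlation matrix of a response matrix
#'
#' Product-moment correlations computed directly on the integer response
#' codes, as done when analysts treat Likert codes as interval-level scores.
#'
#' @param x A `likert_responses` object or an n x p integer matrix.
#' @param pd_tol Smallest eigenvalue above which the matrix is considered
#'   positive definite.
#' @return A `cor_estimate`: list with `matrix`, `kind = "pearson"`,
#'   `converged`, `positive_definite` and `pairwise_flags` (character notes
#'   for degenerate pairs, empty when clean).
#' @export
pearson_matrix <- function(x, pd_tol = 1e-8) {
  m <- response_codes(x)
  flags <- character(0)
  v <- apply(m, 2, stats::var)
  if (any(v == 0)) {
    flags <- paste0("zero variance: ", colnames(m)[v == 0])
  }
  cm <- suppressWarnings(stats::cor(m))
  ok <- all(is.finite(cm))
  pd <- ok && min(eigen(cm, symmetric = TRUE, only.values = TRUE)$values) > pd_tol
  new_cor_estimate(cm, "pearson", converged = ok, positive_definite = pd,
                   pairwise_flags = flags)
}

new_cor_estimate <- function(matrix, kind, converged, positive_definite,
                             pairwise_flags = character(0)) {
  structure(list(matrix = matrix, kind = kind, converged = converged,
                 positive_definite = positive_definite,
                 pairwise_flags = pairwise_flags),
            class = "cor_estimate")
}

#' @export
print.cor_estimate <- function(x, ...) {
  cat(sprintf("<cor_estimate> %s, %dx%d, converged=%s, PD=%s\n", x$kind,
              nrow(x$matrix), ncol(x$matrix), x$converged,
              x$positive_definite))
  invisible(x)
}

response_codes <- function(x) {
  if (inherits(x, "likert_responses")) x$responses else as.matrix(x)
}

#' Normal-scale thresholds from category counts
#'
#' First step of the two-step polychoric estimator: thresholds are the
#' standard-normal quantiles of the cumulative category proportions. A
#' boundary with no probability mass on one of its sides (an empty leading,
#' trailing or internal category) is collapsed away, so fewer than 4
#' thresholds may be returned.
#'
#' @param counts Vector of 5 category counts.
#' @return Numeric vector of strictly increasing finite thresholds (possibly
#'   empty), with attribute `degenerate = TRUE` when all mass is in one
#'   category.
#' @examples
#' estimate_thresholds(c(400, 400, 400, 400, 400))  # qnorm(c(.2,.4,.6,.8))
#' @export
estimate_thresholds <- function(counts) {
  stopifnot(length(counts) >= 2, sum(counts) >= 1, all(counts >= 0))
  cum <- cumsum(counts)[-length(counts)] / sum(counts)
  cum <- unique(cum[cum > 0 & cum < 1])
  tau <- stats::qnorm(cum)
  attr(tau, "degenerate") <- length(tau) == 0
  tau
}

#' Polychoric correlation of one contingency table
#'
#' Two-step maximum-likelihood estimate of the correlation of two latent
#' standard-normal variables observed through ordered categories. Thresholds
#' are fixed at their margin-based estimates; the correlation maximises the
#' bivariate-normal log-likelihood \eqn{\sum n_{ij} \log \pi_{ij}(\rho)} over
#' (-0.999, 0.999) by Brent search (tolerance 1e-6). Rectangle probabilities
#' come from the package's bivariate-normal CDF and are floored at 1e-12
#' before taking logs; no continuity correction is applied to zero cells.
#'
#' @param tab Contingency table of counts (rows: variable a, cols: variable
#'   b). Empty rows/columns are dropped (their thresholds are collapsed).
#' @param thresholds_a,thresholds_b Optional fixed thresholds; by default
#'   estimated from the table margins.
#' @return List with `rho`, `converged` (FALSE for degenerate margins) and
#'   `thresholds` (list of the two threshold sets).
#' @export
polychoric_rho <- function(tab, thresholds_a = NULL, thresholds_b = NULL) {
  tab <- as.matrix(tab)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    return(list(rho = NA_real_, converged = FALSE,
                thresholds = list(a = numeric(0), b = numeric(0))))
  }
  if (is.null(thresholds_a)) thresholds_a <- estimate_thresholds(rowSums(tab))
  if (is.null(thresholds_b)) thresholds_b <- estimate_thresholds(colSums(tab))
  ga <- c(-Inf, thresholds_a, Inf)
  gb <- c(-Inf, thresholds_b, Inf)
  na <- length(ga)
  nb <- length(gb)
  xg <- rep(ga, times = nb)
  yg <- rep(gb, each = na)
  negll <- function(rho) {
    cdf <- matrix(pbvnorm(xg, yg, rho), na, nb)
    pr <- cdf[-1, -1, drop = FALSE] - cdf[-na, -1, drop = FALSE] -
      cdf[-1, -nb, drop = FALSE] + cdf[-na, -nb, drop = FALSE]
    -sum(tab * log(pmax(pr, 1e-12)))
  }
  opt <- stats::optimize(negll, interval = c(-0.999, 0.999), tol = 1e-6)
  list(rho = opt$minimum, converged = is.finite(opt$objective),
       thresholds = list(a = thresholds_a, b = thresholds_b))
}

#' Polychoric correlation matrix of a response matrix
#'
#' Assembles pairwise two-step polychoric estimates into a p x p matrix.
#' Item thresholds are estimated once from each item's margin. Following the
#' study protocol, a matrix with any degenerate/non-convergent pair, or that
#' is not positive definite, is flagged and treated as missing downstream --
#' no smoothing or bending is applied.
#'
#' @inheritParams pearson_matrix
#' @param n_categories Number of response categories (5 for Likert items).
#' @return A `cor_estimate` with `kind = "polychoric"`.
#' @export
polychoric_matrix <- function(x, pd_tol = 1e-8, n_categories = 5L) {
  m <- response_codes(x)
  p <- ncol(m)
  flags <- character(0)
  taus <- lapply(seq_len(p), function(j) {
    estimate_thresholds(tabulate(m[, j], nbins = n_categories))
  })
  cm <- diag(p)
  dimnames(cm) <- list(colnames(m), colnames(m))
  ok <- TRUE
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      tab <- table(factor(m[, i], 1:n_categories),
                   factor(m[, j], 1:n_categories))
      est <- polychoric_rho(tab, taus[[i]], taus[[j]])
      if (!isTRUE(est$converged)) {
        ok <- FALSE
        flags <- c(flags, sprintf("pair (%s,%s) degenerate or non-convergent",
                                  colnames(m)[i], colnames(m)[j]))
        cm[i, j] <- cm[j, i] <- NA_real_
      } else {
        cm[i, j] <- cm[j, i] <- est$rho
      }
    }
  }
  pd <- ok && min(eigen(cm, symmetric = TRUE, only.values = TRUE)$values) > pd_tol
  new_cor_estimate(cm, "polychoric", converged = ok, positive_definite = pd,
                   pairwise_flags = flags)
}

#' Write a correlation estimate to CSV with a JSON sidecar
#'
#' Exports the correlation matrix as plain CSV and (when `jsonlite` is
#' available) a sidecar recording the kind, the convergence and
#' positive-definiteness flags, pairwise notes and an optional condition id.
#'
#' @param estimate A `cor_estimate`.
#' @param path Output CSV path.
#' @param condition_id Optional identifier copied into the sidecar.
#' @return `path`, invisibly.
#' @export
write_cor_estimate <- function(estimate, path, condition_id = NULL) {
  stopifnot(inherits(estimate, "cor_estimate"))
  utils::write.csv(as.data.frame(estimate$matrix), path, row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    side <- list(kind = estimate$kind,
                 converged = estimate$converged,
                 positive_definite = estimate$positive_definite,
                 pairwise_flags = estimate$pairwise_flags,
                 condition_id = condition_id)
    jsonlite::write_json(side, sub("\\.csv$", ".json", path),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
  }
  invisible(path)
}
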