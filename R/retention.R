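#' Eigenvalues of a correlation matrix
#'
#' Descending eigenvalues of the unreduced (full-diagonal) correlation
#' matrix, the quantity on which the K1 rule, parallel analysis and the
#' acceleration factor all operate. Their sum equals the number of items.
#'
#' @param C Symmetric correlation matrix (or a `cor_estimate`).
#' @param tol Symmetry tolerance.
#' @return Numeric vector of eigenvalues, descending.
#' @export
cor_eigenvalues <- function(C, tol = 1e-8) {
  C <- cor_mat(C)
  if (!isSymmetric(unname(C), tol = tol)) stop("matrix is not symmetric")
  eigen(C, symmetric = TRUE, only.values = TRUE)$values
}

cor_mat <- function(C) {
  if (inherits(C, "cor_estimate")) C$matrix else as.matrix(C)
}

#' K1 (Kaiser) factor-retention rule
#'
#' Retains factors whose eigenvalues exceed a threshold. The classic rule
#' uses 1 (the average eigenvalue of a correlation matrix); 0.7 (Jolliffe)
#' and 1.4 (Raiche) are sometimes discussed. Ties at the threshold are not
#' retained (strict `>`), which is indistinguishable from `>=` for
#' continuous data.
#'
#' @param eigs Descending eigenvalue vector.
#' @param threshold Retention threshold (default 1).
#' @return Integer count of retained factors.
#' @examples
#' k1(c(2.5, 1.2, 0.8, 0.3, 0.2))       # 2
#' k1(c(2.5, 1.2, 0.8, 0.3, 0.2), 0.7)  # 3
#' @export
k1 <- function(eigs, threshold = 1) {
  sum(eigs > threshold)
}

#' Parallel analysis at a given centile
#'
#' Compares the observed eigenvalues, rank by rank, with the chosen centile
#' of eigenvalues from `nrep` random datasets of the same size. By default
#' the reference data are continuous standard-normal draws and the reference
#' eigenvalues come from their Pearson correlation matrix; this single
#' reference is conventionally used for both Pearson and polychoric observed
#' eigenvalues. Optionally, ordinal reference data with given category
#' margins can be used instead. Retention stops at the first rank whose
#' observed eigenvalue does not exceed its reference centile.
#'
#' @param eigs Observed descending eigenvalues.
#' @param n,p Sample size and item count of the analysed dataset.
#' @param nrep Number of random reference datasets (default 100).
#' @param centile Reference centile (default 95, the stringent variant).
#' @param seed Optional seed for the reference simulations.
#' @param margins Optional list of `p` category-probability vectors; when
#'   supplied, reference data are ordinal draws with those margins (Pearson
#'   eigenvalues are still used).
#' @return List with `n_factors` and `centiles` (reference centile per rank).
#' @export
parallel_analysis <- function(eigs, n, p, nrep = 100, centile = 95,
                              seed = NULL, margins = NULL) {
  stopifnot(length(eigs) == p, n >= 2, p >= 2)
  if (nrep < 20) warning("nrep < 20 gives unstable reference centiles")
  cent <- pa_reference(n, p, nrep, centile, seed, margins)
  list(n_factors = pa_count(eigs, cent), centiles = cent)
}

# reference eigenvalue centiles from nrep random datasets
pa_reference <- function(n, p, nrep, centile, seed = NULL, margins = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ref <- matrix(0, nrep, p)
  for (r in seq_len(nrep)) {
    x <- if (is.null(margins)) {
      matrix(stats::rnorm(n * p), n, p)
    } else {
      vapply(margins, function(pr) {
        findInterval(stats::runif(n), cumsum(pr), left.open = TRUE) + 1L
      }, integer(n))
    }
    ref[r, ] <- eigen(suppressWarnings(stats::cor(x)), symmetric = TRUE,
                      only.values = TRUE)$values
  }
  unname(apply(ref, 2, stats::quantile, probs = centile / 100, type = 7))
}

# leading observed eigenvalues above their rank's centile, stopping at the
# first failure
pa_count <- function(eigs, cent) {
  m <- 0L
  for (j in seq_along(eigs)) {
    if (eigs[j] > cent[j]) m <- m + 1L else break
  }
  m
}

#' Acceleration-factor (non-graphical scree) rule
#'
#' Locates the scree elbow at the largest second difference of the
#' eigenvalue sequence: `af_i = e[i+1] - 2 e[i] + e[i-1]` for interior ranks
#' `i = 2..p-1`, retaining `i - 1` factors where `af` is largest (first
#' maximum on ties), floored at one factor.
#'
#' @param eigs Descending eigenvalue vector, length >= 3.
#' @return Integer count of retained factors (between 1 and p - 2).
#' @examples
#' acceleration_factor(c(3, 1, 0.9, 0.8, 0.3))    # 1
#' acceleration_factor(c(4, 2.5, 0.5, 0.4, 0.3))  # 2
#' @export
acceleration_factor <- function(eigs) {
  p <- length(eigs)
  if (p < 3) stop("acceleration factor needs at least 3 eigenvalues")
  i <- 2:(p - 1)
  af <- eigs[i + 1] - 2 * eigs[i] + eigs[i - 1]
  max(1L, which.max(af))
}

#' All eigenvalue-based retention criteria for one correlation matrix
#'
#' Convenience wrapper applying K1, parallel analysis and the acceleration
#' factor to one correlation matrix.
#'
#' @param C Correlation matrix or `cor_estimate`.
#' @param n Sample size behind `C`.
#' @param k1_threshold K1 threshold.
#' @inheritParams parallel_analysis
#' @return List with `eigenvalues`, `n_factors_k1`, `n_factors_pa`,
#'   `n_factors_af`, `pa_centiles`.
#' @export
retention_criteria <- function(C, n, nrep = 100, centile = 95, seed = NULL,
                               k1_threshold = 1) {
  eigs <- cor_eigenvalues(C)
  pa <- parallel_analysis(eigs, n = n, p = length(eigs), nrep = nrep,
                          centile = centile, seed = seed)
  list(eigenvalues = eigs,
       n_factors_k1 = k1(eigs, k1_threshold),
       n_factors_pa = pa$n_factors,
       n_factors_af = acceleration_factor(eigs),
       pa_centiles = pa$centiles)
}
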