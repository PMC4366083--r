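#' Latent population distributions
#'
#' Constructors for the four population distributions of latent respondent
#' positions used in the simulation study. All are defined on (essentially)
#' the 0--100 continuum on which the item boundaries live:
#'
#' * `dist_normal()` -- N(50, 20);
#' * `dist_skew_normal()` -- Azzalini skew-normal with location 15, scale 25,
#'   shape 5 (density \eqn{2/\omega\,\phi((x-\xi)/\omega)\Phi(\alpha(x-\xi)/\omega)});
#' * `dist_bimodal()` -- an equal mixture of N(25, 10) and N(75, 10), with the
#'   component chosen independently per respondent;
#' * `dist_uniform()` -- uniform on \[0, 100\].
#'
#' The four differ not only in shape but also in variance (smallest for the
#' skew-normal, largest for the uniform), which matters for the observed item
#' variances downstream.
#'
#' @param mean,sd Normal mean and standard deviation.
#' @param location,scale,shape Azzalini skew-normal parameters; `scale` > 0.
#' @param mean1,sd1,mean2,sd2 Means and standard deviations of the two mixture
#'   components.
#' @param weights Mixture weights, two nonnegative numbers summing to 1.
#' @param lower,upper Support of the uniform, `lower < upper`.
#' @return An object of class `dist_spec` (a list with `family` and the
#'   family-specific parameters).
#' @examples
#' sample_latent(dist_normal(), 5, seed = 1)
#' @name dist_spec
NULL

new_dist_spec <- function(family, params) {
  structure(c(list(family = family), params), class = "dist_spec")
}

#' @rdname dist_spec
#' @export
dist_normal <- function(mean = 50, sd = 20) {
  stopifnot(sd > 0)
  new_dist_spec("normal", list(mean = mean, sd = sd))
}

#' @rdname dist_spec
#' @export
dist_skew_normal <- function(location = 15, scale = 25, shape = 5) {
  stopifnot(scale > 0)
  new_dist_spec("skew_normal",
                list(location = location, scale = scale, shape = shape))
}

#' @rdname dist_spec
#' @export
dist_bimodal <- function(mean1 = 25, sd1 = 10, mean2 = 75, sd2 = 10,
                         weights = c(0.5, 0.5)) {
  stopifnot(sd1 > 0, sd2 > 0, length(weights) == 2, all(weights >= 0),
            abs(sum(weights) - 1) < 1e-12)
  new_dist_spec("bimodal", list(mean1 = mean1, sd1 = sd1, mean2 = mean2,
                                sd2 = sd2, weights = weights))
}

#' @rdname dist_spec
#' @export
dist_uniform <- function(lower = 0, upper = 100) {
  stopifnot(lower < upper)
  new_dist_spec("uniform", list(lower = lower, upper = upper))
}

#' @export
print.dist_spec <- function(x, ...) {
  pars <- x[setdiff(names(x), "family")]
  cat("<dist_spec>", x$family, ":",
      paste(names(pars), vapply(pars, function(p) paste(p, collapse = "/"),
                                ""), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Default distribution set of the study
#'
#' The four latent population distributions at their study parameterisations,
#' in the fixed order used for grids and tables.
#'
#' @return Named list of `dist_spec` objects
#'   (`normal`, `skew_normal`, `uniform`, `bimodal`).
#' @export
study_distributions <- function() {
  list(normal      = dist_normal(),
       skew_normal = dist_skew_normal(),
       uniform     = dist_uniform(),
       bimodal     = dist_bimodal())
}

#' Draw latent respondent positions
#'
#' Draws `n` i.i.d. positions on the latent continuum from a population
#' distribution. The skew-normal is sampled by the standard two-normal
#' representation (\eqn{\xi + \omega(\delta|u_0| + \sqrt{1-\delta^2}\,u_1)}
#' with \eqn{\delta = \alpha/\sqrt{1+\alpha^2}}); the bimodal mixture assigns
#' each respondent to a component by an independent Bernoulli draw on the
#' mixture weights.
#'
#' @param spec A `dist_spec`.
#' @param n Number of respondents (>= 1).
#' @param seed Optional integer seed for reproducibility.
#' @return Numeric vector of length `n`, with attribute `spec`.
#' @export
sample_latent <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "dist_spec"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  x <- switch(spec$family,
    normal = stats::rnorm(n, spec$mean, spec$sd),
    skew_normal = {
      delta <- spec$shape / sqrt(1 + spec$shape^2)
      u0 <- stats::rnorm(n)
      u1 <- stats::rnorm(n)
      spec$location + spec$scale * (delta * abs(u0) + sqrt(1 - delta^2) * u1)
    },
    bimodal = {
      comp <- stats::runif(n) < spec$weights[1]
      ifelse(comp,
             stats::rnorm(n, spec$mean1, spec$sd1),
             stats::rnorm(n, spec$mean2, spec$sd2))
    },
    uniform = stats::runif(n, spec$lower, spec$upper),
    stop("unknown distribution family: ", spec$family)
  )
  attr(x, "spec") <- spec
  x
}
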