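# Bivariate standard-normal CDF, vectorised over the evaluation points with a
# scalar correlation. Gauss-Legendre quadrature on the Drezner-Wesolowsky
# arcsine integral for |rho| < 0.925, and the Genz singularity-handling
# expansion near |rho| = 1; absolute accuracy ~1e-15, well inside the 1e-7
# the polychoric likelihood needs. Vectorisation matters: each likelihood
# evaluation needs the CDF on a whole threshold grid.

# 6/12/20-point Gauss-Legendre nodes and weights (half-rules; symmetric).
.gl <- list(
  list(w = c(0.1713244923791705, 0.3607615730481384, 0.4679139345726904),
       x = c(-0.9324695142031522, -0.6612093864662647, -0.2386191860831970)),
  list(w = c(0.04717533638651177, 0.1069393259953183, 0.1600783285433464,
             0.2031674267230659, 0.2334925365383547, 0.2491470458134029),
       x = c(-0.9815606342467191, -0.9041172563704750, -0.7699026741943050,
             -0.5873179542866171, -0.3678314989981802, -0.1252334085114692)),
  list(w = c(0.01761400713915212, 0.04060142980038694, 0.06267204833410906,
             0.08327674157670475, 0.1019301198172404, 0.1181945319615184,
             0.1316886384491766, 0.1420961093183821, 0.1491729864726037,
             0.1527533871307259),
       x = c(-0.9931285991850949, -0.9639719272779138, -0.9122344282513259,
             -0.8391169718222188, -0.7463319064601508, -0.6360536807265150,
             -0.5108670019508271, -0.3737060887154196, -0.2277858511416451,
             -0.0765265211334973)))

# Upper-orthant probability P(X > h, Y > k); h, k finite vectors, rho scalar.
bvnd_upper <- function(h, k, rho) {
  rule <- .gl[[if (abs(rho) < 0.3) 1 else if (abs(rho) < 0.75) 2 else 3]]
  w <- rep(rule$w, 2)
  xn <- c(rule$x, -rule$x)
  twopi <- 2 * pi
  hk <- h * k
  bvn <- numeric(length(h))
  if (abs(rho) < 0.925) {
    if (rho != 0) {
      hs <- (h * h + k * k) / 2
      asr <- asin(rho)
      for (i in seq_along(xn)) {
        sn <- sin(asr * (xn[i] + 1) / 2)
        bvn <- bvn + w[i] * exp((sn * hk - hs) / (1 - sn * sn))
      }
      bvn <- bvn * asr / (2 * twopi)
    }
    bvn + stats::pnorm(-h) * stats::pnorm(-k)
  } else {
    if (rho < 0) {
      k <- -k
      hk <- -hk
    }
    if (abs(rho) < 1) {
      as_ <- (1 - rho) * (1 + rho)
      a <- sqrt(as_)
      bs <- (h - k)^2
      cc <- (4 - hk) / 8
      dd <- (12 - hk) / 16
      asr <- -(bs / as_ + hk) / 2
      m <- asr > -100
      bvn[m] <- (a * exp(asr) * (1 - cc * (bs - as_) * (1 - dd * bs / 5) / 3 +
                                   cc * dd * as_^2 / 5))[m]
      m <- -hk < 100
      if (any(m)) {
        b <- sqrt(bs)
        bvn[m] <- bvn[m] - (exp(-hk / 2) * sqrt(twopi) * stats::pnorm(-b / a) *
                              b * (1 - cc * bs * (1 - dd * bs / 5) / 3))[m]
      }
      a <- a / 2
      for (i in seq_along(xn)) {
        xs <- (a * (xn[i] + 1))^2
        rs <- sqrt(1 - xs)
        asr <- -(bs / xs + hk) / 2
        m <- asr > -100
        if (any(m)) {
          term <- a * w[i] * exp(asr) *
            (exp(-hk * (1 - rs) / (2 * (1 + rs))) / rs -
               (1 + cc * xs * (1 + dd * xs)))
          bvn[m] <- bvn[m] + term[m]
        }
      }
      bvn <- -bvn / twopi
    }
    if (rho > 0) {
      bvn + stats::pnorm(-pmax(h, k))
    } else {
      bvn <- -bvn
      gt <- k > h
      bvn[gt] <- bvn[gt] + (stats::pnorm(k) - stats::pnorm(h))[gt]
      bvn
    }
  }
}

#' Bivariate standard-normal CDF
#'
#' `P(X <= x, Y <= y)` for standard bivariate normal variables with
#' correlation `rho`. Vectorised over `x` and `y` (recycled to a common
#' length); `rho` must be a single value in (-1, 1). Infinite bounds are
#' handled (reducing to the univariate CDF or to 0).
#'
#' @param x,y Numeric vectors of upper integration limits.
#' @param rho Scalar correlation in (-1, 1).
#' @return Numeric vector of probabilities.
#' @examples
#' pbvnorm(0, 0, 0.5)  # 1/4 + asin(0.5)/(2*pi) = 1/3
#' @export
pbvnorm <- function(x, y, rho) {
  stopifnot(length(rho) == 1, is.finite(rho), abs(rho) < 1)
  n <- max(length(x), length(y))
  x <- rep_len(as.numeric(x), n)
  y <- rep_len(as.numeric(y), n)
  out <- numeric(n)
  lo <- x == -Inf | y == -Inf
  xi <- x == Inf
  yi <- y == Inf
  out[xi & !lo] <- stats::pnorm(y[xi & !lo])
  out[yi & !xi & !lo] <- stats::pnorm(x[yi & !xi & !lo])
  fin <- !lo & !xi & !yi
  if (any(fin)) out[fin] <- bvnd_upper(-x[fin], -y[fin], rho)
  pmin(pmax(out, 0), 1)
}
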