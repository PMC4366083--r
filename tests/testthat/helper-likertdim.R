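# shared fixtures built in code

equicor <- function(p, r) {
  C <- matrix(r, p, p)
  diag(C) <- 1
  C
}

# discretise bivariate-normal draws through two threshold sets; returns
# integer code matrix used as a simulation oracle for the polychoric tests
rbvn_codes <- function(n, rho, tau_a, tau_b, seed = 1) {
  set.seed(seed)
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  cbind(a = findInterval(z1, tau_a) + 1L,
        b = findInterval(z2, tau_b) + 1L)
}

# standard-normal-scale thresholds of a pool item under a latent population,
# for constructing oracle tables
item_tau <- function(item, mean, sd) {
  (as.numeric(item[, c("b1", "b2", "b3", "b4")]) - mean) / sd
}
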