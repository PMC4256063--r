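## Independent oracles used across the suite. These deliberately avoid the
## package's own helpers so that each check compares two routes to the same
## quantity.

## Circular mean direction and SD straight from the resultant vector.
oracle_circ <- function(deg) {
  rad <- deg * pi / 180
  C <- mean(cos(rad))
  S <- mean(sin(rad))
  list(mean = atan2(S, C) * 180 / pi,
       rho = sqrt(C^2 + S^2),
       sd = sqrt(-2 * log(sqrt(C^2 + S^2))) * 180 / pi)
}

## Exact upper-tail binomial probability P(X >= m) by direct enumeration.
oracle_binom_tail <- function(m, n, p) {
  j <- m:n
  sum(choose(n, j) * p^j * (1 - p)^(n - j))
}

## The Weibull psychometric function assumed by the staircase, written out
## independently: probability correct at log10 intensity x given log10
## threshold t.
oracle_weibull <- function(x, t, beta = 3.5, gamma = 0.5, delta = 0.01,
                           mirrored = FALSE) {
  s <- if (mirrored) t - x else x - t
  delta * gamma + (1 - delta) * (1 - (1 - gamma) * exp(-10^(beta * s)))
}

## A tiny observer factory for readability.
obs <- function(sigma_int, n_samp, lapse = 0) {
  observer_params(sigma_int, n_samp, lapse)
}
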