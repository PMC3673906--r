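# Independent oracles, written before (and kept independent of) the
# implementations they check.

# upper-tail binomial probability by explicit pmf summation on the log
# scale: P(X >= k) for X ~ Binomial(n, p)
oracle_binom_tail <- function(k, n, p) {
  if (k <= 0) return(1)
  x <- k:n
  sum(exp(lchoose(n, x) + x * log(p) + (n - x) * log1p(-p)))
}

# chi-square upper tail by numerical quadrature of the density
oracle_chisq_upper <- function(x, df) {
  if (x <= 0) return(1)
  stats::integrate(stats::dchisq, lower = x, upper = Inf, df = df,
                   rel.tol = 1e-12)$value
}

# exact HWE test by full enumeration of heterozygote configurations:
# P(nAB | nA alleles among n diploids) =
#   n! / (nAA! nAB! nBB!) * 2^nAB / choose(2n, nA)
oracle_hwe_enum <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  nA <- 2 * nAA + nAB
  hets <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  prob <- vapply(hets, function(h) {
    aa <- (nA - h) / 2
    bb <- n - aa - h
    exp(lfactorial(n) - lfactorial(aa) - lfactorial(h) -
          lfactorial(bb) + h * log(2) - lchoose(2 * n, nA))
  }, numeric(1))
  obs <- prob[hets == nAB]
  sum(prob[prob <= obs * (1 + 1e-12)])
}

# two-tailed exact binomial p at null 0.5 by the small-p-values method
oracle_binom_two_tail <- function(k, n) {
  if (n == 0) return(1)
  d <- stats::dbinom(0:n, n, 0.5)
  sum(d[d <= d[k + 1] * (1 + 1e-12)])
}

# null boundary of the pooled caller's composite hypothesis
null_boundary <- function(theta = 0.01, e = 0.01) {
  theta * (1 - e) + (1 - theta) * e
}
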