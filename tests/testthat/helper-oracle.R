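# Independent oracles used across tests. These deliberately avoid the
# package's own estimators: quadrature is done with stats::integrate on the
# analytic densities.

# Exact mutual information between x ~ U(0, L) and g = (x/L)*cmax + N(0, s^2),
# via the marginal density p(g) = (Phi(g/s) - Phi((g - cmax)/s)) / cmax.
oracleLinearChannelMI <- function(cmax, sigma) {
  p <- function(g) (pnorm(g / sigma) - pnorm((g - cmax) / sigma)) / cmax
  negPlogP <- function(g) {
    v <- p(g)
    ifelse(v > 0, -v * log(v), 0)
  }
  h <- integrate(negPlogP, -8 * sigma, cmax + 8 * sigma,
                 rel.tol = 1e-9, subdivisions = 2000L)$value
  h - log(sigma * sqrt(2 * pi * exp(1)))
}

# standard error of a sample SD for n iid Gaussians
sdStderr <- function(sigma, n) sigma / sqrt(2 * n)

# a small embryo spec that keeps tests fast while preserving the default
# geometry
tinyEmbryoSpec <- function(nAP = 60L, nDV = 6L, genes = defaultEmbryoGenes())
  EmbryoSpec(genes = genes, nAP = nAP, nDV = nDV)
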