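# Independent solvers used as oracles against the packaged implementation.

# proximal-gradient (ISTA) solver for the weighted-lasso objective
#   0.5 ||y - Z g||^2 + lambda sum_j omega_j |g_j|
proxGradWLasso <- function(HY, HZ, omega, lambda, iters = 200000,
                           tol = 1e-12) {
  G <- crossprod(HZ)
  cvec <- drop(crossprod(HZ, HY))
  L <- max(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
  g <- numeric(ncol(HZ))
  for (i in seq_len(iters)) {
    grad <- drop(G %*% g) - cvec
    z <- g - grad / L
    gNew <- sign(z) * pmax(abs(z) - lambda * omega / L, 0)
    if (max(abs(gNew - g)) < tol) { g <- gNew; break }
    g <- gNew
  }
  g
}

wlassoObjective <- function(HY, HZ, omega, lambda, g) {
  0.5 * sum((HY - HZ %*% g)^2) + lambda * sum(omega * abs(g))
}
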