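# Small fixture builders shared across test files.

# three-gene chain 1 -> 2 -> 3 with one cis marker per gene
chainSystem <- function(g12 = 0.8, g23 = -0.7, sigma = 0.1) {
  Gamma <- matrix(0, 3, 3)
  Gamma[1, 2] <- g12
  Gamma[2, 3] <- g23
  structuralSystem(Gamma, Psi = diag(3), cis = list(1L, 2L, 3L),
                   sigma = sigma)
}

# simulate a dataset from an arbitrary system with F2-style genotypes
simulateFromSystem <- function(system, n, seed,
                               errorModel = "gaussian") {
  q <- nrow(system@Psi)
  withSeed <- semGRN:::withSeed
  withSeed(seed, {
    X <- sampleGenotypes(n, q)
    sampleDataset(system, X, errorModel = errorModel)
  })
}

# dense random stable system used for algebra checks
randomStableSystem <- function(p, seed, scale = 0.3) {
  semGRN:::withSeed(seed, {
    repeat {
      Gamma <- matrix(stats::rnorm(p * p, sd = scale), p, p)
      diag(Gamma) <- 0
      if (min(svd(diag(p) - Gamma)$d) > 0.2) break
    }
    structuralSystem(Gamma, Psi = diag(p),
                     cis = as.list(seq_len(p)), sigma = 0.1)
  })
}
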