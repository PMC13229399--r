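#' Construct a SimulationDesign
#'
#' Describes one synthetic genetical-genomics benchmark condition.  The
#' defaults reproduce the baseline condition of the simulation benchmark:
#' 300 endogenous variables, sparse acyclic topology (mean one regulatory
#' effect per node, effects uniform on \eqn{(-1,-0.5)\cup(0.5,1)}), one
#' exogenous effect per gene with effect 1, F2-style genotypes taking
#' 0/1/2 with probabilities 0.25/0.5/0.25, and Gaussian errors with SD
#' 0.1.
#'
#' @param p number of endogenous variables (genes).
#' @param n sample size.
#' @param topology `"acyclic"` or `"cyclic"`.
#' @param edgeMean mean regulatory effects per node (1 sparse, 3 dense).
#' @param eePerGene exogenous effects per gene (1 or 3).
#' @param errorModel `"gaussian"` or `"student_t"` (t(3), scaled so the
#'   error variance matches the Gaussian baseline).
#' @param errorSD Gaussian error SD (double/quadruple the variance for the
#'   robustness variants by passing `errorSD * sqrt(2)` or `errorSD * 2`).
#' @param hubCount,hubEdgeMean hub-node variant: `hubCount` nodes get mean
#'   out-degree `hubEdgeMean` instead of `edgeMean` (0 disables).
#' @param correlatedEE correlated-cis-marker variant: each gene's three
#'   markers are correlated (target Pearson 0.8) with effects
#'   (1, 0.5, -0.3); requires `eePerGene = 3`.
#' @return a validated [SimulationDesign-class].
#' @export
simulationDesign <- function(p = 300L, n = 100L, topology = "acyclic",
                             edgeMean = 1, eePerGene = 1L,
                             errorModel = "gaussian", errorSD = 0.1,
                             hubCount = 0L, hubEdgeMean = 5,
                             correlatedEE = FALSE) {
  new("SimulationDesign", p = as.integer(p), q = as.integer(p * eePerGene),
      n = as.integer(n), topology = topology, edgeMean = as.numeric(edgeMean),
      eePerGene = as.integer(eePerGene), errorModel = errorModel,
      errorSD = as.numeric(errorSD), hubCount = as.integer(hubCount),
      hubEdgeMean = as.numeric(hubEdgeMean),
      correlatedEE = isTRUE(correlatedEE))
}

# effect sizes uniform on (-1,-0.5) U (0.5,1), equal mass on both signs
.sampleEffects <- function(m) {
  stats::runif(m, 0.5, 1) * sample(c(-1, 1), m, replace = TRUE)
}

#' Sample a regulatory network (structural system) from a design
#'
#' Edge placement is Erdos-Renyi-style: each admissible ordered pair
#' (i -> k) is included independently with the probability that makes the
#' expected out-degree of node i equal to the design's density target
#' (`edgeMean`, or `hubEdgeMean` for designated hub nodes).  Acyclic
#' topologies restrict edges to pairs ordered by a random node
#' permutation, so the adjacency is strictly triangular under that order;
#' cyclic topologies place edges without the constraint and re-sample the
#' whole system until \eqn{I - \Gamma} passes the numerical stability
#' check.  Nonzero effects are i.i.d. uniform on
#' \eqn{(-1,-0.5)\cup(0.5,1)}; exogenous effects are 1 (or (1, 0.5, -0.3)
#' under the correlated-marker variant), on consecutive disjoint marker
#' blocks.
#'
#' @param design a [SimulationDesign-class].
#' @param seed integer seed, or `NULL` to draw from the current RNG
#'   stream.
#' @return a [StructuralSystem-class].
#' @export
sampleNetwork <- function(design, seed = NULL) {
  stopifnot(is(design, "SimulationDesign"))
  withSeed(seed, {
    p <- design@p; q <- design@q; ee <- design@eePerGene
    outMean <- rep(design@edgeMean, p)
    if (design@hubCount > 0L)
      outMean[sample.int(p, design@hubCount)] <- design@hubEdgeMean
    acyclic <- design@topology == "acyclic"
    for (attempt in seq_len(51L)) {
      if (attempt > 50L)
        stop("more than 50 consecutive unstable systems; use a sparser design")
      Gamma <- matrix(0, p, p)
      if (acyclic) {
        ord <- sample.int(p)                    # ord[i] = rank of node i
        # node i may regulate k iff ord[i] < ord[k]; expected number of
        # admissible targets is (p-1)/2, so prob = 2 * mean / (p-1)
        prob <- pmin(2 * outMean / (p - 1), 1)
        adj <- matrix(stats::runif(p * p), p, p) < prob
        adj <- adj & (outer(ord, ord, "<"))
      } else {
        prob <- pmin(outMean / (p - 1), 1)
        adj <- matrix(stats::runif(p * p), p, p) < prob
        diag(adj) <- FALSE
      }
      m <- sum(adj)
      Gamma[adj] <- .sampleEffects(m)
      if (acyclic || .stabilityMargin(Gamma) >= .STABILITY_TOL) break
    }
    if (.stabilityMargin(Gamma) < .STABILITY_TOL)
      stop("sampled acyclic system is numerically unstable; use a sparser design")
    Psi <- matrix(0, q, p)
    sets <- vector("list", p)
    eff <- if (design@correlatedEE) c(1, 0.5, -0.3) else rep(1, ee)
    for (k in seq_len(p)) {
      sets[[k]] <- ((k - 1L) * ee + 1L):(k * ee)
      Psi[sets[[k]], k] <- eff
    }
    structuralSystem(Gamma, Psi, cisMap(sets, q = q), sigma = design@errorSD)
  })
}

# genotype correlation attained by thresholding an equicorrelated Gaussian
# pair at the 0.25/0.75 quantiles, as a function of the latent correlation
.thresholdedGenoCor <- function(r) {
  if (r <= 0) return(0)
  t1 <- stats::qnorm(0.25); t2 <- stats::qnorm(0.75)
  upper <- function(a, b) {
    # P(Z1 > a, Z2 > b) for correlation r, by 1-D quadrature
    stats::integrate(function(x)
      stats::dnorm(x) * stats::pnorm((r * x - b) / sqrt(1 - r^2)),
      lower = a, upper = Inf, rel.tol = 1e-10)$value
  }
  eg <- upper(t1, t1) + upper(t1, t2) + upper(t2, t1) + upper(t2, t2)
  (eg - 1) / 0.5   # E[g] = 1, Var[g] = 0.5
}

# latent equicorrelation whose thresholded genotypes attain `target`
# Pearson correlation (cached after the first call)
.genoLatentCor <- local({
  cache <- new.env(parent = emptyenv())
  function(target = 0.8) {
    key <- sprintf("%.6f", target)
    if (!is.null(cache[[key]])) return(cache[[key]])
    r <- stats::uniroot(function(r) .thresholdedGenoCor(r) - target,
                        lower = 1e-6, upper = 1 - 1e-9, tol = 1e-10)$root
    cache[[key]] <- r
    r
  }
})

#' Sample genotype matrices
#'
#' Draws n x q genotype codes in \{0, 1, 2\} with marginal probabilities
#' (0.25, 0.5, 0.25), emulating an F2 cross.  Under the correlated-marker
#' variant, consecutive triples of markers (one triple per gene) are
#' generated from an equicorrelated Gaussian copula thresholded at the
#' 0.25/0.75 quantiles; the latent correlation is calibrated so the
#' genotype-scale Pearson correlation attains the 0.8 target, and the
#' calibrated value is attached as attribute `latentCor`.
#'
#' @param n,q sample size and marker count.
#' @param seed integer seed, or `NULL` for the current stream.
#' @param correlatedEE logical; requires `q` divisible by 3 when `TRUE`.
#' @param targetCor target within-triple Pearson correlation.
#' @return n x q numeric matrix of 0/1/2 codes.
#' @export
sampleGenotypes <- function(n, q, seed = NULL, correlatedEE = FALSE,
                            targetCor = 0.8) {
  withSeed(seed, {
    if (!correlatedEE) {
      matrix(sample(c(0, 1, 2), n * q, replace = TRUE,
                    prob = c(0.25, 0.5, 0.25)), n, q)
    } else {
      if (q %% 3L != 0L) stop("correlated genotypes require q divisible by 3")
      r <- .genoLatentCor(targetCor)
      X <- matrix(0, n, q)
      t1 <- stats::qnorm(0.25); t2 <- stats::qnorm(0.75)
      for (b in seq_len(q %/% 3L)) {
        common <- stats::rnorm(n)
        z <- sqrt(r) * common +
          sqrt(1 - r) * matrix(stats::rnorm(3 * n), n, 3)
        X[, (3L * b - 2L):(3L * b)] <- (z > t1) + (z > t2)
      }
      attr(X, "latentCor") <- r
      X
    }
  })
}

#' Sample a dataset from a structural system
#'
#' Draws the error matrix under the design's error model and solves the
#' system through its reduced form: \eqn{Y = (X\Psi + \epsilon)(I -
#' \Gamma)^{-1}}, which satisfies the structural recursion
#' \eqn{Y(I - \Gamma) = X\Psi + \epsilon} exactly.  Student-t errors
#' (3 df) are scaled by \eqn{\sigma/\sqrt{3}} so their variance matches
#' the Gaussian baseline.
#'
#' @param system a [StructuralSystem-class].
#' @param X n x q exogenous matrix.
#' @param errorModel `"gaussian"` or `"student_t"`.
#' @param seed integer seed, or `NULL` for the current stream.
#' @return an [SEMData-class].
#' @export
sampleDataset <- function(system, X, errorModel = "gaussian", seed = NULL) {
  stopifnot(is(system, "StructuralSystem"))
  X <- as.matrix(X)
  p <- ncol(system@Gamma)
  if (ncol(X) != nrow(system@Psi))
    stop("ncol(X) does not match nrow(Psi)")
  n <- nrow(X)
  withSeed(seed, {
    eps <- switch(errorModel,
      gaussian = matrix(stats::rnorm(n * p), n, p) %*% diag(system@sigma, p),
      student_t = matrix(stats::rt(n * p, df = 3), n, p) %*%
        diag(system@sigma / sqrt(3), p),
      stop("unknown error model: ", errorModel))
    rhs <- X %*% system@Psi + eps
    Y <- t(solve(t(diag(p) - system@Gamma), t(rhs)))
    semData(Y, X)
  })
}

#' Simulate a complete benchmark dataset
#'
#' Convenience wrapper: seeds the RNG once, then samples the network, the
#' genotypes, and the observations in sequence.  Identical
#' `(design, seed)` pairs give bit-identical output.
#'
#' @param design a [SimulationDesign-class].
#' @param seed integer seed.
#' @return list with elements `system` ([StructuralSystem-class]),
#'   `data` ([SEMData-class]) and `design`.
#' @export
simulateDataset <- function(design, seed = 1L) {
  stopifnot(is(design, "SimulationDesign"))
  withSeed(seed, {
    system <- sampleNetwork(design, seed = NULL)
    X <- sampleGenotypes(design@n, design@q, seed = NULL,
                         correlatedEE = design@correlatedEE)
    data <- sampleDataset(system, X, errorModel = design@errorModel,
                          seed = NULL)
    list(system = system, data = data, design = design)
  })
}

#' Keep only the strongest estimated cis marker per gene
#'
#' Implements the marker-uncertainty robustness protocol: for each gene,
#' regress its expression marginally on each candidate cis marker, keep
#' the marker with the largest absolute t-statistic, and return the
#' reduced cis map (one marker per gene).  Intended to run before network
#' fitting when multiple correlated candidate markers are available.
#'
#' @param data an [SEMData-class].
#' @param cis a [CisMap-class] with possibly several markers per gene.
#' @return a [CisMap-class] with exactly one marker per gene.
#' @export
selectStrongestCis <- function(data, cis) {
  stopifnot(is(data, "SEMData"), is(cis, "CisMap"))
  sets <- lapply(seq_along(cis@sets), function(k) {
    S <- cis@sets[[k]]
    if (length(S) == 1L) return(S)
    y <- data@Y[, k]
    tstat <- vapply(S, function(m) {
      x <- data@X[, m]
      xc <- x - mean(x); yc <- y - mean(y)
      sxx <- sum(xc^2)
      if (sxx == 0) return(0)
      b <- sum(xc * yc) / sxx
      res <- yc - b * xc
      se <- sqrt(sum(res^2) / (length(y) - 2) / sxx)
      if (se == 0) Inf else abs(b / se)
    }, numeric(1))
    S[which.max(tstat)]
  })
  cisMap(sets, q = cis@q)
}
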