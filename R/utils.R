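# Internal helpers shared across modules.

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards.  seed = NULL means "use the current
# stream" (no save/restore), so composite generators can seed once.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Deterministic per-unit seed derived from a master seed; stays below 2^31.
deriveSeed <- function(seed, index) {
  as.integer((as.double(seed) %% 1000003 + 1) * 1009 + index) %% 2147483562L
}

# Thin spectral decomposition of a design matrix M (n x m): returns the
# left singular vectors U, the nonzero singular values d, and a function
# coef(shrink) mapping per-component shrinkage factors applied to U'y into
# primal ridge coefficients.  Uses eigen of the n x n Gram when n < m.
spectralDecomp <- function(M) {
  n <- nrow(M); m <- ncol(M)
  if (n <= m) {
    e <- eigen(tcrossprod(M), symmetric = TRUE)
    d2 <- pmax(e$values, 0)
    tol <- max(d2) * max(n, m) * .Machine$double.eps
    keep <- d2 > tol
    U <- e$vectors[, keep, drop = FALSE]
    d <- sqrt(d2[keep])
    list(U = U, d = d, M = M, dual = TRUE)
  } else {
    sv <- svd(M)
    tol <- max(sv$d, 0) * max(n, m) * .Machine$double.eps
    keep <- sv$d > tol
    list(U = sv$u[, keep, drop = FALSE], d = sv$d[keep],
         V = sv$v[, keep, drop = FALSE], M = M, dual = FALSE)
  }
}

# Ridge coefficients from a spectralDecomp, a rotated response uty = U'y,
# and penalty tau:  (M'M + tau I)^{-1} M'y.
ridgeCoefFromDecomp <- function(dec, uty, tau) {
  if (dec$dual) {
    # primal coef = M' U diag(1/(d^2+tau)) U'y
    drop(crossprod(dec$M, dec$U %*% (uty / (dec$d^2 + tau))))
  } else {
    drop(dec$V %*% ((dec$d / (dec$d^2 + tau)) * uty))
  }
}

# GCV objective from spectral quantities: d (singular values), uty = U'y,
# yss = y'y, n = sample count.
gcvFromSpectrum <- function(d, uty, yss, n, tau) {
  f <- d^2 / (d^2 + tau)
  rss <- (yss - sum(uty^2)) + sum(((1 - f) * uty)^2)
  trP <- sum(f)
  denom <- n - trP
  if (denom <= 0) stop("GCV denominator n - tr(P) is nonpositive")
  rss / denom^2
}

# Default log-spaced tau grid anchored at the design's spectral scale.
tauGrid <- function(d, nGrid = 50L, lower = 1e-4, upper = 1e4) {
  s2 <- mean(d^2)
  exp(seq(log(lower * s2), log(upper * s2), length.out = nGrid))
}

# Grid + local refinement minimizer of the GCV curve.  Returns the selected
# tau and the grid trace.  A boundary minimum is returned as-is with a
# warning (no refinement beyond the grid).
selectTauSpectrum <- function(d, uty, yss, n, nGrid = 50L) {
  grid <- tauGrid(d, nGrid)
  if (yss <= 0) {
    warning("response is identically zero; returning grid midpoint tau")
    mid <- exp(mean(log(range(grid))))
    return(list(tau = mid,
                trace = data.frame(tau = grid, gcv = rep(0, length(grid)))))
  }
  g <- vapply(grid, function(tt) gcvFromSpectrum(d, uty, yss, n, tt),
              numeric(1))
  i <- which.min(g)
  if (i == 1L || i == length(grid)) {
    warning(sprintf("GCV minimum at %s grid boundary (tau = %.3e)",
                    if (i == 1L) "lower" else "upper", grid[i]))
    return(list(tau = grid[i], trace = data.frame(tau = grid, gcv = g)))
  }
  # golden-section/Brent refinement within the bracketing cells, on log-tau
  opt <- stats::optimize(
    function(lt) gcvFromSpectrum(d, uty, yss, n, exp(lt)),
    lower = log(grid[i - 1L]), upper = log(grid[i + 1L]),
    tol = 1e-6)
  tau <- exp(opt$minimum)
  if (opt$objective > g[i]) tau <- grid[i]   # refinement may never be worse
  list(tau = tau, trace = data.frame(tau = grid, gcv = g))
}

# Ridge fit with GCV-selected penalty for an arbitrary design; used for the
# high-dimensional second-stage initial estimate.
ridgeGCVFit <- function(M, y) {
  dec <- spectralDecomp(M)
  uty <- drop(crossprod(dec$U, y))
  sel <- selectTauSpectrum(dec$d, uty, sum(y^2), nrow(M))
  ridgeCoefFromDecomp(dec, uty, sel$tau)
}

mapOverGenes <- function(indices, fn, workers = 1L) {
  if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(indices, fn, mc.cores = workers,
                       mc.preschedule = TRUE)
  } else {
    lapply(indices, fn)
  }
}
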