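#' Fit a regulatory network by 2SPLS or one of its baselines
#'
#' Orchestrates whole-network estimation.  With `method = "2SPLS"` the
#' first stage ridge-regresses every endogenous variable on all exogenous
#' variables (GCV-tuned) to form instruments, and the second stage runs an
#' adaptive lasso per gene on the cis-projected data.  `"AL"` is the
#' single-equation baseline: each structural equation is fitted directly
#' by adaptive lasso on the *observed* other endogenous variables (no
#' first stage), which is biased because those regressors are correlated
#' with the equation error.  `"2SAL"` replaces the first-stage ridge with
#' an adaptive lasso per reduced-form equation (K-fold CV), keeping the
#' second stage identical to 2SPLS.
#'
#' Cross-validation is fold-honest: one fold assignment per network fit
#' is drawn from `seed`, the first stage is re-estimated on each training
#' split, and held-out rows are predicted from the exogenous variables
#' alone (see the package vignette for why this matters when q >= n).
#' All randomness derives deterministically from `seed`, so results are
#' invariant to the gene-processing order and the number of workers.
#'
#' @param data an [SEMData-class].
#' @param cis a [CisMap-class] (validated before fitting).
#' @param method `"2SPLS"`, `"AL"` or `"2SAL"`.
#' @param delta adaptive-weight exponent (default 1).
#' @param K number of cross-validation folds (default 5).
#' @param nLambda,minRatio lasso path settings.
#' @param seed master integer seed.
#' @param workers parallel workers for the per-gene fits.
#' @param lambda optional fixed second-stage penalty (skips CV).
#' @param rule penalty selection rule, `"1se"` (default) or `"min"`.
#' @return a [NetworkEstimate-class].
#' @export
fitNetwork <- function(data, cis, method = c("2SPLS", "AL", "2SAL"),
                       delta = 1, K = 5L, nLambda = 50L, minRatio = 1e-4,
                       seed = 1L, workers = 1L, lambda = NULL,
                       rule = c("1se", "min")) {
  method <- match.arg(method)
  rule <- match.arg(rule)
  stopifnot(is(data, "SEMData"))
  if (!is(cis, "CisMap")) cis <- cisMap(cis, q = ncol(data@X))
  vrep <- validateCisMap(cis)
  if (nrow(vrep) > 0L)
    stop("invalid cis map: ", paste(vrep$message, collapse = "; "))
  t0 <- proc.time()[["elapsed"]]
  p <- ncol(data@Y); q <- ncol(data@X); n <- nrow(data@Y)
  folds <- withSeed(deriveSeed(seed, 0L),
                    sample(rep_len(seq_len(K), n)))
  inst <- buildInstrumentSet(data, method,
                             folds = if (is.null(lambda)) folds else NULL,
                             K = K, seed = seed, workers = workers)
  caches <- buildCaches(data, inst, folds)
  fits <- mapOverGenes(seq_len(p), function(k) {
    tryCatch(
      fitSecondStage(k, data, inst, cis, folds = folds, delta = delta,
                     K = K, nLambda = nLambda, minRatio = minRatio,
                     seed = deriveSeed(seed, k), lambda = lambda,
                     rule = rule, caches = caches),
      error = function(e)
        simpleError(sprintf("gene %s: %s", data@geneIds[k],
                            conditionMessage(e))))
  }, workers = workers)
  bad <- vapply(fits, inherits, logical(1), "error")
  if (any(bad))
    stop("second-stage failures:\n  ",
         paste(vapply(fits[bad], conditionMessage, character(1)),
               collapse = "\n  "))
  Gamma <- matrix(0, p, p)
  Psi <- matrix(0, q, p)
  for (k in seq_len(p)) {
    Gamma[seq_len(p)[-k], k] <- fits[[k]]@gammaHat
    Psi[cis@sets[[k]], k] <- fits[[k]]@psiHat
  }
  dimnames(Gamma) <- list(data@geneIds, data@geneIds)
  dimnames(Psi) <- list(data@markerIds, data@geneIds)
  new("NetworkEstimate", GammaHat = Gamma, PsiHat = Psi, method = method,
      perGene = fits,
      metadata = list(seed = seed, delta = delta, K = K,
                      nLambda = nLambda, minRatio = minRatio,
                      rule = rule, n = n, p = p, q = q,
                      elapsed = proc.time()[["elapsed"]] - t0))
}

#' First stage of 2SAL: adaptive lasso per reduced-form equation
#'
#' Replaces the ridge first stage by an adaptive lasso of each endogenous
#' variable on all exogenous variables, with initial weights from
#' marginal per-marker OLS coefficients and the penalty chosen by K-fold
#' cross-validation (one fold assignment, seeded, shared across genes so
#' the fold Gram matrices are computed once).
#'
#' @inheritParams fitNetwork
#' @return a [Stage1Fit-class] (`tau` holds the selected lasso penalties).
#' @export
fitFirstStageAL <- function(data, K = 5L, delta = 1, seed = 1L,
                            nLambda = 50L, minRatio = 1e-4) {
  stopifnot(is(data, "SEMData"))
  X <- data@X; Y <- data@Y
  n <- nrow(X); q <- ncol(X); p <- ncol(Y)
  G <- crossprod(X)
  dG <- pmax(diag(G), .Machine$double.eps)
  folds <- withSeed(deriveSeed(seed, 0L), sample(rep_len(seq_len(K), n)))
  foldG <- lapply(seq_len(K), function(f)
    crossprod(X[folds == f, , drop = FALSE]))
  yssFold <- function(y, f) sum(y^2) - sum(y[folds == f]^2)
  piHat <- matrix(0, q, p)
  tauSel <- numeric(p)
  for (j in seq_len(p)) {
    y <- Y[, j]
    cvec <- drop(crossprod(X, y))
    omega <- adaptiveWeights(cvec / dG, delta)   # marginal OLS pilot
    lambdas <- lambdaPath(cvec, omega, nLambda, minRatio)
    sse <- numeric(length(lambdas))
    for (f in seq_len(K)) {
      te <- which(folds == f)
      Xte <- X[te, , drop = FALSE]
      ctr <- cvec - drop(crossprod(Xte, y[te]))
      beta <- cdPath(G - foldG[[f]], ctr, omega, lambdas,
                     dfmax = min(n - 1L, q), yss = yssFold(y, f))
      sse <- sse + colSums((y[te] - Xte %*% beta)^2)
    }
    cv <- sse / n
    best <- which(cv <= min(cv) * (1 + 1e-12))[1L]
    beta <- cdPath(G, cvec, omega, lambdas[seq_len(best)],
                   dfmax = min(n - 1L, q), yss = sum(y^2))
    piHat[, j] <- beta[, best]
    tauSel[j] <- lambdas[best]
  }
  new("Stage1Fit", piHat = piHat, tau = tauSel, ZHat = X %*% piHat,
      gcvTrace = list())
}

#' Paired-bootstrap edge confidence for a fitted network
#'
#' Resamples the rows of `(Y, X)` jointly with replacement (preserving
#' the sample size and the expression-genotype linkage), refits the
#' network on each resample, and records for every directed edge the
#' fraction of resamples in which it was selected, plus the fraction of
#' those selections agreeing with the modal sign.  Per-resample seeds
#' derive from the master seed and the resample index, so the summary is
#' reproducible and independent of execution order.  Resamples whose fit
#' fails are counted and excluded rather than aborting the run.
#'
#' @inheritParams fitNetwork
#' @param B number of bootstrap resamples (>= 1).
#' @return a [BootstrapSummary-class].
#' @export
bootstrapNetwork <- function(data, cis, B, method = "2SPLS", delta = 1,
                             K = 5L, nLambda = 50L, minRatio = 1e-4,
                             seed = 1L, workers = 1L) {
  stopifnot(is(data, "SEMData"), B >= 1L)
  if (!is(cis, "CisMap")) cis <- cisMap(cis, q = ncol(data@X))
  n <- nrow(data@Y); p <- ncol(data@Y)
  runs <- mapOverGenes(seq_len(B), function(b) {
    bseed <- deriveSeed(seed, b)
    idx <- withSeed(bseed, sample.int(n, n, replace = TRUE))
    boot <- semData(data@Y[idx, , drop = FALSE], data@X[idx, , drop = FALSE],
                    geneIds = data@geneIds, markerIds = data@markerIds)
    tryCatch(
      fitNetwork(boot, cis, method = method, delta = delta, K = K,
                 nLambda = nLambda, minRatio = minRatio,
                 seed = bseed)@GammaHat,
      error = function(e) NULL)
  }, workers = workers)
  ok <- !vapply(runs, is.null, logical(1))
  sel <- matrix(0, p, p)
  pos <- matrix(0, p, p)
  neg <- matrix(0, p, p)
  for (Gb in runs[ok]) {
    hit <- abs(Gb) > 0
    sel <- sel + hit
    pos <- pos + (hit & Gb > 0)
    neg <- neg + (hit & Gb < 0)
  }
  nOK <- sum(ok)
  freq <- if (nOK > 0) sel / nOK else sel
  signCons <- matrix(0, p, p)
  nz <- sel > 0
  signCons[nz] <- pmax(pos[nz], neg[nz]) / sel[nz]
  dimnames(freq) <- dimnames(signCons) <-
    list(data@geneIds, data@geneIds)
  new("BootstrapSummary", B = as.integer(B),
      nFailed = as.integer(B - nOK), freq = freq,
      signConsistency = signCons)
}
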