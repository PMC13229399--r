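#' Ridge regression solution
#'
#' Minimizes \eqn{\|y - X\pi\|_2^2 + \tau \|\pi\|_2^2}, whose unique
#' solution is \eqn{\hat\pi = (X^T X + \tau I)^{-1} X^T y}, computed
#' through a thin spectral decomposition of `X` so that the same code path
#' covers both `q < n` and the high-dimensional `q >= n` regime.
#'
#' @param X n x q design matrix.
#' @param y response vector of length n.
#' @param tau positive ridge penalty.
#' @return coefficient vector of length q.
#' @examples
#' X <- qr.Q(qr(matrix(rnorm(40), 8, 4)))   # orthonormal columns
#' y <- rnorm(8)
#' stopifnot(all.equal(ridgeSolve(X, y, tau = 1), drop(crossprod(X, y)) / 2))
#' @export
ridgeSolve <- function(X, y, tau) {
  X <- as.matrix(X)
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0)
    stop("tau must be a single positive finite number")
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stop("non-finite values in the ridge inputs")
  dec <- spectralDecomp(X)
  ridgeCoefFromDecomp(dec, drop(crossprod(dec$U, y)), tau)
}

#' Generalized cross-validation objective for ridge regression
#'
#' Evaluates \eqn{G(\tau) = \|(I - P_\tau) y\|^2 / (n - \mathrm{tr}\,
#' P_\tau)^2} with \eqn{P_\tau = X (X^T X + \tau I)^{-1} X^T}, using the
#' singular values of `X` (no n x n matrix is formed):
#' \eqn{\mathrm{tr}\,P_\tau = \sum_i d_i^2 / (d_i^2 + \tau)} and the
#' residual sum is accumulated in the rotated basis.
#'
#' @inheritParams ridgeSolve
#' @return nonnegative scalar \eqn{G(\tau)}.
#' @export
gcvObjective <- function(X, y, tau) {
  X <- as.matrix(X)
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0)
    stop("tau must be a single positive finite number")
  dec <- spectralDecomp(X)
  gcvFromSpectrum(dec$d, drop(crossprod(dec$U, y)), sum(y^2), nrow(X), tau)
}

#' Select the ridge penalty by generalized cross-validation
#'
#' Minimizes the GCV objective over a log-spaced grid of 50 penalties
#' spanning `[1e-4, 1e4]` times the mean squared singular value of `X`
#' (so the grid adapts to the design's scale), then refines the minimum by
#' a golden-section/Brent search between the bracketing grid cells.  A
#' minimum at a grid boundary is returned unrefined with a warning.
#'
#' @inheritParams ridgeSolve
#' @param nGrid number of grid points.
#' @return list with elements `tau` (the selected penalty) and `trace`
#'   (data.frame of the grid and its GCV values).
#' @export
selectTauGCV <- function(X, y, nGrid = 50L) {
  X <- as.matrix(X)
  dec <- spectralDecomp(X)
  selectTauSpectrum(dec$d, drop(crossprod(dec$U, y)), sum(y^2), nrow(X),
                    nGrid = nGrid)
}

#' First stage of 2SPLS: ridge fits of all reduced-form equations
#'
#' Regresses each endogenous variable on all exogenous variables by ridge
#' regression with a GCV-selected penalty, yielding the fitted conditional
#' expectations \eqn{\hat Z_j = P_{\tau_j} Y_j} used as instruments at the
#' second stage.  The spectral decomposition of `X` is computed once and
#' shared across genes and penalties; the per-gene fits are independent,
#' so results do not depend on the number of workers.
#'
#' @param data an [SEMData-class].
#' @param nGrid grid size for the GCV search.
#' @param standardize if `TRUE`, columns of `X` are scaled to unit SD
#'   before fitting (coefficients are returned on the original scale).
#'   Off by default: genotype codes already share a scale.
#' @param workers number of parallel workers (forked; unix only).
#' @return a [Stage1Fit-class].
#' @export
fitFirstStage <- function(data, nGrid = 50L, standardize = FALSE,
                          workers = 1L) {
  stopifnot(is(data, "SEMData"))
  X <- data@X
  scl <- rep(1, ncol(X))
  if (standardize) {
    scl <- apply(X, 2, stats::sd)
    scl[scl == 0] <- 1
    X <- sweep(X, 2, scl, "/")
  }
  dec <- spectralDecomp(X)
  UtY <- crossprod(dec$U, data@Y)
  yss <- colSums(data@Y^2)
  n <- nrow(X); p <- ncol(data@Y)
  fits <- mapOverGenes(seq_len(p), function(j) {
    sel <- tryCatch(
      selectTauSpectrum(dec$d, UtY[, j], yss[j], n, nGrid = nGrid),
      error = function(e)
        stop(sprintf("first-stage fit failed for gene %s: %s",
                     data@geneIds[j], conditionMessage(e)), call. = FALSE))
    f <- dec$d^2 / (dec$d^2 + sel$tau)
    list(tau = sel$tau,
         pi = ridgeCoefFromDecomp(dec, UtY[, j], sel$tau) / scl,
         z = drop(dec$U %*% (f * UtY[, j])),
         trace = sel$trace)
  }, workers = workers)
  new("Stage1Fit",
      piHat = vapply(fits, `[[`, numeric(ncol(X)), "pi"),
      tau = vapply(fits, `[[`, numeric(1), "tau"),
      ZHat = vapply(fits, `[[`, numeric(n), "z"),
      gcvTrace = lapply(fits, `[[`, "trace"))
}
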