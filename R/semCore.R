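#' Construct a CisMap
#'
#' @param sets list of integer vectors; element `k` gives the exogenous
#'   column indices (1-based) assigned to endogenous variable `k`.
#' @param q number of exogenous columns the indices refer to; defaults to
#'   the largest index present.
#' @return a validated [CisMap-class].
#' @examples
#' cisMap(list(1L, 2L, 3L), q = 3L)
#' @export
cisMap <- function(sets, q = max(unlist(sets))) {
  sets <- lapply(sets, function(s) sort(unique(as.integer(s))))
  new("CisMap", sets = sets, q = as.integer(q))
}

#' Validate a cis map against the identifiability assumption
#'
#' Checks that every per-gene marker set is nonempty, that the sets are
#' pairwise disjoint, and that all indices fall in `1..q`.  Returns a
#' report of violations rather than throwing, so callers can present all
#' problems at once; the map is valid iff the report has zero rows.
#'
#' @param sets a [CisMap-class] or a plain list of index vectors.
#' @param q number of exogenous columns.
#' @return data.frame with columns `type` (`"empty"`, `"overlap"`,
#'   `"out_of_range"`), `gene` (comma-separated gene indices involved) and
#'   `message`.
#' @examples
#' validateCisMap(list(1L, 1L), q = 2L)   # overlap between genes 1 and 2
#' @export
validateCisMap <- function(sets, q) {
  if (is(sets, "CisMap")) {
    q <- sets@q
    sets <- sets@sets
  }
  q <- as.integer(q)
  out <- list()
  add <- function(type, gene, message)
    out[[length(out) + 1L]] <<- data.frame(type = type, gene = gene,
                                           message = message)
  for (k in seq_along(sets)) {
    s <- as.integer(sets[[k]])
    if (length(s) == 0L)
      add("empty", as.character(k),
          sprintf("gene %d has an empty exogenous set", k))
    bad <- s[s < 1L | s > q]
    if (length(bad))
      add("out_of_range", as.character(k),
          sprintf("gene %d references out-of-range marker(s) %s", k,
                  paste(bad, collapse = ",")))
  }
  if (length(sets) > 1L) {
    owner <- integer(q)
    for (k in seq_along(sets)) {
      s <- sets[[k]]
      s <- s[s >= 1L & s <= q]
      clash <- s[owner[s] != 0L]
      for (m in clash)
        add("overlap", paste(owner[m], k, sep = ","),
            sprintf("marker %d assigned to genes %d and %d", m, owner[m], k))
      owner[s[owner[s] == 0L]] <- k
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(type = character(), gene = character(),
                  message = character())
}

#' Construct a StructuralSystem
#'
#' @param Gamma p x p matrix of regulatory effects (zero diagonal).
#' @param Psi q x p matrix of exogenous (cis) effects.
#' @param cis a [CisMap-class] (or list of index vectors).
#' @param sigma error SDs, recycled to length p.
#' @return a validated [StructuralSystem-class].
#' @export
structuralSystem <- function(Gamma, Psi, cis, sigma = 0.1) {
  Gamma <- as.matrix(Gamma)
  Psi <- as.matrix(Psi)
  if (!is(cis, "CisMap")) cis <- cisMap(cis, q = nrow(Psi))
  p <- ncol(Gamma)
  new("StructuralSystem", Gamma = Gamma, Psi = Psi, cis = cis,
      sigma = rep_len(as.numeric(sigma), p))
}

#' Construct an SEMData object
#'
#' @param Y n x p endogenous matrix (samples x genes).
#' @param X n x q exogenous matrix (samples x markers).
#' @param sampleIds,geneIds,markerIds optional labels; defaults are taken
#'   from dimnames or generated (`S1..`, `G1..`, `M1..`).
#' @return a validated [SEMData-class].
#' @export
semData <- function(Y, X, sampleIds = NULL, geneIds = NULL,
                    markerIds = NULL) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  storage.mode(Y) <- "double"; storage.mode(X) <- "double"
  if (is.null(sampleIds))
    sampleIds <- if (!is.null(rownames(Y))) rownames(Y)
                 else paste0("S", seq_len(nrow(Y)))
  if (is.null(geneIds))
    geneIds <- if (!is.null(colnames(Y))) colnames(Y)
               else paste0("G", seq_len(ncol(Y)))
  if (is.null(markerIds))
    markerIds <- if (!is.null(colnames(X))) colnames(X)
                 else paste0("M", seq_len(ncol(X)))
  dimnames(Y) <- dimnames(X) <- NULL
  new("SEMData", Y = Y, X = X, sampleIds = as.character(sampleIds),
      geneIds = as.character(geneIds), markerIds = as.character(markerIds))
}

# tolerance below which I - Gamma is considered numerically singular
.STABILITY_TOL <- 1e-8

# smallest singular value of I - Gamma; the stability certificate for the
# reduced form
.stabilityMargin <- function(Gamma) {
  p <- ncol(Gamma)
  min(svd(diag(p) - Gamma, nu = 0, nv = 0)$d)
}

#' Reduced form of a structural system
#'
#' Solves the system for the endogenous variables: the structural model
#' \eqn{Y = Y \Gamma + X \Psi + \epsilon} has reduced form
#' \eqn{Y = X \pi + \xi} with \eqn{\pi = \Psi (I - \Gamma)^{-1}}.
#' Requires \eqn{I - \Gamma} to be numerically invertible (smallest
#' singular value above `1e-8`); cyclic systems violating this are
#' "unstable" and rejected.
#'
#' @param system a [StructuralSystem-class].
#' @return q x p numeric matrix \eqn{\pi}.
#' @examples
#' sys <- structuralSystem(Gamma = matrix(0, 2, 2), Psi = diag(2),
#'                         cis = list(1L, 2L))
#' stopifnot(identical(reducedForm(sys), diag(2)))  # Gamma = 0 => pi = Psi
#' @export
reducedForm <- function(system) {
  stopifnot(is(system, "StructuralSystem"))
  p <- ncol(system@Gamma)
  m <- .stabilityMargin(system@Gamma)
  if (m < .STABILITY_TOL)
    stop(sprintf(
      "unstable system: smallest singular value of I - Gamma is %.3e (tolerance %.0e)",
      m, .STABILITY_TOL))
  t(solve(t(diag(p) - system@Gamma), t(system@Psi)))
}

#' Projection onto the orthogonal complement of the cis markers
#'
#' Returns the symmetric idempotent matrix
#' \eqn{H_k = I - X_{S_k} (X_{S_k}^T X_{S_k})^{-1} X_{S_k}^T}
#' that annihilates the columns of \eqn{X_{S_k}}.  Applying it to the
#' second-stage response and instruments profiles the cis effects out of
#' the objective.  Rank-deficient \eqn{X_{S_k}} falls back to a
#' pseudo-inverse (projection onto the actual column space) with a
#' warning.
#'
#' @param X n x q exogenous matrix.
#' @param Sk integer vector of marker indices (nonempty).
#' @return n x n numeric matrix. For large n prefer [projectOutCis()],
#'   which applies the projection without forming the matrix.
#' @export
exogenousProjector <- function(X, Sk) {
  n <- nrow(X)
  diag(n) - (X[, Sk, drop = FALSE] %*% .cisProjCoef(X, Sk))
}

# basis of col(X_Sk) via thin SVD; tolerant to collinear markers
.cisBasis <- function(X, Sk) {
  Sk <- as.integer(Sk)
  if (length(Sk) == 0L)
    stop("empty exogenous set: every endogenous variable needs at least one cis marker")
  Xs <- X[, Sk, drop = FALSE]
  sv <- svd(Xs)
  tol <- max(dim(Xs)) * max(sv$d, 0) * .Machine$double.eps
  r <- sum(sv$d > tol)
  if (r < length(Sk))
    warning(sprintf(
      "cis marker block is rank-deficient (rank %d of %d columns); using pseudo-inverse",
      r, length(Sk)))
  sv$u[, seq_len(r), drop = FALSE]
}

# coefficient matrix (X_Sk^T X_Sk)^+ X_Sk^T, via the orthonormal basis
.cisProjCoef <- function(X, Sk) {
  U <- .cisBasis(X, Sk)
  Xs <- X[, Sk, drop = FALSE]
  # Xs = U D V^T  =>  Xs (Xs^T Xs)^+ Xs^T = U U^T; express as Xs %*% coef
  sv <- svd(Xs)
  tol <- max(dim(Xs)) * max(sv$d, 0) * .Machine$double.eps
  keep <- sv$d > tol
  di <- ifelse(keep, 1 / sv$d^2, 0)
  (sv$v %*% (di * t(sv$v))) %*% t(Xs)
}

#' Apply the cis-complement projection to a matrix
#'
#' Computes \eqn{H_k M} for the projector of [exogenousProjector()]
#' without forming the n x n matrix: `M - U (U^T M)` for an orthonormal
#' basis `U` of the cis columns.
#'
#' @param X n x q exogenous matrix.
#' @param Sk integer vector of marker indices.
#' @param M n-row matrix or vector to project.
#' @return projected matrix with the same shape as `M`.
#' @export
projectOutCis <- function(X, Sk, M) {
  U <- .cisBasis(X, Sk)
  M <- as.matrix(M)
  M - U %*% crossprod(U, M)
}
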