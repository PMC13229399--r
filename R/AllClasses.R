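#' @useDynLib semGRN, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' CisMap: unique exogenous (cis) assignments per endogenous variable
#'
#' A `CisMap` assigns each endogenous variable (gene) `k` a nonempty set
#' \eqn{S_k} of exogenous (marker) column indices, with the sets pairwise
#' disjoint across genes.  This is the identifiability assumption of the
#' structural-equation model: each gene owns at least one marker (its
#' cis-eQTL) that appears in no other gene's equation.
#'
#' @slot sets list of integer vectors, one per endogenous variable; element
#'   `k` holds the (1-based) exogenous column indices of \eqn{S_k}.
#' @slot q integer, number of exogenous columns the indices refer to.
#'
#' @seealso [cisMap()], [validateCisMap()]
#' @export
setClass("CisMap",
  representation(sets = "list", q = "integer"))

setValidity("CisMap", function(object) {
  rep <- validateCisMap(object@sets, object@q)
  if (nrow(rep) == 0L) TRUE else
    paste0("invalid cis map: ", paste(rep$message, collapse = "; "))
})

#' StructuralSystem: a linear system of structural equations
#'
#' Holds the parameters of the model \eqn{Y = Y \Gamma + X \Psi + \epsilon}:
#' the p x p matrix of regulatory effects among endogenous variables
#' (`Gamma`, zero diagonal), the q x p matrix of direct exogenous effects
#' (`Psi`, supported on the cis map), the cis map itself, and the per-gene
#' error standard deviations.
#'
#' @slot Gamma p x p numeric matrix, `Gamma[j, k]` is the effect of gene j
#'   on gene k; diagonal is zero.
#' @slot Psi q x p numeric matrix; `Psi[i, k]` nonzero only for
#'   `i` in \eqn{S_k}.
#' @slot cis a [CisMap-class].
#' @slot sigma numeric vector of length p, error SDs per equation.
#'
#' @seealso [structuralSystem()], [reducedForm()], [sampleNetwork()]
#' @export
setClass("StructuralSystem",
  representation(Gamma = "matrix", Psi = "matrix", cis = "CisMap",
                 sigma = "numeric"))

setValidity("StructuralSystem", function(object) {
  p <- ncol(object@Gamma)
  msg <- character()
  if (nrow(object@Gamma) != p)
    msg <- c(msg, "Gamma must be square")
  if (p > 0 && any(abs(diag(object@Gamma)) > 0))
    msg <- c(msg, "Gamma must have zero diagonal")
  if (ncol(object@Psi) != p)
    msg <- c(msg, "Psi must have one column per endogenous variable")
  if (length(object@cis@sets) != p)
    msg <- c(msg, "cis map must have one set per endogenous variable")
  if (object@cis@q != nrow(object@Psi))
    msg <- c(msg, "cis map q must match nrow(Psi)")
  if (length(object@sigma) != p)
    msg <- c(msg, "sigma must have length p")
  if (length(object@sigma) && any(object@sigma < 0))
    msg <- c(msg, "sigma must be nonnegative")
  # off-support entries of Psi must vanish
  if (ncol(object@Psi) == p && length(object@cis@sets) == p) {
    for (k in seq_len(p)) {
      off <- setdiff(seq_len(nrow(object@Psi)), object@cis@sets[[k]])
      if (length(off) && any(abs(object@Psi[off, k]) > 0)) {
        msg <- c(msg, sprintf("Psi column %d has nonzeros outside its cis set", k))
        break
      }
    }
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' SEMData: paired endogenous/exogenous sample matrices
#'
#' Container for an observed dataset: an n x p endogenous matrix `Y`
#' (samples x genes, e.g. expression) and an n x q exogenous matrix `X`
#' (samples x markers, e.g. genotype codes 0/1/2), with row and column
#' labels.
#'
#' @slot Y n x p numeric matrix (endogenous).
#' @slot X n x q numeric matrix (exogenous).
#' @slot sampleIds,geneIds,markerIds character label vectors.
#'
#' @seealso [semData()], [sampleDataset()]
#' @export
setClass("SEMData",
  representation(Y = "matrix", X = "matrix", sampleIds = "character",
                 geneIds = "character", markerIds = "character"))

setValidity("SEMData", function(object) {
  msg <- character()
  if (nrow(object@Y) != nrow(object@X))
    msg <- c(msg, "Y and X must have the same number of rows (samples)")
  if (anyNA(object@Y) || anyNA(object@X))
    msg <- c(msg, "Y and X must not contain missing values")
  if (length(object@sampleIds) != nrow(object@Y))
    msg <- c(msg, "sampleIds length must equal nrow(Y)")
  if (length(object@geneIds) != ncol(object@Y))
    msg <- c(msg, "geneIds length must equal ncol(Y)")
  if (length(object@markerIds) != ncol(object@X))
    msg <- c(msg, "markerIds length must equal ncol(X)")
  if (anyDuplicated(object@geneIds))
    msg <- c(msg, "geneIds must be unique")
  if (anyDuplicated(object@markerIds))
    msg <- c(msg, "markerIds must be unique")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' SimulationDesign: parameters of a synthetic genetical-genomics design
#'
#' Describes one simulated benchmark condition: network size and topology,
#' edge density, number of exogenous effects (EEs, cis markers) per gene,
#' sample size, and the error model, plus the optional robustness variants
#' (inflated error variance, t(3) errors, correlated cis markers, hub
#' nodes).
#'
#' @slot p,q,n integer: endogenous count, exogenous count, sample size.
#' @slot topology `"acyclic"` or `"cyclic"`.
#' @slot edgeMean numeric, mean number of regulatory effects per node
#'   (1 for sparse, 3 for dense designs).
#' @slot eePerGene integer, exogenous effects per gene (1 or 3).
#' @slot errorModel `"gaussian"` or `"student_t"` (t with 3 df, scaled to
#'   the same variance as the Gaussian baseline).
#' @slot errorSD numeric, error standard deviation of the Gaussian model
#'   (default 0.1; the variance-inflation variants double or quadruple the
#'   variance).
#' @slot hubCount,hubEdgeMean integer/numeric: number of hub nodes and
#'   their mean out-degree (0 disables hubs).
#' @slot correlatedEE logical: if `TRUE`, each gene's three cis markers are
#'   correlated (target Pearson 0.8) with effects (1, 0.5, -0.3).
#'
#' @seealso [simulationDesign()], [simulateDataset()]
#' @export
setClass("SimulationDesign",
  representation(p = "integer", q = "integer", n = "integer",
                 topology = "character", edgeMean = "numeric",
                 eePerGene = "integer", errorModel = "character",
                 errorSD = "numeric", hubCount = "integer",
                 hubEdgeMean = "numeric", correlatedEE = "logical"))

setValidity("SimulationDesign", function(object) {
  msg <- character()
  if (object@p < 2L) msg <- c(msg, "p must be at least 2")
  if (object@n < 1L) msg <- c(msg, "n must be at least 1")
  if (object@edgeMean <= 0) msg <- c(msg, "edgeMean must be positive")
  if (!object@topology %in% c("acyclic", "cyclic"))
    msg <- c(msg, "topology must be 'acyclic' or 'cyclic'")
  if (!object@errorModel %in% c("gaussian", "student_t"))
    msg <- c(msg, "errorModel must be 'gaussian' or 'student_t'")
  if (!object@eePerGene %in% c(1L, 3L))
    msg <- c(msg, "eePerGene must be 1 or 3")
  if (object@correlatedEE && object@eePerGene != 3L)
    msg <- c(msg, "correlatedEE requires eePerGene = 3")
  if (object@errorSD <= 0) msg <- c(msg, "errorSD must be positive")
  if (object@q != object@p * object@eePerGene)
    msg <- c(msg, "q must equal p * eePerGene")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Stage1Fit: first-stage ridge fits of the reduced-form equations
#'
#' Per-gene ridge regressions of each endogenous variable on all exogenous
#' variables, with the ridge tuning parameter chosen by generalized
#' cross-validation (GCV).  `ZHat[, j]` is the fitted conditional
#' expectation of gene j given the markers, the optimal instrument used at
#' the second stage.
#'
#' @slot piHat q x p matrix of ridge coefficients.
#' @slot tau numeric vector of selected ridge penalties (one per gene).
#' @slot ZHat n x p matrix of fitted conditional expectations.
#' @slot gcvTrace list of per-gene data.frames with columns `tau`, `gcv`.
#'
#' @seealso [fitFirstStage()]
#' @export
setClass("Stage1Fit",
  representation(piHat = "matrix", tau = "numeric", ZHat = "matrix",
                 gcvTrace = "list"))

setValidity("Stage1Fit", function(object) {
  msg <- character()
  if (length(object@tau) != ncol(object@piHat))
    msg <- c(msg, "tau must have one entry per gene")
  if (length(object@tau) && any(object@tau <= 0))
    msg <- c(msg, "all tau must be positive")
  if (ncol(object@ZHat) != ncol(object@piHat))
    msg <- c(msg, "ZHat and piHat must agree on the number of genes")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Stage2Fit: second-stage adaptive-lasso fit for one endogenous variable
#'
#' The selected regulators and effect estimates for one gene: the adaptive
#' lasso is run on the cis-projected response and instruments, then the cis
#' effects are recovered by profiled least squares.
#'
#' @slot k integer, index of the target gene.
#' @slot gammaHat numeric vector of length p-1, regulatory effect
#'   estimates (ordered as the candidate genes, target excluded).
#' @slot psiHat numeric vector, cis effect estimates for \eqn{S_k}.
#' @slot support integer vector, indices (into 1..p) of selected regulators.
#' @slot omega,gammaTilde numeric vectors: adaptive weights and the initial
#'   estimate they derive from.
#' @slot delta numeric, adaptive-weight exponent.
#' @slot lambda numeric, the cross-validation-selected lasso penalty.
#' @slot cvCurve data.frame with columns `lambda`, `cvError`.
#'
#' @seealso [fitSecondStage()]
#' @export
setClass("Stage2Fit",
  representation(k = "integer", gammaHat = "numeric", psiHat = "numeric",
                 support = "integer", omega = "numeric",
                 gammaTilde = "numeric", delta = "numeric",
                 lambda = "numeric", cvCurve = "data.frame"))

#' NetworkEstimate: a fitted regulatory network
#'
#' The assembled result of running 2SPLS (or one of the AL / 2SAL
#' baselines) on a dataset: estimated regulatory effects `GammaHat`
#' (`GammaHat[j, k]` is the effect of gene j on gene k), estimated cis
#' effects `PsiHat`, the per-gene second-stage fits, and run metadata
#' (seed, tuning settings, timing).
#'
#' @slot GammaHat p x p numeric matrix, zero diagonal.
#' @slot PsiHat q x p numeric matrix, supported on the cis map.
#' @slot method `"2SPLS"`, `"AL"` or `"2SAL"`.
#' @slot perGene list of [Stage2Fit-class] objects.
#' @slot metadata list (seed, options, timing).
#'
#' @seealso [fitNetwork()]
#' @export
setClass("NetworkEstimate",
  representation(GammaHat = "matrix", PsiHat = "matrix", method = "character",
                 perGene = "list", metadata = "list"))

setValidity("NetworkEstimate", function(object) {
  msg <- character()
  if (nrow(object@GammaHat) != ncol(object@GammaHat))
    msg <- c(msg, "GammaHat must be square")
  if (any(abs(diag(object@GammaHat)) > 0))
    msg <- c(msg, "GammaHat must have zero diagonal")
  if (!object@method %in% c("2SPLS", "AL", "2SAL"))
    msg <- c(msg, "method must be one of 2SPLS, AL, 2SAL")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' BootstrapSummary: edge selection frequencies over bootstrap resamples
#'
#' Paired-bootstrap stability of the fitted network: `freq[j, k]` is the
#' fraction of resamples in which the edge j -> k was selected, and
#' `signConsistency[j, k]` the fraction of those selections agreeing with
#' the modal sign.
#'
#' @slot B integer, number of bootstrap resamples attempted.
#' @slot nFailed integer, resamples that failed to fit (excluded).
#' @slot freq p x p numeric matrix in `[0, 1]`, zero diagonal.
#' @slot signConsistency p x p numeric matrix in `[0, 1]`.
#'
#' @seealso [bootstrapNetwork()]
#' @export
setClass("BootstrapSummary",
  representation(B = "integer", nFailed = "integer", freq = "matrix",
                 signConsistency = "matrix"))

setValidity("BootstrapSummary", function(object) {
  msg <- character()
  if (any(object@freq < 0 | object@freq > 1))
    msg <- c(msg, "freq entries must lie in [0, 1]")
  if (any(abs(diag(object@freq)) > 0))
    msg <- c(msg, "freq diagonal must be zero")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' EvaluationReport: power/FDR of a method over simulation replicates
#'
#' @slot design a [SimulationDesign-class].
#' @slot method character, method name.
#' @slot perReplicate data.frame with one row per replicate
#'   (`replicate`, `TP`, `FP`, `FN`, `power`, `fdr`, `wrongSign`).
#' @slot nFailed integer, replicates that failed and were excluded.
#'
#' @seealso [runBenchmark()]
#' @export
setClass("EvaluationReport",
  representation(design = "SimulationDesign", method = "character",
                 perReplicate = "data.frame", nFailed = "integer"))
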