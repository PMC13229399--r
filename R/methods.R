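# Accessor generics and show methods.

#' @rdname accessors
#' @param object an object from this package.
#' @export
setGeneric("gammaHat", function(object) standardGeneric("gammaHat"))
#' @rdname accessors
#' @export
setGeneric("psiHat", function(object) standardGeneric("psiHat"))
#' @rdname accessors
#' @export
setGeneric("edgeSupport", function(object) standardGeneric("edgeSupport"))
#' @rdname accessors
#' @export
setGeneric("bootFreq", function(object) standardGeneric("bootFreq"))
#' @rdname accessors
#' @export
setGeneric("cisSets", function(object) standardGeneric("cisSets"))
#' @rdname accessors
#' @export
setGeneric("fittedInstruments", function(object)
  standardGeneric("fittedInstruments"))

#' Accessors for semGRN objects
#'
#' `gammaHat()` returns the estimated regulatory-effect matrix (or the
#' per-gene coefficient vector of a [Stage2Fit-class]); `psiHat()` the
#' estimated exogenous effects; `edgeSupport()` the selected edges;
#' `bootFreq()` the bootstrap selection-frequency matrix; `cisSets()` the
#' list of per-gene marker index sets; `fittedInstruments()` the
#' first-stage fitted conditional expectations.
#'
#' @name accessors
#' @rdname accessors
NULL

#' @rdname accessors
#' @export
setMethod("gammaHat", "NetworkEstimate", function(object) object@GammaHat)
#' @rdname accessors
#' @export
setMethod("gammaHat", "Stage2Fit", function(object) object@gammaHat)
#' @rdname accessors
#' @export
setMethod("psiHat", "NetworkEstimate", function(object) object@PsiHat)
#' @rdname accessors
#' @export
setMethod("psiHat", "Stage2Fit", function(object) object@psiHat)
#' @rdname accessors
#' @export
setMethod("edgeSupport", "NetworkEstimate", function(object) {
  which(abs(object@GammaHat) > 0, arr.ind = TRUE)
})
#' @rdname accessors
#' @export
setMethod("edgeSupport", "Stage2Fit", function(object) object@support)
#' @rdname accessors
#' @export
setMethod("bootFreq", "BootstrapSummary", function(object) object@freq)
#' @rdname accessors
#' @export
setMethod("cisSets", "CisMap", function(object) object@sets)
#' @rdname accessors
#' @export
setMethod("cisSets", "StructuralSystem", function(object) object@cis@sets)
#' @rdname accessors
#' @export
setMethod("fittedInstruments", "Stage1Fit", function(object) object@ZHat)

#' @export
setMethod("show", "CisMap", function(object) {
  cat(sprintf("CisMap: %d endogenous variables over %d exogenous columns\n",
              length(object@sets), object@q))
  sizes <- lengths(object@sets)
  cat(sprintf("  markers per gene: min %d, max %d\n",
              min(sizes), max(sizes)))
})

#' @export
setMethod("show", "StructuralSystem", function(object) {
  p <- ncol(object@Gamma)
  cat(sprintf("StructuralSystem: p = %d endogenous, q = %d exogenous\n",
              p, nrow(object@Psi)))
  cat(sprintf("  regulatory effects: %d; stability margin %.3g\n",
              sum(abs(object@Gamma) > 0), .stabilityMargin(object@Gamma)))
})

#' @export
setMethod("show", "SEMData", function(object) {
  cat(sprintf("SEMData: %d samples, %d endogenous (Y), %d exogenous (X)\n",
              nrow(object@Y), ncol(object@Y), ncol(object@X)))
})

#' @export
setMethod("show", "SimulationDesign", function(object) {
  cat(sprintf(
    "SimulationDesign: p = %d, q = %d, n = %d, %s, mean out-degree %g, %d EE/gene\n",
    object@p, object@q, object@n, object@topology, object@edgeMean,
    object@eePerGene))
  cat(sprintf("  errors: %s (SD %g)%s%s\n", object@errorModel,
              object@errorSD,
              if (object@hubCount > 0)
                sprintf("; %d hub nodes (mean out-degree %g)",
                        object@hubCount, object@hubEdgeMean) else "",
              if (object@correlatedEE) "; correlated cis markers" else ""))
})

#' @export
setMethod("show", "Stage1Fit", function(object) {
  cat(sprintf("Stage1Fit: %d genes, %d exogenous variables\n",
              ncol(object@piHat), nrow(object@piHat)))
  cat(sprintf("  ridge penalties (GCV): median %.3g [%.3g, %.3g]\n",
              stats::median(object@tau), min(object@tau), max(object@tau)))
})

#' @export
setMethod("show", "Stage2Fit", function(object) {
  cat(sprintf("Stage2Fit: gene %d, %d selected regulators, lambda = %.3g\n",
              object@k, length(object@support), object@lambda))
})

#' @export
setMethod("show", "NetworkEstimate", function(object) {
  cat(sprintf("NetworkEstimate (%s): %d genes, %d edges\n",
              object@method, ncol(object@GammaHat),
              sum(abs(object@GammaHat) > 0)))
  if (!is.null(object@metadata$elapsed))
    cat(sprintf("  fitted in %.1f s (seed %s)\n", object@metadata$elapsed,
                as.character(object@metadata$seed)))
})

#' @export
setMethod("show", "BootstrapSummary", function(object) {
  cat(sprintf("BootstrapSummary: B = %d (%d failed)\n", object@B,
              object@nFailed))
  for (thr in c(0.8, 0.9, 0.95))
    cat(sprintf("  edges at frequency >= %.2f: %d\n", thr,
                sum(object@freq >= thr)))
})

#' @export
setMethod("show", "EvaluationReport", function(object) {
  tab <- object@perReplicate
  cat(sprintf("EvaluationReport: %s, %d replicates (%d failed)\n",
              object@method, nrow(tab), object@nFailed))
  if (nrow(tab))
    cat(sprintf("  power %.3f (SD %.3f), FDR %.3f (SD %.3f)\n",
                mean(tab$power), stats::sd(tab$power), mean(tab$fdr),
                stats::sd(tab$fdr)))
})
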