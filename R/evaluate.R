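#' Score an estimated network against the truth
#'
#' A directed edge j -> k (j != k) counts as detected when
#' `|GammaHat[j, k]|` exceeds the detection threshold.  Power is
#' TP / (TP + FN); FDR is FP / (TP + FP), defined as 0 when nothing is
#' discovered.  Detection ignores the estimated sign (a true edge
#' recovered with the wrong sign is still a true positive); the fraction
#' of true positives with the wrong sign is reported separately.
#'
#' @param GammaHat,GammaTrue p x p effect matrices with zero diagonals.
#' @param threshold absolute-value detection threshold.
#' @return one-row data.frame with columns `TP`, `FP`, `FN`, `power`,
#'   `fdr`, `wrongSign`.
#' @examples
#' G <- matrix(0, 3, 3); G[1, 2] <- 0.8
#' scoreNetwork(G, G)   # power 1, fdr 0
#' @export
scoreNetwork <- function(GammaHat, GammaTrue, threshold = 1e-8) {
  GammaHat <- as.matrix(GammaHat); GammaTrue <- as.matrix(GammaTrue)
  if (!all(dim(GammaHat) == dim(GammaTrue)))
    stop("GammaHat and GammaTrue must have the same shape")
  off <- row(GammaHat) != col(GammaHat)
  est <- abs(GammaHat) > threshold & off
  tru <- abs(GammaTrue) > threshold & off
  TP <- sum(est & tru)
  FP <- sum(est & !tru)
  FN <- sum(!est & tru)
  wrong <- sum(est & tru & (sign(GammaHat) != sign(GammaTrue)))
  data.frame(TP = TP, FP = FP, FN = FN,
             power = if (TP + FN > 0) TP / (TP + FN) else 0,
             fdr = FP / max(TP + FP, 1),
             wrongSign = if (TP > 0) wrong / TP else 0)
}

#' Run a simulation benchmark over designs and methods
#'
#' For each design, simulates `nReplicates` datasets (replicate seeds
#' derive deterministically from the master seed, and every method sees
#' the same datasets), fits each requested method, and scores the
#' estimated network against the simulated truth.  Replicates whose fit
#' fails are logged and excluded, with the count reported.
#'
#' @param designs a [SimulationDesign-class] or list of them.
#' @param methods character vector among `"2SPLS"`, `"AL"`, `"2SAL"`.
#' @param nReplicates replicates per design.
#' @param seed master seed.
#' @param workers parallel workers passed to the fitters.
#' @param ... further arguments passed to [fitNetwork()].
#' @return list of [EvaluationReport-class], one per design x method.
#' @export
runBenchmark <- function(designs, methods = "2SPLS", nReplicates = 10L,
                         seed = 1L, workers = 1L, ...) {
  if (is(designs, "SimulationDesign")) designs <- list(designs)
  reports <- list()
  for (di in seq_along(designs)) {
    design <- designs[[di]]
    scores <- replicate(length(methods), list(), simplify = FALSE)
    names(scores) <- methods
    failed <- stats::setNames(integer(length(methods)), methods)
    for (r in seq_len(nReplicates)) {
      simSeed <- deriveSeed(seed, (di - 1L) * nReplicates + r)
      sim <- simulateDataset(design, seed = simSeed)
      cis <- sim$system@cis
      if (design@correlatedEE)
        cis <- selectStrongestCis(sim$data, cis)
      for (m in methods) {
        est <- tryCatch(
          fitNetwork(sim$data, cis, method = m, seed = simSeed,
                     workers = workers, ...),
          error = function(e) {
            warning(sprintf("replicate %d, method %s failed: %s",
                            r, m, conditionMessage(e)))
            NULL
          })
        if (is.null(est)) {
          failed[m] <- failed[m] + 1L
          next
        }
        sc <- scoreNetwork(est@GammaHat, sim$system@Gamma)
        sc$replicate <- r
        scores[[m]][[length(scores[[m]]) + 1L]] <- sc
      }
    }
    for (m in methods) {
      tab <- if (length(scores[[m]])) do.call(rbind, scores[[m]])
             else data.frame(TP = integer(), FP = integer(), FN = integer(),
                             power = numeric(), fdr = numeric(),
                             wrongSign = numeric(), replicate = integer())
      reports[[length(reports) + 1L]] <-
        new("EvaluationReport", design = design, method = m,
            perReplicate = tab, nFailed = failed[[m]])
    }
  }
  reports
}

#' Summarize evaluation reports as a long-format table
#'
#' @param reports list of [EvaluationReport-class] (as returned by
#'   [runBenchmark()]).
#' @return data.frame with one row per design x method: mean/SD of power
#'   and FDR across replicates, pooled counts, and the failure count.
#' @export
summarizeBenchmark <- function(reports) {
  if (is(reports, "EvaluationReport")) reports <- list(reports)
  do.call(rbind, lapply(reports, function(rp) {
    tab <- rp@perReplicate
    data.frame(
      p = rp@design@p, n = rp@design@n, topology = rp@design@topology,
      edgeMean = rp@design@edgeMean, eePerGene = rp@design@eePerGene,
      method = rp@method, nReplicates = nrow(tab), nFailed = rp@nFailed,
      powerMean = mean(tab$power), powerSD = stats::sd(tab$power),
      fdrMean = mean(tab$fdr), fdrSD = stats::sd(tab$fdr),
      pooledTP = sum(tab$TP), pooledFP = sum(tab$FP), pooledFN = sum(tab$FN))
  }))
}
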