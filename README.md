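# semGRN

Constructing large systems of structural equations — gene regulatory
networks inferred from paired expression and genotype data — by
**two-stage penalized least squares (2SPLS)**.

## The problem

Genetical-genomics experiments measure, on the same individuals, the
expression of many genes (an n × p matrix *Y*) and the genotypes at
many marker loci (an n × q matrix *X*). The regulatory wiring among
the genes and the direct genetic effects on each gene are jointly
described by a system of structural equations

    Y = Y Γ + X Ψ + ε,

with Γ (p × p, zero diagonal) the directed regulatory effects and Ψ
(q × p) the cis effects. Each gene *k* owns a known, exclusive set
S\_k of cis markers — the identification assumption. Because the
other genes' expressions Y₋ₖ are correlated with each equation's
error, naive per-equation regression is biased; the classical fix,
two-stage least squares, needs more samples than variables and so
fails at genomic scale (p, q ≥ n).

2SPLS extends the instrumental-variables idea to that scale:

* **Stage 1** — ridge regression of every gene on all markers, with the
  penalty chosen by generalized cross-validation, giving fitted
  conditional expectations Ẑⱼ = P\_τⱼYⱼ (the instruments);
* **Stage 2** — per gene, the cis effects are profiled out in closed
  form and the regulators are selected by an adaptive lasso on
  (H\_kY\_k, H\_kẐ₋ₖ), with the penalty chosen by fold-honest K-fold
  cross-validation (the first stage is re-estimated inside every
  training fold; see the methods vignette for why that matters).

The package also provides the single-equation adaptive-lasso baseline
(AL), the two-stage adaptive lasso (2SAL), paired-bootstrap edge
confidence, a simulator for benchmark network designs, a power/FDR
evaluation harness, TSV input/output, and a small command-line
interface (`inst/scripts/semgrn`).

## A worked example

```r
library(semGRN)

design <- simulationDesign(p = 50, n = 200)   # sparse acyclic network
sim <- simulateDataset(design, seed = 7)
sim$system
#> StructuralSystem: p = 50 endogenous, q = 50 exogenous
#>   regulatory effects: 49; stability margin 0.247

est <- fitNetwork(sim$data, cisSets(sim$system@cis), method = "2SPLS",
                  seed = 1)
est
#> NetworkEstimate (2SPLS): 50 genes, 60 edges
#>   fitted in 0.8 s (seed 1)

scoreNetwork(gammaHat(est), sim$system@Gamma)
#>   TP FP FN power       fdr wrongSign
#> 1 49 11  0     1 0.1833333         0
```

The fitted network recovered all 49 true directed effects (power 1.0)
at the cost of 11 false edges (FDR 0.18). `edgeSupport(est)` lists the edges,
`psiHat(est)` the cis-effect estimates, and
`bootstrapNetwork(sim$data, cisSets(sim$system@cis), B = 100, seed = 1)`
attaches selection frequencies for confidence filtering; `writeEdgeList()`
serializes any of this to TSV.

From a shell, the same analysis is:

```sh
Rscript inst/scripts/semgrn simulate --design design.yaml --out simdir --seed 7
Rscript inst/scripts/semgrn fit --y simdir/Y.tsv --x simdir/X.tsv \
    --cis simdir/cis.tsv --method 2spls --out edges.tsv --seed 1
Rscript inst/scripts/semgrn evaluate --edges edges.tsv \
    --truth-gamma simdir/truth_gamma.tsv --out report.tsv
```

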