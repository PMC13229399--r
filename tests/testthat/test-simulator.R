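test_that("identical design and seed give bit-identical datasets", {
  d <- simulationDesign(p = 20, n = 30)
  a <- simulateDataset(d, seed = 3)
  b <- simulateDataset(d, seed = 3)
  expect_identical(a$data@Y, b$data@Y)
  expect_identical(a$data@X, b$data@X)
  expect_identical(a$system@Gamma, b$system@Gamma)
  c <- simulateDataset(d, seed = 4)
  expect_false(identical(a$data@Y, c$data@Y))
})

test_that("sampled regulatory effects stay in the prescribed magnitude band", {
  d <- simulationDesign(p = 50, n = 10, edgeMean = 3)
  sys <- sampleNetwork(d, seed = 9)
  eff <- abs(sys@Gamma[sys@Gamma != 0])
  expect_gt(length(eff), 0)
  expect_true(all(eff > 0.5 & eff < 1))
  # both signs occur
  expect_true(any(sys@Gamma > 0) && any(sys@Gamma < 0))
})

test_that("acyclic networks admit a topological order", {
  d <- simulationDesign(p = 40, n = 10)
  for (s in 1:3) {
    A <- sampleNetwork(d, seed = s)@Gamma != 0
    # nilpotency of the adjacency matrix certifies acyclicity
    M <- A * 1
    for (i in seq_len(ceiling(log2(40)) + 1)) M <- (M %*% M) > 0
    expect_true(all(M == 0))
  }
})

test_that("sparse networks carry about one edge per node on average", {
  d <- simulationDesign(p = 300, n = 10)
  counts <- vapply(1:5, function(s)
    sum(sampleNetwork(d, seed = s)@Gamma != 0), numeric(1))
  # expected 300 edges; allow 3 * sqrt(300) around the mean count
  expect_lt(abs(mean(counts) - 300), 3 * sqrt(300))
})

test_that("cyclic sampling yields stable systems containing cycles", {
  d <- simulationDesign(p = 30, n = 10, topology = "cyclic", edgeMean = 2)
  sys <- sampleNetwork(d, seed = 2)
  expect_gt(semGRN:::.stabilityMargin(sys@Gamma), 1e-8)
  # with 60 expected edges on 30 nodes a cycle is essentially certain
  A <- (sys@Gamma != 0) * 1
  M <- A
  hasCycle <- FALSE
  for (i in 1:30) {
    M <- (M %*% A) > 0
    if (any(diag(M) > 0)) { hasCycle <- TRUE; break }
  }
  expect_true(hasCycle)
})

test_that("genotypes match the F2 frequencies and moments", {
  X <- sampleGenotypes(1e5, 1, seed = 12)
  expect_true(all(X %in% c(0, 1, 2)))
  expect_lt(abs(mean(X == 1) - 0.5), 0.01)
  expect_lt(abs(mean(X) - 1), 0.01)
  expect_lt(abs(var(drop(X)) - 0.5), 0.01)
})

test_that("correlated marker triples attain the target correlation", {
  X <- sampleGenotypes(1e5, 3, seed = 13, correlatedEE = TRUE)
  r <- cor(X)[upper.tri(diag(3))]
  expect_true(all(abs(r - 0.8) < 0.02))
  # marginals preserved under the copula
  expect_lt(abs(mean(X == 1) - 0.5), 0.01)
  expect_lt(abs(mean(X == 0) - 0.25), 0.01)
})

test_that("datasets satisfy the structural identity exactly", {
  d <- simulationDesign(p = 15, n = 25, topology = "cyclic", edgeMean = 1.5)
  sim <- simulateDataset(d, seed = 21)
  G <- sim$system@Gamma; P <- sim$system@Psi
  eps <- sim$data@Y %*% (diag(15) - G) - sim$data@X %*% P
  # recovered errors have the design SD (loose statistical band)
  expect_lt(abs(sd(eps) - 0.1), 0.03)
  # identity route: rebuilding Y from the recovered errors is exact
  Y2 <- t(solve(t(diag(15) - G), t(sim$data@X %*% P + eps)))
  expect_equal(Y2, sim$data@Y, tolerance = 1e-12)
})

test_that("student-t errors are variance-matched to the gaussian model", {
  sys <- chainSystem()
  X <- sampleGenotypes(20000, 3, seed = 31)
  dat <- sampleDataset(sys, X, errorModel = "student_t", seed = 32)
  eps <- dat@Y %*% (diag(3) - sys@Gamma) - X %*% sys@Psi
  expect_lt(abs(sd(eps) - 0.1), 0.02)
  expect_gt(mean(abs(eps / 0.1) > 3), 0.005)  # heavier tails than normal
})

test_that("hub designs concentrate out-degree on the hub nodes", {
  d <- simulationDesign(p = 100, n = 10, hubCount = 6, hubEdgeMean = 5)
  outs <- sapply(1:8, function(s) {
    deg <- rowSums(sampleNetwork(d, seed = s)@Gamma != 0)
    sort(deg, decreasing = TRUE)[1:6]
  })
  # six hubs at mean 5 against a background of mean 1
  expect_gt(mean(outs), 3)
})

test_that("every emitted system passes validation and stability", {
  for (s in 1:3) {
    d <- simulationDesign(p = 25, n = 10,
                          topology = if (s == 2) "cyclic" else "acyclic",
                          eePerGene = if (s == 3) 3L else 1L)
    sys <- sampleNetwork(d, seed = s)
    expect_identical(nrow(validateCisMap(sys@cis)), 0L)
    expect_gt(semGRN:::.stabilityMargin(sys@Gamma), 1e-8)
    expect_true(validObject(sys))
  }
})

test_that("correlated-EE designs use effects (1, 0.5, -0.3)", {
  d <- simulationDesign(p = 10, n = 10, eePerGene = 3L, correlatedEE = TRUE)
  sys <- sampleNetwork(d, seed = 41)
  expect_equal(sys@Psi[sys@cis@sets[[4]], 4], c(1, 0.5, -0.3))
})

test_that("the strongest-cis filter keeps the dominant marker", {
  # gene 1's expression driven by marker 2 of its three candidates
  semGRN:::withSeed(55, {
    X <- sampleGenotypes(200, 3)
    Y <- cbind(X[, 2] * 1.0 + rnorm(200, sd = 0.1))
  })
  cm <- cisMap(list(1:3), q = 3L)
  filtered <- selectStrongestCis(semData(Y, X), cm)
  expect_identical(filtered@sets[[1]], 2L)
})
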