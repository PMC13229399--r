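test_that("profiled cis effects reduce to OLS when gamma is zero", {
  semGRN:::withSeed(1, {
    Xs <- matrix(rnorm(60), 30, 2)
    Z <- matrix(rnorm(90), 30, 3)
    y <- drop(Xs %*% c(1, -2)) + rnorm(30, sd = 0.1)
  })
  expect_equal(profilePsi(y, Z, rep(0, 3), Xs),
               unname(coef(lm(y ~ Xs - 1))), tolerance = 1e-10)
  # exact fit recovered exactly
  y0 <- drop(Xs %*% c(0.5, 2))
  expect_equal(profilePsi(y0, Z, rep(0, 3), Xs), c(0.5, 2),
               tolerance = 1e-10)
})

test_that("profiling attains the partial minimum over psi for any gamma", {
  semGRN:::withSeed(2, {
    Xs <- matrix(rnorm(40), 20, 2)
    Z <- matrix(rnorm(60), 20, 3)
    y <- rnorm(20)
    gam <- rnorm(3)
  })
  psi <- profilePsi(y, Z, gam, Xs)
  obj <- function(ps) sum((y - Z %*% gam - Xs %*% ps)^2)
  for (i in 1:10) {
    other <- psi + rnorm(2, sd = 0.3)
    expect_lte(obj(psi), obj(other) + 1e-10)
  }
})

test_that("initial estimate recovers exact coefficients without noise", {
  semGRN:::withSeed(3, {
    Z <- qr.Q(qr(matrix(rnorm(200), 40, 5)))
    gam <- c(1, -0.5, 2, 0, 0.3)
  })
  y <- drop(Z %*% gam)
  expect_equal(initialEstimate(y, Z), gam, tolerance = 1e-10)
})

test_that("initial estimate equals textbook 2SLS on a three-gene system", {
  sys <- chainSystem(g12 = 0.8, g23 = -0.7)
  dat <- simulateFromSystem(sys, 200, seed = 44)
  X <- dat@X; Y <- dat@Y
  # textbook two-stage least squares for equation 3 (regulator candidates
  # are genes 1 and 2, instrumented by all markers; own marker exogenous)
  Zhat <- cbind(fitted(lm(Y[, 1] ~ X - 1)), fitted(lm(Y[, 2] ~ X - 1)))
  tsls <- coef(lm(Y[, 3] ~ Zhat + X[, 3] - 1))
  HY <- projectOutCis(X, 3L, Y[, 3])
  HZ <- projectOutCis(X, 3L, Zhat)
  expect_equal(unname(initialEstimate(drop(HY), HZ, dfCis = 1L)),
               unname(tsls[1:2]), tolerance = 1e-8)
})

test_that("initial estimate stays finite in the high-dimensional regime", {
  semGRN:::withSeed(4, {
    Z <- matrix(rnorm(20 * 50), 20, 50)
    y <- rnorm(20)
  })
  est <- suppressWarnings(initialEstimate(y, Z))
  expect_true(all(is.finite(est)))
  expect_length(est, 50)
})

test_that("adaptive weights follow the inverse-power law", {
  expect_equal(adaptiveWeights(c(1, 1), delta = 1),
               rep(1 / (1 + 1e-6), 2))
  g <- c(0.1, 0.5, 2)
  w <- adaptiveWeights(g, delta = 1)
  expect_true(all(diff(w) < 0))  # larger pilot => smaller weight
  w2 <- adaptiveWeights(g, delta = 2)
  # delta = 2 squares the weight ratios (up to the tiny stabilizer)
  expect_equal(w2[1] / w2[3], (w[1] / w[3])^2, tolerance = 1e-3)
  expect_error(adaptiveWeights(g, delta = 0), "positive")
  expect_equal(adaptiveWeights(c(0, 0)), c(1, 1))
})

test_that("the weighted lasso matches its null-solution KKT bound", {
  semGRN:::withSeed(5, {
    HZ <- matrix(rnorm(200), 40, 5)
    HY <- rnorm(40)
  })
  omega <- c(0.5, 1, 2, 1, 3)
  lmax <- max(abs(crossprod(HZ, HY)) / omega)
  expect_equal(adaLassoFit(HY, HZ, omega, lmax * 1.0001), rep(0, 5))
  expect_true(any(adaLassoFit(HY, HZ, omega, lmax * 0.99) != 0))
})

test_that("orthonormal designs give the soft-threshold closed form", {
  semGRN:::withSeed(6, {
    HZ <- qr.Q(qr(matrix(rnorm(240), 40, 6)))
    HY <- rnorm(40)
  })
  omega <- c(1, 2, 0.5, 1, 1.5, 1)
  lambda <- 0.4
  z <- drop(crossprod(HZ, HY))
  closed <- sign(z) * pmax(abs(z) - lambda * omega, 0)
  expect_equal(adaLassoFit(HY, HZ, omega, lambda), closed,
               tolerance = 1e-9)
})

test_that("lambda = 0 with full rank reproduces ordinary least squares", {
  semGRN:::withSeed(7, {
    HZ <- matrix(rnorm(30 * 4), 30, 4)
    HY <- rnorm(30)
  })
  expect_equal(adaLassoFit(HY, HZ, rep(1, 4), 0),
               unname(coef(lm(HY ~ HZ - 1))), tolerance = 1e-7)
})

test_that("coordinate descent matches a generic convex solver and glmnet", {
  skip_if_not_installed("glmnet")
  for (s in 1:6) {
    semGRN:::withSeed(100 + s, {
      n <- sample(15:40, 1)
      m <- sample(2:6, 1)
      HZ <- matrix(rnorm(n * m), n, m)
      gam <- rnorm(m) * rbinom(m, 1, 0.6)
      HY <- drop(HZ %*% gam) + rnorm(n, sd = 0.5)
      omega <- runif(m, 0.3, 3)
    })
    lambda <- 0.3 * max(abs(crossprod(HZ, HY)) / omega)
    mine <- adaLassoFit(HY, HZ, omega, lambda)
    oracle <- proxGradWLasso(HY, HZ, omega, lambda)
    expect_equal(mine, oracle, tolerance = 1e-6)
    # objective can only be at least as good as the oracle's
    expect_lte(wlassoObjective(HY, HZ, omega, lambda, mine),
               wlassoObjective(HY, HZ, omega, lambda, oracle) + 1e-9)
    # glmnet solves (1/2n)||y - Zb||^2 + lam * sum(pf_j |b_j|) with
    # penalty.factor rescaled to sum to m; undo both conventions
    pf <- omega * m / sum(omega)
    gl <- glmnet::glmnet(HZ, HY, lambda = lambda * sum(omega) / (m * n),
                         penalty.factor = pf, standardize = FALSE,
                         intercept = FALSE, thresh = 1e-14)
    expect_equal(mine, drop(as.matrix(gl$beta)), tolerance = 1e-4,
                 ignore_attr = TRUE)
  }
})

test_that("the gram and factored solver modes agree", {
  semGRN:::withSeed(8, {
    F <- matrix(rnorm(20 * 35), 20, 35)  # r < m: rank-deficient Gram
    y <- rnorm(20)
    omega <- runif(35, 0.5, 2)
  })
  cvec <- drop(crossprod(F, y))
  G <- crossprod(F)
  lam <- semGRN:::lambdaPath(cvec, omega, 20L, 1e-2)
  a <- semGRN:::.cdWLassoPathImpl(G, FALSE, cvec, omega, lam, 1e-9,
                                  100000L, 19L, sum(y^2), 0.999)
  b <- semGRN:::.cdWLassoPathImpl(F, TRUE, cvec, omega, lam, 1e-9,
                                  100000L, 19L, sum(y^2), 0.999)
  expect_equal(a$beta, b$beta, tolerance = 1e-6)
})

test_that("descent property holds at the fitted solution", {
  semGRN:::withSeed(9, {
    HZ <- matrix(rnorm(25 * 8), 25, 8)
    HY <- rnorm(25)
    omega <- runif(8, 0.5, 2)
  })
  lambda <- 0.2 * max(abs(crossprod(HZ, HY)) / omega)
  fit <- adaLassoFit(HY, HZ, omega, lambda)
  expect_lte(wlassoObjective(HY, HZ, omega, lambda, fit),
             wlassoObjective(HY, HZ, omega, lambda, numeric(8)))
})

test_that("cross-validation keeps a pure-noise model near the null", {
  semGRN:::withSeed(10, {
    HZ <- matrix(rnorm(60 * 10), 60, 10)
    HY <- rnorm(60)
  })
  omega <- rep(1, 10)
  sel <- selectLambdaCV(HY, HZ, omega, seed = 3)
  # selected penalty is in the top decade of the path
  expect_gte(sel$lambda, max(sel$path) * 0.1)
  fit <- adaLassoFit(HY, HZ, omega, sel$lambda)
  expect_lte(sum(fit != 0), 2)
})

test_that("cross-validation keeps a strong predictor", {
  hits <- 0L
  for (s in 1:20) {
    semGRN:::withSeed(200 + s, {
      HZ <- matrix(rnorm(50 * 8), 50, 8)
      HY <- drop(HZ %*% c(2, rep(0, 7))) + rnorm(50, sd = 0.3)
    })
    gt <- initialEstimate(HY, HZ)
    sel <- selectLambdaCV(HY, HZ, adaptiveWeights(gt), seed = s)
    fit <- adaLassoFit(HY, HZ, adaptiveWeights(gt), sel$lambda)
    if (fit[1] != 0) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("penalty selection is deterministic under a fixed seed", {
  semGRN:::withSeed(11, {
    HZ <- matrix(rnorm(40 * 6), 40, 6)
    HY <- rnorm(40)
  })
  omega <- rep(1, 6)
  a <- selectLambdaCV(HY, HZ, omega, seed = 9)
  b <- selectLambdaCV(HY, HZ, omega, seed = 9)
  expect_identical(a$lambda, b$lambda)
  expect_identical(a$curve, b$curve)
})

test_that("second-stage fits are invariant to candidate gene relabeling", {
  sys <- chainSystem()
  dat <- simulateFromSystem(sys, 150, seed = 77)
  cm <- sys@cis
  fit <- suppressWarnings(
    fitNetwork(dat, cm, method = "2SPLS", seed = 4))
  # permute genes 1 and 2 (and their markers) and refit
  perm <- c(2L, 1L, 3L)
  dat2 <- semData(dat@Y[, perm], dat@X[, perm])
  fit2 <- suppressWarnings(
    fitNetwork(dat2, cisMap(list(1L, 2L, 3L), 3L), method = "2SPLS",
               seed = 4))
  G1 <- unname(gammaHat(fit))
  G2 <- unname(gammaHat(fit2))
  expect_equal(G2[perm, perm], G1, tolerance = 1e-6)
})

test_that("three-gene chain support is recovered across seeds", {
  hits <- 0L
  for (s in 1:25) {
    sys <- chainSystem()
    dat <- simulateFromSystem(sys, 300, seed = 500 + s)
    est <- suppressWarnings(fitNetwork(dat, sys@cis, seed = s))
    G <- unname(gammaHat(est))
    ok <- G[1, 2] != 0 && G[2, 3] != 0 &&
      sum(G != 0) == 2
    if (ok) hits <- hits + 1L
  }
  expect_gte(hits, 22L)  # >= ~88% exact support recovery
})

test_that("a null system yields a near-empty estimate", {
  sys <- structuralSystem(matrix(0, 6, 6), diag(6),
                          as.list(1:6), sigma = 0.1)
  dat <- simulateFromSystem(sys, 200, seed = 91)
  est <- suppressWarnings(fitNetwork(dat, sys@cis, seed = 2))
  expect_lte(sum(gammaHat(est) != 0), 2)
})
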