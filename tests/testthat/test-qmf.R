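test_that("Q is the row-scaled adjacency, with the CP reduction", {
  # 2-node single edge, delta = (2, 4): Q = [[0, 1/2], [1/4, 0]]
  net <- dyadNetwork()
  Q <- buildQ(net, manualRates(c(2, 4)))
  expect_equal(as.matrix(Q), matrix(c(0, 1 / 4, 1 / 2, 0), 2),
               ignore_attr = TRUE)

  # homogeneous delta = 1, uniform scheme: Q = A
  ring <- ringNetwork(6)
  Q <- buildQ(ring, homogeneousRates(6))
  expect_equal(as.matrix(Q), as.matrix(adjacency(ring)),
               ignore_attr = TRUE)

  # contact process at delta = 1: rows of Q sum to 1 (transition matrix P)
  star <- starNetwork(4)
  Q <- buildQ(star, homogeneousRates(5), contactProcessScheme())
  expect_equal(as.numeric(Matrix::rowSums(Q)), rep(1, 5))
  expect_true(all(Matrix::diag(Q) == 0))

  disco <- edgeNetwork(rbind(c(1, 2), c(3, 4)), 4)
  expect_error(buildQ(disco, homogeneousRates(4)), "connected")
})

test_that("leading eigenpair matches closed forms and a dense oracle", {
  # star K_{1,n}: Lambda_max(A) = sqrt(n)
  for (n in c(4, 9)) {
    star <- starNetwork(n)
    ep <- leadingEigenpair(buildQ(star, homogeneousRates(n + 1)))
    expect_equal(ep$value, sqrt(n), tolerance = 1e-10)
  }
  # complete graph K_m: Lambda_max = m - 1
  ep <- leadingEigenpair(buildQ(completeNetwork(7), homogeneousRates(7)))
  expect_equal(ep$value, 6, tolerance = 1e-10)

  # sparse path (ARPACK) vs dense eigensolve on a 150-node instance
  net <- giantComponent(erdosRenyiNetwork(150, 6, seed = 21))
  rates <- inverseGammaRates(nNodes(net), 3, seed = 22)
  Q <- buildQ(net, rates)
  dense <- hetSIS:::.denseLeadingEigenpair(Q)
  sparse <- leadingEigenpair(Q)
  expect_equal(sparse$value, dense$value, tolerance = 1e-8)
  expect_equal(abs(sum(sparse$vector * dense$vector)), 1, tolerance = 1e-7)

  # eigenvector contract: unit norm, nonnegative, small residual
  expect_equal(sum(sparse$vector^2), 1, tolerance = 1e-12)
  expect_true(all(sparse$vector >= 0))
  resid <- sqrt(sum((as.numeric(Q %*% sparse$vector) -
                       sparse$value * sparse$vector)^2))
  expect_lt(resid, 1e-8 * sparse$value)
})

test_that("contact-process threshold is 1 on any connected structure", {
  nets <- list(
    giantComponent(erdosRenyiNetwork(300, 8, seed = 1)),
    giantComponent(powerLawNetwork(300, 2.5, seed = 2)),
    starNetwork(20), ringNetwork(40)
  )
  for (net in nets) {
    rep <- qmfReport(net, homogeneousRates(nNodes(net)),
                     contactProcessScheme())
    expect_equal(lambdaMax(rep), 1, tolerance = 1e-8)
    expect_equal(criticalPoint(rep), 1, tolerance = 1e-8)
  }
})

test_that("QMF report: threshold, sandwich bounds, Gershgorin bound, IPR", {
  net <- giantComponent(erdosRenyiNetwork(400, 8, seed = 5))
  n <- nNodes(net)

  # delta = 1 reduces to the standard QMF threshold 1/Lambda_max(A)
  rep1 <- qmfReport(net, homogeneousRates(n))
  expect_equal(criticalPoint(rep1), 1 / adjacencyLeadingEigenvalue(net),
               tolerance = 1e-10)

  # delta_i = k_i pins the critical point at exactly 1
  repk <- qmfReport(net, degreeCorrelatedRates(net))
  expect_equal(criticalPoint(repk), 1, tolerance = 1e-8)
  expect_equal(repk@infNormBound, 1)

  # sandwich and Gershgorin on heterogeneous instances across alpha
  for (alpha in c(2.2, 3, 5, 10)) {
    rates <- inverseGammaRates(n, alpha, seed = alpha * 10)
    rep <- qmfReport(net, rates)
    expect_lte(rep@boundLow, criticalPoint(rep) + 1e-12)
    expect_gte(rep@boundHigh, criticalPoint(rep) - 1e-12)
    expect_lte(lambdaMax(rep), rep@infNormBound + 1e-10)
    expect_gte(ipr(rep), 1 / n)
    expect_lte(ipr(rep), 1)
  }
})

test_that("QMF prediction is monotone in alpha and approaches the homogeneous limit", {
  net <- giantComponent(erdosRenyiNetwork(300, 8, seed = 9))
  n <- nNodes(net)
  alphas <- c(2.2, 3, 5, 10, 100, 1e4)
  tab <- alphaScan(net, alphas, rateSeed = 77)
  expect_true(all(diff(tab$qmf_critical_point) > -1e-6))
  hom <- 1 / adjacencyLeadingEigenvalue(net)
  expect_equal(tab$qmf_critical_point[length(alphas)], hom,
               tolerance = 1e-2)
  expect_true(all(tab$qmf_critical_point <= tab$bound_high + 1e-12))
  expect_true(all(tab$qmf_critical_point >= tab$bound_low - 1e-12))
})

test_that("QMF rate equations: absorbing state, threshold behavior, fixed point", {
  net <- giantComponent(erdosRenyiNetwork(80, 6, seed = 3))
  n <- nNodes(net)
  rates <- inverseGammaRates(n, 4, seed = 4)
  lc <- criticalPoint(qmfReport(net, rates))

  # y0 = 0 stays 0
  sol <- integrateQMF(net, rates, lambda = 2 * lc, y0 = 0, tMax = 5)
  expect_equal(max(abs(sol$steadyState)), 0)

  # below threshold small seeds die out; above threshold they do not
  below <- integrateQMF(net, rates, lambda = 0.5 * lc, y0 = 0.01,
                        tMax = 2000)
  expect_lt(max(below$steadyState), 1e-5)
  above <- integrateQMF(net, rates, lambda = 2 * lc, y0 = 0.01, tMax = 2000)
  expect_gt(mean(above$steadyState), 0.01)

  # steady state satisfies y_i = F_i / (delta_i + F_i), F = lambda A y
  lam <- 2 * lc
  y <- above$steadyState
  Fi <- lam * as.numeric(adjacency(net) %*% y)
  expect_lt(max(abs(y - Fi / (rateValues(rates) + Fi))), 1e-6)

  # isolated dyad: closed-form endemic fixed point y* = (lam - delta)/lam
  dy <- dyadNetwork()
  lam <- 3
  sol2 <- integrateQMF(dy, homogeneousRates(2, 1), lambda = lam, y0 = 0.9,
                       tMax = 500)
  expect_equal(sol2$steadyState, rep((lam - 1) / lam, 2), tolerance = 1e-6)
})
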