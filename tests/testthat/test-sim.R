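test_that("single Gillespie events have the right law", {
  # lone infected node: only recovery is possible; waiting time ~ Exp(delta)
  net1 <- edgeNetwork(cbind(1, 2), n = 2)
  state <- list(infected = 1L, time = 0)
  rates <- manualRates(c(1, 1))
  set.seed(1)
  # fully infected dyad: only recoveries, chosen with probability
  # delta_i / sum(delta)
  rates2 <- manualRates(c(3, 1))
  picks <- replicate(4000, {
    st <- gillespieStep(list(infected = c(1L, 2L), time = 0),
                        net1, rates2, uniformScheme(1))
    st$node
  })
  expect_equal(mean(picks == 1L), 0.75, tolerance = 0.03)

  # dyad with one infected, delta = lambda = 1: recovery and infection
  # compete with equal rates; times are Exp(2)
  set.seed(2)
  steps <- replicate(4000, {
    st <- gillespieStep(list(infected = 1L, time = 0), net1,
                        manualRates(c(1, 1)), uniformScheme(1))
    c(st$time, st$event == "infection")
  })
  expect_equal(mean(steps[2, ]), 0.5, tolerance = 0.03)
  expect_equal(mean(steps[1, ]), 0.5, tolerance = 0.03)
  # Kolmogorov-Smirnov against the exponential with the total rate
  expect_gt(stats::ks.test(steps[1, ], stats::pexp, rate = 2)$p.value, 0.01)

  expect_error(gillespieStep(list(infected = integer(), time = 0),
                             net1, rates, uniformScheme(1)), "absorbing")
})

test_that("histogram moments reproduce the defining arithmetic", {
  # P(2) = P(4) = 1/2: <n> = 3, <n^2> = 10, chi = 1/3
  probs <- c(0, 0.5, 0, 0.5)
  obs <- observablesFromHistogram(probs)
  expect_equal(obs$chi, 1 / 3)
  expect_equal(obs$rho, 3 / 4)
  # degenerate histogram: zero variance
  expect_equal(observablesFromHistogram(c(0, 1, 0))$chi, 0)
})

test_that("exact oracle: one-node point mass, dyad closed form, symmetry", {
  # single non-absorbing state
  one <- hetSIS:::.newNetwork(
    Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                         dims = c(1, 1)), list())
  ex <- exactQSOracle(one, manualRates(2), uniformScheme(1))
  expect_equal(rho(ex), 1)
  expect_equal(chi(ex), 0)

  # homogeneous dyad, delta = lambda = 1: restricted 3-state generator gives
  # P(n=1) = 2/(2 + sqrt(2)), P(n=2) = sqrt(2)/(2 + sqrt(2))
  ex <- exactQSOracle(dyadNetwork(), manualRates(c(1, 1)), uniformScheme(1))
  expect_equal(qsHistogram(ex), c(2, sqrt(2)) / (2 + sqrt(2)),
               tolerance = 1e-12)
  expect_equal(rho(ex), (1 + sqrt(2)) / (2 + sqrt(2)), tolerance = 1e-12)

  # vertex-transitive ring with homogeneous rates: identical marginals
  ex <- exactQSOracle(ringNetwork(5), manualRates(rep(1, 5)),
                      uniformScheme(0.7))
  marg <- ex@params$marginals
  expect_lt(diff(range(marg)), 1e-10)

  expect_error(exactQSOracle(ringNetwork(13), manualRates(rep(1, 13)),
                             uniformScheme(1)), "N <= 12")
})

test_that("quasistationary simulator matches the exact oracle (3 sigma)", {
  # instances spanning homogeneous/heterogeneous rates, both schemes
  cases <- list(
    list(net = dyadNetwork(), delta = c(1, 1),
         scheme = uniformScheme(), lam = 1),
    list(net = pathNetwork(4), delta = c(0.5, 1, 2, 1.5),
         scheme = uniformScheme(), lam = 0.8),
    list(net = starNetwork(5), delta = c(3, rep(0.7, 5)),
         scheme = uniformScheme(), lam = 0.6),
    list(net = completeNetwork(6), delta = c(0.4, 0.7, 1, 1.3, 1.8, 2.5),
         scheme = uniformScheme(), lam = 0.35),
    list(net = ringNetwork(7), delta = rep(1, 7),
         scheme = contactProcessScheme(), lam = 2),
    list(net = pathNetwork(5), delta = c(2, 1, 0.5, 1, 2),
         scheme = contactProcessScheme(), lam = 3)
  )
  # store settings for tiny systems: small update probability (decorrelates
  # resurrection targets) with windows long enough to fill and turn the
  # store over many times
  for (cs in cases) {
    rates <- manualRates(cs$delta)
    ex <- exactQSOracle(cs$net, rates, cs$scheme, lambda = cs$lam)
    sim <- qsReplicates(cs$net, rates, cs$scheme, cs$lam, nRep = 8,
                        relaxTime = 2e4, avgTime = 1.2e5,
                        sampleInterval = 0.5, pStoreUpdate = 0.05,
                        nStore = 100)
    expect_lt(abs(sim$rho - rho(ex)), 3 * sim$rho_se)
    expect_lt(abs(sim$chi - chi(ex)), 3 * sim$chi_se)
  }
})

test_that("QS estimates are invariant under joint time rescaling", {
  # multiplying all deltas and lambda by c only rescales time
  net <- pathNetwork(5)
  delta <- c(0.5, 1, 2, 1, 0.5)
  a <- qsReplicates(net, manualRates(delta), uniformScheme(), 0.9,
                    nRep = 5, relaxTime = 3000, avgTime = 4e4,
                    sampleInterval = 0.5, pStoreUpdate = 0.02,
                    nStore = 50)
  b <- qsReplicates(net, manualRates(3 * delta), uniformScheme(), 2.7,
                    nRep = 5, relaxTime = 1000, avgTime = 4e4 / 3,
                    sampleInterval = 0.5 / 3, pStoreUpdate = 0.06,
                    nStore = 50)
  expect_lt(abs(a$rho - b$rho), 3 * sqrt(a$rho_se^2 + b$rho_se^2))
  expect_lt(abs(a$chi - b$chi), 3 * sqrt(a$chi_se^2 + b$chi_se^2))
})

test_that("QS run basics: conditioning, bounds, reproducibility", {
  net <- giantComponent(erdosRenyiNetwork(100, 6, seed = 31))
  rates <- homogeneousRates(nNodes(net))

  # lambda -> 0: QS conditioning leaves a single infected node (start from
  # a single seed so the store never sees a large transient)
  est <- quasistationaryRun(net, rates, lambda = 1e-4, relaxTime = 100,
                            avgTime = 2000, sampleInterval = 0.5,
                            initFraction = 0.001, pStoreUpdate = 0.5,
                            seed = 1)
  expect_equal(rho(est), 1 / nNodes(net), tolerance = 0.02)
  expect_lt(chi(est), 0.05)
  expect_equal(sum(qsHistogram(est)), 1)

  # rho in (0,1], chi >= 0, histogram excludes n = 0 by construction
  est2 <- quasistationaryRun(net, rates, lambda = 0.3, relaxTime = 100,
                             avgTime = 2000, seed = 2)
  expect_gt(rho(est2), 0)
  expect_lte(rho(est2), 1)
  expect_gte(chi(est2), 0)
  expect_equal(length(qsHistogram(est2)), nNodes(net))

  # same seed, same estimate
  est3 <- quasistationaryRun(net, rates, lambda = 0.3, relaxTime = 100,
                             avgTime = 2000, seed = 2)
  expect_identical(rho(est2), rho(est3))
  expect_warning(
    quasistationaryRun(net, rates, lambda = 0.3, relaxTime = 1,
                       avgTime = 20, seed = 3),
    "100"
  )
})
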