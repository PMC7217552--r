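#' @useDynLib hetSIS, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## CSR view of the adjacency (dgCMatrix of a symmetric matrix: columns are
## rows), 0-based, as the C++ core expects
.csr <- function(net) {
  A <- adjacency(net)
  list(indptr = A@p, indices = A@i)
}

.edgeRatePerNeighbour <- function(scheme, degrees) {
  switch(scheme@kind,
    uniform = rep(scheme@lambda, length(degrees)),
    contact_process = ifelse(degrees > 0, scheme@lambda / degrees, 0)
  )
}

#' One exact Gillespie event
#'
#' Advances the continuous-time SIS chain by a single event. All Poisson
#' clocks compete: each infected node i recovers at rate \eqn{\delta_i} and
#' transmits along each edge towards a susceptible neighbour at
#' \eqn{\lambda_{ij}} (\eqn{\lambda} for the uniform scheme,
#' \eqn{\lambda/k_i} for the contact process). The waiting time is
#' exponential with the total rate and the event is chosen proportionally to
#' its rate. This reference implementation is O(edges) per call and exists
#' for clarity and testing; production runs use the compiled
#' [quasistationaryRun()] loop.
#'
#' @param state list with `infected` (integer node indices, 1-based) and
#'   `time` (nonnegative)
#' @param net a [ContactNetwork-class]
#' @param rates a [RecoveryRates-class]
#' @param scheme a [SpreadingScheme-class] carrying \eqn{\lambda}
#' @return the new state list, with `event` ("recovery"/"infection") and
#'   `node` describing what happened
#' @export
gillespieStep <- function(state, net, rates,
                          scheme = uniformScheme(1)) {
  infected <- state$infected
  if (length(infected) == 0) {
    stop("absorbing state: no events are possible")
  }
  n <- nNodes(net)
  delta <- rateValues(rates)
  beta <- .edgeRatePerNeighbour(scheme, degrees(net))
  A <- adjacency(net)
  isInf <- logical(n)
  isInf[infected] <- TRUE

  # event table: recoveries then per-edge infections
  evNode <- infected
  evTarget <- rep(NA_integer_, length(infected))
  evRate <- delta[infected]
  for (i in infected) {
    nbrs <- which(A[, i] != 0)
    sus <- nbrs[!isInf[nbrs]]
    if (length(sus)) {
      evNode <- c(evNode, rep(i, length(sus)))
      evTarget <- c(evTarget, sus)
      evRate <- c(evRate, rep(beta[i], length(sus)))
    }
  }
  R <- sum(evRate)
  dt <- stats::rexp(1, rate = R)
  pick <- sample.int(length(evRate), 1, prob = evRate)
  if (is.na(evTarget[pick])) {
    newInfected <- setdiff(infected, evNode[pick])
    event <- "recovery"
    node <- evNode[pick]
  } else {
    newInfected <- sort(c(infected, evTarget[pick]))
    event <- "infection"
    node <- evTarget[pick]
  }
  list(infected = newInfected, time = state$time + dt,
       event = event, node = node)
}

.momentsFromHistogram <- function(probs) {
  n <- seq_along(probs)
  En <- sum(n * probs)
  En2 <- sum(n^2 * probs)
  list(En = En, En2 = En2, chi = (En2 - En^2) / En)
}

#' Quasistationary estimate of rho and chi at one spreading rate
#'
#' Runs the exact Gillespie chain with quasistationary conditioning: a store
#' of `nStore` previously visited active configurations is kept (refreshed
#' with probability `pStoreUpdate * dt` per event) and, whenever the
#' absorbing all-susceptible state is hit, the state is replaced by a
#' uniform draw from the store. After `relaxTime`, the infected count
#' \eqn{n_I} is sampled every `sampleInterval` time units over `avgTime`,
#' building the quasistationary histogram from which
#' \eqn{\rho = \langle n_I\rangle/N} and
#' \eqn{\chi = (\langle n_I^2\rangle - \langle n_I\rangle^2)/\langle
#' n_I\rangle} are computed.
#'
#' Defaults for the windows are production scale (1e5 time units each);
#' scale them down for exploratory work and tests.
#'
#' @param net a connected [ContactNetwork-class]
#' @param rates a [RecoveryRates-class]
#' @param scheme a [SpreadingScheme-class]; its `lambda` slot is overridden
#'   by `lambda` when given
#' @param lambda spreading rate; default takes it from `scheme`
#' @param relaxTime,avgTime relaxation and averaging windows (simulated time)
#' @param nStore configuration-store size
#' @param pStoreUpdate store refresh probability per unit simulated time
#' @param sampleInterval spacing of the sampling time grid
#' @param initFraction fraction of nodes initially infected (rounded up;
#'   default all infected, fastest relaxation near criticality)
#' @param seed integer seed; `NULL` uses the current RNG state
#' @return a [QSEstimate-class]
#' @export
quasistationaryRun <- function(net, rates, scheme = uniformScheme(),
                               lambda = NULL, relaxTime = 1e5,
                               avgTime = 1e5, nStore = 100,
                               pStoreUpdate = 0.01, sampleInterval = 1,
                               initFraction = 1, seed = NULL) {
  stopifnot(methods::is(net, "ContactNetwork"),
            methods::is(rates, "RecoveryRates"))
  if (is.null(lambda)) lambda <- scheme@lambda
  if (lambda <= 0 || relaxTime < 0 || avgTime <= 0) {
    stop("lambda and time windows must be positive")
  }
  n <- nNodes(net)
  delta <- rateValues(rates)
  if (length(delta) != n) stop("rates length does not match the network")
  nInit <- max(1L, ceiling(initFraction * n))
  csr <- .csr(net)
  res <- .withSeed(seed, {
    init <- sample.int(n, nInit) - 1L
    .qs_run_cpp(csr$indptr, csr$indices, delta, lambda,
                scheme@kind == "contact_process", init,
                relaxTime, avgTime, as.integer(nStore), pStoreUpdate,
                sampleInterval)
  })
  if (res$n_samples < 100) {
    warning("fewer than 100 quasistationary samples; increase avgTime ",
            "or decrease sampleInterval")
  }
  probs <- res$hist_counts / sum(res$hist_counts)
  mom <- .momentsFromHistogram(probs)
  methods::new("QSEstimate",
    lambda = lambda,
    rho = mom$En / n,
    chi = mom$chi,
    qsHistogram = probs,
    nSamples = res$n_samples,
    params = list(
      scheme = scheme@kind, relax_time = relaxTime, avg_time = avgTime,
      n_store = nStore, p_store_update = pStoreUpdate,
      sample_interval = sampleInterval, init_fraction = initFraction,
      seed = seed, n_absorptions = res$n_absorptions
    )
  )
}

#' Exact quasistationary distribution for tiny graphs
#'
#' Brute-force oracle: enumerates all \eqn{2^N - 1} active configurations,
#' builds the continuous-time Markov generator restricted to them (recovery
#' of the last infected node leaks to the absorbing state), and takes the
#' left eigenvector of the restricted generator for its dominant (largest
#' real part) eigenvalue — the quasistationary law. \eqn{\rho} and
#' \eqn{\chi} follow exactly. Exponential in N; refuse beyond N = 12.
#'
#' @param net a [ContactNetwork-class] with at most 12 nodes
#' @param rates a [RecoveryRates-class]
#' @param scheme a [SpreadingScheme-class]
#' @param lambda spreading rate; default from `scheme`
#' @return a [QSEstimate-class]; `params$state_probs` holds the full
#'   distribution over configurations (index = bitmask) and
#'   `params$marginals` the per-node infection probabilities
#' @export
exactQSOracle <- function(net, rates, scheme = uniformScheme(),
                          lambda = NULL) {
  n <- nNodes(net)
  if (n > 12) stop("exact oracle limited to N <= 12 (state space 2^N)")
  if (is.null(lambda)) lambda <- scheme@lambda
  delta <- rateValues(rates)
  beta <- .edgeRatePerNeighbour(scheme, degrees(net))
  beta <- beta * lambda / scheme@lambda # rescale to requested lambda
  A <- as.matrix(adjacency(net))
  nState <- 2^n - 1
  G <- matrix(0, nState, nState)
  bits <- function(s) which(bitwAnd(s, bitwShiftL(1L, 0:(n - 1))) != 0L)
  for (s in seq_len(nState)) {
    inf <- bits(s)
    out <- 0
    for (i in inf) {
      # recovery i: target state may be absorbing (leak, no column)
      tgt <- bitwAnd(s, bitwNot(bitwShiftL(1L, i - 1L)))
      if (tgt > 0) G[s, tgt] <- G[s, tgt] + delta[i]
      out <- out + delta[i]
      # infections from i towards susceptible neighbours
      nbrs <- which(A[i, ] != 0)
      for (j in setdiff(nbrs, inf)) {
        tgt <- bitwOr(s, bitwShiftL(1L, j - 1L))
        G[s, tgt] <- G[s, tgt] + beta[i]
        out <- out + beta[i]
      }
    }
    G[s, s] <- G[s, s] - out
  }
  e <- eigen(t(G))
  idx <- which.max(Re(e$values))
  p <- Re(e$vectors[, idx])
  if (sum(p) < 0) p <- -p
  p[p < 0] <- 0
  p <- p / sum(p)
  popcount <- vapply(seq_len(nState), function(s) length(bits(s)), 0L)
  probs <- vapply(seq_len(n), function(m) sum(p[popcount == m]), 0)
  mom <- .momentsFromHistogram(probs)
  marginals <- vapply(seq_len(n), function(i) {
    sum(p[bitwAnd(seq_len(nState), bitwShiftL(1L, i - 1L)) != 0L])
  }, 0)
  methods::new("QSEstimate",
    lambda = lambda,
    rho = mom$En / n,
    chi = mom$chi,
    qsHistogram = probs,
    nSamples = Inf,
    params = list(scheme = scheme@kind, method = "exact_restricted_generator",
                  state_probs = p, marginals = marginals,
                  decay_rate = -Re(e$values[idx]))
  )
}

#' Recompute rho and chi from a quasistationary histogram
#'
#' Utility mirroring the defining moments: with \eqn{P(n_I)} the
#' quasistationary law of the infected count,
#' \eqn{\rho = \langle n_I\rangle / N} and \eqn{\chi = (\langle n_I^2\rangle
#' - \langle n_I\rangle^2)/\langle n_I\rangle}.
#'
#' @param probs probability vector over \eqn{n_I = 1..N}
#' @return list with `rho` and `chi`
#' @export
observablesFromHistogram <- function(probs) {
  if (abs(sum(probs) - 1) > 1e-8) stop("histogram must sum to 1")
  mom <- .momentsFromHistogram(probs)
  list(rho = mom$En / length(probs), chi = mom$chi)
}
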