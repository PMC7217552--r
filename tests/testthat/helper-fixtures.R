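# Small deterministic graph fixtures, built in code.

edgeNetwork <- function(edges, n = max(edges)) {
  A <- Matrix::sparseMatrix(
    i = c(edges[, 1], edges[, 2]), j = c(edges[, 2], edges[, 1]),
    x = 1, dims = c(n, n)
  )
  hetSIS:::.newNetwork(A, list(generator = "fixture"))
}

pathNetwork <- function(n) {
  edgeNetwork(cbind(1:(n - 1), 2:n), n)
}

ringNetwork <- function(n) {
  edgeNetwork(cbind(1:n, c(2:n, 1)), n)
}

starNetwork <- function(nLeaves) {
  edgeNetwork(cbind(1, 2:(nLeaves + 1)), nLeaves + 1)
}

completeNetwork <- function(n) {
  edgeNetwork(t(utils::combn(n, 2)), n)
}

dyadNetwork <- function() edgeNetwork(cbind(1, 2), 2)

manualRates <- function(delta) {
  methods::new("RecoveryRates", delta = as.numeric(delta),
               provenance = list(scheme = "manual"))
}

# mean/se over replicate QS runs, for 3-sigma comparisons with the oracle
qsReplicates <- function(net, rates, scheme, lambda, nRep = 6, ...) {
  vals <- vapply(seq_len(nRep), function(s) {
    est <- quasistationaryRun(net, rates, scheme, lambda = lambda,
                              seed = 1000 + s, ...)
    c(rho(est), chi(est))
  }, numeric(2))
  list(
    rho = mean(vals[1, ]), rho_se = stats::sd(vals[1, ]) / sqrt(nRep),
    chi = mean(vals[2, ]), chi_se = stats::sd(vals[2, ]) / sqrt(nRep)
  )
}
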