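#' Build the contact matrix Q
#'
#' \eqn{Q = \Delta^{-1}(A \circ W)} with \eqn{\Delta_{ii} = \delta_i} and
#' \eqn{W_{ij} = \lambda_{ij}} evaluated at \eqn{\lambda = 1}: entry
#' \eqn{Q_{ij}} is the expected number of contacts node i makes towards j
#' before recovering. Under the uniform scheme \eqn{Q_{ij} = A_{ij}/\delta_i};
#' under the contact process \eqn{Q_{ij} = A_{ij}/(\delta_i k_i)}. The global
#' \eqn{\lambda} only rescales Q, so thresholds are reported in \eqn{\lambda}
#' units from the \eqn{\lambda = 1} matrix.
#'
#' The inverse row scaling is attached as `attr(Q, "scaling")` (the vector
#' \eqn{s_i} with \eqn{Q = S^{-1}A}); the eigensolver uses it for the
#' symmetric similarity transform \eqn{S^{-1/2} A S^{-1/2}}.
#'
#' @param net a connected [ContactNetwork-class]
#' @param rates a [RecoveryRates-class] matching the network
#' @param scheme a [SpreadingScheme-class]; its `lambda` is ignored (fixed
#'   at 1)
#' @return sparse nonnegative matrix with zero diagonal
#' @export
buildQ <- function(net, rates, scheme = uniformScheme()) {
  stopifnot(methods::is(net, "ContactNetwork"),
            methods::is(rates, "RecoveryRates"),
            methods::is(scheme, "SpreadingScheme"))
  delta <- rateValues(rates)
  if (length(delta) != nNodes(net)) {
    stop("rates length does not match the network")
  }
  if (!isConnected(net)) {
    stop("network must be connected (extract the giant component first)")
  }
  s <- switch(scheme@kind,
    uniform = delta,
    contact_process = delta * degrees(net)
  )
  Q <- Matrix::Diagonal(x = 1 / s) %*% adjacency(net)
  Q <- methods::as(Q, "CsparseMatrix")
  attr(Q, "scaling") <- s
  Q
}

## dense leading eigenpair, used as fallback and test oracle for small n
.denseLeadingEigenpair <- function(M) {
  e <- eigen(as.matrix(M))
  i <- which.max(Re(e$values))
  v <- Re(e$vectors[, i])
  if (sum(v) < 0) v <- -v
  list(value = Re(e$values[i]), vector = v / sqrt(sum(v^2)))
}

#' Leading eigenpair of a nonnegative matrix
#'
#' Dominant eigenvalue and right eigenvector, via ARPACK (Lanczos on the
#' symmetric similarity transform \eqn{S^{-1/2} A S^{-1/2}} when the row
#' scaling `s` is available — as it is for every matrix built by [buildQ()] —
#' or directly when the matrix is symmetric). Small or unscalable matrices
#' fall back to a dense solve. The eigenvector is returned with unit
#' Euclidean norm and nonnegative entries (Perron–Frobenius, assuming
#' irreducibility).
#'
#' @param Q nonnegative square matrix (sparse or dense)
#' @param tol relative residual tolerance on \eqn{\|Qv - \Lambda v\|}
#' @param maxIter ARPACK iteration cap
#' @param scaling optional positive vector `s` such that `diag(s) %*% Q` is
#'   symmetric; defaults to `attr(Q, "scaling")`
#' @return list with `value` and unit-norm `vector`
#' @export
leadingEigenpair <- function(Q, tol = 1e-10, maxIter = 1e5,
                             scaling = attr(Q, "scaling")) {
  n <- nrow(Q)
  if (n != ncol(Q)) stop("Q must be square")
  symmetricInput <- is.null(scaling) && Matrix::isSymmetric(Q)
  if (n <= 64 || (!symmetricInput && is.null(scaling))) {
    res <- .denseLeadingEigenpair(Q)
  } else {
    if (symmetricInput) {
      B <- Q
      unscale <- rep(1, n)
    } else {
      # Q = S^-1 A with A symmetric, so S^1/2 Q S^-1/2 = S^-1/2 A S^-1/2
      rs <- 1 / sqrt(scaling)
      B <- Matrix::Diagonal(x = sqrt(scaling)) %*% Q %*%
        Matrix::Diagonal(x = rs)
      B <- Matrix::forceSymmetric(methods::as(B, "CsparseMatrix"))
      unscale <- rs
    }
    ar <- igraph::arpack(
      function(x, extra) as.numeric(B %*% x),
      options = list(n = n, nev = 1, ncv = min(n, 25L), which = "LA",
                     maxiter = as.integer(maxIter), tol = tol),
      sym = TRUE
    )
    v <- unscale * as.numeric(ar$vectors)
    if (sum(v) < 0) v <- -v
    res <- list(value = as.numeric(ar$values[1]), vector = v / sqrt(sum(v^2)))
  }
  resid <- sqrt(sum((as.numeric(Q %*% res$vector) -
                       res$value * res$vector)^2))
  if (resid > max(tol, 1e-9) * abs(res$value) * 100) {
    stop(sprintf("eigensolver did not converge: residual %.3g", resid))
  }
  res$vector <- pmax(res$vector, 0)
  res$vector <- res$vector / sqrt(sum(res$vector^2))
  res
}

#' Leading adjacency eigenvalue
#'
#' \eqn{\Lambda_{max}(A)}; its inverse is the standard (homogeneous) QMF
#' threshold \eqn{\tau_c = 1/\Lambda_{max}(A)}.
#'
#' @param net a [ContactNetwork-class]
#' @param tol,maxIter eigensolver controls
#' @return numeric scalar
#' @export
adjacencyLeadingEigenvalue <- function(net, tol = 1e-10, maxIter = 1e5) {
  leadingEigenpair(adjacency(net), tol = tol, maxIter = maxIter,
                   scaling = NULL)$value
}

#' Quenched mean-field report for a network + rates instance
#'
#' Builds Q, solves for the leading eigenpair, and fills in the epidemic
#' threshold \eqn{\lambda_c = 1/\Lambda_{max}(Q)}, the sandwich bounds
#' \eqn{\min_i\delta_i/\Lambda_{max}(A) \le \lambda_c \le
#' \max_i\delta_i/\Lambda_{max}(A)} (uniform scheme), the Gershgorin
#' infinity-norm bound \eqn{\Lambda_{max}(Q) \le \max_i k_i/\delta_i}, and
#' the inverse participation ratio \eqn{\sum_i v_i^4} of the unit-norm
#' leading eigenvector (near \eqn{1/N} when delocalised, order 1 when
#' localised on few nodes).
#'
#' @inheritParams buildQ
#' @param tol,maxIter eigensolver controls
#' @return a [QMFReport-class]
#' @examples
#' net <- erdosRenyiNetwork(300, 8, seed = 1) |> giantComponent()
#' rep <- qmfReport(net, homogeneousRates(nNodes(net)))
#' criticalPoint(rep)
#' @export
qmfReport <- function(net, rates, scheme = uniformScheme(),
                      tol = 1e-10, maxIter = 1e5) {
  Q <- buildQ(net, rates, scheme)
  ep <- leadingEigenpair(Q, tol = tol, maxIter = maxIter)
  delta <- rateValues(rates)
  k <- degrees(net)
  lamA <- adjacencyLeadingEigenvalue(net, tol = tol, maxIter = maxIter)
  v <- ep$vector
  methods::new("QMFReport",
    lambdaMax = ep$value,
    criticalPoint = 1 / ep$value,
    leadingVector = v,
    boundLow = min(delta) / lamA,
    boundHigh = max(delta) / lamA,
    infNormBound = max(k / delta),
    ipr = sum(v^4)
  )
}

## right-hand side of the QMF rate equations
.qmfDeriv <- function(y, delta, A, lambda, cpScale = NULL) {
  force_ <- if (is.null(cpScale)) {
    lambda * as.numeric(A %*% y)
  } else {
    # contact-process orientation matching Q: sum_j (lambda/k_i) A_ij y_j
    lambda * cpScale * as.numeric(A %*% y)
  }
  -delta * y + (1 - y) * force_
}

#' Integrate the quenched mean-field rate equations
#'
#' Solves \eqn{dy_i/dt = -\delta_i y_i + (1 - y_i)\sum_j \lambda_{ij} A_{ij}
#' y_j} with an adaptive Cash–Karp Runge–Kutta (4,5) integrator. The unit
#' hypercube is invariant for the exact flow; iterates are clamped to
#' \eqn{[0,1]} to guard against round-off. Integration stops early when a
#' steady state is reached (\eqn{\|dy/dt\|_\infty <} `steadyTol`).
#'
#' @param net a [ContactNetwork-class]
#' @param rates a [RecoveryRates-class]
#' @param lambda spreading rate \eqn{\lambda}
#' @param y0 initial per-node infection probabilities in \[0,1\];
#'   scalar is recycled
#' @param tMax integration horizon
#' @param scheme a [SpreadingScheme-class] (kind only; `lambda` argument
#'   wins)
#' @param nOut number of saved trajectory points (uniform in time)
#' @param steadyTol early-stop tolerance on \eqn{\|dy/dt\|_\infty}
#' @param rtol,atol local error controls
#' @return list with `times`, `y` (rows = saved times), `steadyState`
#'   (final y), `converged` (steady state reached before `tMax`)
#' @export
integrateQMF <- function(net, rates, lambda, y0 = 0.5, tMax = 100,
                         scheme = uniformScheme(), nOut = 101,
                         steadyTol = 1e-10, rtol = 1e-8, atol = 1e-10) {
  n <- nNodes(net)
  delta <- rateValues(rates)
  stopifnot(length(delta) == n)
  y <- rep_len(as.numeric(y0), n)
  if (any(y < 0 | y > 1)) stop("y0 entries must lie in [0, 1]")
  A <- adjacency(net)
  cpScale <- if (scheme@kind == "contact_process") 1 / degrees(net) else NULL
  f <- function(y) .qmfDeriv(y, delta, A, lambda, cpScale)

  # Cash-Karp embedded RK45 tableau
  a <- list(
    c(1 / 5),
    c(3 / 40, 9 / 40),
    c(3 / 10, -9 / 10, 6 / 5),
    c(-11 / 54, 5 / 2, -70 / 27, 35 / 27),
    c(1631 / 55296, 175 / 512, 575 / 13824, 44275 / 110592, 253 / 4096)
  )
  b5 <- c(37 / 378, 0, 250 / 621, 125 / 594, 0, 512 / 1771)
  b4 <- c(2825 / 27648, 0, 18575 / 48384, 13525 / 55296, 277 / 14336, 1 / 4)

  tsOut <- seq(0, tMax, length.out = nOut)
  out <- matrix(NA_real_, nOut, n)
  out[1, ] <- y
  nextOut <- 2L
  t <- 0
  h <- min(0.01, tMax / 100)
  converged <- FALSE
  maxSteps <- 1e6
  for (step in seq_len(maxSteps)) {
    if (t >= tMax || converged) break
    h <- min(h, tMax - t)
    k <- vector("list", 6)
    k[[1]] <- f(y)
    if (max(abs(k[[1]])) < steadyTol) {
      converged <- TRUE
      break
    }
    for (s in 2:6) {
      yi <- y
      for (m in seq_len(s - 1)) yi <- yi + h * a[[s - 1]][m] * k[[m]]
      k[[s]] <- f(yi)
    }
    y5 <- y; y4 <- y
    for (s in 1:6) {
      y5 <- y5 + h * b5[s] * k[[s]]
      y4 <- y4 + h * b4[s] * k[[s]]
    }
    err <- max(abs(y5 - y4) / (atol + rtol * pmax(abs(y), abs(y5))))
    if (is.na(err) || !is.finite(err)) stop("step-size failure in RK45")
    if (err <= 1) {
      t <- t + h
      y <- pmin(pmax(y5, 0), 1)
      while (nextOut <= nOut && tsOut[nextOut] <= t + 1e-12) {
        out[nextOut, ] <- y
        nextOut <- nextOut + 1L
      }
    }
    h <- h * min(5, max(0.2, 0.9 * (1 / max(err, 1e-16))^0.2))
    if (h < 1e-14) stop("step-size underflow in RK45")
  }
  if (nextOut <= nOut) {
    out[nextOut:nOut, ] <- matrix(y, nOut - nextOut + 1L, n, byrow = TRUE)
  }
  list(times = tsOut, y = out, steadyState = y, converged = converged)
}
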