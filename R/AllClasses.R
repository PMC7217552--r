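#' @import methods
#' @importFrom Matrix Diagonal Matrix colSums rowSums t isSymmetric diag
#'   sparseMatrix triu forceSymmetric
NULL

#' ContactNetwork: an undirected simple graph substrate
#'
#' Container for the static contact structure an epidemic spreads on: a
#' simple (no self-loops, no multi-edges) undirected graph held as a sparse
#' symmetric 0/1 adjacency matrix together with the degree vector.
#' Node identifiers are contiguous integers starting at 1 (R convention);
#' edge-list input/output translates 0- or 1-based external labels.
#'
#' @slot adjacency sparse symmetric adjacency matrix (\code{dgCMatrix}),
#'   zero diagonal, entries in \{0,1\}
#' @slot degrees integer vector of node degrees, \code{k[i] = sum(A[i, ])}
#' @slot provenance list recording how the network was built (generator,
#'   parameters, seed, any simplification counts)
#'
#' @seealso [erdosRenyiNetwork()], [powerLawNetwork()], [readEdgeList()],
#'   [giantComponent()]
#' @export
setClass("ContactNetwork",
  representation(
    adjacency = "dgCMatrix",
    degrees = "integer",
    provenance = "list"
  )
)

setValidity("ContactNetwork", function(object) {
  A <- object@adjacency
  msgs <- character()
  if (nrow(A) != ncol(A)) msgs <- c(msgs, "adjacency must be square")
  if (nrow(A) > 0) {
    if (any(Matrix::diag(A) != 0)) msgs <- c(msgs, "self-loops present")
    if (!Matrix::isSymmetric(A)) msgs <- c(msgs, "adjacency must be symmetric")
    if (length(A@x) && any(A@x != 1)) {
      msgs <- c(msgs, "adjacency entries must be 0/1 (simple graph)")
    }
    if (length(object@degrees) != nrow(A)) {
      msgs <- c(msgs, "degrees length must equal node count")
    } else if (any(object@degrees != as.integer(Matrix::rowSums(A)))) {
      msgs <- c(msgs, "degrees inconsistent with adjacency")
    }
    if (sum(object@degrees) %% 2L != 0L) {
      msgs <- c(msgs, "degree sum must be even (2 x edge count)")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' RecoveryRates: per-node recovery rate vector
#'
#' Positive recovery rates \eqn{\delta_i} (inverse time units), one per node,
#' with provenance metadata describing the sampling scheme.
#'
#' @slot delta numeric vector of strictly positive finite rates
#' @slot provenance list with at least \code{scheme}; typically also the
#'   scheme parameters and seed
#' @seealso [inverseGammaRates()], [degreeCorrelatedRates()],
#'   [powerLawShuffledRates()], [homogeneousRates()]
#' @export
setClass("RecoveryRates",
  representation(delta = "numeric", provenance = "list")
)

setValidity("RecoveryRates", function(object) {
  d <- object@delta
  if (length(d) == 0) return("delta must be non-empty")
  if (any(!is.finite(d)) || any(d <= 0)) {
    return("all recovery rates must be strictly positive and finite")
  }
  TRUE
})

#' SpreadingScheme: how the per-edge transmission rates are set
#'
#' Either the uniform SIS scheme, where every directed edge emanating from an
#' infected node carries rate \eqn{\lambda_{ij} = \lambda}, or the contact
#' process (CP), where an infected node divides its budget over its
#' neighbours, \eqn{\lambda_{ij} = \lambda / k_i} with \eqn{k_i} the source
#' degree.
#'
#' @slot kind "uniform" or "contact_process"
#' @slot lambda positive global spreading rate \eqn{\lambda}
#' @seealso [uniformScheme()], [contactProcessScheme()]
#' @export
setClass("SpreadingScheme",
  representation(kind = "character", lambda = "numeric")
)

setValidity("SpreadingScheme", function(object) {
  if (!object@kind %in% c("uniform", "contact_process")) {
    return("kind must be 'uniform' or 'contact_process'")
  }
  if (length(object@lambda) != 1 || !is.finite(object@lambda) ||
      object@lambda <= 0) {
    return("lambda must be a single positive number")
  }
  TRUE
})

#' QMFReport: quenched mean-field spectral summary
#'
#' Holds the leading eigenpair of the contact matrix
#' \eqn{Q = \Delta^{-1}(A \circ W)} and the quantities derived from it: the
#' predicted critical point \eqn{\lambda_c = 1/\Lambda_{max}(Q)}, the
#' min/max-\eqn{\delta} sandwich bounds around the homogeneous prediction,
#' the Gershgorin (infinity-norm) bound \eqn{\max_i k_i/\delta_i}, and the
#' inverse participation ratio of the leading eigenvector.
#'
#' @slot lambdaMax leading eigenvalue \eqn{\Lambda_{max}(Q)}
#' @slot criticalPoint \eqn{1/\Lambda_{max}(Q)}
#' @slot leadingVector nonnegative unit-2-norm leading right eigenvector
#' @slot boundLow,boundHigh \eqn{\min_i \delta_i / \Lambda_{max}(A)} and
#'   \eqn{\max_i \delta_i / \Lambda_{max}(A)}
#' @slot infNormBound \eqn{\max_i k_i/\delta_i}; \eqn{\Lambda_{max}(Q)} never
#'   exceeds it, so \eqn{\lambda_c \ge 1/}\code{infNormBound}
#' @slot ipr \eqn{\sum_i v_i^4} for the unit-norm leading vector
#' @seealso [qmfReport()]
#' @export
setClass("QMFReport",
  representation(
    lambdaMax = "numeric",
    criticalPoint = "numeric",
    leadingVector = "numeric",
    boundLow = "numeric",
    boundHigh = "numeric",
    infNormBound = "numeric",
    ipr = "numeric"
  )
)

setValidity("QMFReport", function(object) {
  msgs <- character()
  if (object@lambdaMax <= 0) msgs <- c(msgs, "lambdaMax must be positive")
  if (abs(object@criticalPoint * object@lambdaMax - 1) > 1e-8) {
    msgs <- c(msgs, "criticalPoint must equal 1/lambdaMax")
  }
  if (any(object@leadingVector < -1e-10)) {
    msgs <- c(msgs, "leading eigenvector must be nonnegative")
  }
  n <- length(object@leadingVector)
  if (n > 0 && (object@ipr < 1 / n - 1e-10 || object@ipr > 1 + 1e-10)) {
    msgs <- c(msgs, "ipr must lie in [1/N, 1]")
  }
  if (length(msgs)) msgs else TRUE
})

setClassUnion("QMFReportOrNULL", members = c("QMFReport", "NULL"))

#' QSEstimate: quasistationary observables at one spreading rate
#'
#' The output of one quasistationary run: the order parameter
#' \eqn{\rho = \langle n_I\rangle/N}, the susceptibility
#' \eqn{\chi = (\langle n_I^2\rangle - \langle n_I\rangle^2)/\langle n_I\rangle},
#' and the quasistationary histogram of the infected count over
#' \eqn{n_I \in \{1, \ldots, N\}} (the absorbing state is excluded by
#' construction).
#'
#' @slot lambda spreading rate the run was performed at
#' @slot rho order parameter in (0, 1]
#' @slot chi susceptibility, nonnegative
#' @slot qsHistogram probability vector over infected counts 1..N, sums to 1
#' @slot nSamples number of time-grid samples behind the histogram
#' @slot params list of run metadata (scheme, windows, store settings, seed)
#' @seealso [quasistationaryRun()], [exactQSOracle()]
#' @export
setClass("QSEstimate",
  representation(
    lambda = "numeric",
    rho = "numeric",
    chi = "numeric",
    qsHistogram = "numeric",
    nSamples = "numeric",
    params = "list"
  )
)

setValidity("QSEstimate", function(object) {
  msgs <- character()
  h <- object@qsHistogram
  if (length(h) && abs(sum(h) - 1) > 1e-8) {
    msgs <- c(msgs, "qsHistogram must sum to 1")
  }
  if (any(h < 0)) msgs <- c(msgs, "qsHistogram must be nonnegative")
  if (object@rho <= 0 || object@rho > 1 + 1e-12) {
    msgs <- c(msgs, "rho must lie in (0, 1]")
  }
  if (object@chi < -1e-12) msgs <- c(msgs, "chi must be nonnegative")
  if (length(msgs)) msgs else TRUE
})

#' SweepResult: a susceptibility curve over a spreading-rate grid
#'
#' One quasistationary estimate per grid point, the refined location of the
#' susceptibility peak (the finite-size threshold proxy), and the matching
#' quenched mean-field prediction for the same network/rates instance.
#'
#' @slot lambdas increasing spreading-rate grid
#' @slot rhos,chis matched observable vectors
#' @slot lambdaPeak peak location after local quadratic refinement in
#'   \eqn{\log\lambda}
#' @slot peakAtBoundary TRUE when the raw maximum sits on the grid edge
#'   (no refinement performed)
#' @slot qmf the [QMFReport-class] for the same instance, or NULL
#' @slot params run metadata
#' @seealso [lambdaSweep()]
#' @export
setClass("SweepResult",
  representation(
    lambdas = "numeric",
    rhos = "numeric",
    chis = "numeric",
    lambdaPeak = "numeric",
    peakAtBoundary = "logical",
    qmf = "QMFReportOrNULL",
    params = "list"
  )
)

setValidity("SweepResult", function(object) {
  msgs <- character()
  if (is.unsorted(object@lambdas, strictly = TRUE)) {
    msgs <- c(msgs, "lambdas must be strictly increasing")
  }
  if (length(object@chis) != length(object@lambdas) ||
      length(object@rhos) != length(object@lambdas)) {
    msgs <- c(msgs, "rhos/chis must match lambdas in length")
  }
  if (any(object@chis < -1e-12)) msgs <- c(msgs, "chis must be nonnegative")
  if (!object@peakAtBoundary &&
      (object@lambdaPeak < min(object@lambdas) - 1e-12 ||
       object@lambdaPeak > max(object@lambdas) + 1e-12)) {
    msgs <- c(msgs, "lambdaPeak must lie inside the grid")
  }
  if (length(msgs)) msgs else TRUE
})
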