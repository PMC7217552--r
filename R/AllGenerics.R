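#' Accessors for hetSIS objects
#'
#' @param object a hetSIS S4 object
#' @name accessors
NULL

#' @describeIn accessors number of nodes of a [ContactNetwork-class]
#' @export
setGeneric("nNodes", function(object) standardGeneric("nNodes"))

#' @describeIn accessors number of (undirected) edges
#' @export
setGeneric("nEdges", function(object) standardGeneric("nEdges"))

#' @describeIn accessors integer degree vector
#' @export
setGeneric("degrees", function(object) standardGeneric("degrees"))

#' @describeIn accessors sparse symmetric adjacency matrix
#' @export
setGeneric("adjacency", function(object) standardGeneric("adjacency"))

#' @describeIn accessors per-node recovery-rate vector \eqn{\delta}
#' @export
setGeneric("rateValues", function(object) standardGeneric("rateValues"))

#' @describeIn accessors provenance metadata list
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))

#' @describeIn accessors QMF critical point \eqn{1/\Lambda_{max}(Q)}
#' @export
setGeneric("criticalPoint", function(object) standardGeneric("criticalPoint"))

#' @describeIn accessors leading eigenvalue \eqn{\Lambda_{max}(Q)}
#' @export
setGeneric("lambdaMax", function(object) standardGeneric("lambdaMax"))

#' @describeIn accessors leading eigenvector (unit norm, nonnegative)
#' @export
setGeneric("leadingVector", function(object) standardGeneric("leadingVector"))

#' @describeIn accessors inverse participation ratio of the leading vector
#' @export
setGeneric("ipr", function(object) standardGeneric("ipr"))

#' @describeIn accessors order parameter \eqn{\rho}
#' @export
setGeneric("rho", function(object) standardGeneric("rho"))

#' @describeIn accessors susceptibility \eqn{\chi}
#' @export
setGeneric("chi", function(object) standardGeneric("chi"))

#' @describeIn accessors quasistationary histogram of the infected count
#' @export
setGeneric("qsHistogram", function(object) standardGeneric("qsHistogram"))

#' @describeIn accessors refined susceptibility-peak location
#' @export
setGeneric("lambdaPeak", function(object) standardGeneric("lambdaPeak"))

setMethod("nNodes", "ContactNetwork", function(object) nrow(object@adjacency))
setMethod("nEdges", "ContactNetwork",
          function(object) sum(object@degrees) %/% 2L)
setMethod("degrees", "ContactNetwork", function(object) object@degrees)
setMethod("adjacency", "ContactNetwork", function(object) object@adjacency)
setMethod("provenance", "ContactNetwork", function(object) object@provenance)

setMethod("rateValues", "RecoveryRates", function(object) object@delta)
setMethod("provenance", "RecoveryRates", function(object) object@provenance)

setMethod("lambdaMax", "QMFReport", function(object) object@lambdaMax)
setMethod("criticalPoint", "QMFReport", function(object) object@criticalPoint)
setMethod("leadingVector", "QMFReport", function(object) object@leadingVector)
setMethod("ipr", "QMFReport", function(object) object@ipr)

setMethod("rho", "QSEstimate", function(object) object@rho)
setMethod("chi", "QSEstimate", function(object) object@chi)
setMethod("qsHistogram", "QSEstimate", function(object) object@qsHistogram)

setMethod("lambdaPeak", "SweepResult", function(object) object@lambdaPeak)
setMethod("chi", "SweepResult", function(object) object@chis)
setMethod("rho", "SweepResult", function(object) object@rhos)

#' @describeIn accessors Eq.-style sandwich bounds of a QMF report, returned
#'   as \code{c(low, high)}
#' @export
setGeneric("thresholdBounds",
           function(object) standardGeneric("thresholdBounds"))
setMethod("thresholdBounds", "QMFReport",
          function(object) c(low = object@boundLow, high = object@boundHigh))

setMethod("show", "ContactNetwork", function(object) {
  cat("ContactNetwork:", nNodes(object), "nodes,", nEdges(object), "edges\n")
  k <- degrees(object)
  cat(sprintf("  degrees: mean %.3f, min %d, max %d\n",
              mean(k), min(k), max(k)))
  prov <- provenance(object)
  if (!is.null(prov$generator)) cat("  generator:", prov$generator, "\n")
})

setMethod("show", "RecoveryRates", function(object) {
  d <- rateValues(object)
  cat("RecoveryRates:", length(d), "nodes; scheme:",
      object@provenance$scheme %||% "unknown", "\n")
  cat(sprintf("  delta: mean %.4f, min %.4g, max %.4g\n",
              mean(d), min(d), max(d)))
})

setMethod("show", "SpreadingScheme", function(object) {
  cat(sprintf("SpreadingScheme: %s, lambda = %g\n",
              object@kind, object@lambda))
})

setMethod("show", "QMFReport", function(object) {
  cat("QMFReport\n")
  cat(sprintf("  Lambda_max(Q)   : %.10g\n", object@lambdaMax))
  cat(sprintf("  critical point  : %.10g\n", object@criticalPoint))
  cat(sprintf("  sandwich bounds : [%.6g, %.6g]\n",
              object@boundLow, object@boundHigh))
  cat(sprintf("  inf-norm bound  : Lambda_max <= %.6g\n",
              object@infNormBound))
  cat(sprintf("  IPR             : %.6g (1/N = %.3g)\n", object@ipr,
              1 / length(object@leadingVector)))
})

setMethod("show", "QSEstimate", function(object) {
  cat(sprintf("QSEstimate at lambda = %g\n", object@lambda))
  cat(sprintf("  rho = %.6g, chi = %.6g (%d samples)\n",
              object@rho, object@chi, as.integer(object@nSamples)))
})

setMethod("show", "SweepResult", function(object) {
  cat(sprintf("SweepResult: %d lambda points in [%g, %g]\n",
              length(object@lambdas), min(object@lambdas),
              max(object@lambdas)))
  cat(sprintf("  peak at lambda = %.6g%s\n", object@lambdaPeak,
              if (object@peakAtBoundary) " (at grid boundary!)" else ""))
  if (!is.null(object@qmf)) {
    cat(sprintf("  QMF prediction = %.6g\n", object@qmf@criticalPoint))
  }
})

`%||%` <- function(a, b) if (is.null(a)) b else a
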