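.newRates <- function(delta, provenance) {
  r <- methods::new("RecoveryRates", delta = as.numeric(delta),
                    provenance = provenance)
  methods::validObject(r)
  r
}

#' Unit-mean inverse-gamma recovery rates
#'
#' If infectious periods are gamma distributed, the recovery rates are
#' inverse-gamma: \eqn{\delta \sim \Gamma^{-1}(\alpha, \beta)} with mean
#' \eqn{\beta/(\alpha - 1)} and variance
#' \eqn{\beta^2 / ((\alpha-1)^2(\alpha-2))} for \eqn{\alpha > 2}. To compare
#' distributions on an equal footing, the scale is tied to the shape as
#' \eqn{\beta = \alpha - 1}, which fixes the mean at exactly 1 without
#' rescaling the sample. Small \eqn{\alpha} gives heavy-tailed rates; as
#' \eqn{\alpha \to \infty} the rates concentrate at 1 and the dynamics
#' approach the standard homogeneous SIS model.
#'
#' Sampling goes through the reciprocal-gamma identity: if
#' \eqn{X \sim \Gamma(\alpha, \mathrm{rate} = \beta)} then
#' \eqn{1/X \sim \Gamma^{-1}(\alpha, \beta)}.
#'
#' @param nNodes number of rates to draw
#' @param alpha shape, must exceed 1 (otherwise the mean is undefined);
#'   values at or below 2 are allowed but flagged, since the variance is
#'   then infinite
#' @param seed integer seed; `NULL` uses the current RNG state
#' @return a [RecoveryRates-class] with unit distribution mean
#' @examples
#' d <- inverseGammaRates(10000, alpha = 5, seed = 1)
#' mean(rateValues(d)) # close to 1
#' @export
inverseGammaRates <- function(nNodes, alpha, seed = NULL) {
  if (alpha <= 1) stop("alpha must exceed 1 (mean undefined otherwise)")
  if (alpha <= 2) {
    message("alpha <= 2: inverse-gamma variance is infinite")
  }
  beta <- alpha - 1
  delta <- .withSeed(seed, 1 / stats::rgamma(nNodes, shape = alpha,
                                             rate = beta))
  .newRates(delta, list(scheme = "inverse_gamma", alpha = alpha,
                        beta = beta, seed = seed))
}

#' Degree-correlated recovery rates
#'
#' Sets \eqn{\delta_i = k_i} exactly. On power-law networks this is the
#' structure-dynamics correlation that caps the row sums of
#' \eqn{Q = \Delta^{-1}A} at \eqn{\max_i k_i/\delta_i = 1}, making the
#' quenched mean-field threshold equal to 1 irrespective of the degree
#' distribution (the SIS analogue of the contact process).
#'
#' @param net a [ContactNetwork-class]; isolated nodes are rejected since
#'   rates must be positive
#' @return a [RecoveryRates-class]
#' @export
degreeCorrelatedRates <- function(net) {
  stopifnot(methods::is(net, "ContactNetwork"))
  k <- degrees(net)
  if (any(k == 0L)) {
    stop("isolated node(s) ", paste(utils::head(which(k == 0L), 5),
                                    collapse = ", "),
         ": degree-correlated rates require positive degrees")
  }
  .newRates(as.numeric(k), list(scheme = "degree"))
}

#' Power-law shuffled recovery rates
#'
#' Assigns heavy-tailed rates to the nodes of a homogeneous network:
#' \eqn{\delta_i = k_i^{PL}}, where \eqn{k^{PL}} is either a fresh i.i.d.
#' sample from the truncated discrete power law \eqn{P(k)\propto k^{-\gamma}}
#' or a supplied degree sequence (e.g. that of a matched power-law network),
#' randomly permuted over the nodes so the rates are uncorrelated with the
#' local structure.
#'
#' @param nNodes number of nodes to cover
#' @param gamma,kMin,kMax power-law parameters (ignored when `sequence`
#'   is supplied)
#' @param seed integer seed; `NULL` uses the current RNG state
#' @param sequence optional positive sequence of length `nNodes` to permute
#'   instead of sampling
#' @return a [RecoveryRates-class]
#' @export
powerLawShuffledRates <- function(nNodes, gamma = NULL, kMin = NULL,
                                  kMax = NULL, seed = NULL,
                                  sequence = NULL) {
  if (!is.null(sequence)) {
    if (length(sequence) != nNodes) {
      stop("supplied sequence length ", length(sequence),
           " does not match nNodes = ", nNodes)
    }
    delta <- .withSeed(seed, sample(as.numeric(sequence)))
    prov <- list(scheme = "powerlaw_shuffled", source = "supplied_sequence",
                 seed = seed)
  } else {
    delta <- .withSeed(seed, {
      as.numeric(sampleDiscretePowerLaw(nNodes, gamma, kMin, kMax))
    })
    prov <- list(scheme = "powerlaw_shuffled", source = "sampled",
                 gamma = gamma, k_min = kMin, k_max = kMax, seed = seed)
  }
  .newRates(delta, prov)
}

#' Homogeneous recovery rates
#'
#' Constant \eqn{\delta_i = \delta}: the standard SIS model, whose QMF
#' threshold is \eqn{\delta/\Lambda_{max}(A)}.
#'
#' @param nNodes number of nodes
#' @param delta the common positive rate
#' @return a [RecoveryRates-class]
#' @export
homogeneousRates <- function(nNodes, delta = 1) {
  stopifnot(delta > 0)
  .newRates(rep(as.numeric(delta), nNodes),
            list(scheme = "homogeneous", delta = delta))
}

#' Spreading schemes
#'
#' `uniformScheme()` gives every directed edge the same transmission rate
#' \eqn{\lambda}; `contactProcessScheme()` divides an infected node's budget
#' over its neighbours (\eqn{\lambda_{ij} = \lambda/k_i}, source degree
#' \eqn{k_i}), the contact process, whose QMF threshold is 1 on any
#' connected structure.
#'
#' @param lambda positive global spreading rate
#' @return a [SpreadingScheme-class]
#' @export
uniformScheme <- function(lambda = 1) {
  methods::new("SpreadingScheme", kind = "uniform",
               lambda = as.numeric(lambda))
}

#' @rdname uniformScheme
#' @export
contactProcessScheme <- function(lambda = 1) {
  methods::new("SpreadingScheme", kind = "contact_process",
               lambda = as.numeric(lambda))
}

#' Read/write rate vectors as plain text
#'
#' One value per line, node order; a `#` header records provenance.
#' @param path file path
#' @return [RecoveryRates-class] for the reader; `path` invisibly for the
#'   writer
#' @export
readRates <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  delta <- as.numeric(lines)
  if (anyNA(delta)) stop("non-numeric rate entry in ", path)
  .newRates(delta, list(scheme = "file", path = path))
}

#' @rdname readRates
#' @param rates a [RecoveryRates-class]
#' @export
writeRates <- function(rates, path) {
  prov <- provenance(rates)
  hdr <- sprintf("# recovery rates; scheme: %s", prov$scheme %||% "unknown")
  writeLines(c(hdr, format(rateValues(rates), digits = 17)), path)
  invisible(path)
}
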