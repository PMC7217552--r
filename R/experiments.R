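#' Geometric spreading-rate grid around a centre
#'
#' Experiment drivers centre their grids on the QMF prediction for the
#' instance at hand; the grid spans `span` multiplicatively on each side.
#'
#' @param center grid centre (e.g. a QMF critical point)
#' @param span multiplicative half-width (grid runs center/span..center*span)
#' @param length number of points
#' @return increasing numeric vector
#' @export
geometricLambdaGrid <- function(center, span = 3, length = 25) {
  exp(seq(log(center / span), log(center * span), length.out = length))
}

#' Susceptibility sweep over a spreading-rate grid
#'
#' One [quasistationaryRun()] per grid point; the finite-size threshold
#' proxy is the \eqn{\lambda} maximising \eqn{\chi}, refined by a quadratic
#' fit in \eqn{\log\lambda} through the maximum and its two neighbours.
#' When the raw maximum sits on the grid boundary no refinement is performed
#' and the result is flagged.
#'
#' @param net a connected [ContactNetwork-class]
#' @param rates a [RecoveryRates-class]
#' @param scheme a [SpreadingScheme-class] (kind; per-point \eqn{\lambda}
#'   comes from the grid)
#' @param lambdas strictly increasing grid with at least 5 points
#' @param qsParams list of overrides passed to [quasistationaryRun()]
#'   (relaxTime, avgTime, nStore, pStoreUpdate, sampleInterval,
#'   initFraction)
#' @param seed integer seed; point i uses `seed + i - 1`
#' @param qmf logical: attach the matching [QMFReport-class]?
#' @return a [SweepResult-class]
#' @export
lambdaSweep <- function(net, rates, scheme = uniformScheme(),
                        lambdas, qsParams = list(), seed = NULL,
                        qmf = TRUE) {
  if (length(lambdas) < 5 || is.unsorted(lambdas, strictly = TRUE)) {
    stop("lambdas must be a strictly increasing grid with >= 5 points")
  }
  ests <- vector("list", length(lambdas))
  for (i in seq_along(lambdas)) {
    args <- c(list(net = net, rates = rates, scheme = scheme,
                   lambda = lambdas[i],
                   seed = if (is.null(seed)) NULL else seed + i - 1L),
              qsParams)
    ests[[i]] <- do.call(quasistationaryRun, args)
  }
  chis <- vapply(ests, chi, 0)
  rhos <- vapply(ests, rho, 0)
  pk <- refineChiPeak(lambdas, chis)
  report <- if (qmf) qmfReport(net, rates, scheme) else NULL
  methods::new("SweepResult",
    lambdas = as.numeric(lambdas), rhos = rhos, chis = chis,
    lambdaPeak = pk$lambda, peakAtBoundary = pk$at_boundary,
    qmf = report,
    params = c(list(scheme = scheme@kind, seed = seed), qsParams)
  )
}

#' Refine a susceptibility-peak location
#'
#' Quadratic fit in \eqn{\log\lambda} through the maximum-\eqn{\chi} grid
#' point and its two neighbours; the vertex is the refined peak, clipped to
#' the bracketing interval. A maximum on the grid edge is returned as-is
#' with `at_boundary = TRUE`.
#'
#' @param lambdas increasing grid
#' @param chis matched susceptibilities
#' @return list with `lambda` and `at_boundary`
#' @export
refineChiPeak <- function(lambdas, chis) {
  stopifnot(length(lambdas) == length(chis), length(lambdas) >= 3)
  i <- which.max(chis)
  if (i == 1L || i == length(chis)) {
    return(list(lambda = lambdas[i], at_boundary = TRUE))
  }
  x <- log(lambdas[(i - 1):(i + 1)])
  y <- chis[(i - 1):(i + 1)]
  co <- stats::coef(stats::lm(y ~ x + I(x^2)))
  if (!is.finite(co[3]) || co[3] >= 0) {
    return(list(lambda = lambdas[i], at_boundary = FALSE))
  }
  xv <- -co[2] / (2 * co[3])
  xv <- min(max(xv, x[1]), x[3])
  list(lambda = exp(unname(xv)), at_boundary = FALSE)
}

#' Scan the inverse-gamma shape parameter
#'
#' For each shape \eqn{\alpha}: draw fresh unit-mean inverse-gamma recovery
#' rates (a fixed `rateSeed` gives paired comparisons across \eqn{\alpha}),
#' compute the QMF prediction with its sandwich bounds, and (optionally)
#' sweep the susceptibility to estimate the finite-size threshold. Small
#' \eqn{\alpha} means heavy-tailed rates and a depressed threshold; as
#' \eqn{\alpha} grows both prediction and estimate approach the homogeneous
#' SIS value \eqn{1/\Lambda_{max}(A)}.
#'
#' @param net a connected [ContactNetwork-class]
#' @param alphas vector of shapes, all > 1
#' @param scheme a [SpreadingScheme-class]
#' @param lambdas grid for the sweeps; `NULL` skips simulation and reports
#'   predictions only
#' @param qsParams overrides for [quasistationaryRun()]
#' @param rateSeed seed for the rate draws (shared across alphas)
#' @param sweepSeed seed for the sweeps
#' @return data.frame with one row per alpha: `alpha`, `qmf_critical_point`,
#'   `bound_low`, `bound_high`, `inf_norm_bound`, `ipr`, and when swept
#'   `lambda_peak`, `peak_at_boundary`, `prediction_minus_peak`
#' @export
alphaScan <- function(net, alphas, scheme = uniformScheme(),
                      lambdas = NULL, qsParams = list(),
                      rateSeed = 1L, sweepSeed = 1L) {
  stopifnot(all(alphas > 1))
  rows <- lapply(alphas, function(a) {
    rates <- inverseGammaRates(nNodes(net), a, seed = rateSeed)
    rep <- qmfReport(net, rates, scheme)
    row <- data.frame(
      alpha = a,
      qmf_critical_point = criticalPoint(rep),
      bound_low = rep@boundLow,
      bound_high = rep@boundHigh,
      inf_norm_bound = rep@infNormBound,
      ipr = ipr(rep)
    )
    if (!is.null(lambdas)) {
      sw <- lambdaSweep(net, rates, scheme, lambdas, qsParams,
                        seed = sweepSeed, qmf = FALSE)
      row$lambda_peak <- lambdaPeak(sw)
      row$peak_at_boundary <- sw@peakAtBoundary
      row$prediction_minus_peak <- row$qmf_critical_point - row$lambda_peak
    }
    row
  })
  do.call(rbind, rows)
}

#' Finite-size analysis of the susceptibility peak
#'
#' For each network size: generate the substrate, build the rates, centre a
#' geometric \eqn{\lambda} grid on the QMF prediction, sweep, and record the
#' refined peak. The log-log slope of \eqn{\lambda_{peak}(N)} (least
#' squares, with a normal-theory confidence interval) diagnoses whether the
#' threshold survives the large-N limit: a slope near 0 indicates a finite
#' critical point, a clearly negative slope a vanishing one.
#'
#' @param sizes increasing vector of at least 3 network sizes
#' @param networkFactory function(n, seed) -> connected [ContactNetwork-class]
#' @param ratesFactory function(net, seed) -> [RecoveryRates-class]
#' @param scheme a [SpreadingScheme-class]
#' @param gridSpan,gridLength geometric-grid shape around each QMF
#'   prediction
#' @param qsParams overrides for [quasistationaryRun()]
#' @param replicates independent (network, rates, sweep) replicates per size
#' @param seed base seed; replicates and sizes take offsets
#' @return list with `table` (one row per size x replicate: `n`,
#'   `replicate`, `lambda_peak`, `qmf_critical_point`, `peak_at_boundary`),
#'   `slope`, `slope_ci` (95%), `fit` (the lm object)
#' @export
finiteSizeAnalysis <- function(sizes, networkFactory, ratesFactory,
                               scheme = uniformScheme(),
                               gridSpan = 3, gridLength = 15,
                               qsParams = list(), replicates = 1,
                               seed = 1L) {
  stopifnot(length(sizes) >= 3, !is.unsorted(sizes, strictly = TRUE))
  rows <- list()
  for (si in seq_along(sizes)) {
    for (r in seq_len(replicates)) {
      s <- seed + 1000L * (si - 1L) + 10L * (r - 1L)
      net <- networkFactory(sizes[si], s)
      rates <- ratesFactory(net, s + 1L)
      rep <- qmfReport(net, rates, scheme)
      grid <- geometricLambdaGrid(criticalPoint(rep), gridSpan, gridLength)
      sw <- lambdaSweep(net, rates, scheme, grid, qsParams,
                        seed = s + 2L, qmf = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        n = sizes[si], replicate = r, lambda_peak = lambdaPeak(sw),
        qmf_critical_point = criticalPoint(rep),
        peak_at_boundary = sw@peakAtBoundary
      )
    }
  }
  tab <- do.call(rbind, rows)
  fit <- stats::lm(log(lambda_peak) ~ log(n), data = tab)
  ci <- stats::confint(fit, "log(n)", level = 0.95)
  list(table = tab, slope = unname(stats::coef(fit)["log(n)"]),
       slope_ci = c(ci), fit = fit)
}
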