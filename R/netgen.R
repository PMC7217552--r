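#' @importFrom igraph sample_gnp sample_degseq simplify as_adjacency_matrix
#'   components induced_subgraph graph_from_adjacency_matrix gorder
#'   ecount arpack vcount
#' @importFrom withr with_seed
#' @importFrom stats rgamma runif var
NULL

## internal: wrap a sparse symmetric adjacency into a validated ContactNetwork
.newNetwork <- function(A, provenance = list()) {
  A <- methods::as(methods::as(A, "generalMatrix"), "CsparseMatrix")
  A <- methods::as(A, "dMatrix")
  net <- methods::new("ContactNetwork",
    adjacency = A,
    degrees = as.integer(Matrix::rowSums(A)),
    provenance = provenance
  )
  methods::validObject(net)
  net
}

.fromIgraph <- function(g, provenance = list()) {
  A <- igraph::as_adjacency_matrix(g, type = "both", sparse = TRUE)
  .newNetwork(A, provenance)
}

.withSeed <- function(seed, expr) {
  if (is.null(seed)) eval.parent(substitute(expr))
  else withr::with_seed(seed, eval.parent(substitute(expr)))
}

#' Generate an Erdős–Rényi random graph
#'
#' Draws \eqn{G(N, p)} with \eqn{p = \langle k\rangle / (N - 1)} so that the
#' expected mean degree equals `meanDegree`. The graph is kept as sampled
#' (it may be disconnected); use [giantComponent()] when a single connected
#' component is required downstream.
#'
#' @param nNodes number of nodes, at least 2
#' @param meanDegree target mean degree, in (0, nNodes)
#' @param seed integer seed; `NULL` uses the current RNG state
#' @return a [ContactNetwork-class]
#' @examples
#' net <- erdosRenyiNetwork(500, 10, seed = 1)
#' mean(degrees(net))
#' @export
erdosRenyiNetwork <- function(nNodes, meanDegree, seed = NULL) {
  stopifnot(nNodes >= 2)
  p <- meanDegree / (nNodes - 1)
  if (!is.finite(p) || p <= 0 || p > 1) {
    stop("meanDegree must satisfy 0 < meanDegree <= nNodes - 1")
  }
  g <- .withSeed(seed, igraph::sample_gnp(nNodes, p, directed = FALSE))
  .fromIgraph(g, list(
    generator = "erdos_renyi", n = nNodes, mean_degree = meanDegree,
    p = p, seed = seed
  ))
}

#' Sample from a truncated discrete power law
#'
#' Exact inverse-CDF sampling from \eqn{P(k) \propto k^{-\gamma}} on the
#' integer support \eqn{[k_{min}, k_{max}]}, with the mass function
#' normalised by direct summation (a truncated zeta).
#'
#' @param nSamples number of draws
#' @param gamma power-law exponent (any real; heavy-tail regime is
#'   \eqn{2 < \gamma \le 3})
#' @param kMin,kMax integer support bounds, \eqn{k_{min} \le k_{max}}
#' @param seed integer seed; `NULL` uses the current RNG state
#' @return integer vector of draws
#' @examples
#' k <- sampleDiscretePowerLaw(1000, 2.5, 3, 31, seed = 1)
#' range(k)
#' @export
sampleDiscretePowerLaw <- function(nSamples, gamma, kMin, kMax, seed = NULL) {
  kMin <- as.integer(kMin); kMax <- as.integer(kMax)
  if (kMin < 1L || kMin > kMax) stop("need 1 <= kMin <= kMax")
  support <- kMin:kMax
  pmf <- support^(-gamma)
  pmf <- pmf / sum(pmf)
  cdf <- cumsum(pmf)
  u <- .withSeed(seed, stats::runif(nSamples))
  support[findInterval(u, cdf, left.open = TRUE) + 1L]
}

## exact mean of the truncated discrete power law (used by tests and docs)
discretePowerLawMean <- function(gamma, kMin, kMax) {
  support <- kMin:kMax
  pmf <- support^(-gamma)
  sum(support * pmf) / sum(pmf)
}

#' Generate an uncorrelated configuration-model power-law network
#'
#' Samples a degree sequence from the truncated discrete power law
#' \eqn{P(k) \propto k^{-\gamma}} on \eqn{[k_{min}, \lfloor\sqrt N\rfloor]}
#' (the structural cutoff, which suppresses degree correlations for
#' \eqn{\gamma < 3}), forces the degree sum even by resampling the last
#' entry, matches stubs uniformly, and erases self-loops and multi-edges.
#' The number of removed edges is recorded in the provenance.
#'
#' @param nNodes number of nodes
#' @param gamma degree exponent, must exceed 2
#' @param kMin minimum degree (default 3 keeps the giant component
#'   near-spanning)
#' @param seed integer seed; `NULL` uses the current RNG state
#' @return a [ContactNetwork-class]
#' @examples
#' net <- powerLawNetwork(1000, 2.5, kMin = 3, seed = 1)
#' max(degrees(net)) <= floor(sqrt(1000))
#' @export
powerLawNetwork <- function(nNodes, gamma, kMin = 3, seed = NULL) {
  if (gamma <= 2) stop("gamma must exceed 2")
  kMax <- floor(sqrt(nNodes))
  if (kMin > kMax) {
    stop("empty degree support: kMin exceeds the structural cutoff sqrt(N)")
  }
  .withSeed(seed, {
    ks <- sampleDiscretePowerLaw(nNodes, gamma, kMin, kMax)
    while (sum(ks) %% 2L != 0L) {
      ks[nNodes] <- sampleDiscretePowerLaw(1L, gamma, kMin, kMax)
    }
    g <- igraph::sample_degseq(ks, method = "configuration")
    before <- igraph::ecount(g)
    g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
    removed <- before - igraph::ecount(g)
    .fromIgraph(g, list(
      generator = "powerlaw_configuration", n = nNodes, gamma = gamma,
      k_min = kMin, k_max = kMax, seed = seed, removed_edges = removed
    ))
  })
}

#' Extract the giant component
#'
#' Induced subgraph on the largest connected component, with nodes relabeled
#' contiguously. Ties between equally sized components are broken in favour
#' of the one containing the smallest original node label. The old-to-new
#' label mapping is stored in `provenance(net)$node_map` (NA for dropped
#' nodes).
#'
#' @param net a [ContactNetwork-class]
#' @return a connected [ContactNetwork-class]
#' @export
giantComponent <- function(net) {
  stopifnot(methods::is(net, "ContactNetwork"))
  if (nNodes(net) == 0) stop("empty network")
  g <- igraph::graph_from_adjacency_matrix(adjacency(net), mode = "undirected")
  comps <- igraph::components(g)
  best <- which(comps$csize == max(comps$csize))
  if (length(best) > 1) {
    # tie: component whose smallest member has the smallest original label
    firsts <- vapply(best, function(cc) min(which(comps$membership == cc)), 0)
    best <- best[which.min(firsts)]
  }
  keep <- which(comps$membership == best)
  A <- adjacency(net)[keep, keep, drop = FALSE]
  nodeMap <- rep(NA_integer_, nNodes(net))
  nodeMap[keep] <- seq_along(keep)
  prov <- provenance(net)
  prov$giant_component <- TRUE
  prov$node_map <- nodeMap
  .newNetwork(A, prov)
}

#' Test whether a network is connected
#' @param net a [ContactNetwork-class]
#' @return logical
#' @export
isConnected <- function(net) {
  g <- igraph::graph_from_adjacency_matrix(adjacency(net), mode = "undirected")
  igraph::components(g)$no == 1L
}

#' Read a network from a plain-text edge list
#'
#' Two whitespace-delimited integer columns per line; lines starting with
#' `#` are ignored. Duplicate and reversed pairs are collapsed and
#' self-loops dropped (counts recorded in provenance). `indexing = "auto"`
#' treats the file as 1-based iff the minimum label is 1 and 0 never occurs.
#'
#' @param path file path
#' @param indexing "0-based", "1-based" or "auto"
#' @return a [ContactNetwork-class]
#' @seealso [writeEdgeList()]
#' @export
readEdgeList <- function(path, indexing = c("auto", "0-based", "1-based")) {
  indexing <- match.arg(indexing)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  lineNo <- which(keep)
  if (length(lines) == 0) stop("empty edge list: ", path)
  toks <- strsplit(trimws(lines), "\\s+")
  bad <- which(vapply(toks, length, 0L) != 2L)
  if (length(bad)) {
    stop("expected two tokens on line ", lineNo[bad[1]], " of ", path)
  }
  m <- suppressWarnings(matrix(as.integer(unlist(toks)), ncol = 2,
                               byrow = TRUE))
  if (anyNA(m)) {
    bad <- which(apply(is.na(m), 1, any))[1]
    stop("non-integer token on line ", lineNo[bad], " of ", path)
  }
  lo <- min(m)
  oneBased <- switch(indexing,
    "0-based" = FALSE,
    "1-based" = TRUE,
    "auto" = lo == 1L
  )
  if (oneBased && lo < 1L) stop("1-based edge list contains label < 1")
  if (!oneBased) m <- m + 1L
  loops <- m[, 1] == m[, 2]
  nLoops <- sum(loops)
  if (nLoops) message("dropped ", nLoops, " self-loop(s)")
  m <- m[!loops, , drop = FALSE]
  if (nrow(m) == 0) stop("edge list has no non-loop edges")
  labels <- sort(unique(as.vector(m)))
  i <- match(m[, 1], labels); j <- match(m[, 2], labels)
  lo2 <- pmin(i, j); hi2 <- pmax(i, j)
  dup <- duplicated(cbind(lo2, hi2))
  n <- length(labels)
  A <- Matrix::sparseMatrix(
    i = c(lo2[!dup], hi2[!dup]), j = c(hi2[!dup], lo2[!dup]),
    x = 1, dims = c(n, n)
  )
  .newNetwork(A, list(
    generator = "edge_list", path = path,
    indexing = if (oneBased) "1-based" else "0-based",
    dropped_self_loops = nLoops, collapsed_duplicates = sum(dup),
    original_labels = labels - if (oneBased) 0L else 1L
  ))
}

#' Write a network as a canonical 0-based edge list
#'
#' Emits one `i j` pair per undirected edge with `i < j`, 0-based labels,
#' sorted lexicographically; composing with [readEdgeList()] is the identity
#' on canonical networks.
#'
#' @param net a [ContactNetwork-class]
#' @param path output file path
#' @return `path`, invisibly
#' @export
writeEdgeList <- function(net, path) {
  A <- Matrix::triu(adjacency(net))
  tr <- methods::as(methods::as(A, "generalMatrix"), "TsparseMatrix")
  ord <- order(tr@i, tr@j)
  writeLines(paste(tr@i[ord], tr@j[ord]), path)
  invisible(path)
}
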