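---
title: "SIS epidemics with heterogeneous recovery rates: models and methods"
author: "hetSIS authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SIS epidemics with heterogeneous recovery rates: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetSIS)
```

## The model

A population of $N$ individuals is connected by a simple undirected graph
with adjacency matrix $A$. Each node is susceptible or infected. The
dynamics is a collection of independent Poisson processes: an infected node
$i$ recovers at its own rate $\delta_i$, and transmits along each edge
towards a susceptible neighbour $j$ at rate $\lambda_{ij}$. Two spreading
schemes are supported:

* **uniform** — $\lambda_{ij} = \lambda$ on every edge (standard SIS);
* **contact process (CP)** — $\lambda_{ij} = \lambda / k_i$, the infected
  node divides its budget over its $k_i$ neighbours.

The process is Markovian; the all-susceptible state is absorbing. The
observables are the order parameter and the susceptibility
$$\rho = \frac{1}{N}\sum_i \langle Y_i\rangle, \qquad
  \chi = \frac{\langle n_I^2\rangle - \langle n_I\rangle^2}
              {\langle n_I\rangle},$$
with $n_I$ the infected count, both taken over the quasistationary law
(the chain conditioned on survival).

The only deviation from textbook SIS is the per-node $\delta_i$. That is
enough to change the critical behaviour qualitatively: heterogeneity in the
*dynamical* parameters competes on equal terms with the structural
heterogeneity that usually dominates the discussion of epidemic thresholds
on networks.

## Quenched mean-field theory

Neglecting dynamical correlations
($\langle X_i Y_j\rangle \approx \langle X_i\rangle\langle Y_j\rangle$)
gives the rate equations
$$\frac{dy_i}{dt} = -\delta_i y_i + (1 - y_i)\sum_j \lambda_{ij}A_{ij}y_j,$$
implemented in `integrateQMF()`. Linearising around $y = 0$ shows the
disease-free state loses stability at
$$\lambda_c^{QMF} = \frac{1}{\Lambda_{\max}(Q)}, \qquad
  Q = \Delta^{-1}(A\circ W),\ \Delta_{ii} = \delta_i,$$
where $Q_{ij}$ is the expected number of contacts $i$ makes towards $j$
before recovering (`buildQ()`, `qmfReport()`). Since the global $\lambda$
only rescales $Q$, the matrix is built at $\lambda = 1$ and thresholds are
reported in $\lambda$ units.

Three companion quantities are reported with the threshold:

* **Sandwich bounds.** For the uniform scheme,
  $\min_i(\delta_i)/\Lambda_{\max}(A) \le \lambda_c^{QMF} \le
  \max_i(\delta_i)/\Lambda_{\max}(A)$: the homogeneous prediction brackets
  the heterogeneous one, with a gap that widens with the rate variance.
  Note the homogeneous value is *not* a lower bound for the heterogeneous
  process — that asymmetry is the central phenomenon here.
* **Gershgorin bound.** $\Lambda_{\max}(Q) \le \max_i k_i/\delta_i$
  (row sums of a nonnegative matrix). This is the lever for
  structure–dynamics correlations: $\delta_i = k_i$ caps the row sums at 1,
  so $\lambda_c = 1$ on any connected graph — a power-law network made
  dynamically homogeneous. The CP is the same mechanism expressed through
  the spreading rates ($P_{ij} = A_{ij}/k_i$, $\lambda_c = 1$ always).
* **IPR.** The inverse participation ratio $\sum_i v_i^4$ of the unit-norm
  leading eigenvector: $\approx 1/N$ when the epidemic activity is
  delocalised, $O(1)$ when it concentrates on a few nodes (hubs or slow
  recoverers). The standard $\ell_2$ convention is used.

## Recovery-rate schemes

* `inverseGammaRates(n, alpha)` — if infectious *periods* are
  gamma-distributed (the empirically supported choice), the *rates* are
  inverse-gamma, $\delta \sim \Gamma^{-1}(\alpha, \beta)$ with mean
  $\beta/(\alpha-1)$ and variance $\beta^2/((\alpha-1)^2(\alpha-2))$ for
  $\alpha > 2$. The scale is tied to the shape, $\beta = \alpha - 1$, which
  fixes the mean at exactly 1 *analytically* — comparisons across $\alpha$
  then isolate the effect of the tail, and no post-hoc rescaling distorts
  the distribution shape. $\alpha \le 2$ (infinite variance) is allowed but
  flagged; $\alpha \le 1$ (undefined mean) is rejected. Sampling uses the
  reciprocal-gamma identity $1/X$, $X\sim\Gamma(\alpha, \mathrm{rate}
  = \beta)$.
* `degreeCorrelatedRates(net)` — $\delta_i = k_i$ exactly.
* `powerLawShuffledRates(...)` — heavy-tailed rates on a homogeneous graph:
  draws from the truncated discrete power law $P(k)\propto k^{-\gamma}$
  (or a supplied degree sequence, e.g. that of a matched power-law network)
  assigned to nodes by a seeded random permutation. The permutation makes
  the rates *uncorrelated* with the local ER structure; reusing the
  power-law network's own degree sequence keeps the two finite-size
  scenarios on exactly the same marginal rate distribution. Whether any
  coupling between the rate values and the ER degrees is intended in the
  original protocol is ambiguous; the uncorrelated reading is the one
  implemented, and it is the one that isolates "heterogeneous dynamics on
  homogeneous structure".
* `homogeneousRates(n, delta)` — the standard SIS control.

## Network substrates

`erdosRenyiNetwork()` draws $G(N, p)$ with $p = \langle k\rangle/(N-1)$.
`powerLawNetwork()` is an uncorrelated configuration model: degrees sampled
from $P(k) \propto k^{-\gamma}$ on $[k_{\min}, \lfloor\sqrt N\rfloor]$ by
exact inverse-CDF (`sampleDiscretePowerLaw()`), the structural cutoff
suppressing degree correlations for $\gamma < 3$; an odd degree sum is
fixed by resampling the last entry; stubs are matched uniformly and
self-loops/multi-edges erased (counts recorded in provenance — at these
sizes the erasure bias is negligible). The default $k_{\min} = 3$ keeps the
giant component near-spanning; it is configurable, as are all generator
parameters. `giantComponent()` restricts to the largest connected component
(ties broken towards the smallest original label) because the spectral
theory assumes irreducibility.

**What the generators emulate, and what they do not.** The synthetic
substrates reproduce the two canonical structural regimes — homogeneous
(Poisson degrees) and scale-free with tunable $\gamma$ — under fixed seeds.
They do not emulate clustering, assortativity, communities, weights, or
temporal activity of real contact data. A green test on these substrates
establishes the spectral theory and the simulator against each other in the
stated regimes; it says nothing about confounders real networks add. Real
edge lists can be loaded with `readEdgeList()` and run through the same
machinery.

## The quasistationary simulator

`quasistationaryRun()` is an exact continuous-time Gillespie simulation
(compiled core): per-node total rates $\delta_i + \beta_i\,n^{susc}_i$ are
kept in a binary-indexed tree, giving $O(\log N)$ event selection; waiting
times are exponential in the total rate. Conditioning on survival uses the
standard store-based quasistationary method: a list of `nStore` previously
visited active configurations is maintained, refreshed with probability
`pStoreUpdate`$\times dt$ per event (the store is also *filled* on this
clock), and an absorption event replaces the state by a uniform draw from
the store. After `relaxTime`, $n_I$ is sampled on a fixed grid
(`sampleInterval`) over `avgTime` — on a time grid, not per event, to avoid
event-frequency bias — building the quasistationary histogram from which
$\rho$ and $\chi$ follow.

Defaults (production scale): `relaxTime = avgTime = 1e5`,
`nStore = 100`, `pStoreUpdate = 0.01`, `sampleInterval = 1`, all infected
initially. The method's parameters are not standardised in the literature;
these follow common practice and are recorded in the estimate's metadata.

Two finite-window artifacts matter when the windows are scaled down, and
both are visible in (and guarded by) the tests:

* **Store turnover.** Starting from all infected, the early store holds
  transient high-$n_I$ configurations. Deep subcritically these are
  resurrect targets that inflate $\chi$ enormously (a single contaminated
  resurrection shifts $\langle n_I^2\rangle$ by $O(N^2)$). The store must
  turn over before averaging: choose
  `pStoreUpdate * relaxTime` $\gtrsim 10\times$ `nStore`. The scaled-down
  test settings satisfy this; the production defaults do
  ($0.01 \times 10^5 = 10\times$ store).
* **Finite-store/finite-$p$ bias.** The restart distribution is an
  empirical measure over `nStore` correlated draws, so the stationary law
  differs from the exact quasistationary law by a tiny systematic amount
  (observed $O(10^{-5}$–$10^{-4})$ absolute on $\chi$ for tiny graphs, i.e.
  relative $10^{-4}$). This is intrinsic to the method, not a bug; the
  oracle-agreement tests run at a precision where Monte Carlo error
  dominates this residual, which is the regime any practical use of the
  method lives in.

`exactQSOracle()` provides ground truth for $N \le 12$: the full
$2^N - 1$-state restricted generator, whose dominant left eigenvector *is*
the quasistationary law. The simulator is validated against it across
homogeneous/heterogeneous rates and both schemes at $3\sigma$.

## Experiment drivers

`lambdaSweep()` estimates the finite-size threshold as the $\chi$-maximising
$\lambda$, refined by a quadratic fit in $\log\lambda$ through the maximum
and its two neighbours (peaks are located visually in the source material;
the quadratic vertex is this package's estimator choice, flagged rather
than refined when the raw maximum sits on the grid edge). Grids are
geometric and centred on the QMF prediction for the instance
(`geometricLambdaGrid()`), since the prediction is known before any
simulation. `alphaScan()` pairs predictions and peaks across the
inverse-gamma shape at a fixed rate seed, so the comparison is paired
rather than independently resampled. `finiteSizeAnalysis()` regresses
$\log\lambda_{peak}$ on $\log N$; a slope indistinguishable from 0 is the
signature of a finite large-$N$ threshold, a clearly negative slope of a
vanishing one. The slope's normal-theory 95% interval is reported; with few
sizes it is indicative, not inferential.

## Numerical choices

* **Eigensolver.** $Q = S^{-1}A$ (with $s_i = \delta_i$ or
  $\delta_i k_i$) is nonsymmetric but similar to the symmetric
  $S^{-1/2}AS^{-1/2}$; the Lanczos/ARPACK solve is done on the symmetric
  form (tol $10^{-10}$, residual-checked) and the eigenvector mapped back
  and clipped at 0 (Perron–Frobenius guarantees nonnegativity up to solver
  noise). Dense `eigen()` is the fallback for $n \le 64$ and the
  cross-check oracle in tests ($10^{-8}$ agreement required).
* **ODE integration.** Adaptive Cash–Karp RK45 with mixed
  absolute/relative error control ($10^{-8}/10^{-10}$), early stop at
  $\|dy/dt\|_\infty < 10^{-10}$; iterates clamped to $[0,1]$, which is
  invariant for the exact flow, to guard against round-off. (No installed
  ODE library is available in the target environment; the integrator is
  self-contained.)
* **Degenerate inputs.** Disconnected networks are rejected by `buildQ()`
  (extract the giant component first); isolated nodes are rejected by
  `degreeCorrelatedRates()`; $\alpha \le 1$ inverse-gamma is rejected;
  empty edge lists and non-integer tokens are parse errors with line
  numbers.
* **Seeding.** Every stochastic function takes an explicit `seed` and uses
  it via a scoped RNG (`withr::with_seed`); the compiled simulator draws
  from R's RNG stream, so a seeded call is bit-reproducible. Replicates use
  documented seed offsets.

## Limitations

* The QMF threshold is an approximation that neglects dynamical
  correlations; on finite networks the susceptibility peak generally sits
  near, not on, the prediction, and for heavy-tailed rates the simulated
  threshold falls below the *homogeneous* prediction by design.
* The quasistationary estimates carry the finite-store bias discussed
  above, plus finite-window Monte Carlo error; $\chi$ is particularly
  sensitive to rare high-$n_I$ samples.
* The configuration model's loop/multi-edge erasure slightly perturbs the
  degree sequence at small $N$ or $\gamma$ close to 2.
* Directed, weighted and temporal networks, SIR-type dynamics,
  non-Markovian waiting times, and per-edge rate heterogeneity beyond the
  two schemes are out of scope.
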