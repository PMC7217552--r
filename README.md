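# hetSIS

SIS epidemics on networks when every node recovers at its own rate.

## The problem

The susceptible–infected–susceptible (SIS) model usually assumes a single
recovery rate δ for the whole population. Real infectious periods vary
between hosts — immunity, demographics, access to care — so a more faithful
model gives node *i* its own Poisson recovery clock with rate δᵢ while
infected neighbours transmit along each edge at rate λ. hetSIS implements
this heterogeneous-rate model for people studying epidemic thresholds on
networks: the spectral (quenched mean-field, QMF) theory, an exact
continuous-time stochastic simulator, and the experiment protocols that
compare the two.

The central object is the contact matrix

    Q = Δ⁻¹ (A ∘ W),   Δᵢᵢ = δᵢ,  Wᵢⱼ = λᵢⱼ (λ = 1),

whose entries count the expected infectious contacts from *i* towards *j*
before *i* recovers. The QMF rate equations

    dyᵢ/dt = −δᵢ yᵢ + (1 − yᵢ) Σⱼ λᵢⱼ Aᵢⱼ yⱼ

lose the disease-free state's stability at the epidemic threshold

    λ_c^QMF = 1 / Λ_max(Q),

sandwiched by min(δᵢ)/Λ_max(A) ≤ λ_c ≤ max(δᵢ)/Λ_max(A) and bounded through
Gershgorin's theorem by Λ_max(Q) ≤ max_i kᵢ/δᵢ. That last bound is the
interesting lever: choosing δᵢ = kᵢ pins the threshold of *any* power-law
network at λ_c = 1 (a scale-free graph made dynamically homogeneous), while
assigning power-law-distributed rates to an Erdős–Rényi graph can make a
homogeneous structure behave like a scale-free one, with a threshold that
sinks as the network grows.

Stochastic ground truth comes from a Gillespie simulation conditioned on
survival (the quasistationary method): whenever the chain hits the absorbing
all-susceptible state it restarts from a stored active configuration, and
the quasistationary histogram of the infected count n_I yields the order
parameter ρ = ⟨n_I⟩/N and the susceptibility χ = (⟨n_I²⟩ − ⟨n_I⟩²)/⟨n_I⟩,
whose peak across λ locates the finite-size threshold.

## Worked example

```r
library(hetSIS)

net   <- giantComponent(erdosRenyiNetwork(2000, 10, seed = 1))
rates <- inverseGammaRates(nNodes(net), alpha = 2.5, seed = 2)
rep   <- qmfReport(net, rates)
rep
#> QMFReport
#>   Lambda_max(Q)   : 20.13520685
#>   critical point  : 0.04966425264
#>   sandwich bounds : [0.0104288, 1.6522]
#>   inf-norm bound  : Lambda_max <= 101.793
#>   IPR             : 0.0181254 (1/N = 0.0005)

quasistationaryRun(net, rates, lambda = criticalPoint(rep),
                   relaxTime = 500, avgTime = 2000, pStoreUpdate = 2,
                   seed = 3)
#> QSEstimate at lambda = 0.0496643
#>   rho = 0.0028963, chi = 4.01561 (2001 samples)
```

Heavy-tailed recovery rates (inverse-gamma with shape α = 2.5, unit mean)
nearly halve the threshold relative to the homogeneous prediction for this
graph (1/Λ_max(A) ≈ 0.089): Λ_max(Q) ≈ 20.1 against Λ_max(A) ≈ 11.2. The
simulated susceptibility is already sizeable at the predicted critical
point, consistent with the heterogeneous threshold sitting below the
homogeneous one. The wide sandwich bounds reflect the large rate variance
at this α, and the IPR ≈ 0.018 (well above 1/N = 0.0005) signals a leading
eigenvector concentrating on slowly recovering hubs of the contact matrix.

Experiment drivers: `lambdaSweep()` (χ(λ) curves with refined peak),
`alphaScan()` (threshold vs rate-distribution shape), and
`finiteSizeAnalysis()` (log-log slope of the peak location versus N).
A command-line wrapper around these functions is installed at
`inst/scripts/hetsis.R` (subcommands `qmf`, `simulate`, `sweep`; edge-list
and one-rate-per-line text inputs).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from freshly generated networks, the three spectral headline
numbers: the standard QMF critical point 1/Λ_max(A) of an Erdős–Rényi
network with N = 10⁵ and ⟨k⟩ = 10 (median of three replicates); the
contact-process critical point across varied connected topologies; and the
critical point under degree-matched recovery rates δᵢ = kᵢ on power-law
networks (γ = 2.1, 2.7, 3.5; N = 10⁴). Results are written as JSON to
`--out`.
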