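# decodecap

Stochastic simulation and information-theoretic analysis of how a signaling
pathway's *decoding section* turns a transient kinase input into gene
expression — and how many distinguishable input amplitudes survive the trip.

## The problem

The MAPK/ERK pathway encodes stimulus identity and dose in the temporal
profile of doubly phosphorylated cytoplasmic ERK. A downstream decoding
module — two nested coherent type-I feed-forward loops (FFLs) ending in the
transcription factor pcFos — reads that profile and drives gene expression,
modulated by promoter affinity. Treating the module as a noisy communication
channel, the package asks: for an input family
`ppERK_cyt(t) = L [k2 (e^(-t/T2) - 1) - k1 (e^(-t/T1) - 1)]` whose amplitude
scale `L` is swept over discrete levels (the input symbols), how much mutual
information does the count of a chosen molecular readout at a chosen time
carry about `L`, and what is the channel capacity

```
CC(R; S) = max_{P(S)} I(R; S),    I(R;S) = H(R) - H(R|S)
```

computed with the Arimoto–Blahut algorithm from histogram-estimated
conditional distributions `P(R = r_i | S = s_j)`? For gene sets, the
multivariate mutual information `I(R1,...,Rn; S)` under conditional
independence quantifies the set's non-redundant information. The coefficient
of variation (SD/mean across realizations) tracks where noise is added.

It is aimed at computational/systems biologists studying information
transmission in signaling networks, and doubles as a general toolkit for
exact simulation of small reaction networks with prescribed time-varying
input hazards plus capacity estimation of the resulting channels.

## What's inside

* **Models** — the MAPK/ERK decoding section (14 reactions, published rate
  table), a steady-state-normalized minimal FFL decoder (proteins B–E), a
  linear-chain control, and single-copy two-state promoter reporter genes
  attachable to any species (`compose()`), in three affinity variants.
* **Engines** — an exact SSA in compiled code (Ogata thinning for the
  decaying input hazards; optional piecewise-constant lognormal extrinsic
  noise on a rate constant, default `k11`), and a mean-field ODE integrator
  whose right-hand side is derived from the same propensities
  (`ode_integrate()`, `steady_state()`).
* **Metrics** — `estimate_channel()`, `arimoto_blahut()`, `mmi()`,
  `cc_timeseries()`, `coefficient_of_variation()`, plus bootstrap helpers
  for ordering/equivalence tests.
* **Fixtures** — channels with closed-form capacity and ensembles with
  known laws (`make_channel()`, `make_ensemble()`), so every analysis stage
  is testable without the full pathway.
* **Experiments** — five config-driven drivers (`run_mapk_cc()`,
  `run_minimal_cc()`, `run_linear_vs_ffl()`, `run_affinity_mmi()`,
  `run_extrinsic_noise()`), a `desk` (scaled) and a `full` (reference
  protocol: 200 min, 1000 realizations, 12 L levels) profile, CSV + JSON
  manifest outputs, and a thin shell wrapper in `inst/scripts/`.

## Worked example

Capacity of the minimal decoder's first and last proteins over a two-level
input sweep (small enough to run in a few seconds):

```r
library(decodecap)
cfg <- experiment_config("minimal_cc", L = c(10, 60), n_real = 50,
                         t_end = 120, seed = 1)
res <- run_minimal_cc(cfg)
subset(res$cc, time == 120 & species %in% c("B", "E"))
#>     species time        cc          gap iterations
#> 121       B  120 0.6849992 4.033240e-07         10
#> 484       E  120 0.2523640 7.500245e-07         35
subset(res$cv, species %in% c("B", "E") & L == 60)[, c("species", "cv")]
#>    species        cv
#> B1       B 0.5713488
#> E1       E 1.5661664
```

Reading: at `t = 120` min the first protein of the cascade separates the
two input amplitudes to ~0.68 bits (1 bit would be perfect two-level
discrimination at these noise levels), while the last protein — whose
production rate is bilinear in its upstream regulators and therefore
amplifies the input's cell-to-cell spread — retains ~0.25 bits and carries
almost three times the relative noise (CV 1.57 vs 0.57). Swapping in the
linear-chain control or attaching reporter genes isolates which of those
losses are due to topology, amplification, or promoter affinity.

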