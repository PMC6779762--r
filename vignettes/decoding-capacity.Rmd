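---
title: "Information transmission through a signaling pathway's decoding section"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information transmission through a signaling pathway's decoding section}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(decodecap)
```

## The question

A growth-factor stimulus is encoded by a cell in the temporal profile of
doubly phosphorylated cytoplasmic ERK (ppERK~cyt~), and a downstream
*decoding section* — two nested coherent type-I feed-forward loops (FFLs)
ending in the transcription factor pcFos — turns that profile into gene
expression. How many distinguishable input amplitudes survive this trip,
given intrinsic reaction noise and extrinsic parameter fluctuations? The
package treats the pathway as a communication channel: the input symbol is
the amplitude scale $L$ of the ppERK~cyt~ transient, the response is the
molecule count of a chosen readout at a chosen time, and the figure of merit
is the channel capacity (CC, in bits) computed with the Arimoto–Blahut
algorithm. Two decoding mechanisms are compared and coupled: the FFL
topology itself and the promoter affinity of reporter genes.

## Models

**Input.** The prescribed input trace is the difference of two saturating
exponentials,
$$\mathrm{ppERK_{cyt}}(t) = L\left[k_2(e^{-t/T_2}-1) - k_1(e^{-t/T_1}-1)\right],$$
which starts at 0 and saturates at $L(k_1-k_2)$. Three published shape
parameter sets (`standard_inputs()`: I1–I3) emulate three growth-factor
doses; $L$ is swept (`l_sweep()`, default 10–120 in steps of 10, each level
one input symbol). Stochastically, the positive and negative parts of the
trace's derivative become the production and degradation hazards of a
time-inhomogeneous birth/death pair — so the ensemble mean of the stochastic
input reproduces the trace exactly. Because the printed degradation hazard
does not depend on the current count, it is gated to zero whenever the count
is zero; the bias is negligible since the trace is positive wherever the
hazard is appreciable. A consequence worth keeping in mind: the input's
late-time count is (gated) Skellam-distributed with variance
$L(k_1+k_2)$ — cell-to-cell input spread is substantial at the amplitudes
studied, and that spread is what downstream readouts must decode.

**Decoding section.** Fourteen reactions over eight species (nuclear
import, DUSP feedback, RSK activation, Hill-type cFos transcription with
exponent 1.1, and the ppERK-driven cFos→pcFos stabilization cycle), with
the published rate table pinned in `rate_constants()` and audited in the
tests against the governing differential equations. Three modelling
decisions were genuinely open and are resolved as follows:

* ppERK~cyt~ is *prescribed*: the import and stabilization reactions read
  it catalytically and only the input hazards change its count. Consuming
  one input molecule per import event (a literal reading of the reaction
  arrow) would depress the input four-fold and contradict the closed-form
  trace that defines the model.
* The DUSP balance equation is implemented as production at
  $k\,\mathrm{ppERK_{nuc}}$ (the rate table's propensity); DUSP has no
  decay reaction, so it grows without bound and `steady_state()` reports it
  as divergent rather than failing.
* The promoter activation propensity carries the prefactor
  $\kappa_{pm}=0.1\,\mathrm{min^{-1}}$ from the rate table, and the
  mean-field ODE uses the same rate law — the deterministic equations are
  derived from the stochastic propensities, never maintained separately, so
  the ODE can serve as an oracle for the simulator. (The promoter's
  occupancy at half-saturating factor is then
  $\kappa_{pm}/2 \,/\, (\kappa_{pm}/2 + \gamma_{pm}) = 0.2$.)

**Minimal decoder.** Four identical proteins B–E in the same nested-FFL
wiring, driven by the same input, with propensities normalized by
$A_N = L(k_1-k_2)$ and $G_N = k/g$ so the *deterministic* steady state of
every protein is the common value $SS = A_N G_N$ — amplification is removed
by construction and only the topology differs from a linear relay
(`build_linear_chain_network()`, same parameters). Note that the
normalization fixes the deterministic fixed point, not the stochastic mean:
the bilinear D and E production rates rectify the input's cell-to-cell
spread ($\mathbb{E}[a^2] > A_N^2$), so the late-time ensemble means of D
and E sit above $SS$ by roughly $\mathrm{CV}_a^2$ and $3\,\mathrm{CV}_a^2$
respectively. That surplus *is* the noisy amplification under study, and it
is why the package validates the simulator on the linear species (B, C, the
linear chain, birth–death fixtures), where means follow the ODE exactly.

**Reporter genes.** A single-copy two-state promoter (conserved
active/inactive pair), Hill activation in the transcription factor with
exponent 2 and half-saturation $K_{rp}$ (the inverse affinity; variants
scale it by 0.1/1/10 for high/nominal/low affinity), linear transcription,
translation and decay. Genes read their factor catalytically, so coupling
reporters never perturbs the host pathway — a property asserted
structurally in the tests.

## Simulation

`ssa_simulate()` draws statistically exact trajectories. Propensities are
constant between events except the two input hazards, which decay
monotonically; waiting times therefore come from Ogata thinning with the
current total propensity as the bound — a proposal at rate
$\Lambda(t_0)$ is accepted with probability $\Lambda(t_1)/\Lambda(t_0)$,
which is exact because the bound can only shrink over the waiting interval.
Extrinsic noise is modelled as a piecewise-constant lognormal process on
one rate constant (default the pcFos phosphorylation rate $k_{11}$, nominal
0.11): at absolute times $0, P_{ext}, 2P_{ext}, \dots$ the value is redrawn
as $0.11\,e^{\varepsilon_{noise} Z}$. Update times are treated as hard
barriers — the clock never jumps across one — because a redraw may *raise*
a propensity and would otherwise invalidate the thinning bound. A master
seed spawns per-realization streams, and every ensemble records its seeds,
so results are bit-reproducible.

The mean-field ODE engine (`ode_integrate()`, stiff-capable `lsoda` at
`rtol = 1e-8`, `atol = 1e-10` — oracle-grade accuracy is essentially free
at ten state variables) and the analytic fixtures (`make_channel()`,
`make_ensemble()`: identity/symmetric/binary-symmetric channels with
closed-form capacity, Poisson maps, a birth–death process with Poisson
stationary law) exist so that every stage of the analysis is testable
without simulating the full pathway.

## Information metrics

At each sample minute the per-input response histograms over a pooled
min–max range with 64 equal-width bins (shared support is what makes the
channel well defined; 64 bins keeps three-gene joint summation tractable
and histogram noise modest at the realization counts used) form the
conditional matrix $P(R\mid S)$. `arimoto_blahut()` alternates the standard
posterior/input updates from a uniform start until the upper/lower capacity
bound gap is below $10^{-6}$ bits. `mmi()` computes the multivariate mutual
information of a gene set under conditional independence,
$P(r_1\dots r_n\mid s) = \prod_i P(r_i\mid s)$, with all-zero joint columns
pruned; by default the input distribution is the capacity-achieving
distribution of the joint channel (so the reported MMI is the set's
capacity), and any explicit distribution can be supplied instead. No
small-sample bias correction is applied; instead the experiment-level
conclusions are orderings and trends tested by a one-sided bootstrap over
realizations (200 resamples, 0.05 level), with "no difference" read as a
difference within two bootstrap standard deviations. MMI bootstrap
replicates use 32 bins: the resampling spread dominates the bin-refinement
term there, and the coarser joint support keeps the replicates cheap; the
point estimates themselves stay at 64 bins.

## Experiments and profiles

Five drivers (`run_mapk_cc()`, `run_minimal_cc()`, `run_linear_vs_ffl()`,
`run_affinity_mmi()`, `run_extrinsic_noise()`) reproduce the study's
computational experiments end to end from an `experiment_config()`. The
`full` profile is the reference protocol: 200 min horizon, 1 min sampling,
1000 realizations per input level, 12 levels. The `desk` profile — used by
the test suite and the bundled acceptance script — keeps the protocol but
scales to 200 realizations and 6 levels: the reporter-based experiments
subsample the full amplitude range ($L = 20, 40, \dots, 120$; the
nominal-affinity reporter only engages at the upper levels, so truncating
the range would silence it), while the minimal-decoder experiments, fully
resolved at low amplitude, use $L = 10\dots60$. The extrinsic-noise grids
there are
$\varepsilon_{noise} \in \{0, 1\}$ and $P_{ext} \in \{1, 20, 200\}$ min
(the reference figures likewise contrast zero with the highest intensity;
the exact published grids are not printed anywhere, so the grids are this
package's choice and are config-overridable). MMI is evaluated every
10 min.

A short worked example (a two-level sweep so it runs in seconds):

```{r, eval = FALSE}
cfg <- experiment_config("minimal_cc", L = c(10, 60), n_real = 50,
                         t_end = 120, seed = 1)
res <- run_minimal_cc(cfg)
subset(res$cc, time %in% c(30, 120))   # CC rises then settles
subset(res$cv, species %in% c("B", "E"))  # E noisier than B at t = 150
```

## Numerical choices and degenerate inputs

* Equal-width binning on the pooled range; a degenerate pooled range (all
  observations identical, e.g. $t=0$) yields a valid single-bin channel
  with zero capacity.
* $0\log 0 = 0$ throughout; Arimoto–Blahut works on $2^{D_j - \max_j D_j}$
  to avoid overflow and reports the residual bound gap when the iteration
  cap is hit.
* `steady_state()` integrates to a probe horizon, flags still-drifting
  species as divergent, and polishes the rest with damped Newton iterations
  on the mean-field right-hand side (finite-difference Jacobian), keeping
  the state non-negative.
* Sub-seeds for conditions are derived from the master seed by a fixed
  integer map and stay below $2^{31}$.

## What the generator does and does not emulate

The synthetic data are exact samples of the *model*: intrinsic copy-number
noise, the prescribed input family, and a controlled lognormal extrinsic
process on one parameter. They do not emulate receptor-level encoding
(upstream of ppERK~cyt~), transcriptional bursting beyond the two-state
promoter, cell division, or correlated extrinsic noise across parameters —
so a passing suite says the analysis chain is correct for this model class,
not that a wet-lab pathway attains these capacities. Histogram capacity
estimates carry small-sample bias that grows with bin count and shrinks
with realizations; orderings between conditions estimated at the same
sample size are robust to it, absolute bit values less so.

## Known limitations

* Exact SSA only; no tau-leaping or hybrid acceleration. The compiled core
  handles the reference protocol, but much stiffer networks would not fit
  this design.
* MMI by direct summation is limited to a few genes at 64 bins (the joint
  support is pruned to realized cells, which keeps three-gene sets cheap).
* The capacity of continuous-valued readouts is approached only through
  binning; no differential-entropy or k-NN estimators are provided.
* `steady_state()` reports divergence rather than computing asymptotic
  growth rates (DUSP grows linearly at late times by construction).
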