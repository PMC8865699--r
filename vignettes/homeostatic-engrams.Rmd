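---
title: "Homeostatic structural plasticity and memory engrams: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homeostatic structural plasticity and memory engrams: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(engramnet)
```

## The model

`engramnet` simulates and analyses a recurrent network of current-based
leaky integrate-and-fire (LIF) neurons in which the
excitatory-to-excitatory (EE) wiring itself is the plastic variable.
The membrane potential of neuron $i$ obeys

$$\tau_m \dot V_i = -V_i + \tau_m \sum_j C_{ij} J_{ij} S_j(t - D) + R I_i(t),$$

with integer contact counts $C_{ij}$ (multapses allowed), delta-pulse
synapses of amplitude $J$ (excitatory) or $-gJ$ (inhibitory), a shared
transmission delay $D$, and independent external Poisson drive of rate
$\nu_{ext}$ delivering pulses of amplitude $J$. Spikes reset the membrane
to $V_r$ and clamp it for $t_{ref}$.

Plasticity is homeostatic and structural. Each excitatory neuron low-pass
filters its own spike train into a calcium trace,
$\tau_{Ca}\dot\phi_i = -\phi_i + S_i(t)$, and grows continuous counters of
axonal and dendritic *synaptic elements* at speed
$\beta \dot x_i = \nu - \phi_i$: below the target rate $\nu$ a neuron
offers new half-synapses, above it it withdraws them. At every rewiring
interval $\Delta T_s$, counters below the current degree delete the
deficit among existing contacts (uniformly at the level of individual
contacts, so multapses lose contacts in proportion to their count; the
bonded counterpart of every deleted contact becomes free again), after
which all free axonal and dendritic elements are pooled and
$n = \min(|a^+|,|d^+|)$ of them are paired uniformly at random, excluding
self-connections. Uniform pairing without replacement makes the increment
of a single connection hypergeometric-like: the preferred ensemble of a
pair $(j \to i)$ has size $d_i^+ a_j^+$ among $|a^+||d^+|$ element
combinations. The closed-form hypergeometric is exact whenever
$d_i^+ a_j^+ \le 1$ — the typical situation in a grown network, where free
elements are sparse — and only approximate when a neuron holds several
free elements at once; the test suite checks the exact pairing law by
exhaustive enumeration on small instances and documents both cases.

Co-stimulation of a neuronal ensemble transiently raises its rate, prunes
its synapses homeostatically, and — after stimulus offset — rebuilds them
preferentially *within* the co-stimulated group, because the creation
step pairs free elements combinatorially across the whole network. The
result is an engram: a group of neurons with elevated mutual connectivity
but unchanged total in- and out-degree and unchanged ongoing activity.

## Mean-field theory

The package implements the matching population theory for two plastic
excitatory ensembles (E1, E2) and a static inhibitory population:

* **Rates.** Input moments $\mu_Y, \sigma_Y$ aggregate recurrent,
  inhibitory and external Poisson input into a Gaussian current; the
  stationary rate is the Siegert first-passage formula, evaluated in the
  overflow-safe form $\mathrm{erfcx}(-u)$ with an asymptotic branch for
  drift-dominated input (`siegert_rate()`). Rate dynamics is
  Wilson-Cowan-type relaxation, $\tau_{rate}\dot r_Y = -r_Y + f(\mu_Y,
  \sigma_Y)$, with $\tau_{rate} = \tau_m/2$; results are insensitive to
  this choice for $\tau_{rate} \le \tau_m$.
* **Calcium.** $\tau_{Ca}\dot\phi_Y = r_Y - \phi_Y$, exactly.
* **Connectivity flow.** Element creation/deletion rates are
  noise-corrected: Campbell's theorem gives the stationary calcium
  fluctuation $\sigma_{Ca}^2 = CV^2 \nu/(2\tau_{Ca})$ for a renewal train
  of irregularity $CV$, so the element rate is a rectified Gaussian with
  mean drive $(\nu - \phi_Y)/\beta$ and spread
  $\sigma_x = \eta\sqrt{\nu/(2\tau_{Ca})}/\beta$
  (`element_rate_mean()`, `element_rate_sd()`). Elements freed by
  deletions re-enter the pairing pool (the "corrected" free-element
  rates), and the creation term divides by the network pairing rate
  $\rho = \max(|\rho'_{a^+}|, |\rho'_{d^+}|)$.

With $\eta = 0$ every configuration with the equilibrium in- and
out-degree $K^*$ is stationary: the deterministic system has a line
attractor `line_attractor_point()` (a hyperplane of dimension
$(n_E-1)^2$ for $n_E$ plastic ensembles,
`stationary_hyperplane_dim()`). With $\eta > 0$ spontaneous rewiring
turns the line into a slow manifold along which engrams diffuse back to
the uniform, most entropic configuration $\bar C = K^*/N_E$ at rate

$$|\lambda_1| = \frac{R_{\sigma_a}(0) + R_{\sigma_d}(0)}{c N_E}, \qquad
\tau_{diffusion} = \frac{1}{|\lambda_1|} =
\sqrt{\frac{4\pi\tau_{Ca}}{\eta^2\nu}} \; \frac{c N_E}{1/\beta_a + 1/\beta_d},$$

about $5.7 \times 10^3$ s at the default parameters
(`slow_mode_timescale()`); memory formation, by contrast, is drift-driven
and fast. Because the equilibrium connectivity $c$ itself depends on the
target rate, memory longevity has an interior optimum near 3 Hz
(`optimal_target_rate()`).

Stability is analysed on the assembled $9\times9$ Jacobian
(`build_jacobian()`; calcium and rate blocks analytic, connectivity rows
by Richardson finite differences of `connectivity_flow()`, checked
against the closed-form rank-one block). A reduced one-population
Jacobian gives the oscillation boundary of the homeostatic controller,
$\tau_{Ca} \approx 3\beta_d$ s (`oscillation_boundary()`), and the
two-population rate block gives the critical within-engram connectivity
$c_{crit} = \epsilon(1 + N_{E2}/(N_{E1} j_E))$, about 28% at defaults
(`critical_connectivity()`), beyond which stimulation triggers a
pathological connectivity-rate limit cycle (`classify_regime()`).

## Default parameters

| parameter | default | meaning |
|---|---|---|
| $N_E$, $N_I$ | 10000, 2500 | population sizes (full scale) |
| $V_{th}$, $V_r$ | 20, 10 mV | threshold, reset |
| $t_{ref}$, $D$ | 2, 1.5 ms | refractory period, synaptic delay |
| $J$, $g$ | 0.1 mV, 8 | EPSP amplitude, inhibition ratio |
| $\nu_{ext}$ | 15 kHz | external Poisson rate |
| $\tau_m$ | 20 ms | membrane time constant (see below) |
| $\nu$ | 8 Hz | homeostatic target rate |
| $\tau_{Ca}$ | 10 s | calcium filter (1 s in the conditioning preset) |
| $\beta_a = \beta_d$ | 2 | element growth (0.4 in the conditioning preset) |
| $\Delta T_s$ | 100 ms | rewiring interval (10 ms in the conditioning preset) |
| $\eta$ | 0.7 | irregularity correction in the noise theory |
| $\tau_{rate}$ | $\tau_m/2$ | rate-relaxation constant of the theory |

The membrane time constant is not pinned down by the network class; 20 ms
is the standard choice for cortical balanced networks and reproduces the
equilibrium in-degree $K \approx 1000$ of the reference configuration
almost exactly (`equilibrium_indegree(8)`), which is why it is the
default. It is exposed in `lif_params()` and the operating point shifts
only mildly over 10–30 ms.

## A note on the ISI irregularity

`cv_isi()` evaluates the first-passage-time expression

$$CV^2 = 2\pi (r\tau_m)^2 \int_{y_r}^{y_{th}} e^{x^2}
\int_{-\infty}^{x} e^{y^2}(1+\mathrm{erf}\,y)^2\,dy\,dx$$

and returns its square root, the coefficient of variation proper. At the
grown operating point this gives $CV \approx 0.86$, and an independent
diffusion simulation of the LIF at the same input moments yields the same
empirical value (the unit suite repeats this check against a simulated
spike train). The value $0.7$ often quoted for this configuration is the
*un-rooted* double integral, i.e. $CV^2$; we deliberately report the true
CV and keep the discrepancy visible rather than silently matching the
quoted number. The irregularity correction of the noise theory keeps its
conventional value $\eta = 0.7$, which places $\tau_{diffusion}$ at
$5.7\times10^3$ s; using the computed CV instead would give
$4.6\times10^3$ s — both are "around $5\times10^3$ s" and the package
exposes $\eta$ so either convention can be selected.

## Synthetic data and down-scaling

All inputs are generated internally: Poisson external drive, Gamma
renewal trains (`gamma_spike_train()`) for the calcium shot-noise
analysis, and networks grown from scratch. The spiking experiments of the
test suite use a *scaled preset* (`scaled_network()`): $N_E = 1000$,
$N_I = 250$, but with the **absolute static in-degrees of the full-scale
network** (250 inhibitory contacts per neuron, 1000 excitatory contacts
per inhibitory neuron, multapses absorbing the smaller source pools).
This preserves the mean-field operating point exactly — the grown
equilibrium in-degree, rates and input moments match the full-scale
theory — while reducing wall time by two orders of magnitude. What the
scaled runs cannot reproduce are full-scale fluctuation statistics
(relative finite-size noise is $\sqrt{10}$ larger) and the printed
absolute connectivity values ($\bar C \approx 1$ instead of $0.1$, since
$K^* \approx 1000$ contacts are spread over 999 possible partners);
ordering and convergence claims are unaffected, and the quantitative
connectivity targets are checked on the mean-field model at full scale.

Problem sizes used by the automated checks: growth runs of 500 s at
$dt = 0.5$ ms on the scaled network, three-cycle repeated stimulation for
the engram fixtures, the full 24-episode conditioning protocol at scaled
size, and mean-field integrations of up to 5650 s model time at
$dt = 1.5$ ms. Pattern-completion probes use a handful of subset draws
rather than the 50 of the full protocol; the contrast against an
unstructured control network is already unambiguous at that size.

## Numerical choices

* Clock-driven integration with the exact exponential propagator for the
  leak; delta synapses make this exact up to spike-time discretisation.
  $dt$ must divide the delay $D$; full-scale presets use 0.1 ms, the
  scaled test runs 0.5 ms (the homeostatic controller clamps mean rates,
  so discretisation affects rates well below the tolerances tested).
* Delays via a ring buffer of length $D/dt$; all threshold crossings
  within a step are processed simultaneously (order-independent because
  synapses are delayed). Refractory neurons discard input.
* External drive as per-step Poisson counts, so stimulus multipliers act
  exactly; separate, independently seeded RNG streams (xoshiro256++) for
  construction, drive and rewiring make every protocol bit-reproducible.
* Deletion quotas are fixed when a rewiring step begins and clipped to
  the contacts actually present; deletions run before creations and the
  freed counterparts re-enter the same step's pairing pool. Self-pairings
  are redrawn uniformly among not-yet-consumed partner elements and
  dropped only when every remaining free element belongs to one neuron.
* Siegert quadrature: composite 16-point Gauss-Legendre on segments of
  width 0.5 in normalised units, analytic asymptotics beyond
  $|y| > 10$; `cv_isi()` uses adaptive quadrature on a rescaled inner
  integral that cannot overflow.
* Mean-field integration: explicit Euler at $dt = D = 1.5$ ms (which also
  implements the one-step rate delay); rates are floored at 0,
  connectivities at 0. Runaway excursions beyond $10/t_{ref}$ only raise
  a flag — the limit-cycle regime is a finding, not an error.
* The exponential decay fit (`decay_time_constant()`) starts from the
  post-peak maximum, initialises from the tail mean and a log-linear
  regression, and refines by Levenberg-Marquardt.
* Time-averaged overlaps exclude the first 500 ms of a stimulation
  window (onset transient); configurable.

## Turnover ratio

`turnover_ratio()` implements the definitional spine turnover
$(\Delta N_{new} + \Delta N_{del})/(2 N_{spines})$ per day from the
equilibrium element rates; at the set-point this equals
$86400\,|\lambda_1| \approx 15$/day at default parameters, i.e. the
slow-manifold eigenvalue expressed per day. Experimental turnover ratios
of order 20%/day refer to imaging protocols whose normalisation (fraction
of spines appearing or disappearing between daily snapshots of a stable
population) is not dimensionally recoverable from $\lambda_1$ alone
without an additional per-synapse survival model; the package therefore
reports the definitional quantity and leaves the mapping to imaging
conventions to the user. Scalings (inverse in $\beta$, decreasing in
$\tau_{Ca}$, zero without noise) are tested.

## Limitations

* Current-based delta synapses, one shared delay, no conductances.
* Structural plasticity acts on EE connections only; inhibitory wiring is
  frozen after construction.
* The mean-field model treats two excitatory ensembles; the general
  $n$-population connectivity flow is provided
  (`connectivity_flow_n()`) but the integrator covers the two-ensemble
  case used by the protocols.
* Finite-size effects enter the theory only through the scalar
  irregularity factor $\eta$; pairwise-correlation structure is not
  modelled.
* Forgetting is exponential by construction; power-law forgetting curves
  require mechanisms outside this model.
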