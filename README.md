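# engramnet

Memory engrams from homeostatic structural plasticity: simulation and
theory, in R.

Networks in the brain rewire continuously, yet memories persist. This
package implements a model in which *firing-rate homeostasis alone* —
each neuron growing or withdrawing synaptic half-elements to keep its own
calcium-sensed rate at a set-point, with free elements paired randomly
across the network — is sufficient to form, store and recall memory
engrams in a recurrent spiking network. It is aimed at computational
neuroscientists who want to simulate the model, reproduce its analytic
structure, or build on either part.

The package provides:

* a clock-driven simulator (Rcpp) of the current-based LIF network with
  delayed delta synapses, independent external Poisson drive, and the
  homeostatic structural-plasticity rule on the excitatory-to-excitatory
  block — calcium traces $\tau_{Ca}\dot\phi_i = -\phi_i + S_i$, element
  growth $\beta\dot a_i = \beta\dot d_i = \nu - \phi_i$, and periodic
  random deletion/pairing of synaptic contacts;
* the population mean-field theory: Siegert transfer function
  $r = f(\mu, \sigma)$, ISI irregularity, shot-noise calcium statistics,
  rectified-Gaussian element rates, and the connectivity flow
  $\dot{\bar C}_{YZ} = \rho'^{+}_{d,Y}\rho'^{+}_{a,Z}/\rho -
  \bar C_{YZ}(\rho^-_{d,Y}/K^{in}_Y + \rho^-_{a,Z}/K^{out}_Z)$;
* stability analysis: the line attractor of constant-degree
  configurations, the full and reduced Jacobians, the oscillation
  boundary $\tau_{Ca} \approx 3\beta_d$ s, the critical engram
  connectivity $c_{crit} = \epsilon(1 + N_{E2}/(N_{E1}j_E))$, the
  slow-manifold memory decay time
  $\tau_{diffusion} = \sqrt{4\pi\tau_{Ca}/(\eta^2\nu)}\,cN_E/(1/\beta_a +
  1/\beta_d)$, and spine turnover;
* the stimulation protocols: growing networks to equilibrium, classical
  conditioning (US/C1/C2 with a readout neuron), repeated stimulation,
  pattern completion, overlap statistics and exponential decay fits;
* a YAML-config experiment runner with shipped presets and a thin CLI
  (`inst/cli/engramnet`).

## Worked example

The grown network's operating point and the analytic memory timescales,
at the default parameters ($N_E = 10^4$, $N_I = 2500$, $J = 0.1$ mV,
$g = 8$, $\nu_{ext} = 15$ kHz, $\nu = 8$ Hz, $\beta = 2$,
$\tau_{Ca} = 10$ s):

```r
library(engramnet)

model <- meanfield_model()
equilibrium_indegree(8, model)$k
#> [1] 999.0795
slow_mode_timescale()
#> [1] 5661.896
100 * critical_connectivity(model)
#> [1] 27.75876
optimal_target_rate(model = model)$nu_opt_hz
#> [1] 3
```

So a neuron needs about 1000 excitatory inputs to sustain 8 Hz; an
encoded engram decays along the slow manifold with a time constant of
about 5700 s; rate stability is lost once within-engram connectivity
exceeds about 28%; and memory longevity is maximal for target rates near
3 Hz.

Encoding an engram in the mean-field model (eight cycles of 150 s
stimulation at 1.05 times the external rate, 150 s relaxation):

```r
ep <- do.call(rbind, replicate(8, data.frame(
  duration_s = c(150, 150), mult_e1 = c(1.05, 1), mult_e2 = 1),
  simplify = FALSE))
tr <- integrate_model(model, ep)
tail(tr$c11, 1)
#> [1] 0.2179235
```

The within-engram connectivity has roughly doubled from its grown value
of 0.0999 while every neuron still fires at 8 Hz — a silent memory. The
same protocol on the spiking network (scaled preset) runs through
`repeated_stimulation()`:

```r
net <- scaled_network(1000, 250, seed = 5)
g <- grow_network(net, t_growth_s = 500, dt_ms = 0.5,
                  seeds = list(drive = 1, rewire = 2))
mean(g$net$state$phi)   # mean calcium ~ target rate
#> [1] 8.022689
enc <- repeated_stimulation(g$net, ensemble = 0.1, cycles = 3,
                            dt_ms = 0.5,
                            seeds = list(drive = 31, rewire = 32))
```

Experiments can also be run from configuration files:

```sh
Rscript inst/cli/engramnet stimulate \
  --config inst/extdata/presets/repeated_stimulation_scaled.yaml \
  --out runs/demo
```

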