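# Shared fixtures: tiny deterministic networks and the exhaustive pairing
# oracle used to check the rewiring distribution.

# two-neuron excitatory network with no static wiring and no external drive
tiny_net <- function(n_e = 2, n_i = 1, params = lif_params(),
                     plast = plasticity_params(enabled = FALSE)) {
  new_network(n_e, n_i, params, plast, seed = 1)
}

# Exhaustive enumeration of the random-pairing step: all joint orderings of
# the axonal and dendritic free-element multisets, paired positionally.
# Returns the exact distribution of the number of contacts formed for one
# focal ordered pair (pre -> post).
enumerate_pairing <- function(a_plus, d_plus, pre, post) {
  axons <- rep(seq_along(a_plus), a_plus)
  dends <- rep(seq_along(d_plus), d_plus)
  n <- min(length(axons), length(dends))
  perm <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perm(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  pa <- perm(axons)
  pd <- perm(dends)
  counts <- integer(n + 1)
  for (x in pa)
    for (y in pd) {
      c_focal <- sum(x[seq_len(n)] == pre & y[seq_len(n)] == post)
      counts[c_focal + 1] <- counts[c_focal + 1] + 1L
    }
  counts / sum(counts)
}

# default mean-field model reused across tests
mf_default <- function(...) meanfield_model(...)

# memoized expensive fixtures, shared across test files within one run
.fixture_cache <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, .fixture_cache)) assign(name, force(expr), .fixture_cache)
  get(name, .fixture_cache)
}

# scaled network grown to its homeostatic equilibrium (the growth protocol
# of the reference experiments, down-scaled in size only)
grown_scaled_net <- function() memo("grown", {
  net <- scaled_network(1000, 250, seed = 5)
  grow_network(net, t_growth_s = 500, dt_ms = 0.5,
               seeds = list(drive = 1, rewire = 2),
               record = list(conn_every_s = 50))
})

# grown network with one engram encoded by repeated stimulation
# (three cycles keep the fixture affordable; engram strength grows with
# every cycle, so three are enough for ordering and completion checks)
encoded_net <- function() memo("encoded", {
  g <- grown_scaled_net()
  repeated_stimulation(g$net, ensemble = 0.1, cycles = 3, dt_ms = 0.5,
                       seeds = list(drive = 31, rewire = 32),
                       ensemble_seed = 11)
})
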