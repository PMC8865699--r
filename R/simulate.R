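#' Create a plastic recurrent network
#'
#' Bundles connectivity, neuron state and parameters into a network object
#' that the protocol functions evolve. The excitatory-to-excitatory block
#' grows from scratch under the structural-plasticity rule.
#'
#' @param n_e,n_i population sizes
#' @param params [lif_params()]
#' @param plasticity [plasticity_params()]
#' @param seed construction RNG seed (static wiring)
#' @param indegree static in-degree specification, see
#'   [build_static_network()]
#' @return an object of class \code{engram_net}
#' @export
new_network <- function(n_e, n_i = round(n_e / 4), params = lif_params(),
                        plasticity = plasticity_params(), seed = 1,
                        indegree = NULL) {
  conn <- build_static_network(n_e, n_i, params, seed, indegree)
  structure(list(n_e = n_e, n_i = n_i, params = params,
                 plasticity = plasticity, conn = conn, state = NULL,
                 ensembles = list()), class = "engram_net")
}

#' Scaled-down network preset
#'
#' A reduced network (default \code{n_e = 1000}) that keeps the
#' \emph{absolute} static in-degrees of the reference full-scale network
#' (250 inhibitory contacts per neuron, 1000 excitatory contacts per
#' inhibitory neuron), so that the mean-field operating point — input
#' moments, self-consistent rates and the homeostatic equilibrium in-degree
#' — is preserved under down-scaling. Multapses absorb the reduced number
#' of distinct presynaptic partners.
#'
#' @param n_e number of excitatory neurons
#' @param n_i number of inhibitory neurons
#' @param params [lif_params()]
#' @param plasticity [plasticity_params()]
#' @param seed construction seed
#' @param ref_n_e,ref_n_i reference full-scale sizes defining the in-degrees
#' @return an \code{engram_net}
#' @export
scaled_network <- function(n_e = 1000, n_i = round(n_e / 4),
                           params = lif_params(),
                           plasticity = plasticity_params(), seed = 1,
                           ref_n_e = 10000, ref_n_i = 2500) {
  new_network(n_e, n_i, params, plasticity, seed,
              indegree = list(ei = floor(0.1 * ref_n_i),
                              ie = floor(0.1 * ref_n_e),
                              ii = floor(0.1 * ref_n_i)))
}

#' @export
print.engram_net <- function(x, ...) {
  cat(sprintf("plastic network: N_E=%d, N_I=%d, EE contacts=%d, %s\n",
              x$n_e, x$n_i, sum(x$conn$ee[, 3]),
              if (is.null(x$state)) "fresh" else "with state"))
  invisible(x)
}

#' Stimulation episodes
#'
#' A stimulus protocol is an ordered table of episodes; during each episode
#' every ensemble receives external Poisson drive at
#' \code{multiplier * nu_ext}. Episodes are pure data, so replaying a
#' protocol with the same seeds is bit-reproducible.
#'
#' @param duration_s episode durations (s)
#' @param mult named list (or data frame) of per-ensemble multipliers; one
#'   entry per episode, each a named numeric vector; unnamed ensembles and
#'   the remaining network receive the baseline multiplier 1
#' @param plastic logical vector, whether structural plasticity is active
#' @return data frame of class \code{stimulus_protocol}
#' @examples
#' episodes(c(2, 48), list(c(US = 1.4), c()), plastic = TRUE)
#' @export
episodes <- function(duration_s, mult = NULL, plastic = TRUE) {
  n <- length(duration_s)
  if (any(duration_s <= 0)) stop("durations must be positive")
  if (is.null(mult)) mult <- rep(list(numeric()), n)
  if (!is.list(mult)) stop("mult must be a list of named multiplier vectors")
  plastic <- rep_len(plastic, n)
  bad <- unlist(lapply(mult, function(m) any(m < 0)))
  if (any(bad)) stop("multipliers must be non-negative")
  structure(data.frame(duration_s = duration_s, plastic = plastic),
            mult = mult, class = c("stimulus_protocol", "data.frame"))
}

#' Sample disjoint neuronal ensembles
#'
#' @param n_e number of excitatory neurons to sample from
#' @param fractions named numeric vector of ensemble sizes as fractions of
#'   \code{n_e}
#' @param seed sampling seed
#' @return named list of disjoint integer index vectors
#' @export
make_ensembles <- function(n_e, fractions, seed = 1) {
  if (is.null(names(fractions)) || any(names(fractions) == ""))
    stop("fractions must be named")
  if (sum(fractions) > 1) stop("ensemble fractions exceed the population")
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  pool <- sample.int(n_e)
  sizes <- round(fractions * n_e)
  out <- list()
  ofs <- 0
  for (nm in names(fractions)) {
    out[[nm]] <- sort(pool[ofs + seq_len(sizes[[nm]])])
    ofs <- ofs + sizes[[nm]]
  }
  out
}

# internal: map ensembles to per-neuron stimulation/recording groups
# group 1 is always the unlabelled remainder ("rest"); inhibitory neurons
# are in group 1 (they are never stimulated selectively)
ensemble_groups <- function(n_e, n_i, ensembles) {
  if (length(ensembles) > 1) {
    idx <- unlist(ensembles)
    if (anyDuplicated(idx) > 0) stop("ensembles must be pairwise disjoint")
  }
  g <- rep(1L, n_e + n_i)
  for (k in seq_along(ensembles)) g[ensembles[[k]]] <- k + 1L
  labels <- c("rest", names(ensembles))
  list(group = g, labels = labels)
}

#' Run the spiking network through a stimulation protocol
#'
#' Clock-driven integration with exact exponential leak update, delayed
#' delta synapses, per-step Poisson external input, and (when enabled) the
#' homeostatic structural-plasticity rule interleaved at its rewiring
#' interval. The external drive and the rewiring use independent, explicit
#' RNG streams.
#'
#' @param net an \code{engram_net}
#' @param protocol an [episodes()] table
#' @param ensembles named list of disjoint excitatory index sets referenced
#'   by the protocol's multipliers
#' @param dt_ms integration step; must divide the synaptic delay
#' @param seeds list with integer elements \code{drive} and \code{rewire}
#' @param record list: \code{conn_every_s} cadence of block-connectivity
#'   and calcium snapshots, \code{rate_bin_ms} population-rate bin,
#'   \code{spike_windows_s} two-column matrix of recording windows,
#'   \code{spikes_all} record inhibitory spikes too
#' @param readouts optional list of readout wiring matrices (columns
#'   \code{pre}, \code{count}) as built by [attach_readout()]
#' @param init_v optional initial membrane potentials; by default carried
#'   over from \code{net$state}, or drawn uniformly between reset and
#'   threshold for a fresh network
#' @return list with the updated \code{net} (state and EE connectivity
#'   advanced), \code{conn_series}, \code{calcium_series}, \code{rates},
#'   \code{spikes}, \code{readout_spikes}, \code{episode_rates_hz}, and
#'   the final degree vectors
#' @export
run_network <- function(net, protocol, ensembles = net$ensembles,
                        dt_ms = 0.1, seeds = list(drive = 1, rewire = 2),
                        record = list(), readouts = list(),
                        init_v = NULL) {
  stopifnot(inherits(net, "engram_net"))
  p <- net$params
  if (abs(p$delay_ms / dt_ms - round(p$delay_ms / dt_ms)) > 1e-9)
    stop("dt_ms must divide the synaptic delay exactly")
  if (dt_ms > p$t_ref_ms)
    stop("dt_ms must not exceed the refractory period")
  rec <- modifyList(list(conn_every_s = 0, rate_bin_ms = 100,
                         spike_windows_s = matrix(numeric(), 0, 2),
                         spikes_all = FALSE), record)
  grp <- ensemble_groups(net$n_e, net$n_i, ensembles)
  mult_list <- attr(protocol, "mult")
  if (is.null(mult_list)) mult_list <- rep(list(numeric()), nrow(protocol))
  n_g <- length(grp$labels)
  ep <- matrix(1, nrow(protocol), 2 + n_g)
  ep[, 1] <- protocol$duration_s * 1e3
  ep[, 2] <- as.numeric(protocol$plastic)
  for (e in seq_len(nrow(protocol))) {
    m <- mult_list[[e]]
    for (nm in names(m)) {
      k <- match(nm, grp$labels)
      if (is.na(k)) stop("protocol references undefined ensemble: ", nm)
      ep[e, 2 + k] <- m[[nm]]
    }
  }
  init <- list()
  if (!is.null(init_v)) init$v <- init_v
  else if (!is.null(net$state)) {
    init$v <- net$state$v
    init$phi <- net$state$phi
    init$a <- net$state$a
    init$d <- net$state$d
  }
  pl <- net$plasticity
  res <- sim_network_cpp(
    net$n_e, net$n_i, unclass(p),
    storage_int_matrix(net$conn$static), storage_int_matrix(net$conn$ee),
    list(enabled = pl$enabled, tau_ca_s = pl$tau_ca_s, beta_a = pl$beta_a,
         beta_d = pl$beta_d, nu_target_hz = pl$nu_target_hz,
         rewire_every_ms = pl$delta_t_s_ms),
    ep, as.integer(grp$group), dt_ms, init,
    list(conn_group = as.integer(grp$group[seq_len(net$n_e)]),
         conn_every_ms = rec$conn_every_s * 1e3,
         rate_bin_ms = rec$rate_bin_ms,
         spike_windows = matrix(as.numeric(rec$spike_windows_s * 1e3),
                                ncol = 2),
         spikes_all = isTRUE(rec$spikes_all)),
    readouts, as.integer(seeds$drive), as.integer(seeds$rewire))
  net$conn$ee <- res$ee
  colnames(net$conn$ee) <- c("pre", "post", "count")
  net$state <- list(v = res$v, phi = res$phi, a = res$a, d = res$d)
  net$ensembles <- ensembles

  labels <- grp$labels
  nb <- length(labels)
  conn_series <- data.frame(
    time_s = rep(res$conn_time_ms, each = nb * nb) * 1e-3,
    post = rep(rep(labels, each = nb), length(res$conn_time_ms)),
    pre = rep(labels, nb * length(res$conn_time_ms)),
    cbar = as.numeric(t(res$conn_blocks)))
  calcium_series <- data.frame(
    time_s = rep(res$conn_time_ms, each = nb) * 1e-3,
    group = rep(labels, length(res$conn_time_ms)),
    phi_hz = as.numeric(t(res$calcium_blocks)))
  g_sizes <- c(tabulate(grp$group[seq_len(net$n_e)], nb), net$n_i)
  nbin <- nrow(res$rate_counts)
  rates <- data.frame(
    time_s = rep((seq_len(nbin) - 0.5) * rec$rate_bin_ms, nb + 1) * 1e-3,
    group = rep(c(labels, "I"), each = nbin),
    rate_hz = as.numeric(res$rate_counts) /
      rep(g_sizes, each = nbin) / (rec$rate_bin_ms * 1e-3))
  spikes <- data.frame(time_ms = res$spikes[, 1],
                       neuron = as.integer(res$spikes[, 2]))
  readout_spikes <- data.frame(time_ms = res$readout_spikes[, 1],
                               readout = as.integer(res$readout_spikes[, 2]))
  ep_rates <- res$episode_counts /
    rep(protocol$duration_s, each = nrow(res$episode_counts))
  list(net = net, conn_series = conn_series,
       calcium_series = calcium_series, rates = rates, spikes = spikes,
       readout_spikes = readout_spikes, episode_rates_hz = ep_rates,
       k_in = res$k_in, k_out = res$k_out, labels = labels)
}

# coerce triplet storage to a 3-column integer matrix (possibly 0 rows)
storage_int_matrix <- function(m) {
  if (is.null(m) || nrow(m) == 0) return(matrix(integer(), 0, 3))
  storage.mode(m) <- "integer"
  m
}

#' Run the network for one interval with a fixed stimulus
#'
#' Thin wrapper over [run_network()] for a single episode.
#'
#' @param net an \code{engram_net}
#' @param duration_s interval length (s)
#' @param mult named multiplier vector (ensembles at baseline if omitted)
#' @param plastic whether plasticity is active
#' @param ... passed to [run_network()]
#' @return see [run_network()]
#' @export
run_interval <- function(net, duration_s, mult = numeric(), plastic = TRUE,
                         ...) {
  run_network(net, episodes(duration_s, list(mult), plastic), ...)
}

#' Block mean of the current EE connectivity
#'
#' Average number of contacts per ordered neuron pair between two index
#' sets, computed directly from the connectivity triplets.
#'
#' @param net an \code{engram_net} (or \code{engram_conn})
#' @param pre,post integer index vectors of pre- and postsynaptic neurons
#' @return mean contact count per ordered pair
#' @export
block_connectivity <- function(net, pre, post) {
  conn <- if (inherits(net, "engram_net")) net$conn else net
  ee <- conn$ee
  sel <- ee[, 1] %in% pre & ee[, 2] %in% post
  sum(ee[sel, 3]) / (length(pre) * length(post))
}
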