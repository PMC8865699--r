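#' Grow a network to its homeostatic equilibrium
#'
#' Starting from empty EE connectivity, runs the plastic network under
#' baseline drive until the excitatory neurons fire at their target rate
#' and the in-degree has settled at the self-consistent equilibrium.
#'
#' @param net an \code{engram_net} (fresh or partially grown)
#' @param t_growth_s growth duration (s)
#' @param dt_ms integration step
#' @param seeds RNG streams, see [run_network()]
#' @param record recording options, see [run_network()]
#' @param tol relative tolerance on the final mean calcium used for the
#'   convergence check
#' @return list as [run_network()], with an added logical
#'   \code{converged}; non-convergence warns and leaves the trajectory for
#'   inspection
#' @export
grow_network <- function(net, t_growth_s = 500, dt_ms = 0.1,
                         seeds = list(drive = 1, rewire = 2),
                         record = list(conn_every_s = 10), tol = 0.05) {
  if (t_growth_s <= 0) return(list(net = net, converged = FALSE))
  out <- run_interval(net, t_growth_s, plastic = TRUE, dt_ms = dt_ms,
                      seeds = seeds, record = record)
  phi_end <- mean(out$net$state$phi)
  nu <- net$plasticity$nu_target_hz
  out$converged <- abs(phi_end - nu) / nu <= tol
  if (!out$converged)
    warning(sprintf(
      "network not converged: mean calcium %.2f Hz vs target %g Hz",
      phi_end, nu))
  out
}

#' Repeated stimulation of a single ensemble
#'
#' Encodes an engram by repeatedly raising the external input to one
#' ensemble: each cycle is \code{stim_s} seconds of increased drive
#' followed by \code{relax_s} seconds of relaxation. Connectivity is
#' recorded on a fixed cadence throughout.
#'
#' @param net a grown \code{engram_net}
#' @param ensemble integer indices of the stimulated excitatory neurons,
#'   or a fraction in (0,1) to sample
#' @param cycles number of stimulation cycles
#' @param stim_s,relax_s cycle phase durations (s)
#' @param mult external-rate multiplier during stimulation
#' @param record_every_s cadence of connectivity snapshots
#' @param dt_ms,seeds see [run_network()]
#' @param ensemble_seed sampling seed when \code{ensemble} is a fraction
#' @return list as [run_network()]; the stimulated ensemble is stored in
#'   the returned network as \code{E1}
#' @export
repeated_stimulation <- function(net, ensemble = 0.1, cycles = 8,
                                 stim_s = 150, relax_s = 150, mult = 1.05,
                                 record_every_s = 15, dt_ms = 0.1,
                                 seeds = list(drive = 1, rewire = 2),
                                 ensemble_seed = 11) {
  if (length(ensemble) == 1 && ensemble > 0 && ensemble < 1)
    ensemble <- make_ensembles(net$n_e, c(E1 = ensemble),
                               seed = ensemble_seed)$E1
  ens <- list(E1 = ensemble)
  proto <- episodes(rep(c(stim_s, relax_s), cycles),
                    rep(list(c(E1 = mult), c(E1 = 1)), cycles),
                    plastic = TRUE)
  run_network(net, proto, ensembles = ens, dt_ms = dt_ms, seeds = seeds,
              record = list(conn_every_s = record_every_s))
}

#' Classical-conditioning experiment
#'
#' Implements the five-episode conditioning paradigm on three disjoint 10%
#' ensembles (US, C1, C2): growth, baseline (each ensemble stimulated once,
#' alone), encoding (six cycles; C1 always paired with US, C2 always
#' alone), a decay period, and retrieval (C1 alone, then C2 alone). Each
#' stimulation raises the external input to 1.4 times baseline for 2 s,
#' followed by 48 s of relaxation. A readout neuron receives static
#' contacts from all US neurons, so retrieval success is visible as its
#' firing rate.
#'
#' @param net a fresh or grown \code{engram_net}; conditioning-speed
#'   plasticity parameters (beta = 0.4, tau_Ca = 1 s, rewiring every 10 ms)
#'   are the protocol defaults from the reference experiments
#' @param t_growth_s growth episode duration (s)
#' @param stim_s,relax_s stimulation-cycle phase durations (s)
#' @param mult stimulation multiplier
#' @param decay_s duration of the decay episode (s)
#' @param dt_ms,seeds see [run_network()]
#' @param ensemble_seed seed for sampling the three ensembles
#' @return list as [run_network()] plus \code{episode_table} describing
#'   every episode and \code{readout_rates_hz}, the readout firing rate per
#'   episode
#' @export
conditioning_experiment <- function(net, t_growth_s = 100, stim_s = 2,
                                    relax_s = 48, mult = 1.4, decay_s = 100,
                                    dt_ms = 0.1,
                                    seeds = list(drive = 1, rewire = 2),
                                    ensemble_seed = 7) {
  ens <- make_ensembles(net$n_e, c(US = 0.1, C1 = 0.1, C2 = 0.1),
                        seed = ensemble_seed)
  cycle <- function(who, label) {
    mlt <- setNames(rep(mult, length(who)), who)
    list(dur = c(stim_s, relax_s), mult = list(mlt, numeric()),
         label = c(paste0("stim_", label), paste0("relax_", label)))
  }
  segs <- c(
    list(list(dur = t_growth_s, mult = list(numeric()), label = "growth")),
    lapply(c("US", "C1", "C2"), function(x) cycle(x, paste0("base_", x))),
    unlist(lapply(1:3, function(k) list(
      cycle(c("US", "C1"), sprintf("enc%d_USC1", k)),
      cycle("C2", sprintf("enc%d_C2", k)))), recursive = FALSE),
    list(list(dur = decay_s, mult = list(numeric()), label = "decay")),
    list(cycle("C1", "retr_C1"), cycle("C2", "retr_C2")))
  dur <- unlist(lapply(segs, `[[`, "dur"))
  mlt <- unlist(lapply(segs, `[[`, "mult"), recursive = FALSE)
  lab <- unlist(lapply(segs, `[[`, "label"))
  proto <- episodes(dur, mlt, plastic = TRUE)
  readout <- list(cbind(pre = ens$US, count = 1L))
  out <- run_network(net, proto, ensembles = ens, dt_ms = dt_ms,
                     seeds = seeds, record = list(conn_every_s = 1),
                     readouts = readout)
  ro_row <- net$n_e + net$n_i + 1
  out$episode_table <- data.frame(episode = seq_along(dur), label = lab,
                                  duration_s = dur)
  out$readout_rates_hz <- setNames(out$episode_rates_hz[ro_row, ], lab)
  out
}

#' Wire a readout neuron to a random sample of the network
#'
#' Builds the static input of one extra LIF readout neuron: contacts of
#' weight \eqn{J} from a random sample of the excitatory population and
#' \eqn{-gJ} from an equally sized fraction of the inhibitory population.
#' The readout receives the same external drive as network neurons and
#' projects nowhere.
#'
#' @param net an \code{engram_net}
#' @param sample_frac fraction of each population sampled (default 9%)
#' @param seed sampling seed
#' @return a one-element list suitable for the \code{readouts} argument of
#'   [run_network()]
#' @export
attach_readout <- function(net, sample_frac = 0.09, seed = 1) {
  if (sample_frac < 0 || sample_frac > 1)
    stop("sample_frac must lie in [0, 1]")
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  n_se <- round(sample_frac * net$n_e)
  n_si <- round(sample_frac * net$n_i)
  pre <- c(sample.int(net$n_e, n_se),
           net$n_e + sample.int(net$n_i, n_si))
  list(cbind(pre = as.integer(pre), count = 1L))
}

#' Binary activity pattern
#'
#' @param indices neurons belonging to the pattern
#' @param n total number of neurons the pattern is defined over
#' @return object of class \code{engram_pattern} with the binary vector
#'   \code{xi} and its mean \code{a} (the sparseness)
#' @export
make_pattern <- function(indices, n) {
  xi <- integer(n)
  xi[indices] <- 1L
  a <- mean(xi)
  if (a <= 0 || a >= 1)
    stop("pattern must be non-trivial (0 < mean < 1) for overlaps")
  structure(list(xi = xi, a = a, n = n), class = "engram_pattern")
}

#' Overlap of binned network activity with a stored pattern
#'
#' For each time bin the binary activity vector \eqn{s_i} (neuron spiked in
#' the bin or not) is projected onto the pattern:
#' \deqn{m(t) = [N a (1-a)]^{-1} \sum_i (\xi_i - a) s_i(t).}
#' An overlap of 1 means the active set equals the pattern exactly; 0 is
#' chance level.
#'
#' @param pattern an [make_pattern()] object
#' @param spikes data frame with \code{time_ms}, \code{neuron} (excitatory
#'   spikes)
#' @param bin_ms bin width (ms)
#' @param t_range_ms optional two-element window; defaults to the spike
#'   range
#' @return data frame with \code{time_ms} (bin centres) and \code{m}
#' @export
overlap <- function(pattern, spikes, bin_ms = 10, t_range_ms = NULL) {
  if (bin_ms <= 0) stop("bin_ms must be positive")
  if (is.null(t_range_ms))
    t_range_ms <- c(floor(min(spikes$time_ms) / bin_ms) * bin_ms,
                    ceiling(max(spikes$time_ms) / bin_ms) * bin_ms)
  breaks <- seq(t_range_ms[1], t_range_ms[2], by = bin_ms)
  if (length(breaks) < 2) stop("window shorter than one bin")
  nb <- length(breaks) - 1
  sel <- spikes$time_ms > t_range_ms[1] & spikes$time_ms <= t_range_ms[2] &
    spikes$neuron <= pattern$n
  bin <- pmin(ceiling((spikes$time_ms[sel] - t_range_ms[1]) / bin_ms), nb)
  m <- numeric(nb)
  if (any(sel)) {
    key <- (bin - 1) * pattern$n + spikes$neuron[sel]
    active <- !duplicated(key)      # binary: spiked at least once in bin
    w <- pattern$xi[spikes$neuron[sel][active]] - pattern$a
    agg <- rowsum(w, bin[active])
    m[as.integer(rownames(agg))] <- agg[, 1]
  }
  data.frame(time_ms = breaks[-1] - bin_ms / 2,
             m = m / (pattern$n * pattern$a * (1 - pattern$a)))
}

#' Population firing rate from a spike record
#'
#' @param spikes data frame with \code{time_ms}, \code{neuron}
#' @param n_neurons population size for normalisation
#' @param bin_ms bin width (ms), 100 ms by default
#' @param t_range_ms analysis window
#' @return data frame with \code{time_ms} (bin centres), \code{count} and
#'   \code{rate_hz}; counts sum exactly to the number of spikes in the
#'   window
#' @export
population_rate <- function(spikes, n_neurons, bin_ms = 100,
                            t_range_ms = NULL) {
  if (is.null(t_range_ms))
    t_range_ms <- c(floor(min(spikes$time_ms) / bin_ms) * bin_ms,
                    ceiling(max(spikes$time_ms) / bin_ms) * bin_ms)
  breaks <- seq(t_range_ms[1], t_range_ms[2], by = bin_ms)
  nb <- length(breaks) - 1
  sel <- spikes$time_ms > t_range_ms[1] & spikes$time_ms <= t_range_ms[2]
  bin <- pmin(ceiling((spikes$time_ms[sel] - t_range_ms[1]) / bin_ms), nb)
  cnt <- tabulate(bin, nb)
  data.frame(time_ms = breaks[-1] - bin_ms / 2, count = cnt,
             rate_hz = cnt / n_neurons / (bin_ms * 1e-3))
}

#' Pattern-completion curve of an encoded engram
#'
#' With plasticity frozen, stimulates random subsets of the engram of
#' varying size and measures the time-averaged overlap of excitatory
#' activity with the full engram pattern. Recurrent connectivity above
#' baseline recruits the non-stimulated members, so the curve lies above
#' the one of an unstructured network.
#'
#' @param net an \code{engram_net} after encoding (plasticity is forced
#'   off during the probe)
#' @param engram integer indices of the engram neurons
#' @param fractions stimulated fractions in (0, 1]
#' @param n_draws random subsets per fraction
#' @param stim_s duration of each probe stimulation (s)
#' @param mult stimulation multiplier
#' @param bin_ms overlap bin
#' @param discard_s initial transient excluded from the time average
#' @param dt_ms integration step
#' @param seed seed for subset sampling and drive
#' @return data frame with \code{fraction}, \code{draw},
#'   \code{mean_overlap}
#' @export
pattern_completion_curve <- function(net, engram, fractions = c(0.25, 0.5,
                                                                0.75, 1),
                                     n_draws = 5, stim_s = 10, mult = 1.05,
                                     bin_ms = 10, discard_s = 0.5,
                                     dt_ms = 0.1, seed = 1) {
  if (any(fractions <= 0 | fractions > 1))
    stop("fractions must lie in (0, 1]")
  net$plasticity$enabled <- FALSE
  pat <- make_pattern(engram, net$n_e)
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  rows <- list()
  for (f in fractions) {
    for (dr in seq_len(n_draws)) {
      sub <- sample(engram, max(1, round(f * length(engram))))
      out <- run_network(
        net, episodes(stim_s, list(c(S = mult)), plastic = FALSE),
        ensembles = list(S = sub), dt_ms = dt_ms,
        seeds = list(drive = sample.int(2^30, 1), rewire = 1),
        record = list(conn_every_s = 0, spike_windows_s =
                        matrix(c(0, stim_s), 1)))
      ov <- overlap(pat, out$spikes, bin_ms,
                    t_range_ms = c(discard_s * 1e3, stim_s * 1e3))
      rows[[length(rows) + 1]] <-
        data.frame(fraction = f, draw = dr, mean_overlap = mean(ov$m))
    }
  }
  do.call(rbind, rows)
}

#' Exponential decay time of a connectivity series
#'
#' Least-squares fit of \eqn{C(t) = C_\infty + A e^{-t/\tau}} to the
#' post-peak portion of a connectivity time series. Initial values come
#' from the tail mean and a log-linear regression; a Levenberg-Marquardt
#' refinement follows.
#'
#' @param time_s sample times (s)
#' @param value connectivity values
#' @param from_peak start the fit at the series maximum (default) or at
#'   the first sample
#' @return list with \code{tau_s}, \code{c_inf}, \code{amplitude} and the
#'   fitted model object
#' @examples
#' t <- seq(0, 6000, by = 15)
#' fit <- decay_time_constant(t, 0.1 + 0.05 * exp(-t / 3000))
#' fit$tau_s
#' @export
decay_time_constant <- function(time_s, value, from_peak = TRUE) {
  stopifnot(length(time_s) == length(value), length(value) > 10)
  i0 <- if (from_peak) which.max(value) else 1L
  t <- time_s[i0:length(time_s)] - time_s[i0]
  y <- value[i0:length(value)]
  c_inf0 <- mean(utils::tail(y, max(3, round(length(y) * 0.1))))
  resid0 <- y - c_inf0
  pos <- resid0 > 0
  if (sum(pos) < 5 || y[1] <= c_inf0)
    stop("series does not decay toward a plateau; cannot fit")
  lmfit <- stats::lm(log(resid0[pos]) ~ t[pos])
  tau0 <- -1 / coef(lmfit)[2]
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- diff(range(t)) / 3
  fit <- minpack.lm::nlsLM(
    y ~ c_inf + A * exp(-t / tau),
    start = list(c_inf = unname(c_inf0), A = unname(exp(coef(lmfit)[1])),
                 tau = unname(tau0)),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- coef(fit)
  list(tau_s = unname(cf["tau"]), c_inf = unname(cf["c_inf"]),
       amplitude = unname(cf["A"]), fit = fit)
}

#' Gamma-process spike train
#'
#' Renewal spike train with Gamma-distributed interspike intervals of
#' shape \eqn{\alpha = 1/CV^2} and rate \eqn{\alpha r}, reproducing the
#' first two moments (rate and irregularity) of network spike trains;
#' \code{cv = 1} is the Poisson special case.
#'
#' @param rate_hz mean firing rate
#' @param cv interspike-interval coefficient of variation
#' @param duration_s train length (s)
#' @param seed RNG seed
#' @return numeric vector of spike times in ms
#' @export
gamma_spike_train <- function(rate_hz, cv, duration_s, seed = 1) {
  if (rate_hz <= 0) stop("rate_hz must be positive")
  if (cv <= 0 || cv > 1.5) stop("cv must lie in (0, 1.5]")
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  alpha <- 1 / cv^2
  n_guess <- ceiling(rate_hz * duration_s * 1.5 + 100)
  times <- cumsum(rgamma(n_guess, shape = alpha, rate = alpha * rate_hz))
  while (times[length(times)] < duration_s) {
    times <- c(times, times[length(times)] +
                 cumsum(rgamma(n_guess, shape = alpha,
                               rate = alpha * rate_hz)))
  }
  times[times <= duration_s] * 1e3
}

#' Stationary calcium moments of a filtered renewal train
#'
#' Campbell's theorem for the exponentially filtered spike train: the
#' calcium trace has mean equal to the rate and variance
#' \eqn{CV^2 \nu / (2\tau_{Ca})}.
#'
#' @param rate_hz spike rate
#' @param cv interspike-interval CV of the train
#' @param tau_ca_s filter time constant (s)
#' @return list with \code{mean} and \code{var}
#' @export
calcium_equilibrium_stats <- function(rate_hz, cv, tau_ca_s) {
  list(mean = rate_hz, var = cv^2 * rate_hz / (2 * tau_ca_s))
}

#' Filter a spike train into its calcium trace
#'
#' @param times_ms spike times (ms)
#' @param tau_ca_s filter time constant (s)
#' @param dt_ms sampling step (ms)
#' @param duration_ms trace length; defaults to the last spike
#' @return data frame with \code{time_ms} and \code{phi_hz}
#' @export
filter_calcium <- function(times_ms, tau_ca_s, dt_ms = 10,
                           duration_ms = max(times_ms)) {
  nstep <- ceiling(duration_ms / dt_ms)
  cnt <- tabulate(pmin(ceiling(times_ms / dt_ms), nstep), nstep)
  dec <- exp(-dt_ms * 1e-3 / tau_ca_s)
  phi <- numeric(nstep)
  x <- 0
  for (k in seq_len(nstep)) {
    x <- x * dec + cnt[k] / tau_ca_s
    phi[k] <- x
  }
  data.frame(time_ms = (seq_len(nstep)) * dt_ms, phi_hz = phi)
}
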