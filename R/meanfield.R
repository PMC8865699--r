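#' Two-ensemble population mean-field model
#'
#' Container for the population-level theory: two plastic excitatory
#' ensembles (the stimulated ensemble E1 and the remaining excitatory
#' neurons E2) and one static inhibitory population. The model couples
#' Wilson-Cowan rate dynamics through the Siegert transfer function (with
#' one synaptic delay), the exact population calcium ODE, and the
#' structural-plasticity connectivity flow with noise-corrected
#' (rectified-Gaussian) element rates.
#'
#' The state vector is
#' \eqn{y = (\phi_{E1}, \phi_{E2}, \bar C_{E1E1}, \bar C_{E1E2},
#' \bar C_{E2E1}, \bar C_{E2E2}, r_{E1}, r_{E2}, r_I)}.
#'
#' @param n_e1,n_e2,n_i population sizes
#' @param params [lif_params()] object
#' @param nu_target_hz homeostatic target rate of excitatory neurons
#' @param beta_a,beta_d element growth parameters
#' @param tau_ca_s calcium time constant (s)
#' @param eta spiking-irregularity correction factor; 0 gives the
#'   deterministic (noise-free) flow, the default 0.7 is the ISI CV of the
#'   grown network
#' @param tau_rate_ms relaxation time of the population rate dynamics; the
#'   results are insensitive to its value as long as it does not exceed the
#'   membrane time constant, and it defaults to half of it
#' @param eps static connectivity fraction of the inhibitory wiring
#' @return an object of class \code{meanfield_model}
#' @export
meanfield_model <- function(n_e1 = 1000, n_e2 = 9000, n_i = 2500,
                            params = lif_params(), nu_target_hz = 8,
                            beta_a = 2, beta_d = 2, tau_ca_s = 10,
                            eta = 0.7, tau_rate_ms = params$tau_m_ms / 2,
                            eps = 0.1) {
  stopifnot(n_e1 > 0, n_e2 > 0, n_i > 0, nu_target_hz > 0, tau_ca_s > 0,
            beta_a > 0, beta_d > 0, eta >= 0, tau_rate_ms > 0)
  structure(list(
    n_e1 = n_e1, n_e2 = n_e2, n_i = n_i,
    tau_m_s = params$tau_m_ms * 1e-3, t_ref_s = params$t_ref_ms * 1e-3,
    v_th_mv = params$v_th_mv, v_r_mv = params$v_r_mv, j_mv = params$j_mv,
    g = params$g, nu_ext_hz = params$nu_ext_hz,
    nu_target_hz = nu_target_hz, beta_a = beta_a, beta_d = beta_d,
    tau_ca_s = tau_ca_s, eta = eta, tau_rate_s = tau_rate_ms * 1e-3,
    eps = eps, params = params), class = "meanfield_model")
}

#' @export
print.meanfield_model <- function(x, ...) {
  cat(sprintf("mean-field model: E1=%d, E2=%d, I=%d\n", x$n_e1, x$n_e2, x$n_i))
  cat(sprintf("  nu=%g Hz, beta_a=%g, beta_d=%g, tau_Ca=%g s, eta=%g\n",
              x$nu_target_hz, x$beta_a, x$beta_d, x$tau_ca_s, x$eta))
  invisible(x)
}

#' Gaussian input moments of each population
#'
#' Aggregates recurrent, inhibitory and external Poisson input into the mean
#' and standard deviation of the Gaussian current approximation:
#' \deqn{\mu_Y = J\tau_m \sum_{Z} \bar C_{YZ} N_Z r_Z - g J \tau_m
#'  \epsilon N_I r_I + J \tau_m \nu_{ext} m_Y,}
#' with the variance using weights \eqn{J^2} and \eqn{g^2 J^2}.
#'
#' @param model a [meanfield_model()]
#' @param rates numeric length 3, (delayed) rates of (E1, E2, I) in Hz
#' @param conn numeric length 4, connectivities (C11, C12, C21, C22)
#' @param mult external-rate multipliers for (E1, E2); inhibitory neurons
#'   always receive baseline drive
#' @return list with numeric length-3 components \code{mu} (mV) and
#'   \code{sigma} (mV) for (E1, E2, I)
#' @export
input_moments <- function(model, rates, conn, mult = c(1, 1)) {
  stopifnot(length(rates) == 3, length(conn) == 4, all(rates >= 0))
  tJ <- model$tau_m_s * model$j_mv
  tJ2 <- model$tau_m_s * model$j_mv^2
  n <- c(model$n_e1, model$n_e2)
  rec <- c(conn[1] * n[1] * rates[1] + conn[2] * n[2] * rates[2],
           conn[3] * n[1] * rates[1] + conn[4] * n[2] * rates[2],
           model$eps * (n[1] * rates[1] + n[2] * rates[2]))
  inh <- model$eps * model$n_i * rates[3]
  ext <- model$nu_ext_hz * c(mult, 1)
  mu <- tJ * rec - model$g * tJ * inh + tJ * ext
  sigma2 <- tJ2 * rec + model$g^2 * tJ2 * inh + tJ2 * ext
  list(mu = as.numeric(mu), sigma = sqrt(as.numeric(sigma2)))
}

# internal: population rates from moments
mf_rate <- function(model, mu, sigma) {
  siegert_cpp(mu, sigma, model$tau_m_s, model$t_ref_s, model$v_th_mv,
              model$v_r_mv)
}

#' Self-consistent inhibitory rate with excitatory rates clamped
#'
#' @param model a [meanfield_model()]
#' @param nu_e excitatory firing rate imposed on both ensembles (Hz)
#' @return the inhibitory rate (Hz) solving the Siegert self-consistency
#' @export
selfconsistent_inhibitory_rate <- function(model, nu_e = model$nu_target_hz) {
  f <- function(ri) {
    m <- input_moments(model, c(nu_e, nu_e, ri), rep(model$eps, 4))
    mf_rate(model, m$mu[3], m$sigma[3]) - ri
  }
  uniroot(f, c(1e-6, 2 / model$t_ref_s), tol = 1e-12)$root
}

#' Equilibrium excitatory in-degree under firing-rate homeostasis
#'
#' Solves the two-population self-consistency problem of the grown network:
#' find the excitatory-to-excitatory in-degree \eqn{K} at which the Siegert
#' rate of excitatory neurons equals the homeostatic target, with the
#' inhibitory population itself self-consistent at its fixed static
#' connectivity. This is the in-degree at which the homeostatic controller
#' stops growing new synaptic elements.
#'
#' @param nu_hz target rate (Hz)
#' @param model a [meanfield_model()]; its \code{nu_target_hz} is ignored in
#'   favour of \code{nu_hz}
#' @return list with the in-degree \code{k} (contacts), the inhibitory rate
#'   \code{nu_i}, and the operating-point moments \code{mu}, \code{sigma}
#'   (mV) of the excitatory population
#' @examples
#' equilibrium_indegree(8)$k  # close to 1000 at default parameters
#' @export
equilibrium_indegree <- function(nu_hz, model = meanfield_model()) {
  if (nu_hz <= 0) stop("target rate must be positive")
  n_e <- model$n_e1 + model$n_e2
  nu_i <- selfconsistent_inhibitory_rate(model, nu_hz)
  tJ <- model$tau_m_s * model$j_mv
  tJ2 <- model$tau_m_s * model$j_mv^2
  rate_at_k <- function(k) {
    mu <- tJ * (k * nu_hz - model$g * model$eps * model$n_i * nu_i +
                  model$nu_ext_hz)
    s2 <- tJ2 * (k * nu_hz + model$g^2 * model$eps * model$n_i * nu_i +
                   model$nu_ext_hz)
    list(r = mf_rate(model, mu, sqrt(s2)), mu = mu, sigma = sqrt(s2))
  }
  f <- function(k) rate_at_k(k)$r - nu_hz
  lo <- f(0)
  hi <- f(n_e)
  if (lo > 0 || hi < 0)
    stop("no self-consistent in-degree in [0, N_E] for nu = ", nu_hz, " Hz")
  k <- uniroot(f, c(0, n_e), tol = 1e-9)$root
  op <- rate_at_k(k)
  list(k = k, nu_i = nu_i, mu = op$mu, sigma = op$sigma, rate = op$r)
}

#' Drift of the population connectivity means
#'
#' Time derivative of the four connectivity means \eqn{\bar C_{YZ}} given
#' the calcium state: creation as the product of corrected free-element
#' rates normalised by the network pairing rate, deletion proportional to
#' the existing connectivity, with elements freed by deletion re-entering
#' the pairing pool. For \code{eta = 0} the rates are sharp rectifiers and
#' every constant-in-degree configuration is stationary (a line attractor);
#' for \code{eta > 0} spiking noise drives a slow net flow toward the
#' uniform, most entropic configuration.
#'
#' @param model a [meanfield_model()]
#' @param phi numeric length 2, calcium traces of (E1, E2) in Hz
#' @param conn numeric length 4, (C11, C12, C21, C22)
#' @return numeric length 4, d/dt of (C11, C12, C21, C22) per second
#' @export
connectivity_flow <- function(model, phi, conn) {
  stopifnot(length(phi) == 2, length(conn) == 4)
  dC <- connectivity_flow_n(sizes = c(model$n_e1, model$n_e2), phi = phi,
                            conn = matrix(conn, 2, 2, byrow = TRUE),
                            nu = model$nu_target_hz, beta_a = model$beta_a,
                            beta_d = model$beta_d, tau_ca_s = model$tau_ca_s,
                            eta = model$eta)
  as.numeric(t(dC))
}

#' Connectivity drift for an arbitrary number of plastic populations
#'
#' Generalisation of [connectivity_flow()] to \code{length(sizes)} plastic
#' excitatory populations; used for the hyperplane (multi-engram) analysis.
#'
#' @param sizes population sizes
#' @param phi per-population calcium traces (Hz)
#' @param conn connectivity mean matrix, row = postsynaptic population
#' @param nu target rate (Hz)
#' @param beta_a,beta_d growth parameters
#' @param tau_ca_s calcium time constant (s)
#' @param eta irregularity correction factor
#' @return matrix of time derivatives of \code{conn} (per second)
#' @export
connectivity_flow_n <- function(sizes, phi, conn, nu, beta_a, beta_d,
                                tau_ca_s, eta) {
  n_pop <- length(sizes)
  stopifnot(length(phi) == n_pop, all(dim(conn) == n_pop))
  sig_a <- element_rate_sd(nu, tau_ca_s, beta_a, eta)
  sig_d <- element_rate_sd(nu, tau_ca_s, beta_d, eta)
  ud <- (nu - phi) / beta_d
  ua <- (nu - phi) / beta_a
  rd_p <- rectified_gaussian_mean(ud, sig_d)
  rd_m <- rectified_gaussian_mean(-ud, sig_d)
  ra_p <- rectified_gaussian_mean(ua, sig_a)
  ra_m <- rectified_gaussian_mean(-ua, sig_a)
  n <- as.numeric(sizes)
  k_in <- as.numeric(conn %*% n)
  k_out <- as.numeric(crossprod(conn, n))
  safe_div <- function(x, y) ifelse(y > 0, x / y, 0)
  # counterparts of deleted synapses become free elements again
  rdc_p <- rd_p + as.numeric(conn %*% (n * safe_div(ra_m, k_out)))
  rac_p <- ra_p + as.numeric(crossprod(conn, n * safe_div(rd_m, k_in)))
  rho <- max(sum(n * rac_p), sum(n * rdc_p))
  create <- if (rho > 0) outer(rdc_p, rac_p) / rho else
    matrix(0, n_pop, n_pop)
  del <- conn * (matrix(safe_div(rd_m, k_in), n_pop, n_pop) +
                   matrix(safe_div(ra_m, k_out), n_pop, n_pop, byrow = TRUE))
  create - del
}

#' Grown-network equilibrium state of the mean-field model
#'
#' @param model a [meanfield_model()]
#' @return numeric length 9 state vector at the global fixed point: calcium
#'   and rates at the target, all connectivity means at
#'   \eqn{c = K^{in}/N_E}, and the self-consistent inhibitory rate
#' @export
meanfield_equilibrium <- function(model) {
  eq <- equilibrium_indegree(model$nu_target_hz, model)
  cbar <- eq$k / (model$n_e1 + model$n_e2)
  nu <- model$nu_target_hz
  c(phi_e1 = nu, phi_e2 = nu, c11 = cbar, c12 = cbar, c21 = cbar,
    c22 = cbar, r_e1 = nu, r_e2 = nu, r_i = eq$nu_i)
}

#' Integrate the mean-field model through a stimulation protocol
#'
#' Fixed-step integration (explicit Euler; the step equals the synaptic
#' delay, which also realises the one-step rate delay) of the coupled rate,
#' calcium and connectivity dynamics.
#'
#' @param model a [meanfield_model()]
#' @param episodes data frame with columns \code{duration_s},
#'   \code{mult_e1}, \code{mult_e2}: ordered stimulation episodes given as
#'   external-rate multipliers per ensemble
#' @param y0 initial state (9-vector); defaults to the grown equilibrium
#' @param dt_s integration step (s)
#' @param record_every_s sampling interval of the returned trajectory
#' @return a data frame with columns \code{time_s}, the 9 state variables,
#'   and attribute \code{runaway} flagging excursions beyond
#'   \eqn{10/t_{ref}}
#' @examples
#' \donttest{
#' m <- meanfield_model()
#' ep <- data.frame(duration_s = c(30, 60), mult_e1 = c(1.1, 1),
#'                  mult_e2 = 1)
#' tr <- integrate_model(m, ep)
#' }
#' @export
integrate_model <- function(model, episodes, y0 = meanfield_equilibrium(model),
                            dt_s = 1.5e-3, record_every_s = 0.5) {
  stopifnot(all(c("duration_s", "mult_e1", "mult_e2") %in% names(episodes)),
            all(episodes$duration_s > 0), all(episodes$mult_e1 >= 0),
            all(episodes$mult_e2 >= 0))
  ep <- as.matrix(episodes[, c("duration_s", "mult_e1", "mult_e2")])
  out <- sim_meanfield_cpp(unclass(model), ep, as.numeric(y0), dt_s,
                           record_every_s)
  tr <- data.frame(time_s = out$time_s, out$y)
  names(tr) <- c("time_s", "phi_e1", "phi_e2", "c11", "c12", "c21", "c22",
                 "r_e1", "r_e2", "r_i")
  attr(tr, "runaway") <- out$runaway
  tr
}

#' Classify the post-stimulation regime of a mean-field trajectory
#'
#' Distinguishes homeostatic convergence from the pathological
#' connectivity-rate limit cycle that follows overly strong stimulation:
#' in the limit cycle the ensemble rate alternates between silence and
#' seizure-like bursts while connectivity keeps oscillating.
#'
#' @param trajectory output of [integrate_model()]
#' @param after_s analyse only samples after this time
#' @param low_hz,high_hz rate thresholds defining silence and burst
#' @return list with \code{regime} ("stable" or "limit_cycle"), the number
#'   of silence-to-burst alternations \code{n_bursts}, and the peak-to-peak
#'   connectivity excursion \code{c11_range} in the analysis window
#' @export
classify_regime <- function(trajectory, after_s = 0, low_hz = 0.5,
                            high_hz = 50) {
  w <- trajectory[trajectory$time_s >= after_s, ]
  r <- w$r_e1
  state <- ifelse(r > high_hz, 1L, ifelse(r < low_hz, -1L, 0L))
  state <- state[state != 0L]
  n_bursts <- if (length(state) > 1)
    sum(state[-1] == 1L & state[-length(state)] == -1L) else 0L
  regime <- if (n_bursts >= 2) "limit_cycle" else "stable"
  list(regime = regime, n_bursts = n_bursts,
       c11_range = diff(range(w$c11)))
}
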