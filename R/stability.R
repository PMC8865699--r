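#' Operating point and effective couplings of the grown network
#'
#' Solves the grown-network equilibrium and differentiates the Siegert
#' transfer function there to obtain the effective dimensionless couplings
#' \eqn{j_{EE}, j_{EI}, j_{IE}, j_{II}} used throughout the linear-stability
#' analysis, e.g.
#' \eqn{j_{EE} = J\tau_m \partial f/\partial\mu +
#'  (J^2 \tau_m / 2\sigma) \partial f/\partial\sigma}.
#' Derivatives are central finite differences with Richardson extrapolation.
#'
#' @param model a [meanfield_model()]
#' @param nu_hz target rate at which to evaluate the operating point
#' @return list with the equilibrium in-degree \code{k}, connectivity
#'   fraction \code{c}, rates, input moments of the excitatory and
#'   inhibitory populations, and the couplings \code{j_ee}, \code{j_ei},
#'   \code{j_ie}, \code{j_ii}
#' @export
operating_point <- function(model = meanfield_model(),
                            nu_hz = model$nu_target_hz) {
  eq <- equilibrium_indegree(nu_hz, model)
  mI <- input_moments(model, c(nu_hz, nu_hz, eq$nu_i), rep(model$eps, 4))
  tau <- model$tau_m_s
  J <- model$j_mv
  g <- model$g
  df <- function(mu, sigma, wrt) {
    f <- function(h) {
      if (wrt == "mu")
        (mf_rate(model, mu + h, sigma) - mf_rate(model, mu - h, sigma)) /
          (2 * h)
      else
        (mf_rate(model, mu, sigma + h) - mf_rate(model, mu, sigma - h)) /
          (2 * h)
    }
    (4 * f(5e-5) - f(1e-4)) / 3  # Richardson step halving
  }
  dmu_e <- df(eq$mu, eq$sigma, "mu")
  dsg_e <- df(eq$mu, eq$sigma, "sigma")
  dmu_i <- df(mI$mu[3], mI$sigma[3], "mu")
  dsg_i <- df(mI$mu[3], mI$sigma[3], "sigma")
  list(k = eq$k, c = eq$k / (model$n_e1 + model$n_e2), nu_e = nu_hz,
       nu_i = eq$nu_i, mu_e = eq$mu, sigma_e = eq$sigma,
       mu_i = mI$mu[3], sigma_i = mI$sigma[3],
       j_ee = J * tau * dmu_e + J^2 * tau / (2 * eq$sigma) * dsg_e,
       j_ei = -g * J * tau * dmu_e +
         g^2 * J^2 * tau / (2 * eq$sigma) * dsg_e,
       j_ie = J * tau * dmu_i + J^2 * tau / (2 * mI$sigma[3]) * dsg_i,
       j_ii = -g * J * tau * dmu_i +
         g^2 * J^2 * tau / (2 * mI$sigma[3]) * dsg_i)
}

#' Point on the line attractor of the deterministic two-ensemble system
#'
#' The stationary states of the noise-free system form a line segment
#' parameterised by the within-engram connectivity
#' \eqn{x = \bar C_{E1E1}}: calcium and excitatory rates sit at the target,
#' and the remaining connectivity components are fixed by the requirement
#' that every neuron keeps the equilibrium in-degree (and out-degree)
#' \eqn{K^*}. The position along the line encodes the strength of a stored
#' engram.
#'
#' @param x within-engram connectivity \eqn{\bar C_{E1E1}}
#' @param model a [meanfield_model()]
#' @param k_star stationary in-degree; defaults to the grown equilibrium
#' @return named 9-component state vector (see [meanfield_model()])
#' @export
line_attractor_point <- function(x, model = meanfield_model(),
                                 k_star = NULL) {
  if (is.null(k_star)) k_star <- equilibrium_indegree(model$nu_target_hz,
                                                      model)$k
  n1 <- model$n_e1
  n2 <- model$n_e2
  x_max <- k_star / n1
  x_min <- max(0, k_star * (n1 - n2) / n1^2)
  if (x < x_min - 1e-12 || x > x_max + 1e-12)
    stop(sprintf("x = %g outside the admissible segment [%g, %g]",
                 x, x_min, x_max))
  c12 <- (k_star - x * n1) / n2
  c22 <- k_star * (n2 - n1) / n2^2 + x * (n1 / n2)^2
  nu <- model$nu_target_hz
  c(phi_e1 = nu, phi_e2 = nu, c11 = x, c12 = c12, c21 = c12, c22 = c22,
    r_e1 = nu, r_e2 = nu,
    r_i = selfconsistent_inhibitory_rate(model, nu))
}

#' Jacobian of the mean-field system at a state
#'
#' Assembles the full 9x9 Jacobian of the coupled calcium / connectivity /
#' rate dynamics. Calcium and rate blocks are analytic (rate entries built
#' from the effective couplings of [operating_point()]); the connectivity
#' rows are Richardson-extrapolated finite differences of
#' [connectivity_flow()], whose sparsity (no direct dependence on rates)
#' matches the analytic block structure.
#'
#' @param model a [meanfield_model()]
#' @param at 9-component state vector (ordering as [meanfield_model()])
#' @param op optional precomputed [operating_point()]
#' @return list with the full Jacobian \code{J}, the connectivity block
#'   \code{J_c} (rows/cols 3:6), and the rate block \code{J_r}
#' @export
build_jacobian <- function(model, at = meanfield_equilibrium(model),
                           op = operating_point(model)) {
  at <- as.numeric(at)
  tau_ca <- model$tau_ca_s
  tau_r <- model$tau_rate_s
  n1 <- model$n_e1
  n2 <- model$n_e2
  J <- matrix(0, 9, 9)
  J[1, 1] <- -1 / tau_ca; J[1, 7] <- 1 / tau_ca
  J[2, 2] <- -1 / tau_ca; J[2, 8] <- 1 / tau_ca
  # connectivity rows by numerical differentiation of the flow
  flow <- function(y) connectivity_flow(model, y[1:2], y[3:6])
  for (col in 1:6) {
    fd <- function(h) {
      yp <- at[1:6]; ym <- at[1:6]
      yp[col] <- yp[col] + h
      ym[col] <- ym[col] - h
      (flow(yp) - flow(ym)) / (2 * h)
    }
    h0 <- if (col <= 2) 1e-5 else 1e-7
    J[3:6, col] <- (4 * fd(h0 / 2) - fd(h0)) / 3
  }
  # rate rows: effective couplings, rates evaluated at the state
  r1 <- at[7]; r2 <- at[8]
  J[7, 3] <- op$j_ee * n1 * r1 / tau_r
  J[7, 4] <- op$j_ee * n2 * r2 / tau_r
  J[8, 5] <- op$j_ee * n1 * r1 / tau_r
  J[8, 6] <- op$j_ee * n2 * r2 / tau_r
  J[7, 7] <- (-1 + op$j_ee * at[3] * n1) / tau_r
  J[7, 8] <- op$j_ee * at[4] * n2 / tau_r
  J[7, 9] <- op$j_ei * model$eps * model$n_i / tau_r
  J[8, 7] <- op$j_ee * at[5] * n1 / tau_r
  J[8, 8] <- (-1 + op$j_ee * at[6] * n2) / tau_r
  J[8, 9] <- op$j_ei * model$eps * model$n_i / tau_r
  J[9, 7] <- op$j_ie * model$eps * n1 / tau_r
  J[9, 8] <- op$j_ie * model$eps * n2 / tau_r
  J[9, 9] <- (-1 + op$j_ii * model$eps * model$n_i) / tau_r
  list(J = J, J_c = J[3:6, 3:6], J_r = J[7:8, 7:8])
}

#' Analytic connectivity block at the global fixed point
#'
#' Closed-form rank-one connectivity block
#' \eqn{J_c = c_0 \, v \otimes (1, -1, -1, 1)} with prefactor
#' \eqn{c_0 = \eta \sqrt{\nu/(\pi \tau_{Ca})}\,(1/\beta_a + 1/\beta_d) /
#'  (2 c N_E^3)}; its spectrum is \eqn{\{0,0,0,\lambda_1\}} with
#' \eqn{\lambda_1 = -(R_{\sigma_a}(0) + R_{\sigma_d}(0))/(c N_E)}.
#'
#' @param model a [meanfield_model()]
#' @param cbar equilibrium connectivity fraction
#' @return list with the 4x4 block \code{J_c}, \code{lambda1}, and the
#'   slow eigenvector \code{v1} in (C11, C12, C21, C22) coordinates
#' @export
analytic_connectivity_block <- function(model, cbar = NULL) {
  if (is.null(cbar))
    cbar <- equilibrium_indegree(model$nu_target_hz, model)$k /
      (model$n_e1 + model$n_e2)
  n1 <- model$n_e1
  n2 <- model$n_e2
  n_e <- n1 + n2
  nu <- model$nu_target_hz
  c0 <- model$eta * sqrt(nu / (pi * model$tau_ca_s)) *
    (1 / model$beta_a + 1 / model$beta_d) / (2 * cbar * n_e^3)
  v <- c(-n2^2, n1 * n2, n1 * n2, -n1^2)
  J_c <- c0 * outer(v, c(1, -1, -1, 1))
  r0a <- rectified_gaussian_mean(0, element_rate_sd(nu, model$tau_ca_s,
                                                    model$beta_a, model$eta))
  r0d <- rectified_gaussian_mean(0, element_rate_sd(nu, model$tau_ca_s,
                                                    model$beta_d, model$eta))
  list(J_c = J_c, lambda1 = -(r0a + r0d) / (cbar * n_e),
       v1 = c(1, -n1 / n2, -n1 / n2, (n1 / n2)^2))
}

#' Relaxation time of the slow connectivity mode
#'
#' Reciprocal of the non-zero eigenvalue of the connectivity block,
#' \eqn{\tau_{diffusion} = 1/|\lambda_1|}, with
#' \eqn{\lambda_1 = -(R_{\sigma_a}(0)+R_{\sigma_d}(0))/(cN_E)} assembled
#' from the rectified-Gaussian element rates at the set-point. Equivalent
#' closed form:
#' \eqn{\tau_{diffusion} = \sqrt{4\pi\tau_{Ca}/(\eta^2\nu)}\; c N_E /
#' (1/\beta_a + 1/\beta_d)}. This is the time scale on which stored
#' engrams diffuse back to the uniform configuration, i.e. the memory
#' lifetime.
#'
#' @param tau_ca_s calcium time constant (s)
#' @param nu_hz target rate (Hz)
#' @param eta irregularity correction
#' @param n_e number of excitatory neurons
#' @param c_bar mean excitatory connectivity fraction
#' @param beta_a,beta_d growth parameters
#' @return relaxation time in seconds
#' @examples
#' slow_mode_timescale()  # ~5.7e3 s at default parameters
#' @export
slow_mode_timescale <- function(tau_ca_s = 10, nu_hz = 8, eta = 0.7,
                                n_e = 10000, c_bar = 0.1, beta_a = 2,
                                beta_d = 2) {
  stopifnot(tau_ca_s > 0, nu_hz > 0, eta > 0, n_e > 0, c_bar > 0,
            beta_a > 0, beta_d > 0)
  r0a <- rectified_gaussian_mean(0, element_rate_sd(nu_hz, tau_ca_s, beta_a,
                                                    eta))
  r0d <- rectified_gaussian_mean(0, element_rate_sd(nu_hz, tau_ca_s, beta_d,
                                                    eta))
  c_bar * n_e / (r0a + r0d)
}

#' Reduced one-population Jacobian for the oscillation analysis
#'
#' With identical axonal and dendritic dynamics the damped oscillations of
#' the homeostatic controller are captured by one plastic excitatory
#' population plus the static inhibitory population, with state
#' (\eqn{\phi}, \eqn{\bar C}, \eqn{r_E}, \eqn{r_I}).
#'
#' @param model a [meanfield_model()]
#' @param beta_d element growth parameter
#' @param tau_ca_s calcium time constant (s)
#' @param op precomputed [operating_point()] (couplings are independent of
#'   \code{beta_d} and \code{tau_ca_s}, so it can be reused across a scan)
#' @return 4x4 Jacobian matrix
#' @export
reduced_jacobian <- function(model = meanfield_model(), beta_d = 2,
                             tau_ca_s = 10, op = operating_point(model)) {
  n_e <- model$n_e1 + model$n_e2
  tau_r <- model$tau_rate_s
  nu <- model$nu_target_hz
  rbind(
    c(-1 / tau_ca_s, 0, 1 / tau_ca_s, 0),
    c(-1 / (n_e * beta_d), 0, 0, 0),
    c(0, op$j_ee * n_e * nu / tau_r, (-1 + op$j_ee * op$c * n_e) / tau_r,
      op$j_ei * model$eps * model$n_i / tau_r),
    c(0, 0, op$j_ie * model$eps * n_e / tau_r,
      (-1 + op$j_ii * model$eps * model$n_i) / tau_r))
}

# least-stable eigenvalue pair of a matrix (sorted by real part)
top_eigen <- function(m, k = 2) {
  ev <- eigen(m, only.values = TRUE)$values
  ev[order(Re(ev), decreasing = TRUE)][seq_len(k)]
}

#' Oscillation boundary of the homeostatic controller
#'
#' For each growth parameter \eqn{\beta_d}, bisects in the calcium time
#' constant for the point at which the least-stable eigenvalue pair of the
#' reduced Jacobian acquires a non-zero imaginary part (onset of damped
#' oscillations in network remodelling). Along the scan all real parts must
#' stay non-positive (the controller never loses linear stability).
#'
#' @param beta_grid values of \eqn{\beta_d} to scan
#' @param model a [meanfield_model()]
#' @param tau_range search interval for the boundary (s)
#' @param tol_s bisection tolerance (s)
#' @return data frame with \code{beta_d}, boundary \code{tau_ca_s},
#'   \code{max_re} (largest real part seen along the scan), and attribute
#'   \code{slope_s}: the origin-constrained least-squares slope of
#'   \eqn{\tau_{Ca}} versus \eqn{\beta_d}
#' @export
oscillation_boundary <- function(beta_grid = c(0.5, 1, 2, 4),
                                 model = meanfield_model(),
                                 tau_range = c(0.05, 100), tol_s = 1e-3) {
  stopifnot(all(beta_grid > 0))
  op <- operating_point(model)
  res <- lapply(beta_grid, function(bd) {
    osc <- function(tau_ca) {
      ev <- top_eigen(reduced_jacobian(model, bd, tau_ca, op))
      list(osc = abs(Im(ev[1])) > 1e-9, max_re = max(Re(ev)))
    }
    lo <- tau_range[1]
    hi <- tau_range[2]
    max_re <- -Inf
    s_lo <- osc(lo)
    s_hi <- osc(hi)
    max_re <- max(max_re, s_lo$max_re, s_hi$max_re)
    if (s_lo$osc || !s_hi$osc)
      return(data.frame(beta_d = bd, tau_ca_s = NA_real_, max_re = max_re))
    while (hi - lo > tol_s) {
      mid <- (lo + hi) / 2
      s <- osc(mid)
      max_re <- max(max_re, s$max_re)
      if (s$osc) hi <- mid else lo <- mid
    }
    data.frame(beta_d = bd, tau_ca_s = (lo + hi) / 2, max_re = max_re)
  })
  out <- do.call(rbind, res)
  ok <- !is.na(out$tau_ca_s)
  attr(out, "slope_s") <- sum(out$tau_ca_s[ok] * out$beta_d[ok]) /
    sum(out$beta_d[ok]^2)
  out
}

#' Critical within-engram connectivity
#'
#' Closed-form upper bound of rate stability for a fixed-in-degree network
#' with one strengthened ensemble:
#' \eqn{c_{crit} = \epsilon (1 + N_{E2} / (N_{E1} j_E))} with the effective
#' excitatory excitability \eqn{j_E = \epsilon N_E j_{EE}}. Beyond this
#' connectivity the engram's recurrent feedback breaks the
#' excitation-inhibition balance and population bursts become inevitable.
#'
#' @param model a [meanfield_model()]
#' @param op optional precomputed [operating_point()]
#' @return the critical connectivity fraction (dimensionless); \code{Inf}
#'   if the effective excitability is non-positive (no instability)
#' @export
critical_connectivity <- function(model = meanfield_model(),
                                  op = operating_point(model)) {
  j_e <- model$eps * (model$n_e1 + model$n_e2) * op$j_ee
  if (j_e <= 0) return(Inf)
  model$eps * (1 + model$n_e2 / (model$n_e1 * j_e))
}

#' Target rate that maximises memory longevity
#'
#' The slow-mode relaxation time scales as \eqn{c/\sqrt{\nu}}, but the
#' equilibrium connectivity \eqn{c} itself depends on the target rate.
#' Recomputing \eqn{c(\nu)} from the in-degree solver at every grid point
#' yields an interior optimum at low rates: very small targets make the
#' grown network so sparse that memories are lost quickly, large targets
#' speed up noise-driven rewiring.
#'
#' @param nu_grid candidate target rates (Hz)
#' @param model a [meanfield_model()]
#' @param tau_ca_s calcium time constant used in the longevity formula (s)
#' @return list with \code{nu_opt_hz} (grid argmax) and a data frame
#'   \code{table} of \code{nu_hz}, \code{c_bar}, \code{tau_diffusion_s}
#' @export
optimal_target_rate <- function(nu_grid = c(1, 1.5, 2, 2.5, 3, 3.5, 4, 5, 6,
                                            8, 12, 16, 24, 32),
                                model = meanfield_model(),
                                tau_ca_s = model$tau_ca_s) {
  n_e <- model$n_e1 + model$n_e2
  rows <- lapply(nu_grid, function(nu) {
    k <- tryCatch(equilibrium_indegree(nu, model)$k, error = function(e) NA)
    if (is.na(k)) {
      warning("no self-consistent in-degree at nu = ", nu, " Hz; skipped")
      return(data.frame(nu_hz = nu, c_bar = NA, tau_diffusion_s = NA))
    }
    cb <- k / n_e
    data.frame(nu_hz = nu, c_bar = cb,
               tau_diffusion_s = slow_mode_timescale(
                 tau_ca_s, nu, model$eta, n_e, cb, model$beta_a,
                 model$beta_d))
  })
  tab <- do.call(rbind, rows)
  list(nu_opt_hz = tab$nu_hz[which.max(tab$tau_diffusion_s)], table = tab)
}

#' Spine turnover ratio implied by equilibrium rewiring
#'
#' Definitional turnover ratio
#' \eqn{TOR = (\Delta N_{new} + \Delta N_{del}) / (2 N_{spines})} per day,
#' evaluated from the fluctuation-driven element creation and deletion
#' rates at the homeostatic set-point: each neuron creates and deletes
#' synapses at rate \eqn{R_{\sigma_a}(0) + R_{\sigma_d}(0)} while holding
#' \eqn{K = cN_E} spines, so the daily turnover fraction equals
#' \eqn{86400\,|\lambda_1|}. Without spiking noise (\code{eta = 0}) there
#' is no rewiring at the set-point and the turnover vanishes.
#'
#' @inheritParams slow_mode_timescale
#' @return turnover fraction per day (1 = all spines exchanged once a day)
#' @export
turnover_ratio <- function(tau_ca_s = 10, nu_hz = 8, eta = 0.7,
                           n_e = 10000, c_bar = 0.1, beta_a = 2,
                           beta_d = 2) {
  stopifnot(tau_ca_s > 0, nu_hz > 0, eta >= 0, beta_a > 0, beta_d > 0)
  if (eta == 0) return(0)
  86400 / slow_mode_timescale(tau_ca_s, nu_hz, eta, n_e, c_bar, beta_a,
                              beta_d)
}

#' Dimension of the stationary connectivity hyperplane
#'
#' For \eqn{n_E} plastic populations the stationary states of the
#' deterministic system form a hyperplane of dimension
#' \eqn{n_E(n_E-2)+1 = (n_E-1)^2}: the \eqn{n_E^2} connectivity means are
#' constrained by fixed in-degrees, fixed out-degrees, and one shared total
#' (in-degrees and out-degrees sum to the same element count). The function
#' constructs the constraint system explicitly and returns the dimension of
#' its null space.
#'
#' @param sizes plastic population sizes
#' @return integer dimension of the stationary hyperplane
#' @export
stationary_hyperplane_dim <- function(sizes) {
  n_pop <- length(sizes)
  n <- as.numeric(sizes)
  # constraints on vec(C) (row-major YZ): in-degree per row, out-degree per
  # column; one is redundant since both sum to the total element count
  A <- matrix(0, 2 * n_pop, n_pop^2)
  for (y in seq_len(n_pop))
    for (z in seq_len(n_pop)) {
      A[y, (y - 1) * n_pop + z] <- n[z]
      A[n_pop + z, (y - 1) * n_pop + z] <- n[y]
    }
  as.integer(n_pop^2 - qr(A)$rank)
}
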