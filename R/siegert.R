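#' Stationary firing rate of a noise-driven LIF neuron (Siegert formula)
#'
#' First-passage-time rate of a leaky integrate-and-fire neuron receiving
#' Gaussian white-noise current with mean \code{mu} and standard deviation
#' \code{sigma} (both in mV, on the scale of the free membrane potential):
#' \deqn{r = \left[t_{ref} + \tau_m \sqrt{\pi}
#'   \int_{(V_r-\mu)/\sigma}^{(V_{th}-\mu)/\sigma} e^{u^2}(1+\mathrm{erf}\,u)
#'   \, du\right]^{-1}.}
#' The integrand is evaluated in the numerically stable form
#' \eqn{\mathrm{erfcx}(-u)} with an asymptotic branch for strongly
#' drift-dominated input, so the formula is usable over the whole range of
#' sub- and suprathreshold drive.
#'
#' @param mu mean input (mV); vectorized
#' @param sigma input standard deviation (mV); must be positive
#' @param params a [lif_params()] object
#' @return firing rate(s) in spikes/s
#' @examples
#' siegert_rate(14, 5.5, lif_params())
#' @export
siegert_rate <- function(mu, sigma, params = lif_params()) {
  sigma <- rep_len(sigma, length(mu))
  if (any(sigma <= 0)) stop("sigma must be positive")
  siegert_cpp(as.numeric(mu), as.numeric(sigma), params$tau_m_ms * 1e-3,
              params$t_ref_ms * 1e-3, params$v_th_mv, params$v_r_mv)
}

#' Coefficient of variation of LIF interspike intervals
#'
#' Evaluates the first-passage-time expression for the squared coefficient
#' of variation of the interspike intervals of an LIF neuron driven by
#' Gaussian white noise,
#' \deqn{CV^2 = 2\pi (r \tau_m)^2 \int_{y_r}^{y_{th}} e^{x^2}
#'   \int_{-\infty}^{x} e^{y^2}(1+\mathrm{erf}\,y)^2 \, dy \, dx,}
#' with \eqn{y = (V-\mu)/\sigma} and \eqn{r} the Siegert rate, and returns
#' its square root. The inner integral is computed in a rescaled form that
#' never overflows.
#'
#' @inheritParams siegert_rate
#' @return the CV (dimensionless); 1 corresponds to Poisson irregularity
#' @export
cv_isi <- function(mu, sigma, params = lif_params()) {
  if (sigma <= 0) stop("sigma must be positive")
  tau_s <- params$tau_m_ms * 1e-3
  r0 <- siegert_rate(mu, sigma, params)
  if (r0 <= 0) stop("firing rate vanishes at this operating point")
  yth <- (params$v_th_mv - mu) / sigma
  yr <- (params$v_r_mv - mu) / sigma
  # e^{x^2} * inner(x), written as an integral that stays finite for all x
  outer_fn <- function(x) {
    vapply(x, function(xx) {
      integrate(function(s) erfcx_cpp(s - xx)^2 * exp(2 * xx * s - s^2),
                0, Inf, rel.tol = 1e-9)$value
    }, numeric(1))
  }
  val <- tryCatch(
    integrate(outer_fn, yr, yth, rel.tol = 1e-8)$value,
    error = function(e) stop("CV quadrature failed: ", conditionMessage(e)))
  sqrt(2 * pi * (r0 * tau_s)^2 * val)
}

#' Mean element creation and deletion rates under calcium noise
#'
#' The homeostatic growth rule turns the (noisy) calcium deviation from the
#' set-point into rates of creation and deletion of synaptic elements. With
#' the calcium trace fluctuating as a Gaussian with standard deviation
#' \code{sigma_x} (in element/s units), the mean creation rate at mean drive
#' \eqn{\mu} is the rectified-Gaussian mean
#' \deqn{R_\sigma(\mu) = \frac{1}{2}\left(\mu + \mu\,\mathrm{erf}
#'  \frac{\mu}{\sqrt{2}\sigma} \right) + \sqrt{\frac{1}{2\pi}}\,\sigma\,
#'   e^{-\mu^2/2\sigma^2},}
#' and the deletion rate is \eqn{R_\sigma(-\mu)}. At \eqn{\sigma_x = 0} the
#' rates reduce to the sharp rectifiers \eqn{[\mu]_\pm}. Even at the
#' set-point (\eqn{\mu = 0}) noise keeps both rates at
#' \eqn{\sigma_x/\sqrt{2\pi} > 0}, which is what drives spontaneous synaptic
#' turnover and memory decay.
#'
#' @param mu_drive mean element drive, \eqn{(\nu - \bar\phi)/\beta}
#'   (elements/s); vectorized
#' @param sigma_x standard deviation of the element rate (elements/s)
#' @return a list with components \code{creation} and \code{deletion}
#' @examples
#' r <- element_rate_mean(0, 0.22)
#' r$creation  # sigma_x / sqrt(2*pi)
#' @export
element_rate_mean <- function(mu_drive, sigma_x) {
  if (sigma_x < 0) stop("sigma_x must be non-negative")
  list(creation = rectified_gaussian_mean(mu_drive, sigma_x),
       deletion = rectified_gaussian_mean(-mu_drive, sigma_x))
}

# E[max(X, 0)] for X ~ N(mu, sigma^2)
rectified_gaussian_mean <- function(mu, sigma) {
  if (sigma <= 0) return(pmax(mu, 0))
  z <- mu / sigma
  mu * pnorm(z) + sigma * dnorm(z)
}

#' Standard deviation of the element growth rate induced by spiking noise
#'
#' Campbell's theorem gives the stationary variance of the exponentially
#' filtered spike train (the calcium trace) as
#' \eqn{\sigma_{Ca}^2 = CV^2 \nu / (2 \tau_{Ca})}; passed through the linear
#' growth rule this yields an element-rate standard deviation
#' \eqn{\sigma_x = \eta \sqrt{\nu / (2\tau_{Ca})} / \beta}, with the
#' irregularity correction \eqn{\eta = CV} of the spike trains.
#'
#' @param nu_hz firing rate at the set-point (spikes/s)
#' @param tau_ca_s calcium time constant (s)
#' @param beta element growth parameter
#' @param eta irregularity correction factor (the ISI CV; 0 disables noise)
#' @return sigma_x in elements/s
#' @export
element_rate_sd <- function(nu_hz, tau_ca_s, beta, eta = 0.7) {
  eta * sqrt(nu_hz / (2 * tau_ca_s)) / beta
}
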