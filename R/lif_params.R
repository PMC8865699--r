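#' Leaky integrate-and-fire neuron and input parameters
#'
#' Parameters of the current-based LIF neurons with delta-pulse synapses and
#' independent external Poisson drive. Excitatory synaptic contacts have peak
#' amplitude \code{j_mv}; inhibitory contacts have amplitude \code{-g * j_mv}.
#'
#' The membrane time constant has no canonical value for this network class
#' in the 10--30 ms range changes the operating point only mildly; the
#' default of 20 ms is the textbook value for cortical balanced-network
#' models and can be overridden in every entry point.
#'
#' @param tau_m_ms membrane time constant (ms)
#' @param v_th_mv firing threshold (mV)
#' @param v_r_mv reset potential (mV)
#' @param t_ref_ms absolute refractory period (ms)
#' @param delay_ms synaptic transmission delay (ms), shared by all synapses
#' @param j_mv excitatory postsynaptic potential amplitude (mV)
#' @param g ratio of inhibitory to excitatory synaptic amplitude
#' @param nu_ext_hz rate of the external Poisson input (spikes/s)
#' @return an object of class \code{lif_params}
#' @examples
#' p <- lif_params()
#' p$nu_ext_hz
#' @export
lif_params <- function(tau_m_ms = 20, v_th_mv = 20, v_r_mv = 10,
                       t_ref_ms = 2, delay_ms = 1.5, j_mv = 0.1, g = 8,
                       nu_ext_hz = 15000) {
  p <- list(tau_m_ms = tau_m_ms, v_th_mv = v_th_mv, v_r_mv = v_r_mv,
            t_ref_ms = t_ref_ms, delay_ms = delay_ms, j_mv = j_mv, g = g,
            nu_ext_hz = nu_ext_hz)
  stopifnot(is.numeric(unlist(p)), !anyNA(unlist(p)))
  if (v_th_mv <= v_r_mv) stop("v_th_mv must exceed v_r_mv")
  if (t_ref_ms < 0) stop("t_ref_ms must be non-negative")
  if (delay_ms <= 0) stop("delay_ms must be positive")
  if (j_mv <= 0 || g <= 0) stop("j_mv and g must be positive")
  if (tau_m_ms <= 0) stop("tau_m_ms must be positive")
  if (nu_ext_hz < 0) stop("nu_ext_hz must be non-negative")
  structure(p, class = "lif_params")
}

#' @export
print.lif_params <- function(x, ...) {
  cat("LIF parameters:\n")
  cat(sprintf("  tau_m = %g ms, V_th = %g mV, V_r = %g mV, t_ref = %g ms\n",
              x$tau_m_ms, x$v_th_mv, x$v_r_mv, x$t_ref_ms))
  cat(sprintf("  delay = %g ms, J = %g mV, g = %g, nu_ext = %g Hz\n",
              x$delay_ms, x$j_mv, x$g, x$nu_ext_hz))
  invisible(x)
}

#' Homeostatic structural-plasticity parameters
#'
#' Parameters of the calcium-based homeostatic controller and the periodic
#' rewiring step acting on excitatory-to-excitatory connections. Each neuron
#' low-pass filters its own spike train into a calcium trace (time constant
#' \code{tau_ca_s}); deviations of the trace from the target rate grow or
#' shrink continuous axonal and dendritic element counters at speed
#' \code{1/beta}; every \code{delta_t_s_ms} negative elements delete randomly
#' chosen contacts and free elements are randomly paired into new contacts.
#'
#' @param tau_ca_s calcium filter time constant (s)
#' @param beta_a axonal element growth parameter (s * Hz per element)
#' @param beta_d dendritic element growth parameter
#' @param nu_target_hz homeostatic set-point of the firing rate (spikes/s)
#' @param delta_t_s_ms interval between rewiring steps (ms)
#' @param enabled logical; \code{FALSE} freezes all structural plasticity
#'   (the infinitely slow growth limit), leaving a pure spiking network
#' @return an object of class \code{plasticity_params}
#' @export
plasticity_params <- function(tau_ca_s = 10, beta_a = 2, beta_d = 2,
                              nu_target_hz = 8, delta_t_s_ms = 100,
                              enabled = TRUE) {
  if (tau_ca_s <= 0 || beta_a <= 0 || beta_d <= 0)
    stop("tau_ca_s, beta_a and beta_d must be positive")
  if (nu_target_hz <= 0) stop("nu_target_hz must be positive")
  if (delta_t_s_ms <= 0) stop("delta_t_s_ms must be positive")
  structure(list(tau_ca_s = tau_ca_s, beta_a = beta_a, beta_d = beta_d,
                 nu_target_hz = nu_target_hz, delta_t_s_ms = delta_t_s_ms,
                 enabled = isTRUE(enabled)),
            class = "plasticity_params")
}
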