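#' Exact calcium-trace update
#'
#' The calcium trace is a first-order low-pass filter of the spike train,
#' \eqn{\tau_{Ca}\dot\phi = -\phi + S(t)}; over a step of length
#' \code{dt_s} with \code{n_spikes} delta events the exact update is
#' \eqn{\phi \leftarrow \phi e^{-dt/\tau_{Ca}} + n / \tau_{Ca}}. Its
#' stationary mean equals the firing rate in Hz.
#'
#' @param phi calcium trace(s) (Hz-equivalent)
#' @param n_spikes spikes emitted during the step
#' @param dt_s step length (s)
#' @param tau_ca_s calcium time constant (s)
#' @return updated trace
#' @examples
#' update_calcium(8, 0, 10, 10)  # 8/e after one time constant
#' @export
update_calcium <- function(phi, n_spikes, dt_s, tau_ca_s) {
  if (dt_s <= 0) stop("dt_s must be positive")
  phi * exp(-dt_s / tau_ca_s) + n_spikes / tau_ca_s
}

#' Homeostatic growth of synaptic-element counters
#'
#' Continuous axonal and dendritic element counters integrate the deviation
#' of the calcium trace from the target rate:
#' \eqn{\beta \dot x = \nu - \phi}. Counters may drop below the current
#' degree (producing negative elements that trigger deletions at the next
#' rewiring step) but are floored at zero.
#'
#' @param a,d element counters
#' @param phi calcium trace(s) (Hz)
#' @param dt_s step length (s)
#' @param plasticity a [plasticity_params()] object
#' @return list with updated \code{a} and \code{d}
#' @export
update_elements <- function(a, d, phi, dt_s, plasticity) {
  if (dt_s <= 0) stop("dt_s must be positive")
  drive <- dt_s * (plasticity$nu_target_hz - phi)
  list(a = pmax(a + drive / plasticity$beta_a, 0),
       d = pmax(d + drive / plasticity$beta_d, 0))
}

#' One structural rewiring step
#'
#' Executes the periodic rewiring of the EE block: (deletion phase) each
#' neuron whose floored element counter lies below its degree deletes the
#' deficit among its existing contacts, chosen uniformly at the level of
#' individual contacts (a multapse loses contacts in proportion to its
#' count), with the bonded counterparts becoming free elements; (creation
#' phase) all free axonal and dendritic elements are collected and
#' \eqn{n = \min(|a^+|, |d^+|)} uniform random pairings without replacement
#' are formed, rejecting and redrawing self-pairings. The uniform pairing
#' realises the hypergeometric increment law of the model exactly.
#'
#' @param ee EE triplet matrix (\code{pre}, \code{post}, \code{count})
#' @param n_e number of excitatory neurons
#' @param a,d continuous element counters (length \code{n_e})
#' @param seed rewiring RNG seed
#' @return list with the new \code{ee} triplets and degree vectors
#'   \code{k_in}, \code{k_out}
#' @examples
#' # one free axonal element on neuron 1, one free dendritic on neuron 2
#' rewire_step(matrix(integer(), 0, 3), 2, a = c(1, 0), d = c(0, 1),
#'             seed = 1)$ee
#' @export
rewire_step <- function(ee, n_e, a, d, seed = 1) {
  stopifnot(length(a) == n_e, length(d) == n_e)
  res <- rewire_step_cpp(storage_int_matrix(ee), n_e, as.numeric(a),
                         as.numeric(d), as.integer(seed))
  colnames(res$ee) <- c("pre", "post", "count")
  res
}
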