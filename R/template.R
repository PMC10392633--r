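#' Model current pulse for a single exocytotic event
#'
#' Difference-of-exponentials pulse used by the simulator:
#' \deqn{i(t) = c \left(e^{-t/\tau_d} - e^{-t/\tau_r}\right), \quad t \ge 0,}
#' with the scale \eqn{c = Q/(\tau_d - \tau_r)} chosen so that the time
#' integral over \eqn{[0, \infty)} equals the requested charge. With
#' charge in fC and time constants in ms, \eqn{c} is directly in pA
#' (1 fC/ms = 1 pA). The pulse is non-negative for any ordering of the
#' two time constants; when they coincide it degenerates continuously to
#' the alpha function \eqn{Q\, t\, e^{-t/\tau} / \tau^2}.
#'
#' This is a generative model for the simulator only: real spike shapes
#' are characterised downstream purely by i_max, t_half, t_rise and
#' t_fall, so any strictly positive pulse with controllable rise and
#' decay would serve.
#'
#' @param t_rel Time since event onset, in seconds (vectorised; values
#'   < 0 return 0).
#' @param charge Total charge carried by the pulse, fC.
#' @param rise_tau,decay_tau Rise and decay time constants, ms.
#' @return Current in pA, same length as `t_rel`.
#' @examples
#' t <- seq(0, 0.05, by = 1 / 5000)
#' i <- spike_template(t, charge = 1000, rise_tau = 1, decay_tau = 5)
#' sum((i[-1] + i[-length(i)]) / 2) * (1000 / 5000)  # ~1000 fC
#' @export
spike_template <- function(t_rel, charge, rise_tau, decay_tau) {
  if (!is.numeric(rise_tau) || !is.numeric(decay_tau) ||
      rise_tau <= 0 || decay_tau <= 0) {
    stop("rise_tau and decay_tau must be positive", call. = FALSE)
  }
  stopifnot(is.numeric(charge), length(charge) == 1L, charge > 0)
  t_ms <- t_rel * 1000
  out <- numeric(length(t_ms))
  pos <- t_ms >= 0
  tp <- t_ms[pos]
  if (abs(decay_tau - rise_tau) < 1e-9 * decay_tau) {
    tau <- decay_tau
    out[pos] <- charge * tp * exp(-tp / tau) / tau^2
  } else {
    cc <- charge / (decay_tau - rise_tau)
    out[pos] <- cc * (exp(-tp / decay_tau) - exp(-tp / rise_tau))
  }
  out
}

#' Analytic peak of the template pulse
#'
#' Closed-form peak time and amplitude of [spike_template()]: the peak is
#' at \eqn{t^* = \tau_r \tau_d \ln(\tau_d/\tau_r) / (\tau_d - \tau_r)}
#' (or \eqn{t^* = \tau} in the equal-tau limit). Used to record the
#' ground-truth i_max in the simulator ledger.
#'
#' @inheritParams spike_template
#' @return List with `t_peak_s` (s) and `i_max_pA`.
#' @keywords internal
template_peak <- function(charge, rise_tau, decay_tau) {
  if (abs(decay_tau - rise_tau) < 1e-9 * decay_tau) {
    t_ms <- decay_tau
  } else {
    t_ms <- rise_tau * decay_tau * log(decay_tau / rise_tau) / (decay_tau - rise_tau)
  }
  list(
    t_peak_s = t_ms / 1000,
    i_max_pA = spike_template(t_ms / 1000, charge, rise_tau, decay_tau)
  )
}
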