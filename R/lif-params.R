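#' Leaky integrate-and-fire neuron parameters
#'
#' Container for the parameters of a current-based LIF neuron with
#' exponentially decaying synaptic currents.  Defaults are the standard
#' cortical-microcircuit values: tau_m = 10 ms, tau_s = 0.5 ms,
#' tau_ref = 2 ms, R_m = 40 MOhm, E_L = -65 mV, theta = -50 mV,
#' V_r = -65 mV.
#'
#' Subthreshold dynamics:
#' \deqn{\tau_m dV/dt = -(V - E_L) + R_m I(t)}
#' \deqn{\tau_s dI/dt = -I + \tau_s \sum_j J_{ij} s_j(t - d_j)}
#' A spike is emitted when \code{V >= theta}; the membrane is then clamped
#' to \code{V_r} for \code{tau_ref}.
#'
#' @param tau_m membrane time constant, ms.
#' @param tau_s synaptic time constant, ms.
#' @param tau_ref absolute refractory period, ms.
#' @param R_m membrane resistance, MOhm (so R_m * I with I in nA gives mV).
#' @param E_L leak (resting) potential, mV.
#' @param theta spike threshold, mV.
#' @param V_r reset potential, mV; must satisfy \code{V_r <= theta}.
#' @return an object of class \code{"lif_params"}.
#' @examples
#' p <- neuron_params()
#' p$tau_m
#' @export
neuron_params <- function(tau_m = 10, tau_s = 0.5, tau_ref = 2,
                          R_m = 40, E_L = -65, theta = -50, V_r = -65) {
  if (!all(is.finite(c(tau_m, tau_s, tau_ref, R_m, E_L, theta, V_r))))
    stop("neuron parameters must be finite")
  if (tau_m <= 0 || tau_s <= 0 || tau_ref < 0)
    stop("time constants must be positive (tau_ref >= 0)")
  if (R_m <= 0) stop("R_m must be positive")
  if (V_r > theta) stop("V_r must not exceed theta")
  structure(list(tau_m = tau_m, tau_s = tau_s, tau_ref = tau_ref,
                 R_m = R_m, E_L = E_L, theta = theta, V_r = V_r),
            class = "lif_params")
}

#' @export
print.lif_params <- function(x, ...) {
  cat("LIF neuron parameters:\n")
  cat(sprintf("  tau_m = %g ms, tau_s = %g ms, tau_ref = %g ms\n",
              x$tau_m, x$tau_s, x$tau_ref))
  cat(sprintf("  R_m = %g MOhm, E_L = %g mV, theta = %g mV, V_r = %g mV\n",
              x$R_m, x$E_L, x$theta, x$V_r))
  invisible(x)
}

#' Dynamic state of a single LIF neuron
#'
#' @param V membrane potential, mV.
#' @param I synaptic current, nA.
#' @param refractory_remaining remaining refractory time, ms (>= 0).  While
#'   positive the membrane is clamped to \code{V_r}.
#' @return an object of class \code{"lif_state"}.
#' @export
neuron_state <- function(V, I = 0, refractory_remaining = 0) {
  stopifnot(is.finite(V), is.finite(I), refractory_remaining >= 0)
  structure(list(V = V, I = I,
                 refractory_remaining = refractory_remaining),
            class = "lif_state")
}
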