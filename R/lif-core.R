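#' One-step exact propagator of the subthreshold LIF system
#'
#' Closed-form map of the linear membrane/synapse system over one step
#' \code{h}: with \code{alpha = exp(-h/tau_m)}, \code{beta = exp(-h/tau_s)}
#' and \code{P21 = R_m * tau_s * (beta - alpha) / (tau_s - tau_m)}, the
#' update is \code{I' = beta * I} and
#' \code{V' = E_L + (V - E_L) * alpha + I * P21}, which is the analytical
#' solution sampled at \code{h}.  The degenerate case
#' \code{tau_s == tau_m} uses the removable-singularity limit
#' \code{P21 = R_m * (h/tau_m) * alpha}.
#'
#' @param params a [neuron_params()] object.
#' @param h step size, ms; \code{h = 0} yields the identity map.
#' @return object of class \code{"exact_propagator"} with fields \code{h},
#'   \code{alpha}, \code{beta}, \code{P21}.
#' @examples
#' pr <- exact_propagator(neuron_params(), 0.1)
#' pr$P21  # about 0.3607 mV/nA for the default parameters
#' @export
exact_propagator <- function(params, h) {
  stopifnot(inherits(params, "lif_params"))
  if (!is.finite(h) || h < 0) stop("h must be non-negative and finite")
  alpha <- exp(-h / params$tau_m)
  beta <- exp(-h / params$tau_s)
  P21 <- if (params$tau_s == params$tau_m) {
    params$R_m * (h / params$tau_m) * alpha
  } else {
    params$R_m * params$tau_s * (beta - alpha) / (params$tau_s - params$tau_m)
  }
  structure(list(h = h, alpha = alpha, beta = beta, P21 = P21),
            class = "exact_propagator")
}

#' Advance a neuron state one step with the exact propagator
#'
#' Per-step order: (1) propagate V and decay I, (2) add the incoming weight
#' sum to I, (3) threshold test (spike when \code{V >= theta}, reset to
#' \code{V_r}, refractory for \code{tau_ref}).  While refractory the
#' membrane is clamped to \code{V_r} and the counter decreases by \code{h}.
#'
#' @param state a [neuron_state()].
#' @param prop an [exact_propagator()].
#' @param params the matching [neuron_params()].
#' @param incoming_weight_sum signed total of deliveries due this step, nA.
#' @param I_dc constant DC current, nA (propagated exactly).
#' @return a [neuron_state()] with attribute \code{"spiked"} (logical).
#' @export
step_exact <- function(state, prop, params, incoming_weight_sum = 0,
                       I_dc = 0) {
  stopifnot(inherits(state, "lif_state"), inherits(prop, "exact_propagator"))
  V <- params$E_L + (state$V - params$E_L) * prop$alpha +
    state$I * prop$P21 + params$R_m * I_dc * (1 - prop$alpha)
  I <- prop$beta * state$I + incoming_weight_sum
  spiked <- FALSE
  ref <- state$refractory_remaining
  if (ref > 0) {
    V <- params$V_r
    ref <- max(ref - prop$h, 0)
  } else if (V >= params$theta) {
    spiked <- TRUE
    V <- params$V_r
    ref <- params$tau_ref
  }
  out <- neuron_state(V, I, ref)
  attr(out, "spiked") <- spiked
  out
}

#' Advance a neuron state one step with exponential (separated) integration
#'
#' The synaptic current is treated as piecewise constant within the step:
#' \code{I' = beta * I + q * w_in} followed by
#' \code{V' = E_L + (V - E_L) * alpha + R_m * (I' + I_dc) * (1 - alpha)}.
#' The default input scaling \code{q = tau_s * (1 - beta) / h} enforces the
#' charge contract that the total charge transferred per synaptic event is
#' \code{J * tau_s} (geometric series \code{h * J * q / (1 - beta)});
#' \code{scheme = "decay_then_add"} instead uses \code{q = beta}, the
#' literal decay-over-one-step-before-adding reading.
#'
#' @inheritParams step_exact
#' @param h step size, ms.
#' @param scheme input scaling rule, \code{"charge"} (default) or
#'   \code{"decay_then_add"}.
#' @return a [neuron_state()] with attribute \code{"spiked"}.
#' @export
step_exponential <- function(state, params, h, incoming_weight_sum = 0,
                             I_dc = 0, scheme = c("charge", "decay_then_add")) {
  stopifnot(inherits(state, "lif_state"), h > 0)
  scheme <- match.arg(scheme)
  alpha <- exp(-h / params$tau_m)
  beta <- exp(-h / params$tau_s)
  q <- if (scheme == "charge") params$tau_s * (1 - beta) / h else beta
  I <- beta * state$I + q * incoming_weight_sum
  V <- params$E_L + (state$V - params$E_L) * alpha +
    params$R_m * (I + I_dc) * (1 - alpha)
  spiked <- FALSE
  ref <- state$refractory_remaining
  if (ref > 0) {
    V <- params$V_r
    ref <- max(ref - h, 0)
  } else if (V >= params$theta) {
    spiked <- TRUE
    V <- params$V_r
    ref <- params$tau_ref
  }
  out <- neuron_state(V, I, ref)
  attr(out, "spiked") <- spiked
  out
}

#' Locate an off-grid threshold crossing within one step
#'
#' With inputs constrained to the grid, the membrane potential within a step
#' follows the closed-form solution from the step's initial state.  This
#' finds the earliest \code{t*} in \code{[0, h]} with \code{V(t*) = theta}
#' by scanning for a sign change and bisecting to tolerance \code{tol}.
#'
#' @param state a [neuron_state()] at the start of the step.
#' @param params a [neuron_params()].
#' @param h step size, ms.
#' @param tol bisection tolerance on the crossing time, ms (> 0).
#' @param I_dc constant DC current, nA.
#' @return crossing time in ms, or \code{NA_real_} if the threshold is not
#'   reached within the step.
#' @export
find_precise_crossing <- function(state, params, h, tol = 1e-9, I_dc = 0) {
  stopifnot(inherits(state, "lif_state"), h > 0)
  if (!is.finite(tol) || tol <= 0) stop("tol must be positive")
  tc <- cpp_precise_crossing(unclass(params), state$V, state$I, I_dc, h, tol)
  if (tc < 0) NA_real_ else tc
}

#' Closed-form subthreshold membrane potential
#'
#' Evaluates the analytical solution \code{V(t)} of the subthreshold system
#' from initial state \code{(V0, I0)} under an optional DC current.  Used as
#' the oracle for the off-grid crossing search.
#'
#' @param state a [neuron_state()].
#' @param params a [neuron_params()].
#' @param t vector of times, ms (>= 0).
#' @param I_dc constant DC current, nA.
#' @return numeric vector of membrane potentials, mV.
#' @export
subthreshold_voltage <- function(state, params, t, I_dc = 0) {
  em <- exp(-t / params$tau_m)
  P21t <- if (params$tau_s == params$tau_m) {
    params$R_m * (t / params$tau_m) * em
  } else {
    es <- exp(-t / params$tau_s)
    params$R_m * params$tau_s * (es - em) / (params$tau_s - params$tau_m)
  }
  params$E_L + (state$V - params$E_L) * em + state$I * P21t +
    params$R_m * I_dc * (1 - em)
}

.backend_codes <- c("exact-grid" = 0L, "exponential-grid" = 1L,
                    "exponential-fixed" = 2L, "precise" = 3L)

#' Simulate a single LIF neuron under grid-constrained input
#'
#' Runs one neuron for \code{length(input)} steps of size \code{h} under one
#' of four numerical backends:
#' \describe{
#'   \item{\code{exact-grid}}{exact subthreshold propagation, spikes on the
#'     grid (the reference grid integrator).}
#'   \item{\code{exponential-grid}}{separated (piecewise-constant-current)
#'     integration in double precision.}
#'   \item{\code{exponential-fixed}}{separated integration with s16.15
#'     fixed-point state and weights quantized to an unsigned 16-bit format
#'     with \code{frac_bits} fractional bits (hardware emulation).}
#'   \item{\code{precise}}{exact propagation with off-grid threshold
#'     crossing located on the closed-form solution (the reference for the
#'     accuracy measures).}
#' }
#' The run is deterministic given \code{(backend, input)}; multiple input
#' spikes in one step are aggregated as \code{count * J} before delivery.
#'
#' @param params a [neuron_params()].
#' @param backend backend name, see above.
#' @param input integer vector of input spike counts per step (from
#'   [generate_grid_poisson()] or supplied explicitly).
#' @param h step size, ms.
#' @param J synaptic weight per input spike, nA (default 0.0878 nA, the
#'   standard excitatory strength).
#' @param I_dc constant DC current, nA.
#' @param frac_bits fractional bits of the 16-bit weight format used by the
#'   \code{exponential-fixed} backend (default 16: all bits fractional, the
#'   single-neuron test format).
#' @param tol crossing tolerance for the \code{precise} backend, ms.
#' @param scheme input scaling of the exponential backends, see
#'   [step_exponential()].
#' @param record_trace record the membrane potential at every step?
#' @return list with \code{spikes} (numeric, ms), \code{trace} (data.frame
#'   \code{time_ms}, \code{V_mV}, or NULL), \code{overflow_count}.
#' @examples
#' p <- neuron_params()
#' inp <- generate_grid_poisson(8000, h = 0.1, duration = 200, seed = 1)
#' r <- run_single_neuron(p, "exact-grid", inp, h = 0.1)
#' length(r$spikes)
#' @export
run_single_neuron <- function(params, backend, input, h, J = 0.0878,
                              I_dc = 0, frac_bits = 16, tol = 1e-9,
                              scheme = c("charge", "decay_then_add"),
                              record_trace = TRUE) {
  stopifnot(inherits(params, "lif_params"), h > 0)
  scheme <- match.arg(scheme)
  if (!backend %in% names(.backend_codes))
    stop("unknown backend '", backend, "'; expected one of ",
         paste(names(.backend_codes), collapse = ", "))
  input <- as.integer(input)
  if (anyNA(input) || any(input < 0)) stop("input counts must be >= 0")
  res <- cpp_run_single_neuron(unclass(params), .backend_codes[[backend]],
                               input, h, J, as.integer(frac_bits), tol,
                               scheme == "decay_then_add", I_dc,
                               record_trace)
  trace <- NULL
  if (record_trace) {
    trace <- data.frame(time_ms = seq_len(length(input)) * h,
                        V_mV = res$trace)
  }
  list(spikes = as.numeric(res$spikes), trace = trace,
       overflow_count = res$overflow_count)
}
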