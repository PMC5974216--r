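#' CPU-cycle cost model of the neuromorphic platform
#'
#' At the hardware design point — 1 ms step, 1,000 incoming synapses per
#' neuron, 200 MHz clock — the per-step budget splits as 10% (20,000
#' cycles) for neural updates and 90% (180,000 cycles) for synapse
#' processing.  Shrinking the biological step multiplies the neural work
#' per millisecond of biological time; the synaptic work per millisecond
#' stays constant but scales with the number of synapses per neuron.
#'
#' @param neural_cycles_per_ms_at_spec cycles per ms for neural updates at
#'   the design point.
#' @param synaptic_cycles_per_ms_at_spec cycles per ms for synapse
#'   processing at the design point.
#' @param design_synapses_per_neuron synapses per neuron at the design
#'   point.
#' @param clock_cycles_per_ms clock rate in cycles per ms (200,000 for
#'   200 MHz).
#' @param spread_fraction fraction of the step over which outgoing packets
#'   are spread (1 uses the whole step; 0.5 leaves the second half for
#'   processing at the receiving end).
#' @return object of class \code{"cost_model_spec"}.
#' @export
cost_model_spec <- function(neural_cycles_per_ms_at_spec = 20000,
                            synaptic_cycles_per_ms_at_spec = 180000,
                            design_synapses_per_neuron = 1000,
                            clock_cycles_per_ms = 200000,
                            spread_fraction = 0.5) {
  stopifnot(neural_cycles_per_ms_at_spec > 0,
            synaptic_cycles_per_ms_at_spec > 0,
            design_synapses_per_neuron > 0, clock_cycles_per_ms > 0,
            spread_fraction > 0, spread_fraction <= 1)
  structure(as.list(environment()), class = "cost_model_spec")
}

#' Required CPU cycles per millisecond of biological time
#'
#' \code{neural * (1 ms / h_b) + synaptic * (synapses_per_neuron / design)}.
#' At the design point this is 200,000 cycles/ms; at \code{h_b = 0.1} ms
#' with 10,000 synapses per neuron it is 2,000,000 cycles/ms.
#'
#' @param spec a [cost_model_spec()].
#' @param h_b biological step, ms.
#' @param synapses_per_neuron incoming synapses per neuron.
#' @return cycles per ms of biological time.
#' @examples
#' cycles_per_ms(cost_model_spec(), h_b = 0.1, synapses_per_neuron = 10000)
#' @export
cycles_per_ms <- function(spec = cost_model_spec(), h_b,
                          synapses_per_neuron) {
  stopifnot(inherits(spec, "cost_model_spec"), h_b > 0,
            synapses_per_neuron > 0)
  spec$neural_cycles_per_ms_at_spec * (1 / h_b) +
    spec$synaptic_cycles_per_ms_at_spec *
      (synapses_per_neuron / spec$design_synapses_per_neuron)
}

#' Theoretical slowdown factor
#'
#' Ceiling of required cycles per ms over the clock rate, with a floor of 1
#' (real time).  2,000,000 cycles/ms on a 200,000 cycles/ms clock gives a
#' factor of 10.  Measured factors include scheduling overheads and are
#' recorded in run manifests as configured constants, not computed here.
#'
#' @param cycles cycles per ms of biological time.
#' @param clock_cycles_per_ms clock rate, cycles per ms.
#' @return integer slowdown factor >= 1.
#' @export
slowdown_factor <- function(cycles, clock_cycles_per_ms = 200000) {
  stopifnot(clock_cycles_per_ms > 0)
  max(1, ceiling(cycles / clock_cycles_per_ms))
}

#' Clock cycles between outgoing packet sends
#'
#' Spreads \code{n_packets} over \code{spread_fraction} of a
#' \code{cycles_per_step}-cycle time step:
#' \code{floor(cycles_per_step * spread_fraction / n_packets)}.  100
#' packets over a full 20,000-cycle step gives 200 cycles between packets;
#' spreading over half the step gives 100.
#'
#' @param n_packets packets to send in the step (>= 1).
#' @param cycles_per_step clock cycles in one wall-clock step.
#' @param spread_fraction fraction of the step used for sending.
#' @return integer cycle spacing.
#' @examples
#' packet_spacing(100, 20000, 1.0)
#' @export
packet_spacing <- function(n_packets, cycles_per_step,
                           spread_fraction = 1.0) {
  stopifnot(n_packets >= 1, cycles_per_step > 0, spread_fraction > 0,
            spread_fraction <= 1)
  floor(cycles_per_step * spread_fraction / n_packets)
}

#' Cost report for a run configuration
#'
#' @param spec a [cost_model_spec()].
#' @param h_b biological step, ms.
#' @param synapses_per_neuron incoming synapses per neuron.
#' @param n_packets_per_step packets per step for the spacing estimate.
#' @return list with \code{cycles_per_ms}, \code{slowdown_factor},
#'   \code{packet_spacing_cycles}.
#' @export
cost_report <- function(spec = cost_model_spec(), h_b = 0.1,
                        synapses_per_neuron = 10000,
                        n_packets_per_step = 100) {
  cyc <- cycles_per_ms(spec, h_b, synapses_per_neuron)
  sf <- slowdown_factor(cyc, spec$clock_cycles_per_ms)
  step_cycles <- spec$clock_cycles_per_ms * h_b * sf
  list(cycles_per_ms = cyc, slowdown_factor = sf,
       packet_spacing_cycles = packet_spacing(n_packets_per_step,
                                              step_cycles,
                                              spec$spread_fraction))
}
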