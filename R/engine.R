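#' Engine configuration
#'
#' Settings for a grid-based network run.  \code{h_b} is the biological time
#' step; \code{h_w}, the wall-clock step, only enters cost reports (the
#' slowdown factor is \code{h_w / h_b}).
#'
#' @param backend \code{"exact-grid"}, \code{"exponential-grid"} or
#'   \code{"exponential-fixed"}.
#' @param duration biological duration, ms.
#' @param h_b biological step, ms.
#' @param h_w wall-clock step, ms (cost model only; defaults to \code{h_b}).
#' @param transient_discard transient discarded before analysis, ms.
#' @param seed master seed for the run (drive substream and analysis
#'   subsampling derive from it).
#' @param sigma standard-deviation overhead of the ring-buffer weight
#'   scaling (see [ring_buffer_max()]).
#' @param expected_rate assumed in-network firing rate for the weight
#'   scaling, spikes/s (default 30).
#' @return object of class \code{"engine_config"}.
#' @export
engine_config <- function(backend = c("exact-grid", "exponential-grid",
                                      "exponential-fixed"),
                          duration = 10000, h_b = 0.1, h_w = NULL,
                          transient_discard = 1000, seed = 1,
                          sigma = 5, expected_rate = 30) {
  backend <- match.arg(backend)
  if (is.null(h_w)) h_w <- h_b
  stopifnot(h_b > 0, duration > 0, transient_discard >= 0,
            transient_discard < duration)
  if (h_w / h_b < 1)
    warning("slowdown h_w/h_b below 1 is not achievable on the hardware")
  structure(list(backend = backend, duration = duration, h_b = h_b,
                 h_w = h_w, transient_discard = transient_discard,
                 seed = as.integer(seed), sigma = sigma,
                 expected_rate = expected_rate),
            class = "engine_config")
}

#' Split a connection delay into extension multiples and a remainder
#'
#' The hardware ring buffer spans 16 steps (1.6 ms at \code{h_b = 0.1} ms).
#' Longer delays are split into a multiple of the span, handled by a delay
#' extension stage, plus a deliverable remainder:
#' \code{extended = span * (ceil(total/span) - 1)},
#' \code{remaining = total - extended}, so the remainder lies in
#' \code{(0, span]} — an exact multiple takes the maximal remainder, since a
#' zero remainder is undeliverable.  The extension stage supports up to 8
#' span multiples, so the maximum total delay is \code{(8 + 1) * span}
#' (14.4 ms at \code{h_b = 0.1} ms).
#'
#' @param delay_total total delay(s), ms; must lie in
#'   \code{[h_b, (8+1)*16*h_b]}.
#' @param h_b biological step, ms.
#' @return data.frame with \code{delay_total}, \code{delay_extended},
#'   \code{delay_remaining}.
#' @examples
#' split_delay(c(1.0, 3.0, 3.2), h_b = 0.1)
#' @export
split_delay <- function(delay_total, h_b = 0.1) {
  stopifnot(h_b > 0)
  span <- 16 * h_b
  lim <- delay_limits(h_b)
  if (any(delay_total < h_b - 1e-12))
    stop("delay below one step")
  if (any(delay_total > lim$max_total + 1e-9))
    stop("unsupported delay: maximum total is ", lim$max_total, " ms at h_b = ",
         h_b, " ms")
  ext <- ifelse(delay_total <= span, 0,
                span * (ceiling(delay_total / span - 1e-12) - 1))
  data.frame(delay_total = delay_total, delay_extended = ext,
             delay_remaining = delay_total - ext)
}

#' Delay capacity of the ring-buffer plus extension architecture
#'
#' @param h_b biological step, ms.
#' @return list with \code{span} (ring-buffer span, \code{16 * h_b}),
#'   \code{max_extension} (\code{8 * span}) and \code{max_total}
#'   (\code{9 * span}).
#' @examples
#' delay_limits(0.1)  # span 1.6, max_extension 12.8, max_total 14.4
#' @export
delay_limits <- function(h_b = 0.1) {
  span <- 16 * h_b
  list(span = span, max_extension = 8 * span, max_total = 9 * span)
}

#' Pack and unpack the 32-bit synapse word
#'
#' A synapse is stored as a 32-bit record: 8 bits target neuron index (the
#' core identity lives in the routing tables), 4 bits delay slot, 2 bits
#' synapse type, 2 reserved bits, and 16 bits of fixed-point weight.
#' Layout (most significant first): target | delay | type | reserved |
#' weight.  The round trip \code{decode(encode(x))} is lossless for all
#' in-range fields.
#'
#' @param target target index, 0–255.
#' @param delay_slots delay in ring-buffer slots, 0–15.
#' @param type synapse type, 0–3.
#' @param weight_bits raw 16-bit weight, 0–65535.
#' @return \code{encode_synapse_word}: the word as a double (exact up to
#'   2^32); \code{decode_synapse_word}: a list of the four fields.
#' @examples
#' w <- encode_synapse_word(17, 5, 1, 5754)
#' decode_synapse_word(w)
#' @export
encode_synapse_word <- function(target, delay_slots, type, weight_bits) {
  if (any(target < 0 | target > 255)) stop("target out of 8-bit range")
  if (any(delay_slots < 0 | delay_slots > 15)) stop("delay out of 4-bit range")
  if (any(type < 0 | type > 3)) stop("type out of 2-bit range")
  if (any(weight_bits < 0 | weight_bits > 65535))
    stop("weight out of 16-bit range")
  target * 2^24 + delay_slots * 2^20 + type * 2^18 + weight_bits
}

#' @rdname encode_synapse_word
#' @param word encoded word(s).
#' @export
decode_synapse_word <- function(word) {
  stopifnot(word >= 0, word < 2^32, word == floor(word))
  list(target = word %/% 2^24,
       delay_slots = (word %/% 2^20) %% 16,
       type = (word %/% 2^18) %% 4,
       weight_bits = word %% 2^16)
}

#' Saturating ring-buffer accumulator
#'
#' An R-level model of one neuron's 16-slot synaptic input ring buffer in a
#' 16-bit unsigned weight format: additions saturate at the format maximum
#' and saturations are counted, never raised.  The compiled network engine
#' implements the identical semantics.
#'
#' @param n_slots number of slots (16 on the hardware).
#' @param frac_bits fractional bits of the accumulator format.
#' @return object of class \code{"ring_buffer"} with fields \code{slots}
#'   (raw integer accumulators), \code{frac_bits},
#'   \code{overflow_count}.
#' @export
ring_buffer <- function(n_slots = 16, frac_bits = 16) {
  structure(list(slots = numeric(n_slots), frac_bits = frac_bits,
                 overflow_count = 0L),
            class = "ring_buffer")
}

#' @rdname ring_buffer
#' @param buffer a [ring_buffer()].
#' @param slot slot index, 0-based (0..n_slots-1).
#' @param weight weight to add, in nA (quantized to the buffer format).
#' @export
accumulate <- function(buffer, slot, weight) {
  stopifnot(inherits(buffer, "ring_buffer"),
            slot >= 0, slot < length(buffer$slots))
  raw <- floor(weight * 2^buffer$frac_bits)
  if (raw < 0) stop("ring-buffer additions must be non-negative")
  v <- buffer$slots[slot + 1] + raw
  if (v > 65535) {
    v <- 65535
    buffer$overflow_count <- buffer$overflow_count + 1L
  }
  buffer$slots[slot + 1] <- v
  buffer
}

#' @rdname ring_buffer
#' @export
rb_values <- function(buffer) buffer$slots / 2^buffer$frac_bits

#' Compute the fixed-point weight scaling for a network instance
#'
#' For every (target population, synapse type) pair, bounds the expected
#' maximum ring-buffer element value with [ring_buffer_max()] — combining
#' the in-network arrival rate (in-degree times \code{expected_rate}) with
#' the external Poisson arrivals, and the empirical mean/variance of the
#' instantiated weight magnitudes — then picks the binary point with
#' [allocate_bits()].
#'
#' @param net a [instantiate_network()] result.
#' @param expected_rate assumed in-network rate, spikes/s.
#' @param sigma overhead standard deviations.
#' @return data.frame with one row per (population, type): \code{n},
#'   \code{w_mean}, \code{w_var}, \code{M}, \code{integer_bits},
#'   \code{frac_bits}.
#' @export
weight_scaling <- function(net, expected_rate = 30, sigma = 5) {
  pops <- net$populations
  syn <- net$synapses
  h <- net$h
  tgt_pop <- findInterval(syn$target, pops$offset + 1)
  out <- vector("list", 2 * nrow(pops))
  row <- 0
  for (k in seq_len(nrow(pops))) {
    idx0 <- pops$offset[k] + 1
    for (ty in 0:1) {
      sel <- tgt_pop == k & syn$type == ty
      w <- abs(syn$weight[sel])
      n_net <- length(w) / pops$N[k] * expected_rate * h / 1000
      w_mean <- if (length(w)) mean(w) else 0
      w_var <- if (length(w) > 1) stats::var(w) else 0
      if (ty == 0) {
        # fold in the external Poisson arrivals (DC drive contributes none)
        lam <- net$lambda_ext[idx0]
        if (lam > 0) {
          je <- net$w_ext[idx0]
          ntot <- n_net + lam
          m2 <- (n_net * (w_var + w_mean^2) + lam * je^2) / max(ntot, 1e-300)
          w_mean <- (n_net * w_mean + lam * je) / max(ntot, 1e-300)
          w_var <- max(m2 - w_mean^2, 0)
          n_net <- ntot
        }
      }
      row <- row + 1
      if (n_net > 0 && w_mean > 0) {
        rb <- ring_buffer_max(n_net, w_mean, w_var, sigma)
        ab <- allocate_bits(rb$M)
        out[[row]] <- data.frame(population = pops$name[k],
                                 type = c("exc", "inh")[ty + 1],
                                 n = n_net, w_mean = w_mean, w_var = w_var,
                                 M = rb$M,
                                 integer_bits = ab$integer_bits,
                                 frac_bits = ab$frac_bits)
      } else {
        out[[row]] <- data.frame(population = pops$name[k],
                                 type = c("exc", "inh")[ty + 1],
                                 n = n_net, w_mean = w_mean, w_var = w_var,
                                 M = 0, integer_bits = 0L, frac_bits = 16L)
      }
    }
  }
  do.call(rbind, out)
}

#' Run a network simulation
#'
#' Iterates the grid-based engine over \code{duration / h_b} steps with the
#' documented substep order: deliver due ring-buffer slots, per-neuron
#' backend step, collect spikes, route each spike into the target ring
#' buffers at slot (current + delay), advance the external drive.  Runs are
#' bit-reproducible given \code{(network, config)}: the Poisson drive draws
#' from the substream \code{derive_seed(config$seed, "drive")}.
#'
#' For the \code{exponential-fixed} backend, weights are quantized to the
#' per-population 16-bit format chosen by [weight_scaling()], ring-buffer
#' additions saturate (counted in the manifest), and the neuron state is
#' kept in s16.15.
#'
#' @param network a [instantiate_network()] result.
#' @param config an [engine_config()].
#' @return object of class \code{"network_run"}: \code{spikes} (data.frame
#'   \code{neuron}, \code{time_ms}; ids are global and 1-based),
#'   \code{populations}, and \code{manifest} (seeds, overflow count, weight
#'   scaling, conservation totals, config echo).
#' @export
run_network <- function(network, config) {
  stopifnot(inherits(network, "network_instance"),
            inherits(config, "engine_config"))
  if (network$h != config$h_b)
    stop("network instantiated at h = ", network$h,
         " but engine configured with h_b = ", config$h_b)
  h <- config$h_b
  n_steps <- as.integer(round(config$duration / h))
  syn <- network$synapses
  N <- sum(network$populations$N)

  # validate all delays against the extension architecture
  invisible(split_delay(unique(syn$delay), h))
  d_steps <- as.integer(round(syn$delay / h))
  n_slots <- max(16L, max(d_steps, 1L))

  ord <- order(syn$source)
  syn <- syn[ord, , drop = FALSE]
  counts <- tabulate(syn$source, nbins = N)
  syn_ptr <- c(0L, cumsum(counts))

  backend_code <- c("exact-grid" = 0L, "exponential-grid" = 1L,
                    "exponential-fixed" = 2L)[[config$backend]]
  fixed <- backend_code == 2L

  frac_exc <- rep.int(16L, N); frac_inh <- rep.int(16L, N)
  wraw <- integer(nrow(syn)); w_ext_raw <- integer(N)
  ws <- NULL
  if (fixed) {
    ws <- weight_scaling(network, config$expected_rate, config$sigma)
    pops <- network$populations
    tgt_pop <- findInterval(syn$target, pops$offset + 1)
    for (k in seq_len(nrow(pops))) {
      fe <- ws$frac_bits[ws$population == pops$name[k] & ws$type == "exc"]
      fi <- ws$frac_bits[ws$population == pops$name[k] & ws$type == "inh"]
      idx <- pops$offset[k] + seq_len(pops$N[k])
      frac_exc[idx] <- fe; frac_inh[idx] <- fi
    }
    f_syn <- ifelse(syn$type == 0L, frac_exc[syn$target],
                    frac_inh[syn$target])
    wraw <- as.integer(pmin(floor(abs(syn$weight) * 2^f_syn), 65535))
    w_ext_raw <- as.integer(pmin(floor(network$w_ext *
                                         2^frac_exc), 65535))
  }

  d_steps <- as.integer(round(syn$delay / h))
  poisson <- any(network$lambda_ext > 0)
  res <- with_substream(config$seed, "drive",
    cpp_run_network(unclass(network$params), backend_code, h, n_steps,
                    syn_ptr, as.integer(syn$target - 1L), syn$weight,
                    d_steps, as.integer(syn$type), wraw,
                    frac_exc, frac_inh, network$V0, network$I_dc,
                    network$lambda_ext, network$w_ext, w_ext_raw,
                    poisson, n_slots, FALSE))

  manifest <- list(
    backend = config$backend, h_b = h, h_w = config$h_w,
    duration = config$duration, transient_discard = config$transient_discard,
    seed = config$seed, network_seed = network$seed,
    drive = if (poisson) "poisson" else "dc",
    n_neurons = N, n_synapses = nrow(syn), n_slots = n_slots,
    overflow_count = res$overflow_count,
    state_saturations = res$state_saturations,
    conservation = list(total_routed = res$total_routed,
                        total_delivered = res$total_delivered,
                        total_external = res$total_external,
                        saturated_excess = res$saturated_excess,
                        buffer_remaining = res$buffer_remaining),
    weight_scaling = ws)
  structure(list(spikes = data.frame(neuron = res$spike_id,
                                     time_ms = res$spike_time),
                 populations = network$populations,
                 manifest = manifest),
            class = "network_run")
}

#' @export
print.network_run <- function(x, ...) {
  cat(sprintf("network_run: %s, %d neurons, %d spikes in %g ms\n",
              x$manifest$backend, x$manifest$n_neurons, nrow(x$spikes),
              x$manifest$duration))
  invisible(x)
}
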