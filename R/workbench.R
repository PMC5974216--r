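#' Grid-constrained Poisson input
#'
#' Independent Poisson spike counts per integration step with mean
#' \code{rate * h / 1000}; the standard single-neuron benchmark drives with
#' 8,000 or 10,000 spikes/s on a 0.1 ms grid.
#'
#' @param rate input rate, spikes/s (>= 0).
#' @param h step, ms.
#' @param duration duration, ms.
#' @param seed seed (substream \code{"grid-poisson"} of it).
#' @return integer vector of per-step counts, length
#'   \code{round(duration/h)}.
#' @export
generate_grid_poisson <- function(rate, h, duration, seed) {
  stopifnot(rate >= 0, h > 0, duration > 0)
  n <- as.integer(round(duration / h))
  if (rate == 0) return(integer(n))
  with_substream(seed, "grid-poisson", rpois(n, rate * h / 1000))
}

#' Canned deterministic fixtures
#'
#' \describe{
#'   \item{\code{single-spike-response}}{one input spike of 87.8 pA into a
#'     neuron at rest: the protocol behind the four-curve comparison of
#'     integration scheme x numeric type (exact vs. separated, float vs.
#'     fixed).}
#'   \item{\code{two-neuron-chain}}{neuron A driven above threshold by DC,
#'     a strong synapse (delay 0.5 ms) onto neuron B.}
#'   \item{\code{toy-8-pop}}{an 8-population network of 250 neurons each
#'     with the synthetic probability matrix, DC drive; a smoke-scale
#'     microcircuit.}
#' }
#'
#' @param name fixture name.
#' @param h step, ms (where applicable).
#' @return a list describing the fixture; see details per fixture.
#' @export
make_fixture <- function(name = c("single-spike-response",
                                  "two-neuron-chain", "toy-8-pop"),
                         h = 0.1) {
  name <- match.arg(name)
  params <- neuron_params()
  if (name == "single-spike-response") {
    n <- as.integer(round(20 / h))      # 20 ms horizon
    input <- integer(n)
    input[1] <- 1L
    return(list(params = params, input = input, h = h, J = 0.0878,
                duration = 20))
  }
  if (name == "two-neuron-chain") {
    pops <- list(population_spec("A", 1L, params, I_DC = 0.45),
                 population_spec("B", 1L, params, I_DC = 0))
    proj <- list(projection_spec("A", "B", K = 1L, weight_mean = 60,
                                 sign = "excitatory", delay_mean = 0.5))
    return(network_spec(pops, proj))
  }
  # toy-8-pop: synthetic matrix, all populations at 250 neurons
  spec <- synthetic_microcircuit(drive = "dc", params = params)
  pops <- lapply(spec$populations, function(p) { p$N <- 250L; p })
  network_spec(pops, spec$projections)
}

# ---- TSV / JSON input-output ------------------------------------------------

.write_tsv <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  fmt <- paste(rep("%.15g", ncol(df)), collapse = "\t")
  writeLines(do.call(sprintf, c(list(fmt), unname(as.list(df)))), con)
  invisible(path)
}

.read_tsv <- function(path, cols) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "#"))
    stop("missing '#' header line in ", path)
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (!length(body)) {
    out <- as.data.frame(stats::setNames(rep(list(numeric()), length(cols)),
                                         cols))
    return(out)
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != length(cols)))
    stop("parse error at line ", which(nf != length(cols))[1] + 1, " of ",
         path, ": expected ", length(cols), " columns")
  vals <- suppressWarnings(lapply(seq_along(cols), function(j)
    as.numeric(vapply(parts, `[[`, "", j))))
  bad <- which(vapply(vals, anyNA, TRUE))
  if (length(bad))
    stop("parse error in ", path, ": non-numeric field in column ",
         cols[bad[1]])
  stats::setNames(as.data.frame(vals), cols)
}

#' Spike and voltage TSV files
#'
#' Spike records serialize as \code{neuron_id<TAB>time_ms}, voltage traces
#' as \code{time_ms<TAB>value_mV}, 15 significant digits, with a header
#' line starting with \code{#}.  Reading is the exact inverse; malformed
#' lines raise a parse error with the line number.
#'
#' @param spikes data.frame with \code{neuron} and \code{time_ms}.
#' @param trace data.frame with \code{time_ms} and \code{V_mV}.
#' @param path file path.
#' @return readers return data.frames; writers return \code{path}
#'   invisibly.
#' @name spike_tsv
#' @export
write_spikes_tsv <- function(spikes, path) {
  .write_tsv(spikes[, c("neuron", "time_ms")], path, "# neuron_id\ttime_ms")
}

#' @rdname spike_tsv
#' @export
read_spikes_tsv <- function(path) {
  out <- .read_tsv(path, c("neuron", "time_ms"))
  out$neuron <- as.integer(out$neuron)
  out
}

#' @rdname spike_tsv
#' @export
write_voltage_tsv <- function(trace, path) {
  .write_tsv(trace[, c("time_ms", "V_mV")], path, "# time_ms\tvalue_mV")
}

#' @rdname spike_tsv
#' @export
read_voltage_tsv <- function(path) {
  .read_tsv(path, c("time_ms", "V_mV"))
}

#' Write a report or manifest as JSON
#'
#' @param x a list (report, manifest).
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
write_report_json <- function(x, path) {
  x <- rapply(x, unclass, how = "replace")
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_report_json
#' @export
read_report_json <- function(path) jsonlite::read_json(path,
                                                       simplifyVector = TRUE)

# ---- protocol orchestration -------------------------------------------------

#' Run a named benchmarking protocol
#'
#' \describe{
#'   \item{\code{single-neuron}}{for each seed, input rate (8,000 and
#'     10,000 spikes/s) and step (0.1 and 1 ms), simulates the precise
#'     reference plus each discrete backend on the same input realization
#'     and emits the four accuracy measures.  Low-rate runs last 16 s,
#'     high-rate runs 4 s (comparable spike counts).}
#'   \item{\code{microcircuit-dc}, \code{microcircuit-poisson}}{scaled
#'     synthetic microcircuit runs with the requested backend(s), returning
#'     runs and population statistics (1 s transient discarded).}
#'   \item{\code{seed-sensitivity}}{the [seed_sensitivity_protocol()] on
#'     the scaled synthetic microcircuit.}
#' }
#'
#' @param protocol protocol name.
#' @param backends discrete backends to compare.
#' @param seeds master seeds (default 1:10 for single-neuron, per-protocol
#'   defaults otherwise).
#' @param scale_factor microcircuit scale (default 0.1).
#' @param duration override, ms (single-neuron durations are fixed by the
#'   protocol).
#' @param h_values integration steps for the single-neuron protocol, ms.
#' @param rates input rates for the single-neuron protocol, spikes/s.
#' @param drive \code{"dc"} or \code{"poisson"} for microcircuit protocols.
#' @param verbose print progress?
#' @return protocol-specific result object.
#' @export
run_protocol <- function(protocol = c("single-neuron", "microcircuit-dc",
                                      "microcircuit-poisson",
                                      "seed-sensitivity"),
                         backends = c("exact-grid", "exponential-grid",
                                      "exponential-fixed"),
                         seeds = NULL, scale_factor = 0.1, duration = NULL,
                         h_values = c(0.1, 1), rates = c(8000, 10000),
                         drive = NULL, verbose = FALSE) {
  protocol <- match.arg(protocol)
  if (protocol == "single-neuron") {
    if (is.null(seeds)) seeds <- 1:10
    params <- neuron_params()
    rows <- list()
    for (rate in rates) {
      dur <- if (!is.null(duration)) duration else
        if (rate <= 8000) 16000 else 4000
      for (h in h_values) {
        for (seed in seeds) {
          input <- generate_grid_poisson(rate, h, dur, seed)
          precise <- run_single_neuron(params, "precise", input, h)
          for (be in backends) {
            disc <- run_single_neuron(params, be, input, h)
            rep <- compare_single(precise, disc, h)
            rows[[length(rows) + 1]] <- data.frame(
              rate = rate, h = h, seed = seed, backend = be,
              duration = dur,
              n_spikes_precise = length(precise$spikes),
              n_spikes_discrete = length(disc$spikes),
              rate_out = length(disc$spikes) / (dur / 1000),
              pearson_r = rep$pearson_r,
              lead_lag_fraction = rep$lead_lag_fraction,
              rmse_ms = rep$rmse_ms)
          }
          if (verbose) message("single-neuron rate=", rate, " h=", h,
                               " seed=", seed)
        }
      }
    }
    return(do.call(rbind, rows))
  }
  if (protocol == "seed-sensitivity") {
    spec <- scale_network(synthetic_microcircuit(drive = drive %||% "dc"),
                          scale_factor)
    return(seed_sensitivity_protocol(
      spec, test_backends = setdiff(backends, "exact-grid"),
      duration = duration %||% 10000, verbose = verbose))
  }
  # microcircuit protocols
  drv <- if (protocol == "microcircuit-dc") "dc" else "poisson"
  if (is.null(seeds)) seeds <- 1
  spec <- scale_network(synthetic_microcircuit(drive = drv), scale_factor)
  out <- list()
  for (seed in seeds) {
    net <- instantiate_network(spec, h = 0.1, seed = seed)
    for (be in backends) {
      cfg <- engine_config(backend = be, duration = duration %||% 10000,
                           h_b = 0.1, seed = seed)
      run <- run_network(net, cfg)
      out[[paste0(be, ":seed", seed)]] <-
        list(run = run, stats = population_statistics(run))
      if (verbose) message(protocol, " ", be, " seed=", seed, ": ",
                           nrow(run$spikes), " spikes")
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
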