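#' Pair of spike trains for single-neuron accuracy measures
#'
#' Bundles the reference ("precise", off-grid spike times) and discrete
#' (grid-based) trains.  \code{N = min(N_precise, N_discrete)} spikes enter
#' the lead/lag and RMSE measures.
#'
#' @param precise,discrete ascending spike-time vectors, ms.
#' @return object of class \code{"spike_train_pair"}.
#' @export
spike_train_pair <- function(precise, discrete) {
  stopifnot(!is.unsorted(precise), !is.unsorted(discrete),
            all(precise >= 0), all(discrete >= 0))
  structure(list(precise = as.numeric(precise),
                 discrete = as.numeric(discrete),
                 N = min(length(precise), length(discrete))),
            class = "spike_train_pair")
}

#' Cross-correlation histogram of two spike trains
#'
#' Counts all pairwise differences \code{t_discrete - t_precise} within
#' \code{±window}, binned at half the integration step.  The bin layout is
#' symmetric around zero lag (the central bin is centred on 0).
#'
#' @param pair a [spike_train_pair()].
#' @param h integration step, ms (bin width is \code{h/2}).
#' @param window half-width of the lag window, ms; must be a multiple of
#'   \code{h/2} (default 5 ms).
#' @return list of class \code{"cch"} with \code{breaks} (bin edges, ms),
#'   \code{centers}, \code{counts}.
#' @export
cross_correlation_histogram <- function(pair, h, window = 5) {
  stopifnot(inherits(pair, "spike_train_pair"), h > 0, window > 0)
  bw <- h / 2
  k <- window / bw
  if (abs(k - round(k)) > 1e-9)
    stop("window must be a multiple of h/2")
  k <- round(k)
  breaks <- (seq(-k, k + 1) - 0.5) * bw
  centers <- seq(-k, k) * bw
  counts <- integer(length(centers))
  if (length(pair$precise) && length(pair$discrete)) {
    # block over the discrete train to bound the outer-product size
    step <- max(1L, floor(2e6 / max(length(pair$precise), 1L)))
    for (i0 in seq(1L, length(pair$discrete), by = step)) {
      i1 <- min(i0 + step - 1L, length(pair$discrete))
      d <- outer(pair$discrete[i0:i1], pair$precise, "-")
      d <- d[d >= breaks[1] & d < breaks[length(breaks)]]
      if (length(d)) {
        idx <- floor((d - breaks[1]) / bw) + 1
        counts <- counts + tabulate(idx, nbins = length(centers))
      }
    }
  }
  structure(list(breaks = breaks, centers = centers, counts = counts,
                 window = window, binwidth = bw),
            class = "cch")
}

#' Pearson correlation between two membrane-potential traces
#'
#' Traces must be sampled on a common grid.  A zero-variance trace makes
#' the coefficient undefined; \code{NA} is returned.
#'
#' @param trace_a,trace_b numeric vectors of equal length (mV), or
#'   data.frames with a \code{V_mV} column as returned by
#'   [run_single_neuron()].
#' @return Pearson r, or \code{NA} if undefined.
#' @export
membrane_correlation <- function(trace_a, trace_b) {
  if (is.data.frame(trace_a)) trace_a <- trace_a$V_mV
  if (is.data.frame(trace_b)) trace_b <- trace_b$V_mV
  stopifnot(length(trace_a) == length(trace_b))
  if (sd(trace_a) == 0 || sd(trace_b) == 0) return(NA_real_)
  cor(trace_a, trace_b)
}

#' Accumulated fractional lead or lag in spike times
#'
#' \code{(t_discrete(N) - t_precise(N)) / t_discrete(N)} over the first
#' \code{N = min} spikes.  Negative values mean the discrete simulation
#' leads (fires early); positive values mean it lags.
#'
#' @param pair a [spike_train_pair()].
#' @return list with \code{fraction} and \code{N}; \code{fraction} is
#'   \code{NA} when either train is empty.
#' @export
accumulated_lead_lag <- function(pair) {
  stopifnot(inherits(pair, "spike_train_pair"))
  N <- pair$N
  if (N < 1) return(list(fraction = NA_real_, N = 0L))
  td <- pair$discrete[N]; tp <- pair$precise[N]
  if (td <= 0) stop("t_discrete(N) must be positive")
  list(fraction = (td - tp) / td, N = N)
}

#' RMSE of spike times after warping out the accumulated lead or lag
#'
#' The discrete spike times are scaled by
#' \code{t_precise(N) / t_discrete(N)} so that the last considered spikes
#' coincide, then
#' \deqn{RMSE = \sqrt{\frac{1}{N}\sum_{i=1}^{N} (t^*_{discrete}(i) - t_{precise}(i))^2}.}
#' A uniform rate difference (pure dilation) therefore yields zero.
#'
#' @param pair a [spike_train_pair()].
#' @return list with \code{rmse} (ms), \code{warp_factor}, \code{N}.
#' @export
warped_rmse <- function(pair) {
  stopifnot(inherits(pair, "spike_train_pair"))
  N <- pair$N
  if (N < 1) return(list(rmse = NA_real_, warp_factor = NA_real_, N = 0L))
  warp <- pair$precise[N] / pair$discrete[N]
  ts <- pair$discrete[seq_len(N)] * warp
  list(rmse = sqrt(mean((ts - pair$precise[seq_len(N)])^2)),
       warp_factor = warp, N = N)
}

#' All four single-neuron accuracy measures
#'
#' Compares a discrete-backend run against the precise reference: the
#' cross-correlation histogram of spike times, the Pearson correlation of
#' the membrane traces, the accumulated fractional lead/lag, and the
#' warped RMSE.
#'
#' @param precise,discrete results of [run_single_neuron()] (lists with
#'   \code{spikes} and \code{trace}).
#' @param h integration step, ms.
#' @param window CCH half-window, ms.
#' @return list of class \code{"single_neuron_report"} with \code{cch},
#'   \code{pearson_r}, \code{lead_lag_fraction}, \code{rmse_ms},
#'   \code{warp_factor}, \code{N}.
#' @export
compare_single <- function(precise, discrete, h, window = 5) {
  pair <- spike_train_pair(precise$spikes, discrete$spikes)
  cch <- cross_correlation_histogram(pair, h, window)
  r <- if (!is.null(precise$trace) && !is.null(discrete$trace))
    membrane_correlation(precise$trace, discrete$trace) else NA_real_
  ll <- accumulated_lead_lag(pair)
  rm <- warped_rmse(pair)
  structure(list(cch = cch, pearson_r = r,
                 lead_lag_fraction = ll$fraction,
                 rmse_ms = rm$rmse, warp_factor = rm$warp_factor,
                 N = pair$N),
            class = "single_neuron_report")
}
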