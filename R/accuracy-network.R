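#' Per-neuron firing rates over an analysis window
#'
#' Spike count in \code{[t_start, t_stop)} divided by the window length,
#' per neuron, including silent neurons as zero.  The default window
#' discards a 1 s transient from a 10 s run.
#'
#' @param spikes data.frame with \code{neuron} (1-based ids) and
#'   \code{time_ms}.
#' @param n_neurons number of neurons (ids run 1..n_neurons).
#' @param t_start,t_stop analysis window, ms.
#' @return numeric vector of rates, spikes/s, length \code{n_neurons}.
#' @export
single_neuron_rates <- function(spikes, n_neurons, t_start = 1000,
                                t_stop = 10000) {
  stopifnot(t_stop > t_start)
  sel <- spikes$time_ms >= t_start & spikes$time_ms < t_stop
  counts <- tabulate(spikes$neuron[sel], nbins = n_neurons)
  counts / ((t_stop - t_start) / 1000)
}

#' Coefficients of variation of interspike intervals
#'
#' \code{sd(ISI) / mean(ISI)} per neuron over the analysis window.  A
#' neuron is included only with at least 3 spikes (2 intervals); a long
#' Poisson train approaches CV = 1, a perfectly periodic one gives 0.
#'
#' @inheritParams single_neuron_rates
#' @return numeric vector of CV values (one per included neuron).
#' @export
cv_isi <- function(spikes, t_start = 1000, t_stop = 10000) {
  sel <- spikes$time_ms >= t_start & spikes$time_ms < t_stop
  sp <- spikes[sel, , drop = FALSE]
  sp <- sp[order(sp$neuron, sp$time_ms), , drop = FALSE]
  byn <- split(sp$time_ms, sp$neuron)
  out <- vapply(byn, function(t) {
    if (length(t) < 3) return(NA_real_)
    isi <- diff(t)
    sd(isi) / mean(isi)
  }, numeric(1))
  unname(out[!is.na(out)])
}

#' Pairwise correlations of binned spike trains
#'
#' Pearson correlation coefficients between spike trains binned at
#' \code{binwidth} (2 ms by default, the refractory time) from all disjoint
#' neuron pairs within a uniformly subsampled subpopulation of
#' \code{sample_size} neurons (19,900 pairs at the default 200).
#' Zero-variance (silent or constant) trains yield undefined coefficients;
#' these are excluded and counted.
#'
#' @inheritParams single_neuron_rates
#' @param neuron_ids the ids forming the population to sample from.
#' @param binwidth bin width, ms.
#' @param sample_size neurons to subsample (uses all, with a warning, if
#'   the population is smaller).
#' @param seed seed for the subsample draw.
#' @return numeric vector of coefficients with attribute
#'   \code{"n_excluded"}.
#' @export
pairwise_correlations <- function(spikes, neuron_ids, binwidth = 2,
                                  sample_size = 200, seed = 1,
                                  t_start = 1000, t_stop = 10000) {
  stopifnot(t_stop > t_start, binwidth > 0)
  if (length(neuron_ids) < sample_size) {
    warning("population smaller than sample_size; using all ",
            length(neuron_ids), " neurons")
    ids <- neuron_ids
  } else {
    ids <- with_substream(seed, "correlation-subsample",
                          sort(sample(neuron_ids, sample_size)))
  }
  n_bins <- floor((t_stop - t_start) / binwidth)
  sel <- spikes$neuron %in% ids & spikes$time_ms >= t_start &
    spikes$time_ms < t_start + n_bins * binwidth
  sp <- spikes[sel, , drop = FALSE]
  row <- match(sp$neuron, ids)
  col <- floor((sp$time_ms - t_start) / binwidth) + 1
  M <- matrix(tabulate((col - 1L) * length(ids) + row,
                       nbins = length(ids) * n_bins),
              nrow = length(ids))
  v <- apply(M, 1, stats::var)
  ok <- v > 0
  C <- suppressWarnings(cor(t(M[ok, , drop = FALSE])))
  out <- C[upper.tri(C)]
  n_pairs <- length(ids) * (length(ids) - 1) / 2
  attr(out, "n_excluded") <- n_pairs - length(out)
  out
}

#' Freedman-Diaconis histogram specification
#'
#' Bin size \code{2 * IQR(x) * n^(-1/3)} with the interquartile range from
#' linear-interpolation quartiles; edges span the data range.  A zero IQR
#' (degenerate data) falls back to Scott-like sizing from the standard
#' deviation, or to a single unit bin if that is also zero.
#'
#' @param x numeric samples (n >= 2).
#' @return list of class \code{"histogram_spec"} with \code{binsize},
#'   \code{breaks}, \code{centers}, \code{IQR}, \code{n}.
#' @examples
#' fd_binsize(1:8)$binsize  # 3.5
#' @export
fd_binsize <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2) stop("need at least 2 observations")
  iqr <- unname(diff(quantile(x, c(0.25, 0.75), type = 7)))
  binsize <- 2 * iqr * n^(-1 / 3)
  if (binsize <= 0) {
    s <- sd(x)
    binsize <- if (s > 0) 3.5 * s * n^(-1 / 3) else 1
  }
  lo <- min(x); hi <- max(x)
  k <- max(1, ceiling((hi - lo) / binsize - 1e-9))
  breaks <- lo + seq(0, k) * binsize
  structure(list(binsize = binsize, breaks = breaks,
                 centers = (breaks[-1] + breaks[-length(breaks)]) / 2,
                 IQR = iqr, n = n),
            class = "histogram_spec")
}

#' Gaussian-kernel smoothed density on a histogram grid
#'
#' Kernel density estimate with an absolute kernel standard deviation
#' (\code{bandwidth}, in data units), evaluated at the grid centers and
#' renormalized to sum to 1.  The standard bandwidths are 0.3 /s for
#' rates, 0.04 for CV ISI and 0.002 for correlation coefficients.
#' \code{scaled = TRUE} instead interprets \code{bandwidth} as a factor
#' multiplying the sample standard deviation (the convention of
#' covariance-scaled KDE routines).
#'
#' @param samples numeric samples (non-empty).
#' @param bandwidth kernel standard deviation (data units), > 0.
#' @param grid a [fd_binsize()] spec, or a numeric vector of evaluation
#'   points.
#' @param scaled interpret bandwidth as a covariance scale factor?
#' @return list of class \code{"smoothed_density"} with \code{grid},
#'   \code{values} (summing to 1), \code{bandwidth}.
#' @export
smooth_density <- function(samples, bandwidth, grid, scaled = FALSE) {
  samples <- samples[is.finite(samples)]
  if (!length(samples)) stop("no samples to smooth")
  stopifnot(bandwidth > 0)
  if (inherits(grid, "histogram_spec")) grid <- grid$centers
  bw <- if (scaled) bandwidth * sd(samples) else bandwidth
  vals <- vapply(grid, function(g) sum(dnorm(g - samples, sd = bw)),
                 numeric(1))
  total <- sum(vals)
  if (total <= 0) stop("density vanishes on the whole grid")
  structure(list(grid = grid, values = vals / total, bandwidth = bw),
            class = "smoothed_density")
}

#' Kullback-Leibler divergence between smoothed densities
#'
#' \code{D_KL(P||Q) = sum p * log(p/q)} over the common grid, ignoring bins
#' where either normalized density is below \code{floor} (default 1e-15) to
#' avoid excessive contributions from vanishing bins.  No renormalization
#' is applied after the exclusion; the renormalized value is also reported
#' (\code{kl_renormalized}), and is guaranteed non-negative.
#'
#' @param P,Q [smooth_density()] results on the same grid (P is the
#'   reference).
#' @param floor exclusion threshold for either density.
#' @return list of class \code{"kl_result"} with \code{kl},
#'   \code{kl_renormalized}, \code{n_excluded}.
#' @examples
#' g <- 1:2
#' P <- structure(list(grid = g, values = c(0.75, 0.25)),
#'                class = "smoothed_density")
#' Q <- structure(list(grid = g, values = c(0.5, 0.5)),
#'                class = "smoothed_density")
#' kl_divergence(P, Q)$kl  # 0.1308
#' @export
kl_divergence <- function(P, Q, floor = 1e-15) {
  if (length(P$grid) != length(Q$grid) ||
      any(abs(P$grid - Q$grid) > 1e-12))
    stop("P and Q must share the evaluation grid")
  p <- P$values; q <- Q$values
  keep <- p >= floor & q >= floor
  kl <- sum(p[keep] * log(p[keep] / q[keep]))
  pr <- p[keep] / sum(p[keep]); qr <- q[keep] / sum(q[keep])
  structure(list(kl = kl, kl_renormalized = sum(pr * log(pr / qr)),
                 n_excluded = sum(!keep)),
            class = "kl_result")
}

#' Distributions of the three population statistics of a run
#'
#' Per population: single-neuron firing rates (silent neurons included as
#' zero), CV ISI (neurons with >= 3 spikes), and pairwise correlations of
#' 2 ms-binned spike trains from a 200-neuron subsample.
#'
#' @param run a [run_network()] result.
#' @param t_start,t_stop analysis window, ms; defaults honour the run's
#'   transient-discard setting.
#' @param sample_size,binwidth see [pairwise_correlations()].
#' @return named list (one entry per population) of lists with
#'   \code{rates}, \code{cv_isi}, \code{correlations}.
#' @export
population_statistics <- function(run, t_start = NULL, t_stop = NULL,
                                  sample_size = 200, binwidth = 2) {
  stopifnot(inherits(run, "network_run"))
  if (is.null(t_start)) t_start <- run$manifest$transient_discard
  if (is.null(t_stop)) t_stop <- run$manifest$duration
  pops <- run$populations
  out <- vector("list", nrow(pops))
  names(out) <- pops$name
  for (k in seq_len(nrow(pops))) {
    ids <- pops$offset[k] + seq_len(pops$N[k])
    sel <- run$spikes$neuron >= ids[1] & run$spikes$neuron <= ids[length(ids)]
    sp <- run$spikes[sel, , drop = FALSE]
    sp$neuron <- sp$neuron - pops$offset[k]
    rates <- single_neuron_rates(sp, pops$N[k], t_start, t_stop)
    cvs <- cv_isi(sp, t_start, t_stop)
    cors <- pairwise_correlations(sp, seq_len(pops$N[k]), binwidth,
                                  sample_size,
                                  seed = run$manifest$seed,
                                  t_start = t_start, t_stop = t_stop)
    out[[k]] <- list(rates = rates, cv_isi = cvs, correlations = cors)
  }
  out
}

.stat_bandwidths <- c(rates = 0.3, cv_isi = 0.04, correlations = 0.002)

#' Smoothed-histogram KL comparison of two runs
#'
#' For each population and statistic, histogram bins are set by the
#' Freedman-Diaconis rule on the REFERENCE run's samples, both sample sets
#' are smoothed by Gaussian KDE with the statistic's standard bandwidth,
#' and \code{D_KL(P||Q)} is computed with P the reference.
#'
#' @param ref_stats,test_stats [population_statistics()] results.
#' @return data.frame with columns \code{population}, \code{statistic},
#'   \code{kl}, \code{kl_renormalized}, \code{n_excluded}.
#' @export
compare_network <- function(ref_stats, test_stats) {
  stopifnot(identical(names(ref_stats), names(test_stats)))
  rows <- list()
  for (pop in names(ref_stats)) {
    for (st in names(.stat_bandwidths)) {
      p_samp <- as.numeric(ref_stats[[pop]][[st]])
      q_samp <- as.numeric(test_stats[[pop]][[st]])
      if (length(p_samp) < 2 || length(q_samp) < 1) {
        rows[[length(rows) + 1]] <- data.frame(
          population = pop, statistic = st, kl = NA_real_,
          kl_renormalized = NA_real_, n_excluded = NA_integer_)
        next
      }
      spec <- fd_binsize(p_samp)
      P <- smooth_density(p_samp, .stat_bandwidths[[st]], spec)
      Q <- smooth_density(q_samp, .stat_bandwidths[[st]], spec)
      r <- kl_divergence(P, Q)
      rows[[length(rows) + 1]] <- data.frame(
        population = pop, statistic = st, kl = r$kl,
        kl_renormalized = r$kl_renormalized, n_excluded = r$n_excluded)
    }
  }
  do.call(rbind, rows)
}
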