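#' Population specification
#'
#' One neural population of a multi-population network: a name (for the
#' layered cortical microcircuit conventionally \code{"2/3E"} ...
#' \code{"6I"}), a size, shared neuron parameters, and exactly one external
#' drive mode: an independent Poisson drive \code{(nu_ext, J_ext)} or a
#' constant current \code{I_DC}.
#'
#' @param name population label.
#' @param N neuron count (> 0).
#' @param params a [neuron_params()] object.
#' @param nu_ext external Poisson rate per neuron, spikes/s (with
#'   \code{J_ext}), or NULL.
#' @param J_ext external synaptic weight, nA.
#' @param I_DC constant drive current, nA, or NULL.
#' @return object of class \code{"population_spec"}.
#' @export
population_spec <- function(name, N, params = neuron_params(),
                            nu_ext = NULL, J_ext = 0.0878, I_DC = NULL) {
  stopifnot(is.character(name), length(name) == 1L, N > 0)
  if (is.null(nu_ext) == is.null(I_DC))
    stop("exactly one of nu_ext (Poisson) or I_DC (DC) must be given")
  structure(list(name = name, N = as.integer(N), params = params,
                 nu_ext = nu_ext, J_ext = J_ext, I_DC = I_DC),
            class = "population_spec")
}

#' Projection specification
#'
#' A projection between two populations: with-replacement random
#' connectivity given either as a pair-connection probability \code{p} or a
#' synapse count \code{K}; normally distributed weight magnitudes (sign
#' applied via \code{sign}) and normally distributed delays clipped below at
#' the simulation step.
#'
#' @param pre,post population labels.
#' @param p pair-connection probability in \code{[0, 1)}; or
#' @param K explicit synapse count (exactly one of \code{p}, \code{K}).
#' @param weight_mean,weight_sd weight magnitude distribution, nA (>= 0).
#' @param sign \code{"excitatory"} or \code{"inhibitory"}.
#' @param delay_mean,delay_sd delay distribution, ms.
#' @return object of class \code{"projection_spec"}.
#' @export
projection_spec <- function(pre, post, p = NULL, K = NULL,
                            weight_mean, weight_sd = 0,
                            sign = c("excitatory", "inhibitory"),
                            delay_mean, delay_sd = 0) {
  sign <- match.arg(sign)
  if (is.null(p) == is.null(K))
    stop("exactly one of p or K must be given")
  if (!is.null(p)) stopifnot(p >= 0, p < 1)
  stopifnot(weight_mean >= 0, weight_sd >= 0, delay_mean > 0, delay_sd >= 0)
  structure(list(pre = pre, post = post, p = p, K = K,
                 weight_mean = weight_mean, weight_sd = weight_sd,
                 sign = sign, delay_mean = delay_mean, delay_sd = delay_sd),
            class = "projection_spec")
}

#' Network specification
#'
#' @param populations list of [population_spec()] objects.
#' @param projections list of [projection_spec()] objects.
#' @return object of class \code{"network_spec"}.
#' @export
network_spec <- function(populations, projections) {
  nm <- vapply(populations, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicate population names")
  for (pr in projections) {
    if (!pr$pre %in% nm || !pr$post %in% nm)
      stop("projection references unknown population")
  }
  structure(list(populations = populations, projections = projections),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("network_spec: %d populations, %d projections, %d neurons\n",
              length(x$populations), length(x$projections),
              sum(vapply(x$populations, `[[`, 0L, "N"))))
  invisible(x)
}

#' Synapse count for with-replacement connectivity
#'
#' Number of synapses \code{K} to draw (source and target with replacement,
#' multapses allowed) so that the induced probability that a given ordered
#' pair is connected at least once equals \code{p}:
#' \deqn{K = round\left(\frac{\ln(1-p)}{\ln(1 - 1/(N_{pre} N_{post}))}\right)}
#' The \code{"binomial"} alternative uses \code{K = round(p N_pre N_post)}.
#'
#' @param p pair-connection probability in \code{[0, 1)}.
#' @param N_pre,N_post population sizes.
#' @param method \code{"log"} (default, exact inverse) or \code{"binomial"}.
#' @return integer synapse count.
#' @examples
#' total_synapse_count(0.1, 100, 100)
#' @export
total_synapse_count <- function(p, N_pre, N_post,
                                method = c("log", "binomial")) {
  method <- match.arg(method)
  stopifnot(p >= 0, N_pre > 0, N_post > 0)
  if (p >= 1) stop("p = 1 has no finite with-replacement synapse count")
  if (p == 0) return(0L)
  K <- if (method == "log") {
    log1p(-p) / log1p(-1 / (as.numeric(N_pre) * N_post))
  } else {
    p * as.numeric(N_pre) * N_post
  }
  as.integer(round(K))
}

#' Instantiate the synapses of one projection
#'
#' Draws \code{K} independent (source, target) pairs uniformly with
#' replacement, weight magnitudes \code{Normal(weight_mean, weight_sd)}
#' (draws crossing zero are clipped to zero magnitude), and delays
#' \code{Normal(delay_mean, delay_sd)} clipped below at the step \code{h}
#' and rounded to the grid.  Uses the current RNG stream; callers seed a
#' dedicated substream per projection (see [derive_seed()]).
#'
#' @param proj a [projection_spec()].
#' @param N_pre,N_post population sizes.
#' @param h simulation step, ms.
#' @param method passed to [total_synapse_count()] when \code{proj$p} is
#'   given.
#' @return data.frame with columns \code{source}, \code{target} (1-based,
#'   population-local), \code{weight} (signed, nA), \code{delay} (ms).
#' @export
instantiate_connections <- function(proj, N_pre, N_post, h = 0.1,
                                    method = "log") {
  K <- if (!is.null(proj$K)) as.integer(proj$K) else
    total_synapse_count(proj$p, N_pre, N_post, method)
  if (K == 0L)
    return(data.frame(source = integer(), target = integer(),
                      weight = numeric(), delay = numeric()))
  source <- sample.int(N_pre, K, replace = TRUE)
  target <- sample.int(N_post, K, replace = TRUE)
  w <- rnorm(K, proj$weight_mean, proj$weight_sd)
  w <- pmax(w, 0)                         # clip sign-crossing draws
  if (proj$sign == "inhibitory") w <- -w
  d <- rnorm(K, proj$delay_mean, proj$delay_sd)
  d <- pmax(round(d / h) * h, h)          # grid-rounded, clipped below at h
  data.frame(source = source, target = target, weight = w, delay = d)
}

#' Mean current equivalent of a Poisson drive
#'
#' The mean of the shot-noise current produced by a Poisson spike train of
#' rate \code{nu_ext} through synapses of weight \code{J_ext} and decay time
#' \code{tau_s}: \code{I_DC = nu_ext * J_ext * tau_s} (rate in spikes/s,
#' tau_s in ms, J in nA gives I in nA after the ms/s factor).
#'
#' @param nu_ext Poisson rate, spikes/s (>= 0).
#' @param J_ext synaptic weight, nA.
#' @param tau_s synaptic time constant, ms.
#' @return DC current, nA.
#' @examples
#' dc_equivalent(8000, 0.0878, 0.5)  # 0.3512 nA
#' @export
dc_equivalent <- function(nu_ext, J_ext, tau_s) {
  stopifnot(nu_ext >= 0)
  nu_ext / 1000 * J_ext * tau_s
}

#' Scale a network specification
#'
#' Multiplies every population size by \code{factor} (rounding), preserving
#' connection probabilities and external drive.  The expected synapse count
#' then scales approximately with \code{factor^2}.  Dynamics are not
#' guaranteed invariant under scaling; the run manifest records the factor.
#'
#' @param spec a [network_spec()].
#' @param factor scale factor in \code{(0, 1]}.
#' @return scaled [network_spec()].
#' @export
scale_network <- function(spec, factor) {
  stopifnot(inherits(spec, "network_spec"), factor > 0, factor <= 1)
  pops <- lapply(spec$populations, function(p) {
    p$N <- as.integer(round(factor * p$N))
    if (p$N == 0L) stop("scaling factor ", factor,
                        " reduces population ", p$name, " to zero neurons")
    p
  })
  out <- network_spec(pops, spec$projections)
  attr(out, "scale_factor") <- factor
  out
}

#' Instantiate a network from its specification
#'
#' Draws all synapses, initial membrane potentials (uniform on
#' \code{[V_r, theta)}) and resolves the external drive, each from a named
#' substream of \code{seed} (labels \code{"projection:<pre>-><post>"},
#' \code{"population-init:<name>"}), so the instance is bit-reproducible
#' from \code{(spec, seed)} and individual projections can be regenerated.
#'
#' @param spec a [network_spec()].
#' @param h simulation step, ms.
#' @param seed master seed.
#' @param method connectivity count rule, see [total_synapse_count()].
#' @return object of class \code{"network_instance"}: populations table
#'   (name, N, offset), synapse data.frame with global 1-based ids, initial
#'   potentials, drive vectors, and the master seed.
#' @export
instantiate_network <- function(spec, h = 0.1, seed = 1, method = "log") {
  stopifnot(inherits(spec, "network_spec"))
  nm <- vapply(spec$populations, `[[`, "", "name")
  N <- vapply(spec$populations, `[[`, 0L, "N")
  offset <- c(0L, cumsum(N))[seq_along(N)]
  pops <- data.frame(name = nm, N = N, offset = offset,
                     stringsAsFactors = FALSE)
  params <- spec$populations[[1]]$params

  syn <- vector("list", length(spec$projections))
  for (k in seq_along(spec$projections)) {
    pr <- spec$projections[[k]]
    i_pre <- match(pr$pre, nm); i_post <- match(pr$post, nm)
    s <- with_substream(seed, paste0("projection:", pr$pre, "->", pr$post),
                        instantiate_connections(pr, N[i_pre], N[i_post],
                                                h, method))
    if (nrow(s)) {
      s$source <- s$source + offset[i_pre]
      s$target <- s$target + offset[i_post]
      s$type <- if (pr$sign == "inhibitory") 1L else 0L
    } else {
      s$type <- integer()
    }
    syn[[k]] <- s
  }
  syn <- do.call(rbind, syn)

  V0 <- numeric(sum(N))
  I_dc <- numeric(sum(N))
  lambda <- numeric(sum(N))
  w_ext <- numeric(sum(N))
  for (k in seq_along(spec$populations)) {
    p <- spec$populations[[k]]
    idx <- offset[k] + seq_len(N[k])
    V0[idx] <- with_substream(seed, paste0("population-init:", p$name),
                              runif(N[k], p$params$V_r, p$params$theta))
    if (!is.null(p$I_DC)) {
      I_dc[idx] <- p$I_DC
    } else {
      lambda[idx] <- p$nu_ext * h / 1000   # expected spikes per step
      w_ext[idx] <- p$J_ext
    }
  }
  structure(list(populations = pops, synapses = syn, params = params,
                 V0 = V0, I_dc = I_dc, lambda_ext = lambda, w_ext = w_ext,
                 h = h, seed = seed, spec = spec),
            class = "network_instance")
}

#' @export
print.network_instance <- function(x, ...) {
  cat(sprintf("network_instance: %d neurons, %d synapses, h = %g ms, seed %d\n",
              sum(x$populations$N), nrow(x$synapses), x$h, x$seed))
  invisible(x)
}
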