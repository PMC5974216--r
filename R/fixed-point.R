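#' Describe a fixed-point number format
#'
#' The hardware emulation uses two families of formats: the signed s16.15
#' state format (32 bits, 15 fractional) for membrane potentials and
#' currents, and unsigned 16-bit weight formats \code{(16, f)} whose binary
#' point is chosen dynamically so that the largest expected ring-buffer sum
#' is representable (see [ring_buffer_max()] and [allocate_bits()]).
#'
#' @param total_bits total word width (<= 32).
#' @param frac_bits fractional bits (0 <= frac_bits <= total_bits).
#' @param signed logical.
#' @return an object of class \code{"fixed_point_format"}.
#' @examples
#' s16_15 <- fixed_point_format(32, 15, signed = TRUE)
#' @export
fixed_point_format <- function(total_bits, frac_bits, signed = FALSE) {
  stopifnot(frac_bits >= 0, frac_bits <= total_bits, total_bits <= 32)
  structure(list(total_bits = as.integer(total_bits),
                 frac_bits = as.integer(frac_bits),
                 signed = isTRUE(signed)),
            class = "fixed_point_format")
}

#' Truncating quantization to an unsigned fixed-point grid
#'
#' Returns \code{floor(x * 2^f) / 2^f}, i.e. truncation toward minus
#' infinity, which for the unsigned weight formats equals truncation toward
#' zero.  For example a 0.0878 nA weight becomes 0.0869140625 with 10
#' fractional bits, 0.0859375 with 9, and 0.087799072265625 when the whole
#' 16 bits are fractional.
#'
#' @param x non-negative value(s), nA.
#' @param frac_bits number of fractional bits \code{f}.
#' @param total_bits word width for the overflow check (default 16).
#' @return the representable value(s), \code{floor(x * 2^f) / 2^f}.
#' @examples
#' quantize_truncate(0.0878, 10)  # 0.0869140625
#' @export
quantize_truncate <- function(x, frac_bits, total_bits = 16) {
  stopifnot(is.numeric(x), frac_bits >= 0, frac_bits <= total_bits)
  if (any(x < 0)) stop("unsigned format: x must be >= 0")
  raw <- floor(x * 2^frac_bits)
  if (any(raw > 2^total_bits - 1))
    stop("integer part overflows a ", total_bits, "-bit word")
  raw / 2^frac_bits
}

#' Round to the nearest IEEE-style binary16/32/64 value
#'
#' Round-to-nearest (ties to even) into the requested binary floating-point
#' format.  \code{precision = 64} is the native double and returns \code{x}
#' unchanged; \code{precision = 32} uses the machine's float conversion;
#' \code{precision = 16} implements binary16 (5 exponent bits, 10 stored
#' significand bits, subnormals, overflow to \code{Inf}).
#'
#' @param x finite numeric vector.
#' @param precision 16, 32 or 64.
#' @return nearest representable value(s) as doubles.
#' @examples
#' float_round(0.0878, 32)  # 0.087800003588199615478515625
#' @export
float_round <- function(x, precision = c(64, 32, 16)) {
  precision <- match.arg(as.character(precision[1]), c("64", "32", "16"))
  stopifnot(is.numeric(x), all(is.finite(x)))
  switch(precision,
    "64" = x,
    "32" = readBin(writeBin(as.numeric(x), raw(), size = 4L),
                   "double", n = length(x), size = 4L),
    "16" = vapply(x, .round_binary16, numeric(1)))
}

.round_binary16 <- function(x) {
  if (x == 0) return(0)
  s <- sign(x)
  a <- abs(x)
  if (a >= 65520) return(s * Inf)          # above max finite + half ulp
  e <- floor(log2(a))
  if (a / 2^e >= 2) e <- e + 1             # guard log2 rounding
  if (a / 2^e < 1) e <- e - 1
  if (e < -14) {
    # subnormal range: fixed quantum 2^-24
    return(s * round(a / 2^-24) * 2^-24)   # round() ties to even
  }
  q <- round(a / 2^e * 1024) / 1024
  s * q * 2^e
}

#' Closed-form bound on the maximum ring-buffer element value
#'
#' Models the per-step sum of synaptic weights landing in any one delay
#' ring-buffer element as a compound Poisson sum: \code{n} spikes per step
#' on average, weights with mean \code{w_mean} and variance \code{w_var}.
#' The bound is
#' \deqn{M = n w_{mean} + \sigma \sqrt{v_r + v_w}}
#' with \code{v_r = n * w_mean^2},
#' \code{U = round(n + 3 sqrt(n))} and
#' \deqn{v_w = e^{-n} n w_{var} \frac{-n^U + e^n \Gamma_{inc}(1+U, n)}{\Gamma(1+U)}}
#' where \eqn{\Gamma_{inc}} is the non-regularized upper incomplete gamma
#' function.  Numerically this is evaluated in log space as
#' \code{v_w = n * w_var * (Q(1+U, n) - exp(U log n - n - lgamma(1+U)))}
#' with \code{Q} the regularized upper gamma, so that \code{v_w -> n w_var}
#' (the compound-Poisson variance) as \code{U} grows.  \code{M} is the value
#' that a \code{sigma}-standard-deviation overhead must accommodate; the
#' weight format is then chosen with [allocate_bits()].
#'
#' @param n expected incoming spikes per step (> 0).
#' @param w_mean mean incoming weight magnitude, nA.
#' @param w_var variance of incoming weight magnitudes, nA^2.
#' @param sigma number of standard deviations of overhead (default 5).
#' @param U override for the truncation index (used in regression tests).
#' @return list with \code{v_r}, \code{U}, \code{v_w}, \code{M}.
#' @examples
#' ring_buffer_max(3, 0.0878, 0.00878^2)
#' @export
ring_buffer_max <- function(n, w_mean, w_var, sigma = 5, U = NULL) {
  if (!is.finite(n) || n <= 0) stop("n must be positive")
  stopifnot(w_mean >= 0, w_var >= 0, sigma > 0)
  if (is.null(U)) U <- round(n + 3 * sqrt(n))
  v_r <- n * w_mean^2
  # Q(1+U, n): regularized upper incomplete gamma
  logQ <- pgamma(n, shape = 1 + U, lower.tail = FALSE, log.p = TRUE)
  v_w <- n * w_var * (exp(logQ) - exp(U * log(n) - n - lgamma(1 + U)))
  v_w <- max(v_w, 0)  # guards tiny negative round-off at small n
  M <- n * w_mean + sigma * sqrt(v_r + v_w)
  list(v_r = v_r, U = U, v_w = v_w, M = M)
}

#' Split a 16-bit weight word into integer and fractional bits
#'
#' Chooses the smallest number of integer bits \code{i} such that
#' \code{2^i - 1 >= M}, where \code{M} is the expected maximum ring-buffer
#' element value in nA; the remaining \code{total - i} bits are fractional.
#' \code{M = 60} gives (6, 10), \code{M = 100} gives (7, 9); \code{M = 0}
#' gives (0, 16), the single-neuron test format.
#'
#' @param M expected maximum summed input, nA (>= 0).
#' @param total total weight bits (default 16).
#' @return list with \code{integer_bits} and \code{frac_bits}.
#' @export
allocate_bits <- function(M, total = 16) {
  stopifnot(is.finite(M), M >= 0)
  i <- 0L
  while (2^i - 1 < M) {
    i <- i + 1L
    if (i > total) stop("M = ", M, " nA cannot be represented in ",
                        total, " bits")
  }
  list(integer_bits = i, frac_bits = as.integer(total - i))
}

# ---- s16.15 arithmetic emulation (R reference; the C++ engine mirrors it) --

.S1615_ONE <- 2^15
.S1615_MAX <- 2^31 - 1
.S1615_MIN <- -2^31

#' s16.15 arithmetic emulation
#'
#' Reference implementation of the signed s16.15 fixed-point operations used
#' by the hardware-emulation backend: quantization truncates toward minus
#' infinity to the 2^-15 grid; multiplication forms the exact product of the
#' raw values and truncates back to 15 fractional bits; addition saturates
#' at the 32-bit raw bounds.  The compiled engine performs the identical
#' operations on int64 intermediates.
#'
#' @param x,a,b values in nA or mV.
#' @return \code{s1615_quantize}: the representable value;
#'   \code{s1615_mul}, \code{s1615_add}: the s16.15 result, with attribute
#'   \code{"saturated"} on \code{s1615_add}.
#' @name s1615
#' @examples
#' s1615_quantize(0.1)          # 3276/32768
#' s1615_mul(0.5, 0.0878)
#' @export
s1615_quantize <- function(x) {
  raw <- pmin(pmax(floor(x * .S1615_ONE), .S1615_MIN), .S1615_MAX)
  raw / .S1615_ONE
}

#' @rdname s1615
#' @export
s1615_mul <- function(a, b) {
  ra <- floor(a * .S1615_ONE)
  rb <- floor(b * .S1615_ONE)
  if (any(abs(ra * rb) >= 2^53))
    stop("raw product exceeds exact double range")  # int64 in the engine
  floor(ra * rb / .S1615_ONE) / .S1615_ONE
}

#' @rdname s1615
#' @export
s1615_add <- function(a, b) {
  raw <- floor(a * .S1615_ONE) + floor(b * .S1615_ONE)
  sat <- raw > .S1615_MAX | raw < .S1615_MIN
  raw <- pmin(pmax(raw, .S1615_MIN), .S1615_MAX)
  out <- raw / .S1615_ONE
  attr(out, "saturated") <- sat
  out
}
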