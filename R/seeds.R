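#' Derive a named random substream seed from a master seed
#'
#' Every source of randomness in the package draws from its own substream,
#' identified by a label such as \code{"projection:4E->4I"} or
#' \code{"population-init:2/3E"}.  The substream seed is a deterministic
#' function of \code{(master, label)} so that partial re-instantiation (for
#' example, regenerating one projection) is reproducible, and so that ports
#' to other languages can match draws given the same generator family.
#'
#' The derivation is a 32-bit multiplicative hash: the label is folded
#' byte-wise into an accumulator \code{a <- (a * 31 + byte) mod (2^31 - 1)},
#' then combined with the master seed as
#' \code{(master * 48271 + a) mod (2^31 - 1)}, forced into \code{[1, 2^31-2]}.
#' All arithmetic is exact in doubles (intermediates stay far below 2^53).
#'
#' @param master integer master seed (non-negative, < 2^31).
#' @param label  character scalar naming the substream.
#' @return an integer seed in \code{[1, 2^31 - 2]}, suitable for
#'   \code{set.seed()}.
#' @examples
#' derive_seed(1, "drive") != derive_seed(1, "init")
#' @export
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L, master >= 0,
            master < 2^31, is.character(label), length(label) == 1L)
  m <- 2^31 - 1
  a <- 0
  for (b in utf8ToInt(label)) {
    a <- (a * 31 + b) %% m
  }
  s <- (as.numeric(master) %% m * 48271 + a) %% m
  if (s < 1) s <- s + 1
  as.integer(s)
}

#' Evaluate an expression under a dedicated substream seed
#'
#' Sets the RNG to Mersenne-Twister with the derived substream seed, runs
#' \code{expr}, and restores the caller's RNG state afterwards.
#'
#' @param master,label passed to [derive_seed()].
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @keywords internal
with_substream <- function(master, label, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(derive_seed(master, label), kind = "Mersenne-Twister")
  expr
}
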