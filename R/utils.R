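#' Derive a per-repetition RNG substream seed
#'
#' Maps a master seed and a repetition index to a deterministic seed via one
#' multiplicative-congruential step modulo 2^31 - 1 (Park-Miller constants).
#' Any repetition of a simulation run can therefore be reproduced in
#' isolation, without replaying the repetitions before it.
#'
#' @param master integer master seed.
#' @param r repetition index (1-based).
#' @return an integer seed in \[1, 2^31 - 2\].
#' @export
substream_seed <- function(master, r) {
  stopifnot(is.numeric(master), length(master) == 1L,
            is.numeric(r), length(r) == 1L, r >= 1)
  m <- 2147483647 # 2^31 - 1, prime
  x <- (as.double(master) %% m) + 1
  # two mixing steps so master and r both move every bit
  x <- (x * 48271) %% m
  x <- ((x + as.double(r)) * 69621) %% m
  as.integer(x) + 1L
}

# Gauss-Legendre nodes/weights on [0, 1], cached per order.
.gl_cache <- new.env(parent = emptyenv())
gauss_legendre_01 <- function(n = 64L) {
  key <- as.character(n)
  if (is.null(.gl_cache[[key]])) {
    gl <- pracma::gaussLegendre(n, 0, 1)
    .gl_cache[[key]] <- list(x = gl$x, w = gl$w)
  }
  .gl_cache[[key]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
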