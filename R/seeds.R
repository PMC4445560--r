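#' Derive a reproducible child seed from a master seed
#'
#' Deterministic counter scheme `(master * 48271 + i * 16807) mod (2^31 - 1)`
#' (all arithmetic exact in doubles), so batch rows, matrix cells and
#' pipeline stages get independent, order-free seeds from one master seed.
#'
#' @param master master seed (integer-valued).
#' @param i counter (>= 1).
#' @return Integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, i) {
  m <- 2147483647
  s <- (as.numeric(master) %% m) * 48271 + as.numeric(i) * 16807
  as.integer(s %% m + 1)
}
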