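# internal helpers shared across modules

# round-half-away-from-zero; stats::round() rounds half to even
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# derive a per-unit RNG seed from a base seed; keeps results < 2^31
mix_seed <- function(seed, i) {
  s <- (as.numeric(seed) %% 2147483647) + 1009 * as.numeric(i)
  as.integer(s %% 2147483647)
}

an_log <- function(...) {
  if (isTRUE(getOption("adnetworks.verbose", FALSE))) message(...)
  invisible(NULL)
}

stopifnot_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 1 || x != floor(x))
    stop(name, " must be a single positive integer", call. = FALSE)
  invisible(as.integer(x))
}
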