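# internal numerical helpers shared across modules

# full linear convolution via FFT (stats::convolve handles the padding)
conv_full <- function(x, y) {
  stats::convolve(x, rev(y), type = "open")
}

# windowed-sinc pulse: unit-gain fractional-delay kernel centred at `center`
# (samples, may be fractional), Hann-windowed with half-width `half_width`.
sinc_pulse <- function(length_out, center, half_width = 32L) {
  t <- seq_len(length_out) - 1
  x <- t - center
  v <- numeric(length_out)
  keep <- abs(x) <= half_width
  xx <- x[keep]
  s <- ifelse(abs(xx) < 1e-12, 1, sin(pi * xx) / (pi * xx))
  v[keep] <- s * (0.5 + 0.5 * cos(pi * xx / half_width))
  v
}

rms <- function(x) sqrt(mean(x^2))

db <- function(ratio) 10 * log10(ratio)

stopifnot_scalar <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}
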