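# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the likelihood is re-derived from dbinom, the
# ANOVA from an explicit mean decomposition, and convolution from the
# definition where feasible.

# psychometric function, written out independently of the package
oracle_psi <- function(mu, pse, beta, lapse) {
  lapse + (1 - 2 * lapse) * pnorm((mu - pse) / beta)
}

oracle_nll <- function(par, data) {
  p <- oracle_psi(data$offset_deg, par[1], par[2], par[3])
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  ll <- lgamma(data$n + 1) - lgamma(data$k + 1) - lgamma(data$n - data$k + 1) +
    data$k * log(p) + (data$n - data$k) * log(1 - p)
  -sum(ll)
}

# coarse 3-D grid search plus Nelder-Mead refinement from the best cell
oracle_fit_grid <- function(data, pse_grid = NULL, beta_grid = NULL,
                            lapse_grid = c(0, 0.01, 0.02, 0.04, 0.06)) {
  span <- diff(range(data$offset_deg))
  if (is.null(pse_grid)) {
    pse_grid <- seq(min(data$offset_deg), max(data$offset_deg),
                    length.out = 41)
  }
  if (is.null(beta_grid)) beta_grid <- seq(span / 40, span, length.out = 40)
  grid <- expand.grid(pse = pse_grid, beta = beta_grid, lapse = lapse_grid)
  vals <- apply(grid, 1, function(g) oracle_nll(g, data))
  best <- as.numeric(grid[which.min(vals), ])
  ref <- optim(best, function(p) {
    if (p[2] <= 0 || p[3] < 0 || p[3] > 0.06) return(1e10)
    oracle_nll(p, data)
  }, method = "Nelder-Mead",
  control = list(maxit = 2000, reltol = 1e-12))
  list(par = ref$par, nll = ref$value)
}

# explicit sums-of-squares decomposition for a balanced subject x A x B
# within-subject design (one observation per cell)
oracle_rm_anova <- function(d) {
  # d: data.frame with columns s, A, B, y (factors s, A, B)
  m <- mean(d$y)
  ns <- nlevels(d$s); na <- nlevels(d$A); nb <- nlevels(d$B)
  mean_by <- function(f) tapply(d$y, f, mean)
  m_s <- mean_by(d$s); m_a <- mean_by(d$A); m_b <- mean_by(d$B)
  m_sa <- tapply(d$y, list(d$s, d$A), mean)
  m_sb <- tapply(d$y, list(d$s, d$B), mean)
  m_ab <- tapply(d$y, list(d$A, d$B), mean)
  ss_a <- ns * nb * sum((m_a - m)^2)
  ss_b <- ns * na * sum((m_b - m)^2)
  ss_ab <- ns * sum((m_ab - outer(m_a, rep(1, nb)) -
                       outer(rep(1, na), m_b) + m)^2)
  ss_sa <- nb * sum((m_sa - outer(m_s, rep(1, na)) -
                       outer(rep(1, ns), m_a) + m)^2)
  ss_sb <- na * sum((m_sb - outer(m_s, rep(1, nb)) -
                       outer(rep(1, ns), m_b) + m)^2)
  resid <- with(d, y - m_ab[cbind(A, B)] - m_sa[cbind(s, A)] -
                  m_sb[cbind(s, B)] + m_a[A] + m_b[B] + m_s[s] - m)
  ss_sab <- sum(resid^2)
  f_of <- function(ss_e, df_e, ss_r, df_r) (ss_e / df_e) / (ss_r / df_r)
  data.frame(
    effect = c("A", "B", "A:B"),
    df_num = c(na - 1, nb - 1, (na - 1) * (nb - 1)),
    df_den = c((na - 1) * (ns - 1), (nb - 1) * (ns - 1),
               (na - 1) * (nb - 1) * (ns - 1)),
    F = c(
      f_of(ss_a, na - 1, ss_sa, (na - 1) * (ns - 1)),
      f_of(ss_b, nb - 1, ss_sb, (nb - 1) * (ns - 1)),
      f_of(ss_ab, (na - 1) * (nb - 1), ss_sab, (na - 1) * (nb - 1) * (ns - 1))
    )
  )
}

# direct O(n*m) convolution for small oracle checks
oracle_conv <- function(x, h) {
  n <- length(x) + length(h) - 1
  out <- numeric(n)
  for (i in seq_along(h)) {
    out[(i - 1) + seq_along(x)] <- out[(i - 1) + seq_along(x)] + h[i] * x
  }
  out
}

# in-band relative L2 spectral error between a recovered and a true filter,
# both padded to a common length
inband_error <- function(recovered, truth, fs, f1, f2) {
  len <- max(length(recovered), length(truth))
  nfft <- 2^ceiling(log2(2 * len))
  pad <- function(v) c(v, numeric(nfft - length(v)))
  H <- fft(pad(truth))
  HR <- fft(pad(recovered))
  f <- (0:(nfft - 1)) / nfft * fs
  band <- f >= f1 & f <= f2
  sqrt(sum(Mod(HR - H)[band]^2) / sum(Mod(H)[band]^2))
}

# deterministic synthetic exponential-decay impulse response: 60 dB of
# amplitude-envelope decay in `t60` seconds
decay_ir <- function(t60, fs = 48000, dur = NULL, seed = NULL) {
  if (is.null(dur)) dur <- 1.5 * t60
  t <- (seq_len(round(dur * fs)) - 1) / fs
  env <- 10^(-3 * t / t60)
  if (is.null(seed)) env else env * withr::with_seed(seed, rnorm(length(t)))
}
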