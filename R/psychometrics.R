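# cumulative-Gaussian psychometric function with symmetric lapses
psi_fun <- function(mu, pse, beta, lapse) {
  lapse + (1 - 2 * lapse) * stats::pnorm((mu - pse) / beta)
}

as_counts <- function(data) {
  if (inherits(data, "response_set")) data <- data$counts
  if (!all(c("offset_deg", "n", "k") %in% names(data))) {
    stop("data must have columns offset_deg, n, k (see response_counts())",
         call. = FALSE)
  }
  if (any(data$k < 0 | data$k > data$n)) {
    stop("counts must satisfy 0 <= k <= n", call. = FALSE)
  }
  data
}

#' Negative log-likelihood of a psychometric function
#'
#' Binomial negative log-likelihood of per-offset response counts under the
#' cumulative-Gaussian model `psi(mu) = lapse + (1 - 2 lapse) *
#' Phi((mu - pse) / beta)`. Fractional counts (e.g. expected proportions)
#' are accepted; the binomial coefficient is evaluated through `lgamma`.
#'
#' @param params numeric vector `c(pse, beta, lapse)`; `beta > 0`,
#'   `lapse` in \[0, 0.06\].
#' @param data per-offset counts: data.frame with `offset_deg`, `n`, `k`
#'   ("vision leads" responses), or a `response_set`.
#' @return negative log-likelihood in nats.
#' @export
neg_log_lik <- function(params, data) {
  data <- as_counts(data)
  pse <- params[1]; beta <- params[2]; lapse <- params[3]
  if (!is.finite(pse) || !is.finite(beta) || !is.finite(lapse) ||
      beta <= 0 || lapse < 0 || lapse > 0.06) {
    stop("invalid parameters: need beta > 0 and lapse in [0, 0.06]",
         call. = FALSE)
  }
  p <- psi_fun(data$offset_deg, pse, beta, lapse)
  xlogy <- function(x, y) ifelse(x == 0, 0, x * log(y))
  coef <- lgamma(data$n + 1) - lgamma(data$k + 1) -
    lgamma(data$n - data$k + 1)
  -sum(coef + xlogy(data$k, p) + xlogy(data$n - data$k, 1 - p))
}

# fast likelihood kernel for the optimizer: drops the data-only binomial
# coefficient (restored as a constant in the reported nll) and clamps psi
# away from 0/1 so boundary parameter values stay finite
make_nll_kernel <- function(data) {
  mu <- data$offset_deg
  n <- data$n
  k <- data$k
  function(params) {
    p <- params[3] + (1 - 2 * params[3]) *
      stats::pnorm((mu - params[1]) / params[2])
    p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
    v <- -sum(k * log(p) + (n - k) * log1p(-p))
    if (!is.finite(v)) 1e10 else v
  }
}

# bounded MLE from one start; polishes with Nelder-Mead if the quasi-Newton
# run reports a line-search failure
optimize_pf <- function(kernel, start, lower, upper, span) {
  r <- tryCatch(
    stats::optim(start, kernel, method = "L-BFGS-B",
                 lower = lower, upper = upper,
                 control = list(maxit = 200, factr = 1e7,
                                parscale = c(span, span, 0.06))),
    error = function(e) NULL
  )
  if (is.null(r) || r$convergence != 0) {
    start2 <- if (is.null(r)) start else r$par
    r2 <- tryCatch(
      stats::optim(start2, function(p) {
        if (any(p < lower) || any(p > upper)) return(1e10)
        kernel(p)
      }, method = "Nelder-Mead", control = list(maxit = 400)),
      error = function(e) NULL
    )
    if (!is.null(r2) && (is.null(r) || r2$value <= r$value)) {
      r2$convergence <- 0L
      return(r2)
    }
  }
  r
}

#' Fit a psychometric function by constrained maximum likelihood
#'
#' Fits the cumulative-Gaussian model with symmetric lapses to per-offset
#' 2AFC counts. The lapse rate is capped at 0.06 and the spread `beta` is
#' positive. Optimisation runs bounded quasi-Newton (`L-BFGS-B`) from five
#' deterministic starts (a probit-regression moment estimate plus spread and
#' location jitters); ties resolve to the lowest negative log-likelihood,
#' then the smallest lapse. Perfectly separated data drive `beta` to the
#' lower optimizer bound and are flagged `degenerate`.
#'
#' @param data per-offset counts (`offset_deg`, `n`, `k`) or a
#'   `response_set`; at least three distinct offsets and one response in
#'   each category overall.
#' @param beta_min lower optimizer bound for `beta`, degrees.
#' @return a `psychometric_fit`: list with `pse`, `beta` (spread, degrees),
#'   `beta_var` (its square), `lapse`, `neg_log_likelihood`, `converged`,
#'   `degenerate`, `data`, and empty CI slots until [bootstrap_ci()].
#' @export
fit_pf <- function(data, beta_min = 0.01) {
  data <- as_counts(data)
  if (length(unique(data$offset_deg)) < 3L) {
    stop("need at least 3 distinct offsets to fit a psychometric function",
         call. = FALSE)
  }
  if (sum(data$k) == 0 || sum(data$k) == sum(data$n)) {
    warning("all responses in one category; fit is unconstrained on one side",
            call. = FALSE)
  }
  span <- diff(range(data$offset_deg))
  # probit-regression starting point on jittered empirical proportions
  p_emp <- (data$k + 0.5) / (data$n + 1)
  z <- stats::qnorm(p_emp)
  co <- tryCatch(stats::coef(stats::lm(z ~ data$offset_deg)),
                 error = function(e) c(0, NA))
  if (is.finite(co[2]) && co[2] > 1e-6) {
    pse0 <- -co[1] / co[2]
    beta0 <- 1 / co[2]
  } else {
    pse0 <- stats::weighted.mean(data$offset_deg, data$n)
    beta0 <- span / 4
  }
  pse0 <- min(max(pse0, min(data$offset_deg)), max(data$offset_deg))
  beta0 <- min(max(beta0, beta_min * 2), span)
  starts <- list(
    c(pse0, beta0, 0.01),
    c(pse0, beta0 / 2, 0.01),
    c(pse0, beta0 * 2, 0.01),
    c(pse0 - span / 4, beta0, 0.03),
    c(pse0 + span / 4, beta0, 0.03)
  )
  lower <- c(min(data$offset_deg) - span, beta_min, 0)
  upper <- c(max(data$offset_deg) + span, span * 10, 0.06)
  kernel <- make_nll_kernel(data)
  runs <- lapply(starts, function(s) {
    optimize_pf(kernel, pmin(pmax(s, lower), upper), lower, upper, span)
  })
  runs <- Filter(Negate(is.null), runs)
  if (length(runs) == 0L) stop("all optimizer starts failed", call. = FALSE)
  vals <- vapply(runs, function(r) r$value, numeric(1))
  lapses <- vapply(runs, function(r) r$par[3], numeric(1))
  best <- runs[[order(vals, lapses)[1]]]
  nll_const <- -sum(lgamma(data$n + 1) - lgamma(data$k + 1) -
                      lgamma(data$n - data$k + 1))   # binomial coefficient
  structure(
    list(
      pse = best$par[1], beta = best$par[2], beta_var = best$par[2]^2,
      lapse = best$par[3], neg_log_likelihood = best$value + nll_const,
      converged = best$convergence == 0,
      degenerate = best$par[2] <= beta_min * (1 + 1e-6),
      data = data,
      ci95_pse = NULL, ci95_beta = NULL, n_bootstrap = 0L
    ),
    class = "psychometric_fit"
  )
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf(
    "<psychometric_fit> pse %+.3f deg, beta %.3f deg, lapse %.3f (nll %.2f)\n",
    x$pse, x$beta, x$lapse, x$neg_log_likelihood
  ))
  if (!is.null(x$ci95_pse)) {
    cat(sprintf("  95%% CI (n_boot %d): pse [%.3f, %.3f], beta [%.3f, %.3f]\n",
                x$n_bootstrap, x$ci95_pse[1], x$ci95_pse[2],
                x$ci95_beta[1], x$ci95_beta[2]))
  }
  if (x$degenerate) cat("  (degenerate: beta at lower bound)\n")
  invisible(x)
}

#' Parametric bootstrap confidence limits for a psychometric fit
#'
#' Draws `n_boot` synthetic datasets from the fitted psychometric function
#' at the observed offsets and trial counts, refits each (single start at
#' the parent estimate), and attaches 95% percentile intervals for PSE and
#' beta to the fit. A warning is raised if more than 5% of refits fail.
#'
#' @param fit a [fit_pf()] result.
#' @param data counts to resample at; defaults to the fit's own data.
#' @param n_boot bootstrap replicates (default 1000; 0 returns the fit
#'   unchanged).
#' @param seed integer; fixes the resampling stream.
#' @return the fit with `ci95_pse`, `ci95_beta` and `n_bootstrap` filled.
#' @export
bootstrap_ci <- function(fit, data = NULL, n_boot = 1000L, seed = 1L) {
  if (n_boot == 0L) return(fit)
  data <- as_counts(if (is.null(data)) fit$data else data)
  p_hat <- psi_fun(data$offset_deg, fit$pse, fit$beta, fit$lapse)
  span <- diff(range(data$offset_deg))
  lower <- c(min(data$offset_deg) - span, 0.01, 0)
  upper <- c(max(data$offset_deg) + span, span * 10, 0.06)
  start <- pmin(pmax(c(fit$pse, fit$beta, fit$lapse), lower), upper)
  est <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      db <- list(offset_deg = data$offset_deg, n = data$n,
                 k = stats::rbinom(nrow(data), data$n, p_hat))
      r <- optimize_pf(make_nll_kernel(db), start, lower, upper, span)
      if (is.null(r) || r$convergence != 0) c(NA_real_, NA_real_)
      else r$par[1:2]
    }, numeric(2))
  })
  fail_rate <- mean(is.na(est[1, ]))
  if (fail_rate > 0.05) {
    warning(sprintf("%.1f%% of bootstrap refits failed", 100 * fail_rate),
            call. = FALSE)
  }
  fit$ci95_pse <- unname(stats::quantile(est[1, ], c(0.025, 0.975),
                                         na.rm = TRUE))
  fit$ci95_beta <- unname(stats::quantile(est[2, ], c(0.025, 0.975),
                                          na.rm = TRUE))
  fit$n_bootstrap <- as.integer(n_boot)
  fit
}

#' Fit psychometric functions for every cell of a simulated study
#'
#' @param trials data.frame from [simulate_study()] (columns `subject`,
#'   `condition`, `velocity`, `offset_deg`, `response`).
#' @return data.frame with one row per subject-condition-velocity cell:
#'   `pse`, `beta`, `lapse`, `neg_log_likelihood`, `converged`.
#' @export
fit_study <- function(trials) {
  cells <- unique(trials[, c("subject", "condition", "velocity")])
  cells <- cells[order(cells$subject, cells$condition, cells$velocity), ]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- trials$subject == cells$subject[i] &
      trials$condition == cells$condition[i] &
      trials$velocity == cells$velocity[i]
    f <- fit_pf(response_counts(trials[sel, ]))
    cbind(cells[i, ],
          data.frame(pse = f$pse, beta = f$beta, lapse = f$lapse,
                     neg_log_likelihood = f$neg_log_likelihood,
                     converged = f$converged))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-way repeated-measures ANOVA
#'
#' Within-subject decomposition of a complete balanced subject x A x B
#' table: each main effect and the interaction is tested against its own
#' subject-by-effect interaction error term (no sphericity correction),
#' via `stats::aov` with `Error(subject/(A*B))` strata.
#'
#' @param data data.frame in long format.
#' @param value name of the measure column (e.g. `"pse"` or `"beta"`).
#' @param subject name of the subject identifier column.
#' @param factors names of the two within-subject factor columns.
#' @return an `anova_table` data.frame: one row per effect (`A`, `B`,
#'   `A:B`) with `df_num`, `df_den`, `F`, `p`. Effects with zero sum of
#'   squares report `F = 0`, `p = 1`.
#' @export
rm_anova <- function(data, value = "pse", subject = "subject",
                     factors = c("condition", "velocity")) {
  need <- c(value, subject, factors)
  if (!all(need %in% names(data))) {
    stop("data must contain columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  d <- data.frame(
    y = data[[value]],
    s = factor(data[[subject]]),
    A = factor(data[[factors[1]]]),
    B = factor(data[[factors[2]]])
  )
  tab <- table(d$s, d$A, d$B)
  if (any(tab != 1L)) {
    stop("design must be complete and balanced: one value per subject x ",
         factors[1], " x ", factors[2], " cell", call. = FALSE)
  }
  if (nlevels(d$s) < 2L) stop("need at least 2 subjects", call. = FALSE)
  # scale reference for detecting zero-variance (degenerate) decompositions
  total_ss <- sum((d$y - mean(d$y))^2)
  degenerate <- total_ss <= 1e-12 * max(sum(d$y^2), .Machine$double.xmin)
  fit <- stats::aov(y ~ A * B + Error(s / (A * B)), data = d)
  sm <- summary(fit)
  pull <- function(stratum, effect) {
    st <- sm[[paste0("Error: ", stratum)]][[1]]
    rn <- trimws(rownames(st))
    eff <- st[rn == effect, , drop = FALSE]
    res <- st[rn == "Residuals", , drop = FALSE]
    ss_e <- eff[1, "Sum Sq"]; ss_r <- res[1, "Sum Sq"]
    df_n <- eff[1, "Df"]; df_d <- res[1, "Df"]
    if (degenerate || ss_e <= 1e-12 * total_ss) {
      f_val <- 0; p_val <- 1
    } else {
      ms_e <- ss_e / df_n; ms_r <- ss_r / df_d
      f_val <- if (ms_r > 0) ms_e / ms_r else Inf
      p_val <- if (is.finite(f_val)) stats::pf(f_val, df_n, df_d,
                                               lower.tail = FALSE) else 0
    }
    data.frame(effect = effect, df_num = df_n, df_den = df_d,
               F = f_val, p = p_val)
  }
  out <- rbind(
    pull("s:A", "A"),
    pull("s:B", "B"),
    pull("s:A:B", "A:B")
  )
  out$effect <- c(factors[1], factors[2],
                  paste(factors[1], factors[2], sep = ":"))
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Group means and between-participant standard errors
#'
#' @param fits data.frame from [fit_study()] (needs `subject`, `condition`,
#'   `velocity` plus the measure columns).
#' @param measures columns to summarise.
#' @return data.frame with one row per condition-velocity-measure cell:
#'   `mean`, `se` (sd over subjects / sqrt(n)), `n_subjects`.
#' @export
summarize_group <- function(fits, measures = c("pse", "beta")) {
  cells <- unique(fits[, c("condition", "velocity")])
  cells <- cells[order(cells$condition, cells$velocity), ]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- fits$condition == cells$condition[i] &
      fits$velocity == cells$velocity[i]
    do.call(rbind, lapply(measures, function(m) {
      v <- fits[[m]][sel]
      if (length(v) < 2L) stop("need >= 2 subjects per cell", call. = FALSE)
      data.frame(
        condition = cells$condition[i], velocity = cells$velocity[i],
        measure = m, mean = mean(v), se = stats::sd(v) / sqrt(length(v)),
        n_subjects = length(v)
      )
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
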