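#' Spatial offsets tested at each velocity
#'
#' The nine signed audio-visual offsets (degrees) paired with each motion
#' velocity in the trial design: faster motion uses proportionally wider
#' offsets. Positive offsets are auditory lags (the visual stimulus leads in
#' space), negative offsets auditory leads, zero spatiotemporal equality.
#'
#' @param velocity 25, 50 or 100 (degrees per second).
#' @return sorted numeric vector of nine offsets, degrees.
#' @export
#' @examples
#' offsets_for(25)
offsets_for <- function(velocity) {
  sets <- list(
    `25` = c(0, 1.25, -1.25, 2.5, -2.5, 5, -5, 10, -10),
    `50` = c(0, 2.5, -2.5, 5, -5, 7.5, -7.5, 10, -10),
    `100` = c(0, 5, -5, 10, -10, 15, -15, 20, -20)
  )
  key <- as.character(velocity)
  if (!key %in% names(sets)) {
    stop("velocity must be one of 25, 50, 100 deg/s (supply custom offsets directly for other designs)",
         call. = FALSE)
  }
  sort(sets[[key]])
}

#' Build a randomized block of 2AFC trials
#'
#' A block is `repeats` passes over the velocity's nine offsets (90 trials
#' by default), offset order shuffled uniformly within each pass, and motion
#' direction strictly alternating from trial to trial (the starting
#' direction is drawn from the seed). Responses are left empty for
#' [run_block()].
#'
#' @param velocity degrees per second (one of 25, 50, 100 unless `offsets`
#'   is supplied).
#' @param condition label for the acoustic condition (e.g. `"anechoic1"`,
#'   `"anechoic5"`, `"reverberant5"`).
#' @param repeats passes over the offset set (default 10).
#' @param seed integer; fixes the shuffle.
#' @param offsets optional custom offset set (degrees) overriding
#'   [offsets_for()].
#' @return data.frame with columns `trial`, `velocity`, `condition`,
#'   `offset_deg`, `direction`, `repeat_index`, `response` (NA).
#' @export
build_schedule <- function(velocity, condition = "anechoic5", repeats = 10L,
                           seed = 1L, offsets = NULL) {
  if (repeats < 1) stop("repeats must be >= 1", call. = FALSE)
  if (is.null(offsets)) offsets <- offsets_for(velocity)
  n_off <- length(offsets)
  sched <- withr::with_seed(seed, {
    order_mat <- replicate(repeats, sample(offsets))
    first_dir <- sample(c("leftward", "rightward"), 1)
    list(offsets = as.numeric(order_mat), first_dir = first_dir)
  })
  n <- n_off * repeats
  dirs <- rep(c("leftward", "rightward"), length.out = n)
  if (sched$first_dir == "rightward") {
    dirs <- rep(c("rightward", "leftward"), length.out = n)
  }
  data.frame(
    trial = seq_len(n),
    velocity = velocity,
    condition = condition,
    offset_deg = sched$offsets,
    direction = dirs,
    repeat_index = rep(seq_len(repeats), each = n_off),
    response = NA_character_
  )
}

#' Define a simulated 2AFC observer
#'
#' A decision-level observer whose probability of responding "vision leads"
#' at offset `mu` is `psi(mu) = lapse + (1 - 2 lapse) * Phi((mu - pse) /
#' sigma)`: a cumulative Gaussian centred on the observer's point of
#' subjective equality with symmetric lapses at both asymptotes.
#'
#' @param pse point of subjective equality, degrees.
#' @param sigma spread of the underlying Gaussian, degrees, > 0.
#' @param lapse stimulus-independent error rate in \[0, 0.06\].
#' @param seed integer; fixes the observer's response stream in
#'   [run_block()].
#' @return an `observer_model`.
#' @export
observer_model <- function(pse, sigma, lapse = 0, seed = 1L) {
  stopifnot_scalar(pse); stopifnot_scalar(sigma)
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  if (lapse < 0 || lapse > 0.06) {
    stop("lapse must lie in [0, 0.06]", call. = FALSE)
  }
  structure(
    list(pse = pse, sigma = sigma, lapse = lapse, seed = as.integer(seed)),
    class = "observer_model"
  )
}

#' @export
print.observer_model <- function(x, ...) {
  cat(sprintf("<observer_model> pse %+.2f deg, sigma %.2f deg, lapse %.3f\n",
              x$pse, x$sigma, x$lapse))
  invisible(x)
}

#' Probability of a "vision leads" response at a given offset
#'
#' @param obs an [observer_model()].
#' @param mu signed offset, degrees (vectorised).
#' @return probability in \[lapse, 1 - lapse\].
#' @export
response_probability <- function(obs, mu) {
  obs$lapse + (1 - 2 * obs$lapse) * stats::pnorm((mu - obs$pse) / obs$sigma)
}

#' Draw 2AFC responses from an observer
#'
#' Bernoulli draws at `psi(mu)` using the current RNG state; seed the
#' stream (e.g. with `withr::with_seed()`) or use [run_block()], which
#' seeds from the observer, for reproducibility.
#'
#' @param obs an [observer_model()].
#' @param mu signed offset, degrees.
#' @param n number of draws.
#' @return character vector of `"vision_leads"` / `"audition_leads"`.
#' @export
simulate_response <- function(obs, mu, n = 1L) {
  p <- response_probability(obs, mu)
  ifelse(stats::runif(n) < p, "vision_leads", "audition_leads")
}

#' Run an observer through a trial schedule
#'
#' Fills every trial of a [build_schedule()] block with a simulated
#' response, seeding the draw stream from the observer's `seed`.
#'
#' @param obs an [observer_model()].
#' @param schedule data.frame from [build_schedule()] with empty responses.
#' @return a `response_set`: list with `trials` (the filled schedule) and
#'   `counts` (per-offset totals `n` and `"vision leads"` counts `k`).
#' @export
run_block <- function(obs, schedule) {
  if (!all(is.na(schedule$response))) {
    stop("schedule already contains responses", call. = FALSE)
  }
  schedule$response <- withr::with_seed(
    obs$seed,
    vapply(schedule$offset_deg, function(mu) simulate_response(obs, mu),
           character(1))
  )
  structure(
    list(trials = schedule, counts = response_counts(schedule)),
    class = "response_set"
  )
}

#' @export
print.response_set <- function(x, ...) {
  cat(sprintf("<response_set> %d trials, %d offsets\n",
              nrow(x$trials), nrow(x$counts)))
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' Aggregate trial responses into per-offset counts
#'
#' @param trials data.frame of filled trials (or a `response_set`).
#' @return data.frame with `offset_deg`, `n` (trials) and `k`
#'   ("vision leads" responses), sorted by offset.
#' @export
response_counts <- function(trials) {
  if (inherits(trials, "response_set")) trials <- trials$trials
  agg <- stats::aggregate(
    cbind(n = 1, k = trials$response == "vision_leads") ~ offset_deg,
    data = trials, FUN = sum
  )
  agg[order(agg$offset_deg), , drop = FALSE]
}

#' Simulate a full factorial study
#'
#' Runs every observer through one block per condition-by-velocity cell,
#' mirroring the experimental design (e.g. 6 subjects x 2 conditions x 3
#' velocities = 36 blocks of 90 trials). Block seeds are derived from
#' `seed` so the whole study is reproducible.
#'
#' @param observers data.frame with columns `subject`, `pse`, `sigma`,
#'   `lapse` — one simulated participant per row (true parameters shared
#'   across cells).
#' @param conditions character vector of acoustic condition labels.
#' @param velocities numeric vector of velocities, deg/s.
#' @param repeats passes over the offset set per block.
#' @param seed integer master seed.
#' @return data.frame of all trials with `subject` prepended.
#' @export
simulate_study <- function(observers,
                           conditions = c("anechoic5", "reverberant5"),
                           velocities = c(25, 50, 100),
                           repeats = 10L, seed = 1L) {
  cells <- expand.grid(
    subject = observers$subject, condition = conditions,
    velocity = velocities, stringsAsFactors = FALSE
  )
  blocks <- lapply(seq_len(nrow(cells)), function(i) {
    row <- cells[i, ]
    pars <- observers[observers$subject == row$subject, ]
    block_seed <- (seed + 7919L * i) %% 2147483647L
    obs <- observer_model(pars$pse, pars$sigma, pars$lapse,
                          seed = block_seed + 1L)
    sched <- build_schedule(row$velocity, row$condition, repeats,
                            seed = block_seed)
    cbind(subject = row$subject, run_block(obs, sched)$trials)
  })
  do.call(rbind, blocks)
}
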