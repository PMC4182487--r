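#' Direct-to-reverberant energy ratio of an impulse response
#'
#' Splits the response at its main peak: the direct part is the window from
#' 0.5 ms before the peak to `direct_window` seconds after it (the default
#' 1 ms sits safely inside the ~2.5 ms first-reflection gap of the default
#' room), the reverberant part everything later. Returns
#' `10 log10(direct energy / reverberant energy)` in dB, or `Inf` when the
#' tail holds less than 1e-12 of the total energy. Binaural `ir_pair` input
#' is scored per ear and the two dB values averaged.
#'
#' @param ir numeric vector or `ir_pair`.
#' @param fs sampling rate, Hz (taken from an `ir_pair`).
#' @param direct_window seconds of direct sound kept after the peak.
#' @return D/R in dB.
#' @export
estimate_drr <- function(ir, fs = NULL, direct_window = 0.001) {
  if (inherits(ir, "ir_pair")) {
    return(mean(c(
      estimate_drr(ir$left, ir$fs, direct_window),
      estimate_drr(ir$right, ir$fs, direct_window)
    )))
  }
  if (is.null(fs)) stop("fs is required for plain-vector input", call. = FALSE)
  if (all(ir == 0)) stop("silent impulse response", call. = FALSE)
  peak <- which.max(abs(ir))
  from <- max(1L, peak - round(0.0005 * fs))
  to <- min(length(ir), peak + round(direct_window * fs))
  direct <- sum(ir[from:to]^2)
  tail_e <- if (to < length(ir)) sum(ir[(to + 1):length(ir)]^2) else 0
  if (tail_e < 1e-12 * (direct + tail_e)) return(Inf)
  db(direct / tail_e)
}

#' Reverberation time by Schroeder backward integration
#'
#' Integrates the squared response backwards in time to form the energy
#' decay curve, locates the -5 and -35 dB crossings, and doubles the
#' duration of that 30 dB span to obtain RT60. If the response never decays
#' to -35 dB the estimate extrapolates from the available span and a
#' warning is raised.
#'
#' @param ir numeric vector or `ir_pair` (channels averaged).
#' @param fs sampling rate, Hz (taken from an `ir_pair`).
#' @return RT60 in seconds.
#' @export
estimate_rt60 <- function(ir, fs = NULL) {
  if (inherits(ir, "ir_pair")) {
    return(mean(c(estimate_rt60(ir$left, ir$fs),
                  estimate_rt60(ir$right, ir$fs))))
  }
  if (is.null(fs)) stop("fs is required for plain-vector input", call. = FALSE)
  if (all(ir == 0)) stop("silent impulse response", call. = FALSE)
  energy <- rev(cumsum(rev(ir^2)))
  edc <- db(energy / energy[1])
  t <- (seq_along(edc) - 1) / fs
  t5 <- t[which(edc <= -5)[1]]
  i35 <- which(edc <= -35)[1]
  if (is.na(i35) || is.na(t5)) {
    floor_db <- min(edc[is.finite(edc)])
    warning(sprintf(
      "decay range only %.1f dB (< 35 dB); RT60 extrapolated", -floor_db
    ), call. = FALSE)
    span_db <- max(floor_db + 5, -30)   # use what decay there is
    tf <- t[which(edc <= span_db)[1]]
    if (is.na(t5) || is.na(tf) || tf <= t5) return(NA_real_)
    return(60 / (-(span_db + 5)) * (tf - t5))
  }
  2 * (t[i35] - t5)
}

#' Detect early reflections in an impulse response
#'
#' Local maxima of `|ir|` after the direct peak that exceed
#' `rel_threshold_db` relative to that peak, thinned so that reported peaks
#' are at least 0.25 ms apart (ringing within a reflection is not counted
#' twice).
#'
#' @param ir numeric vector or `ir_pair`. A binaural pair is scored per ear
#'   relative to that ear's own direct peak (so the far ear's ITD-delayed
#'   direct arrival is not mistaken for a reflection) and the two ears'
#'   detections merged under the separation floor.
#' @param fs sampling rate, Hz.
#' @param rel_threshold_db detection threshold in dB relative to the direct
#'   peak; must be negative.
#' @param min_separation minimum spacing between reported peaks, seconds.
#' @return numeric vector of reflection times in seconds after the direct
#'   peak (empty if none), with attribute `level_db` giving each peak's
#'   level relative to the direct peak.
#' @export
detect_reflections <- function(ir, fs = NULL, rel_threshold_db = -20,
                               min_separation = 0.00025) {
  if (inherits(ir, "ir_pair")) {
    l <- detect_reflections(ir$left, ir$fs, rel_threshold_db, min_separation)
    r <- detect_reflections(ir$right, ir$fs, rel_threshold_db, min_separation)
    all_t <- c(l, r)
    all_db <- c(attr(l, "level_db"), attr(r, "level_db"))
    if (length(all_t) == 0L) return(numeric(0))
    keep_t <- numeric(0)
    keep_db <- numeric(0)
    for (i in order(all_db, decreasing = TRUE)) {
      if (all(abs(all_t[i] - keep_t) >= min_separation) || length(keep_t) == 0L) {
        keep_t <- c(keep_t, all_t[i])
        keep_db <- c(keep_db, all_db[i])
      }
    }
    o <- order(keep_t)
    return(structure(keep_t[o], level_db = keep_db[o]))
  }
  if (is.null(fs)) stop("fs is required for plain-vector input", call. = FALSE)
  if (rel_threshold_db >= 0) {
    stop("rel_threshold_db must be negative (relative to the direct peak)",
         call. = FALSE)
  }
  x <- abs(ir)
  peak <- which.max(x)
  gap <- round(min_separation * fs)
  thresh <- x[peak] * 10^(rel_threshold_db / 20)
  n <- length(x)
  if (peak + gap + 1 > n) return(numeric(0))
  # local maxima at or above threshold, strictly after the separation floor
  region <- (peak + gap):(n - 1)
  region <- region[region >= 2]
  cand <- region[x[region] >= thresh &
                   x[region] >= x[region - 1] &
                   x[region] > x[region + 1]]
  if (length(cand) == 0L) return(numeric(0))
  # greedy thinning by magnitude, enforcing the separation floor against the
  # direct peak and already-kept reflections
  cand <- cand[order(x[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (c0 in cand) {
    if (all(abs(c0 - c(peak, kept)) >= gap)) kept <- c(kept, c0)
  }
  kept <- sort(kept)
  structure((kept - peak) / fs, level_db = 20 * log10(x[kept] / x[peak]))
}

#' Acoustic summary of an impulse response
#'
#' Bundles [estimate_drr()], [estimate_rt60()] and [detect_reflections()]
#' into one report row, as used to validate synthetic rooms.
#'
#' @param ir numeric vector or `ir_pair`.
#' @param fs sampling rate, Hz.
#' @param direct_window seconds, see [estimate_drr()].
#' @param rel_threshold_db dB, see [detect_reflections()].
#' @return an `acoustic_report`: list with `drr_db`, `rt60`,
#'   `reflection_times` (s after the direct onset) and `direct_onset` (s).
#' @export
acoustic_report <- function(ir, fs = NULL, direct_window = 0.001,
                            rel_threshold_db = -20) {
  if (inherits(ir, "ir_pair")) {
    fs <- ir$fs
    onset <- min(direct_onset(ir$left), direct_onset(ir$right))
  } else {
    if (is.null(fs)) stop("fs is required for plain-vector input", call. = FALSE)
    onset <- direct_onset(ir)
  }
  structure(
    list(
      drr_db = estimate_drr(ir, fs, direct_window),
      rt60 = suppressWarnings(estimate_rt60(ir, fs)),
      reflection_times = detect_reflections(ir, fs, rel_threshold_db),
      direct_onset = (onset - 1) / fs
    ),
    class = "acoustic_report"
  )
}

#' @export
print.acoustic_report <- function(x, ...) {
  cat(sprintf(
    "<acoustic_report> D/R %.1f dB, RT60 %.3f s, %d reflections (first at %.2f ms)\n",
    x$drr_db, x$rt60, length(x$reflection_times),
    if (length(x$reflection_times)) x$reflection_times[1] * 1000 else NA
  ))
  invisible(x)
}
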