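#' Time spent at each quantized azimuth position
#'
#' A motion at `velocity` degrees per second rendered on a `step`-degree
#' filter grid dwells `step / velocity` seconds at each position: 10 ms per
#' 1-degree step and 50 ms per 5-degree step at 100 deg/s.
#'
#' @param velocity degrees per second, > 0.
#' @param step grid spacing, degrees, > 0.
#' @return dwell time in seconds.
#' @export
#' @examples
#' segment_dwell(100, 1)  # 0.01 s
#' segment_dwell(100, 5)  # 0.05 s
segment_dwell <- function(velocity, step) {
  if (any(velocity <= 0)) stop("velocity must be positive", call. = FALSE)
  if (any(step <= 0)) stop("step must be positive", call. = FALSE)
  step / velocity
}

#' Describe a quantized motion path along the frontal azimuth arc
#'
#' @param start_az,end_az first and last occupied azimuths, degrees; their
#'   difference must be a whole multiple of `step`.
#' @param step grid spacing, degrees.
#' @param velocity degrees per second.
#' @return a `motion_path` with fields `start_az`, `end_az`, `step`,
#'   `velocity` and `direction` (`"rightward"` if azimuth increases,
#'   `"leftward"` otherwise).
#' @export
#' @examples
#' motion_path(-70, 70, step = 5, velocity = 50)
motion_path <- function(start_az, end_az, step, velocity) {
  stopifnot_scalar(start_az); stopifnot_scalar(end_az)
  if (step <= 0) stop("step must be positive", call. = FALSE)
  if (velocity <= 0) stop("velocity must be positive", call. = FALSE)
  span <- end_az - start_az
  if (span == 0) {
    direction <- "rightward"   # degenerate single-position path
  } else {
    direction <- if (span > 0) "rightward" else "leftward"
  }
  if (abs(span / step - round(span / step)) > 1e-9) {
    stop("end_az - start_az must be a whole multiple of step", call. = FALSE)
  }
  structure(
    list(start_az = start_az, end_az = end_az, step = step,
         velocity = velocity, direction = direction),
    class = "motion_path"
  )
}

#' @export
print.motion_path <- function(x, ...) {
  cat(sprintf(
    "<motion_path> %+g -> %+g deg (%s), step %g deg, %g deg/s, %.3g s\n",
    x$start_az, x$end_az, x$direction, x$step, x$velocity, total_duration(x)
  ))
  invisible(x)
}

#' Azimuths occupied by a motion path
#'
#' @param path a [motion_path()].
#' @return numeric vector of occupied grid azimuths, in traversal order
#'   (both endpoints included).
#' @export
path_azimuths <- function(path) {
  if (path$end_az == path$start_az) return(path$start_az)
  seq(path$start_az, path$end_az,
      by = path$step * sign(path$end_az - path$start_az))
}

#' Total duration of a quantized motion
#'
#' Every occupied position (endpoints included) is held for one
#' [segment_dwell()]: a -70..+70 sweep on a 5-degree grid occupies 29
#' positions, giving 5.8, 2.9 and 1.45 s at 25, 50 and 100 deg/s.
#'
#' @param path a [motion_path()].
#' @return duration in seconds.
#' @export
total_duration <- function(path) {
  n_pos <- length(path_azimuths(path))
  n_pos * segment_dwell(path$velocity, path$step)
}

#' Displace an auditory path behind or ahead of a visual trajectory
#'
#' The visual stimulus travels a fixed trajectory; the auditory stimulus is
#' displaced by the signed offset `mu` along the motion direction. Positive
#' `mu` is an auditory lag (the auditory path trails the visual one by `mu`
#' degrees; equivalently the visual stimulus leads in space), negative `mu`
#' an auditory lead. Step, velocity and direction are preserved.
#'
#' @param visual_path a [motion_path()] for the visual stimulus.
#' @param mu signed spatial offset, degrees.
#' @return a [motion_path()] for the auditory stimulus.
#' @export
#' @examples
#' v <- motion_path(-70, 70, 5, 50)
#' plan_trajectory(v, 10)$start_az   # -80: trails a rightward motion
plan_trajectory <- function(visual_path, mu) {
  stopifnot_scalar(mu)
  d <- if (visual_path$direction == "rightward") 1 else -1
  shift <- -mu * d       # "behind" is opposite the motion direction
  start_az <- visual_path$start_az + shift
  end_az <- visual_path$end_az + shift
  if (abs(start_az) > 90 || abs(end_az) > 90) {
    stop(sprintf(
      "offset %g deg pushes the auditory path (%g..%g) outside the measured -90..+90 grid",
      mu, start_az, end_az), call. = FALSE)
  }
  motion_path(start_az, end_az, visual_path$step, visual_path$velocity)
}

# centre frequencies of the carrier's bandpass bank: 400..16000 Hz in 200 Hz
# steps (79 bands)
#' Centre frequencies of the carrier filter bank
#'
#' @param band_lo,band_hi first and last centre frequency, Hz.
#' @param spacing centre-to-centre spacing, Hz.
#' @return numeric vector of centre frequencies.
#' @export
carrier_band_centers <- function(band_lo = 400, band_hi = 16000,
                                 spacing = 200) {
  seq(band_lo, band_hi, by = spacing)
}

#' Build the amplitude-modulated multiband noise carrier
#'
#' White noise passed through a bank of narrow bandpass filters (centres
#' from `band_lo` to `band_hi` at `spacing` Hz apart, each `bandwidth` Hz
#' wide at -3 dB, realised as a zero-phase raised-cosine-edged magnitude
#' mask in the frequency domain), then multiplied by a common full-depth
#' raised-sine envelope at `am_rate` Hz starting from the envelope minimum.
#' The coherent 20 Hz modulation across all bands promotes fusion of the
#' bands into a single auditory object.
#'
#' @param duration seconds.
#' @param fs sampling rate, Hz.
#' @param seed integer; fixes the noise realisation.
#' @param am_rate amplitude-modulation rate, Hz.
#' @param band_lo,band_hi,spacing filter-bank layout, Hz (see
#'   [carrier_band_centers()]).
#' @param bandwidth -3 dB full width of each band, Hz.
#' @param target_rms RMS level of the returned waveform.
#' @return mono numeric waveform of `round(duration * fs)` samples.
#' @export
make_carrier <- function(duration, fs = 48000, seed = 1L, am_rate = 20,
                         band_lo = 400, band_hi = 16000, spacing = 200,
                         bandwidth = 100, target_rms = 0.1) {
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  n <- round(duration * fs)
  noise <- withr::with_seed(seed, stats::rnorm(n))
  centers <- carrier_band_centers(band_lo, band_hi, spacing)
  f <- (0:(n - 1)) / n * fs
  ffold <- pmin(f, fs - f)
  # nearest band centre; bands do not overlap at this layout
  cf <- pmin(pmax(round((ffold - band_lo) / spacing), 0),
             length(centers) - 1) * spacing + band_lo
  dev <- abs(ffold - cf)
  # raised cosine in power between bandwidth/2 -/+ 40% transition, so the
  # half-power point sits exactly at bandwidth/2
  inner <- bandwidth / 2 * 0.6
  outer <- bandwidth / 2 * 1.4
  p <- numeric(n)
  p[dev <= inner] <- 1
  tr <- dev > inner & dev < outer
  p[tr] <- 0.5 + 0.5 * cos(pi * (dev[tr] - inner) / (outer - inner))
  mask <- sqrt(p)
  carrier <- Re(stats::fft(stats::fft(noise) * mask, inverse = TRUE)) / n
  t <- (seq_len(n) - 1) / fs
  envelope <- 0.5 - 0.5 * cos(2 * pi * am_rate * t)
  carrier <- carrier * envelope
  carrier * (target_rms / rms(carrier))
}

#' Render apparent auditory motion through a spatial filter grid
#'
#' Slices the carrier into consecutive dwell-length segments, convolves each
#' segment with the binaural filter pair at its azimuth, and joins segments
#' by overlap-add: the convolution tail of every segment rings into the
#' start of the next one (the tail of the final segment is appended), which
#' is the exact splice for piecewise time-invariant filtering — a constant
#' filter renders identically to one full convolution. A linear crossfade
#' join is available as an alternative. Segment sample counts follow the
#' cumulative-rounding rule `round(k * dwell * fs)` so timing drift never
#' exceeds half a sample.
#'
#' @param carrier mono waveform from [make_carrier()]; must cover the path's
#'   total duration.
#' @param path a [motion_path()] whose azimuths all lie on the filter grid.
#' @param filters a `spatial_filter_set` with `step` equal to the path's.
#' @param method `"overlap_add"` (default) or `"crossfade"`.
#' @param crossfade crossfade length in seconds (crossfade method only).
#' @param normalize if `TRUE`, peak-normalise the output to -1 dBFS.
#' @return a `binaural_stimulus`: list with `wave` (two-column matrix,
#'   left/right), `fs`, `path`, `segment_boundaries` (data frame of azimuth
#'   and first/last carrier sample per segment) and per-channel `rms`.
#' @export
render_motion <- function(carrier, path, filters,
                          method = c("overlap_add", "crossfade"),
                          crossfade = 0.001, normalize = FALSE) {
  method <- match.arg(method)
  if (abs(filters$step - path$step) > 1e-9) {
    stop("filter set step does not match path step", call. = FALSE)
  }
  az <- path_azimuths(path)
  idx <- vapply(az, function(a) {
    i <- which(abs(filters$azimuths - a) < 1e-6)
    if (length(i) != 1L) {
      stop(sprintf("azimuth %g deg is not in the filter set", a),
           call. = FALSE)
    }
    i
  }, integer(1))
  fs <- filters$fs
  dwell <- segment_dwell(path$velocity, path$step)
  bounds <- round(fs * dwell * (0:length(az)))
  n_total <- bounds[length(bounds)]
  if (length(carrier) < n_total) {
    stop(sprintf("carrier too short: need %d samples, got %d",
                 n_total, length(carrier)), call. = FALSE)
  }
  flen <- nrow(filters$left)
  out_len <- n_total + flen - 1
  left <- numeric(out_len)
  right <- numeric(out_len)
  n_fade <- max(2L, round(crossfade * fs))
  for (s in seq_along(az)) {
    seg <- carrier[(bounds[s] + 1):bounds[s + 1]]
    yl <- conv_full(seg, filters$left[, idx[s]])
    yr <- conv_full(seg, filters$right[, idx[s]])
    at <- bounds[s]
    if (method == "overlap_add") {
      span <- at + seq_along(yl)
      left[span] <- left[span] + yl
      right[span] <- right[span] + yr
    } else {
      # crossfade: ramp this segment's head against the previous tail
      if (s > 1L) {
        nf <- min(n_fade, length(yl))
        ramp <- seq(0, 1, length.out = nf)
        yl[seq_len(nf)] <- yl[seq_len(nf)] * ramp
        yr[seq_len(nf)] <- yr[seq_len(nf)] * ramp
        fade_span <- at + seq_len(nf)
        left[fade_span] <- left[fade_span] * rev(ramp)
        right[fade_span] <- right[fade_span] * rev(ramp)
      }
      keep <- if (s < length(az)) {
        min(length(yl), bounds[s + 1] - bounds[s] + n_fade)
      } else {
        length(yl)
      }
      span <- at + seq_len(keep)
      left[span] <- left[span] + yl[seq_len(keep)]
      right[span] <- right[span] + yr[seq_len(keep)]
    }
  }
  wave <- cbind(left = left, right = right)
  if (normalize) {
    peak <- max(abs(wave))
    if (peak > 0) wave <- wave * (10^(-1 / 20) / peak)
  }
  structure(
    list(
      wave = wave, fs = fs, path = path,
      segment_boundaries = data.frame(
        azimuth = az,
        start_sample = bounds[-length(bounds)] + 1,
        end_sample = bounds[-1]
      ),
      rms = c(left = rms(wave[, 1]), right = rms(wave[, 2]))
    ),
    class = "binaural_stimulus"
  )
}

#' @export
print.binaural_stimulus <- function(x, ...) {
  cat(sprintf(
    "<binaural_stimulus> %d segments, %.3g s @ %d Hz (rms L %.3g / R %.3g)\n",
    nrow(x$segment_boundaries), nrow(x$wave) / x$fs, as.integer(x$fs),
    x$rms[1], x$rms[2]
  ))
  print(x$path)
  invisible(x)
}
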