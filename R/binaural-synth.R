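#' Woodworth interaural time difference for a spherical head
#'
#' ITD of a distant source at lateral angle `azimuth` for a rigid sphere of
#' radius `head_radius`: `(a/c) * (theta + sin(theta))` with `theta = |azimuth|`
#' in radians, signed so that positive azimuths (source to the right) give a
#' positive ITD (right ear leads).
#'
#' @param azimuth degrees in \[-90, 90\]; 0 is straight ahead, positive right.
#' @param head_radius metres (default 0.0875, an average adult head).
#' @param speed_of_sound m/s.
#' @return ITD in seconds (vectorised over `azimuth`).
#' @export
#' @examples
#' woodworth_itd(90) * 1e6  # ~656 microseconds
woodworth_itd <- function(azimuth, head_radius = 0.0875, speed_of_sound = 343) {
  if (any(abs(azimuth) > 90)) {
    stop("azimuth must lie in [-90, 90] degrees", call. = FALSE)
  }
  if (head_radius <= 0) stop("head_radius must be positive", call. = FALSE)
  th <- abs(azimuth) * pi / 180
  sign(azimuth) * (head_radius / speed_of_sound) * (th + sin(th))
}

# Single-pole/single-zero head-shadow filter (spherical-head model):
# H(s) = (alpha * s + beta) / (s + beta), beta = 2c/a, discretised by the
# bilinear transform. alpha depends on the angle between the source and the
# ear axis: ~2 (high-shelf boost) at the ear, ~0.1 on the far side.
shadow_alpha <- function(incidence_deg) {
  1.05 + 0.95 * cos(incidence_deg * pi / 150)
}

apply_head_shadow <- function(x, incidence_deg, head_radius, fs,
                              speed_of_sound = 343) {
  alpha <- shadow_alpha(incidence_deg)
  beta <- 2 * speed_of_sound / head_radius
  b <- c(beta + 2 * fs * alpha, beta - 2 * fs * alpha) / (beta + 2 * fs)
  a <- c(1, (beta - 2 * fs) / (beta + 2 * fs))
  as.numeric(signal::filter(b, a, x))
}

#' Synthesise an anechoic binaural impulse-response pair
#'
#' Spherical-head stand-in for a measured head-related impulse response:
#' each ear receives a fractional-delay (windowed-sinc) pulse at the
#' Woodworth ITD for its side, shaped by a first-order head-shadow filter
#' whose high-frequency gain depends on the angle between source and ear.
#' At azimuth 0 the two ears are identical by construction.
#'
#' @param azimuth source lateral angle, degrees in \[-90, 90\].
#' @param head_radius metres.
#' @param fs sampling rate, Hz.
#' @param length output length in samples.
#' @param speed_of_sound m/s.
#' @param base_delay common causal lead-in, samples (leaves room for the
#'   anti-causal half of the sinc kernel).
#' @return an `ir_pair`: list with `left`, `right` (numeric, `length`
#'   samples), `fs`, `azimuth` and the applied `itd` in seconds.
#' @export
#' @examples
#' h <- synth_hrir(45)
#' h$itd * 1e6
synth_hrir <- function(azimuth, head_radius = 0.0875, fs = 48000,
                       length = 256L, speed_of_sound = 343,
                       base_delay = 48) {
  stopifnot_scalar(azimuth)
  if (abs(azimuth) > 90) stop("azimuth must lie in [-90, 90] degrees", call. = FALSE)
  if (head_radius <= 0) stop("head_radius must be positive", call. = FALSE)
  itd <- woodworth_itd(azimuth, head_radius, speed_of_sound)
  # positive itd: right ear leads, left ear delayed by |itd|
  delay_left <- base_delay + max(itd, 0) * fs
  delay_right <- base_delay + max(-itd, 0) * fs
  half_width <- min(32L, base_delay)
  pulse_l <- sinc_pulse(length, delay_left, half_width)
  pulse_r <- sinc_pulse(length, delay_right, half_width)
  left <- apply_head_shadow(pulse_l, abs(-90 - azimuth), head_radius, fs,
                            speed_of_sound)
  right <- apply_head_shadow(pulse_r, abs(90 - azimuth), head_radius, fs,
                             speed_of_sound)
  structure(
    list(left = left, right = right, fs = fs, azimuth = azimuth, itd = itd),
    class = "ir_pair"
  )
}

#' @export
print.ir_pair <- function(x, ...) {
  cat(sprintf(
    "<ir_pair> azimuth %+.1f deg, %d samples @ %d Hz\n",
    x$azimuth, length(x$left), as.integer(x$fs)
  ))
  invisible(x)
}

#' Specify a shoebox room for image-source synthesis
#'
#' Geometry and acoustics of a rectangular room. If `wall_absorption` is not
#' given it is derived from `target_rt60` with [sabine_absorption()]. The
#' default is a 3.4 x 2.5 x 2.0 m (17 m^3) room with a 200 ms target RT60,
#' the listener slightly off-centre so the nearest image (the ceiling) trails
#' the direct sound by about 2.5 ms, and sources on a 1 m frontal arc.
#'
#' Axes: x is the facing direction, y the interaural axis (positive = right),
#' z height. Azimuth 0 is straight ahead (+x), positive azimuths to the right.
#'
#' @param dimensions length-3 numeric, room edge lengths in metres.
#' @param listener_position length-3 numeric, ear-height listener position (m).
#' @param target_rt60 desired reverberation time, seconds.
#' @param wall_absorption energy absorption coefficient in (0, 1\] applied to
#'   all six surfaces; derived from `target_rt60` when `NULL`.
#' @param source_radius distance of sources from the listener, metres.
#' @param speed_of_sound m/s.
#' @return a `room_spec` object.
#' @export
#' @examples
#' room_spec()   # the default 17 m^3 room
room_spec <- function(dimensions = c(3.4, 2.5, 2.0),
                      listener_position = c(1.3, 1.15, 1.2),
                      target_rt60 = 0.2,
                      wall_absorption = NULL,
                      source_radius = 1.0,
                      speed_of_sound = 343) {
  if (length(dimensions) != 3L || any(dimensions <= 0)) {
    stop("dimensions must be 3 positive edge lengths (m)", call. = FALSE)
  }
  if (length(listener_position) != 3L) {
    stop("listener_position must be a 3-vector (m)", call. = FALSE)
  }
  if (any(listener_position <= 0) || any(listener_position >= dimensions)) {
    stop("listener must be strictly inside the room", call. = FALSE)
  }
  if (source_radius <= 0) stop("source_radius must be positive", call. = FALSE)
  if (!is.null(target_rt60) && target_rt60 <= 0) {
    stop("target_rt60 must be positive", call. = FALSE)
  }
  room <- structure(
    list(
      dimensions = as.numeric(dimensions),
      listener_position = as.numeric(listener_position),
      target_rt60 = target_rt60,
      wall_absorption = wall_absorption,
      source_radius = source_radius,
      speed_of_sound = speed_of_sound
    ),
    class = "room_spec"
  )
  if (is.null(wall_absorption)) {
    room$wall_absorption <- sabine_absorption(room)
  } else if (wall_absorption <= 0 || wall_absorption > 1) {
    stop("wall_absorption must lie in (0, 1]", call. = FALSE)
  }
  room
}

#' @export
print.room_spec <- function(x, ...) {
  d <- x$dimensions
  cat(sprintf(
    paste0(
      "<room_spec> %.2f x %.2f x %.2f m (V = %.2f m^3)\n",
      "  listener at (%.2f, %.2f, %.2f) m, sources on a %.2f m arc\n",
      "  wall absorption %.3f (target RT60 %s s)\n"
    ),
    d[1], d[2], d[3], prod(d),
    x$listener_position[1], x$listener_position[2], x$listener_position[3],
    x$source_radius, x$wall_absorption,
    if (is.null(x$target_rt60)) "-" else format(x$target_rt60)
  ))
  invisible(x)
}

#' Uniform wall absorption from a Sabine reverberation-time target
#'
#' Inverts the Sabine equation `RT60 = 0.161 V / (S alpha)` for the energy
#' absorption coefficient `alpha` shared by all six surfaces: `alpha =
#' 0.161 V / (S RT60)` with `V` the volume and `S` the total surface area.
#'
#' @param room a [room_spec()] with a positive `target_rt60`.
#' @return absorption coefficient in (0, 1\].
#' @export
#' @examples
#' sabine_absorption(room_spec())  # ~0.337 for the default room
sabine_absorption <- function(room) {
  if (is.null(room$target_rt60) || room$target_rt60 <= 0) {
    stop("room$target_rt60 must be positive", call. = FALSE)
  }
  d <- room$dimensions
  vol <- prod(d)
  surf <- 2 * (d[1] * d[2] + d[1] * d[3] + d[2] * d[3])
  alpha <- 0.161 * vol / (surf * room$target_rt60)
  if (alpha > 1) {
    stop(sprintf(
      paste0("infeasible room: Sabine absorption %.3f exceeds 1; ",
             "increase target_rt60 or enlarge the room"), alpha
    ), call. = FALSE)
  }
  alpha
}

# position of a source at `azimuth` degrees on the frontal arc
source_position <- function(room, azimuth) {
  az <- azimuth * pi / 180
  room$listener_position + room$source_radius * c(cos(az), sin(az), 0)
}

#' Enumerate image sources for a shoebox room
#'
#' Mirror-image virtual sources of the source at `azimuth` on the room's
#' frontal arc, up to `max_order` wall reflections. Each image carries its
#' reflection order, travel distance and delay, the lateral (interaural)
#' angle it arrives from, and its amplitude gain
#' `(1 - alpha)^(order/2) / distance` (energy loss `1 - alpha` per bounce,
#' spherical spreading referenced to 1 m).
#'
#' @param room a [room_spec()].
#' @param azimuth source azimuth, degrees.
#' @param max_order maximum total number of wall reflections (>= 0).
#' @param max_delay optional cutoff: drop images arriving after this many
#'   seconds.
#' @return data.frame with columns `order`, `distance` (m), `delay` (s),
#'   `gain`, `lateral_deg`, `x`, `y`, `z`, sorted by delay.
#' @export
image_sources <- function(room, azimuth, max_order, max_delay = NULL) {
  if (max_order < 0) stop("max_order must be >= 0", call. = FALSE)
  lp <- room$listener_position
  if (any(lp <= 0) || any(lp >= room$dimensions)) {
    stop("listener must be strictly inside the room", call. = FALSE)
  }
  src <- source_position(room, azimuth)
  if (any(src <= 0) || any(src >= room$dimensions)) {
    stop(sprintf("source at azimuth %g lies outside the room", azimuth),
         call. = FALSE)
  }
  n_max <- ceiling((max_order + 1) / 2)
  # per-dimension image coordinates and reflection counts:
  # coord = (1-2u) s + 2 n L, count = |2n - u|, u in {0,1}
  per_dim <- lapply(1:3, function(i) {
    g <- expand.grid(n = -n_max:n_max, u = 0:1)
    coord <- (1 - 2 * g$u) * src[i] + 2 * g$n * room$dimensions[i]
    cnt <- abs(2 * g$n - g$u)
    keep <- cnt <= max_order
    list(coord = coord[keep], cnt = cnt[keep])
  })
  idx <- expand.grid(
    i = seq_along(per_dim[[1]]$coord),
    j = seq_along(per_dim[[2]]$coord),
    k = seq_along(per_dim[[3]]$coord)
  )
  ord <- per_dim[[1]]$cnt[idx$i] + per_dim[[2]]$cnt[idx$j] +
    per_dim[[3]]$cnt[idx$k]
  keep <- ord <= max_order
  x <- per_dim[[1]]$coord[idx$i[keep]]
  y <- per_dim[[2]]$coord[idx$j[keep]]
  z <- per_dim[[3]]$coord[idx$k[keep]]
  ord <- ord[keep]
  dx <- x - lp[1]; dy <- y - lp[2]; dz <- z - lp[3]
  dist <- sqrt(dx^2 + dy^2 + dz^2)
  delay <- dist / room$speed_of_sound
  if (!is.null(max_delay)) {
    keep2 <- delay <= max_delay
    x <- x[keep2]; y <- y[keep2]; z <- z[keep2]
    ord <- ord[keep2]; dist <- dist[keep2]; delay <- delay[keep2]
    dy <- dy[keep2]
  }
  gain <- (1 - room$wall_absorption)^(ord / 2) / pmax(dist, 1e-6)
  lateral <- asin(pmax(-1, pmin(1, dy / pmax(dist, 1e-12)))) * 180 / pi
  out <- data.frame(
    order = ord, distance = dist, delay = delay, gain = gain,
    lateral_deg = lateral, x = x, y = y, z = z
  )
  out[order(out$delay), , drop = FALSE]
}

#' Synthesise a binaural room impulse response by the image-source method
#'
#' Builds the direct arrival plus all image-source reflections up to
#' `max_order` bounces. Each arrival is spatialised through [synth_hrir()]
#' at its lateral arrival angle, scaled by `(1 - alpha)^(order/2) / distance`
#' and placed at its propagation delay. The direct arrival uses the exact
#' source azimuth; reflections share head filters cached on a 1-degree
#' arrival-angle grid.
#'
#' @param room a [room_spec()].
#' @param azimuth source azimuth, degrees in \[-90, 90\].
#' @param max_order maximum reflection order (default 3, enough to populate
#'   the first ~21 ms of this room).
#' @param fs sampling rate, Hz.
#' @param duration output length in seconds; defaults to the latest image
#'   arrival plus the head-filter length.
#' @param hrir_length per-arrival head-filter length, samples.
#' @param head_radius metres.
#' @return an `ir_pair` with an `images` attribute holding the reflection
#'   census from [image_sources()].
#' @export
image_source_brir <- function(room, azimuth, max_order = 3L, fs = 48000,
                              duration = NULL, hrir_length = 128L,
                              head_radius = 0.0875) {
  imgs <- image_sources(room, azimuth, max_order,
                        max_delay = if (is.null(duration)) NULL else duration)
  if (!is.null(duration)) {
    imgs <- imgs[imgs$delay < duration, , drop = FALSE]
  }
  if (nrow(imgs) == 0L) stop("no image sources within duration", call. = FALSE)
  if (is.null(duration)) {
    duration <- max(imgs$delay) + (hrir_length + 2) / fs
  }
  n <- ceiling(duration * fs)
  left <- numeric(n)
  right <- numeric(n)
  cache <- new.env(parent = emptyenv())
  get_hrir <- function(lat, exact = FALSE) {
    lat_q <- if (exact) lat else round(lat)
    key <- format(lat_q, digits = 10)
    h <- cache[[key]]
    if (is.null(h)) {
      h <- synth_hrir(lat_q, head_radius = head_radius, fs = fs,
                      length = hrir_length,
                      speed_of_sound = room$speed_of_sound)
      cache[[key]] <- h
    }
    h
  }
  for (r in seq_len(nrow(imgs))) {
    g <- imgs$gain[r]
    if (g == 0) next
    h <- get_hrir(imgs$lateral_deg[r], exact = imgs$order[r] == 0L)
    start <- round(imgs$delay[r] * fs)
    span <- seq_len(min(hrir_length, n - start)) + start
    m <- length(span)
    if (m <= 0) next
    left[span] <- left[span] + g * h$left[seq_len(m)]
    right[span] <- right[span] + g * h$right[seq_len(m)]
  }
  structure(
    list(left = left, right = right, fs = fs, azimuth = azimuth,
         itd = woodworth_itd(azimuth, head_radius, room$speed_of_sound)),
    class = "ir_pair",
    images = imgs
  )
}

#' Generate an exponential sine sweep and its inverse filter
#'
#' Farina-style exponential (logarithmic) sweep from `f1` to `f2` with a
#' short raised-cosine onset/offset taper, plus its inverse filter. The
#' inverse is the amplitude-compensated time-reversed sweep computed by
#' regularised spectral inversion: unit round-trip gain across \[f1, f2\],
#' raised-cosine roll-off over a third of an octave outside the band, so
#' `sweep * inverse` (linear convolution) is a band-limited unit pulse whose
#' maximum falls at the object's `lag0` index.
#'
#' @param f1,f2 start and end frequencies, Hz, `0 < f1 < f2 < fs/2`.
#' @param duration sweep length, seconds.
#' @param fs sampling rate, Hz.
#' @param fade onset/offset raised-cosine taper length, seconds.
#' @return an `ess` object: list with `sweep`, `inverse`, `lag0` (index of
#'   zero lag in `conv(x, inverse)` for a recording `x` aligned with the
#'   sweep), `fs`, `f1`, `f2`, `duration`.
#' @export
ess_generate <- function(f1, f2, duration, fs = 48000, fade = 0.002) {
  if (!(f1 > 0 && f2 > f1 && f2 < fs / 2)) {
    stop("need 0 < f1 < f2 < fs/2", call. = FALSE)
  }
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  ratio <- log(f2 / f1)
  sweep <- sin(2 * pi * f1 * duration / ratio * (exp(t * ratio / duration) - 1))
  n_fade <- min(round(fade * fs), floor(n / 4))
  if (n_fade > 0) {
    ramp <- 0.5 - 0.5 * cos(pi * seq_len(n_fade) / n_fade)
    sweep[seq_len(n_fade)] <- sweep[seq_len(n_fade)] * ramp
    sweep[n - n_fade + seq_len(n_fade)] <-
      sweep[n - n_fade + seq_len(n_fade)] * rev(ramp)
  }
  nfft <- 2^ceiling(log2(2 * n))
  spec <- stats::fft(c(sweep, numeric(nfft - n)))
  f <- (0:(nfft - 1)) / nfft * fs
  ffold <- pmin(f, fs - f)
  lo <- f1 * 2^(-1 / 3)
  hi <- min(f2 * 2^(1 / 3), 0.98 * fs / 2)
  target <- numeric(nfft)
  target[ffold >= f1 & ffold <= f2] <- 1
  i <- ffold >= lo & ffold < f1
  target[i] <- 0.5 - 0.5 * cos(pi * (ffold[i] - lo) / (f1 - lo))
  i <- ffold > f2 & ffold <= hi
  target[i] <- 0.5 + 0.5 * cos(pi * (ffold[i] - f2) / (hi - f2))
  # delay margin keeps the inverse's slightly anti-causal high-frequency end
  # from wrapping circularly
  margin <- 2048
  delay <- n - 1 + margin
  k <- 0:(nfft - 1)
  target_c <- target * exp(-2i * pi * k * delay / nfft)
  beta <- 1e-6 * max(Mod(spec)^2)    # Tikhonov floor outside the band
  inv_spec <- target_c * Conj(spec) / (Mod(spec)^2 + beta)
  inverse <- Re(stats::fft(inv_spec, inverse = TRUE)) / nfft
  structure(
    list(sweep = sweep, inverse = inverse, lag0 = delay + 1, fs = fs,
         f1 = f1, f2 = f2, duration = duration),
    class = "ess"
  )
}

#' @export
print.ess <- function(x, ...) {
  cat(sprintf("<ess> %g-%g Hz, %.3g s @ %d Hz\n",
              x$f1, x$f2, x$duration, as.integer(x$fs)))
  invisible(x)
}

#' Recover an impulse response from a sweep recording
#'
#' Convolves a recording of the exponential sweep played through a linear
#' system with the sweep's inverse filter and reads the impulse response off
#' at zero lag: for `recording = sweep * h` the result approximates `h`
#' within the sweep band.
#'
#' @param recording numeric vector, the captured sweep response.
#' @param ess the [ess_generate()] object used for playback (or a raw
#'   inverse-filter vector, in which case zero lag is taken at its last
#'   sample).
#' @param ir_length number of impulse-response samples to return.
#' @param pre number of pre-onset samples to include before zero lag
#'   (captures the band-limiting pre-ringing; default 0).
#' @return numeric vector of length `pre + ir_length`, the recovered
#'   response with its zero-lag sample at position `pre + 1`.
#' @export
ess_deconvolve <- function(recording, ess, ir_length, pre = 0L) {
  if (inherits(ess, "ess")) {
    inverse <- ess$inverse
    lag0 <- ess$lag0
  } else {
    inverse <- as.numeric(ess)
    lag0 <- length(inverse)
  }
  if (ir_length <= 0) stop("ir_length must be positive", call. = FALSE)
  full <- conv_full(recording, inverse)
  idx <- (lag0 - pre) + seq_len(pre + ir_length) - 1
  out <- numeric(length(idx))
  ok <- idx >= 1 & idx <= length(full)
  out[ok] <- full[idx[ok]]
  out
}

# index of the direct-path onset: first sample within 20 dB of the peak
direct_onset <- function(x) {
  peak <- max(abs(x))
  if (peak == 0) stop("silent impulse response", call. = FALSE)
  which(abs(x) >= peak * 10^(-20 / 20))[1]
}

#' Truncate a room impulse response after its direct-path onset
#'
#' Keeps the first `keep` seconds following the direct-path onset (the first
#' sample within 20 dB of the peak) and discards the later tail, applying a
#' short raised-cosine fade at the cut to avoid a spectral splatter click.
#' Responses already shorter than the window are returned unchanged. Binaural
#' `ir_pair` inputs are cut at the earlier of the two ears' onsets so the
#' channels stay aligned.
#'
#' @param ir numeric vector or `ir_pair`.
#' @param keep seconds to preserve after the onset (default 0.021).
#' @param fs sampling rate, Hz (taken from the pair when `ir` is an
#'   `ir_pair`).
#' @param fade raised-cosine fade length at the cut, seconds.
#' @return object of the same shape as `ir`, truncated.
#' @export
truncate_brir <- function(ir, keep = 0.021, fs = NULL, fade = 0.001) {
  if (keep <= 0) stop("keep must be positive", call. = FALSE)
  if (inherits(ir, "ir_pair")) {
    fs <- ir$fs
    onset <- min(direct_onset(ir$left), direct_onset(ir$right))
    ir$left <- truncate_at(ir$left, onset, keep, fs, fade)
    ir$right <- truncate_at(ir$right, onset, keep, fs, fade)
    return(ir)
  }
  if (is.null(fs)) stop("fs is required for plain-vector input", call. = FALSE)
  truncate_at(ir, direct_onset(ir), keep, fs, fade)
}

truncate_at <- function(x, onset, keep, fs, fade) {
  last <- onset + round(keep * fs) - 1
  if (length(x) <= last) return(x)
  out <- x[seq_len(last)]
  n_fade <- min(round(fade * fs), length(out))
  if (n_fade > 1) {
    ramp <- 0.5 + 0.5 * cos(pi * seq_len(n_fade) / n_fade)
    out[last - n_fade + seq_len(n_fade)] <-
      out[last - n_fade + seq_len(n_fade)] * ramp
  }
  out
}

#' Build a binaural spatial filter set over the frontal azimuth span
#'
#' Constructs the grid of binaural impulse-response pairs covering -90..+90
#' degrees at a uniform `step`, either anechoic (spherical-head
#' [synth_hrir()] at every azimuth, 1-degree default step) or reverberant
#' (image-source [image_source_brir()] per azimuth, optionally passed through
#' a simulated exponential-sweep measurement round trip, then truncated to
#' the first 21 ms with [truncate_brir()]; 5-degree default step).
#'
#' @param mode `"anechoic"` or `"reverberant"`.
#' @param step azimuth grid spacing, degrees (must divide 180); defaults to 1
#'   for anechoic and 5 for reverberant sets.
#' @param room a [room_spec()]; required in reverberant mode.
#' @param fs sampling rate, Hz.
#' @param hrir_length anechoic filter length, samples.
#' @param head_radius metres.
#' @param max_order image-source reflection order for reverberant sets.
#' @param keep truncation window after the direct onset, seconds.
#' @param ess_roundtrip logical; if `TRUE` each reverberant response is
#'   measured through a simulated sweep playback/deconvolution chain rather
#'   than taken directly from the image-source model (a fidelity check on the
#'   measurement simulation, not required for rendering).
#' @param ess_band,ess_duration sweep band (Hz) and length (s) for the round
#'   trip.
#' @return a `spatial_filter_set`: list with `azimuths`, `step`, `fs`,
#'   `condition`, and `left`/`right` matrices (one column per azimuth).
#' @export
build_filter_set <- function(mode = c("anechoic", "reverberant"),
                             step = NULL, room = NULL, fs = 48000,
                             hrir_length = 256L, head_radius = 0.0875,
                             max_order = 3L, keep = 0.021,
                             ess_roundtrip = FALSE,
                             ess_band = c(300, 16000), ess_duration = 1) {
  mode <- match.arg(mode)
  if (is.null(step)) step <- if (mode == "anechoic") 1 else 5
  if (step <= 0 || abs(180 / step - round(180 / step)) > 1e-9) {
    stop("step must be a positive divisor of 180 degrees", call. = FALSE)
  }
  azimuths <- seq(-90, 90, by = step)
  if (mode == "anechoic") {
    pairs <- lapply(azimuths, function(az) {
      synth_hrir(az, head_radius = head_radius, fs = fs, length = hrir_length)
    })
  } else {
    if (is.null(room)) {
      stop("reverberant mode requires a room_spec", call. = FALSE)
    }
    sweep <- if (ess_roundtrip) {
      ess_generate(ess_band[1], ess_band[2], ess_duration, fs)
    }
    pairs <- lapply(azimuths, function(az) {
      brir <- image_source_brir(room, az, max_order = max_order, fs = fs,
                                head_radius = head_radius)
      if (ess_roundtrip) {
        len <- length(brir$left)
        brir$left <- ess_deconvolve(conv_full(sweep$sweep, brir$left),
                                    sweep, len)
        brir$right <- ess_deconvolve(conv_full(sweep$sweep, brir$right),
                                     sweep, len)
      }
      truncate_brir(brir, keep = keep)
    })
  }
  len <- max(vapply(pairs, function(p) length(p$left), integer(1)))
  left <- vapply(pairs, function(p) c(p$left, numeric(len - length(p$left))),
                 numeric(len))
  right <- vapply(pairs, function(p) c(p$right, numeric(len - length(p$right))),
                  numeric(len))
  if (!all(is.finite(left)) || !all(is.finite(right))) {
    stop("non-finite samples in generated filters", call. = FALSE)
  }
  structure(
    list(azimuths = azimuths, step = step, fs = fs, condition = mode,
         left = left, right = right),
    class = "spatial_filter_set"
  )
}

#' @export
print.spatial_filter_set <- function(x, ...) {
  cat(sprintf(
    "<spatial_filter_set> %s, %d azimuths (%+g..%+g deg, step %g), %d samples @ %d Hz\n",
    x$condition, length(x$azimuths), min(x$azimuths), max(x$azimuths),
    x$step, nrow(x$left), as.integer(x$fs)
  ))
  invisible(x)
}

#' Look up the impulse-response pair at one azimuth
#'
#' @param filters a `spatial_filter_set`.
#' @param azimuth degrees; must be a grid position of the set.
#' @return an `ir_pair`.
#' @export
filter_pair <- function(filters, azimuth) {
  i <- which(abs(filters$azimuths - azimuth) < 1e-6)
  if (length(i) != 1L) {
    stop(sprintf("azimuth %g deg is not in the filter set", azimuth),
         call. = FALSE)
  }
  structure(
    list(left = filters$left[, i], right = filters$right[, i],
         fs = filters$fs, azimuth = filters$azimuths[i]),
    class = "ir_pair"
  )
}

#' Write a filter set as per-azimuth stereo WAV files
#'
#' One float32 stereo file per azimuth named `az{+DDD}.wav` (e.g.
#' `az+005.wav`, `az-090.wav`), left ear in channel 1.
#'
#' @param filters a `spatial_filter_set`.
#' @param dir output directory (created if missing).
#' @return the vector of file paths, invisibly.
#' @export
write_filter_set <- function(filters, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(seq_along(filters$azimuths), function(i) {
    p <- file.path(dir, sprintf("az%+04d.wav", round(filters$azimuths[i])))
    write_wav(cbind(filters$left[, i], filters$right[, i]), filters$fs, p)
    p
  }, character(1))
  invisible(paths)
}

#' Read a filter set written by [write_filter_set()]
#'
#' @param dir directory of `az{+DDD}.wav` files.
#' @param condition label for the loaded set (`"anechoic"` or
#'   `"reverberant"`).
#' @return a `spatial_filter_set`.
#' @export
read_filter_set <- function(dir, condition = "anechoic") {
  files <- list.files(dir, pattern = "^az[+-][0-9]{3}\\.wav$",
                      full.names = TRUE)
  if (length(files) < 2L) stop("no filter WAV files found", call. = FALSE)
  az <- as.numeric(sub("^az([+-][0-9]{3})\\.wav$", "\\1", basename(files)))
  o <- order(az)
  az <- az[o]
  files <- files[o]
  waves <- lapply(files, read_wav)
  fs <- waves[[1]]$fs
  len <- max(vapply(waves, function(w) nrow(w$wave), integer(1)))
  pad <- function(v) c(v, numeric(len - length(v)))
  left <- vapply(waves, function(w) pad(w$wave[, 1]), numeric(len))
  right <- vapply(waves, function(w) pad(w$wave[, 2]), numeric(len))
  steps <- diff(az)
  if (max(abs(steps - steps[1])) > 1e-9) {
    stop("azimuth grid in directory is not uniform", call. = FALSE)
  }
  structure(
    list(azimuths = az, step = steps[1], fs = fs, condition = condition,
         left = left, right = right),
    class = "spatial_filter_set"
  )
}
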