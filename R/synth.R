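# Parametric 12-lead ECG simulator.
#
# Beats are sums of Gaussian bumps (P, Q, R, S, T).  The frontal-plane signal
# is a two-component dipole whose QRS bumps point along the frontal QRS axis
# theta_R, the T bump along theta_T, and the P bump along a fixed atrial
# axis.  Limb leads I and II are projections of that dipole onto the hexaxial
# directions 0 deg and 60 deg; III, aVR, aVL, aVF are derived through the
# Einthoven/Goldberger identities so those hold exactly by construction.
# Chest leads V1-V6 are fixed linear mixtures of the wave signals through
# pseudo-electrode angles in a horizontal half-plane, so their morphology
# depends on both axes and on QRS width.

#' Standard lead names
#'
#' `LEAD_NAMES` is the canonical 12-lead order used throughout the package;
#' `TARGET_LEADS` drops Lead I (the input) and is the fixed row order of
#' every 11-lead reconstruction target.
#' @export
LEAD_NAMES <- c("I", "II", "III", "aVR", "aVL", "aVF",
                "V1", "V2", "V3", "V4", "V5", "V6")

#' @rdname LEAD_NAMES
#' @export
TARGET_LEADS <- LEAD_NAMES[-1]

# pseudo-electrode angles (degrees) for V1..V6 and per-wave projection gains
PRECORDIAL_ANGLES <- c(V1 = 115, V2 = 95, V3 = 75, V4 = 55, V5 = 35, V6 = 15)
PRECORDIAL_W_QRS <- c(0.8, 1.1, 1.3, 1.4, 1.2, 1.0)
PRECORDIAL_W_T <- c(0.5, 0.8, 0.9, 0.9, 0.8, 0.7)
P_AXIS_DEG <- 50   # fixed atrial axis for the P wave

#' Beat morphology: Gaussian-bump parameters for the five ECG waves
#'
#' Wave centers are offsets from the R peak in ms, amplitudes are signed mV,
#' and widths are Gaussian standard deviations in ms.  The Q/R/S widths and
#' the Q/S offsets scale with the QRS duration: the R bump has
#' `sigma = qrs_duration_ms / 12` (so +/-3 sigma spans half the QRS
#' envelope), Q and S have `sigma = qrs_duration_ms / 16` and sit at
#' `-/+ 0.25 * qrs_duration_ms`.
#'
#' @param qrs_duration_ms QRS duration in ms (> 0).
#' @param r_amp,q_amp,s_amp,p_amp,t_amp wave amplitudes in mV; `r_amp` must
#'   be positive.
#' @param p_center,t_center P/T centers relative to the R peak (ms).
#' @param p_width,t_width P/T Gaussian sigmas (ms).
#' @return An object of class `beat_morphology`: a data frame with one row
#'   per wave (`P`, `Q`, `R`, `S`, `T`) and columns `center`, `amp`, `width`.
#' @export
beat_morphology <- function(qrs_duration_ms = 90,
                            r_amp = 1.1, q_amp = -0.12, s_amp = -0.25,
                            p_amp = 0.12, t_amp = 0.35,
                            p_center = -170, t_center = 300,
                            p_width = 22, t_width = 60) {
  if (qrs_duration_ms <= 0) stop("qrs_duration_ms must be > 0")
  if (r_amp <= 0) stop("R amplitude must be > 0")
  m <- data.frame(
    wave = c("P", "Q", "R", "S", "T"),
    center = c(p_center, -0.25 * qrs_duration_ms, 0,
               0.25 * qrs_duration_ms, t_center),
    amp = c(p_amp, q_amp, r_amp, s_amp, t_amp),
    width = c(p_width, qrs_duration_ms / 16, qrs_duration_ms / 12,
              qrs_duration_ms / 16, t_width))
  if (any(m$width <= 0)) stop("wave widths must be > 0")
  if (any(diff(m$center) <= 0))
    stop("wave centers must be strictly ordered P < Q < R < S < T")
  class(m) <- c("beat_morphology", "data.frame")
  m
}

#' Subject-level parameters of the simulator
#'
#' @param theta_r frontal QRS axis in degrees, in (-180, 180].
#' @param theta_t frontal T axis in degrees, in (-180, 180].
#' @param heart_rate heart rate in bpm (> 0).
#' @param qrs_duration QRS duration in ms (> 0).
#' @param rr_jitter beat-to-beat multiplicative RR jitter (SD, fraction of
#'   the RR interval); draws are truncated at +/- 3 SD.
#' @param noise_amp additive Gaussian noise SD (mV) applied to the dipole
#'   components and chest leads.
#' @param baseline_amp amplitude of an optional 0.25-Hz baseline-wander sine
#'   (mV) added to the dipole.
#' @param w_qrs,w_t chest-lead projection gains, 6 values per wave-axis pair
#'   (QRS and T).
#' @param duration record duration in seconds.
#' @param fs sampling rate in Hz (500 or 100).
#' @return An object of class `subject_params` (a named list).
#' @export
subject_params <- function(theta_r = 45, theta_t = 40, heart_rate = 72,
                           qrs_duration = 90, rr_jitter = 0,
                           noise_amp = 0, baseline_amp = 0,
                           w_qrs = PRECORDIAL_W_QRS, w_t = PRECORDIAL_W_T,
                           duration = 10, fs = 500) {
  check_angle <- function(x, nm) {
    if (!is.finite(x) || x <= -180 || x > 180)
      stop(nm, " must lie in (-180, 180]")
  }
  check_angle(theta_r, "theta_r"); check_angle(theta_t, "theta_t")
  if (heart_rate <= 0) stop("heart_rate must be > 0")
  if (qrs_duration <= 0) stop("qrs_duration must be > 0")
  if (!fs %in% c(500, 100)) stop("fs must be 500 or 100 Hz")
  if (length(w_qrs) != 6 || length(w_t) != 6)
    stop("w_qrs and w_t must have 6 entries each")
  structure(list(theta_r = theta_r, theta_t = theta_t,
                 heart_rate = heart_rate, qrs_duration = qrs_duration,
                 rr_jitter = rr_jitter, noise_amp = noise_amp,
                 baseline_amp = baseline_amp, w_qrs = w_qrs, w_t = w_t,
                 duration = duration, fs = fs),
            class = "subject_params")
}

#' 12-lead ECG record container
#'
#' @param signal numeric 12 x T matrix in mV, rows named with the standard
#'   leads `I, II, III, aVR, aVL, aVF, V1..V6`.
#' @param fs sampling rate in Hz.
#' @param meta named list of raw metadata (`RAxis`, `TAxis`,
#'   `VentricularRate`, `QRSCount`, `QRSDuration`), possibly with `NA`s.
#' @param id record identifier.
#' @param params optional generating [subject_params()] (ground truth).
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(signal, fs, meta = NULL, id = "rec", params = NULL) {
  if (!is.matrix(signal) || nrow(signal) != 12)
    stop("signal must be a 12 x T matrix")
  if (is.null(rownames(signal))) rownames(signal) <- LEAD_NAMES
  if (!identical(rownames(signal), LEAD_NAMES))
    stop("signal rows must be named exactly ",
         paste(LEAD_NAMES, collapse = ", "))
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive")
  structure(list(id = id, signal = signal, fs = fs, meta = meta,
                 params = params),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record '%s'> 12 leads x %d samples @ %g Hz (%.2f s)\n",
              x$id, ncol(x$signal), x$fs, ncol(x$signal) / x$fs))
  if (!is.null(x$meta))
    cat("  metadata:",
        paste(names(x$meta), unlist(x$meta), sep = "=", collapse = ", "),
        "\n")
  invisible(x)
}

#' Evaluate a single beat as a sum of Gaussian bumps
#'
#' The beat is evaluated on a sample grid spanning +/- 3 sigma beyond the
#' outermost wave centers, so the waveform is (numerically) zero outside
#' that support.
#'
#' @param morph a [beat_morphology()].
#' @param fs sampling rate in Hz (> 0).
#' @return A list with `offsets` (sample offsets relative to the R peak) and
#'   `values` (mV).
#' @export
generate_beat <- function(morph, fs) {
  stopifnot(inherits(morph, "beat_morphology"))
  if (fs <= 0) stop("fs must be > 0")
  if (any(morph$width <= 0)) stop("wave widths must be > 0")
  lo <- floor((min(morph$center - 3 * morph$width)) / 1000 * fs)
  hi <- ceiling((max(morph$center + 3 * morph$width)) / 1000 * fs)
  k <- lo:hi
  t_ms <- k / fs * 1000
  v <- rep(0, length(k))
  for (i in seq_len(nrow(morph)))
    v <- v + morph$amp[i] *
      exp(-(t_ms - morph$center[i])^2 / (2 * morph$width[i]^2))
  list(offsets = k, values = v)
}

#' Project a frontal-plane dipole onto the six limb leads
#'
#' Leads I and II are projections of the (rotated) dipole onto the hexaxial
#' directions 0 deg and 60 deg; the remaining four are derived through the
#' Einthoven/Goldberger identities `III = II - I`, `aVR = -(I + II)/2`,
#' `aVL = I - II/2`, `aVF = II - I/2`, which therefore hold exactly.
#'
#' @param dipole numeric 2 x T matrix: frontal-plane dipole components along
#'   0 deg (row 1) and 90 deg (row 2, ECG convention: positive toward aVF).
#' @param theta additional rotation of the dipole in degrees (default 0).
#' @return A 6 x T matrix with rows `I, II, III, aVR, aVL, aVF` (mV).
#' @export
project_frontal_leads <- function(dipole, theta = 0) {
  if (!is.matrix(dipole) || nrow(dipole) != 2)
    stop("dipole must be a 2 x T matrix")
  if (!all(is.finite(dipole))) stop("dipole must be finite")
  th <- theta * pi / 180
  dx <- cos(th) * dipole[1, ] - sin(th) * dipole[2, ]
  dy <- sin(th) * dipole[1, ] + cos(th) * dipole[2, ]
  I <- dx
  II <- cos(pi / 3) * dx + sin(pi / 3) * dy
  out <- rbind(I = I, II = II, III = II - I, aVR = -(I + II) / 2,
               aVL = I - II / 2, aVF = II - I / 2)
  out
}

# Add Gaussian bumps for one wave group at given beat times onto a length-T
# zero vector; evaluated only on +/- 4 sigma local support for speed.
.add_bumps <- function(n, fs, beat_times, center_ms, amp, width_ms) {
  v <- numeric(n)
  w_s <- width_ms / 1000
  c_s <- center_ms / 1000
  for (bt in beat_times) {
    mu <- bt + c_s
    i0 <- max(1L, floor((mu - 4 * w_s) * fs) + 1L)
    i1 <- min(n, ceiling((mu + 4 * w_s) * fs) + 1L)
    if (i0 > i1) next
    tt <- (i0:i1 - 1L) / fs
    v[i0:i1] <- v[i0:i1] + amp * exp(-(tt - mu)^2 / (2 * w_s^2))
  }
  v
}

#' Generate one synthetic 12-lead ECG record
#'
#' Beats are placed at the stated heart rate (with optional multiplicative
#' RR jitter truncated at +/- 3 SD) starting at 0.42 of one RR interval.
#' The emitted ground-truth metadata are `QRSCount` = number of placed
#' beats, `VentricularRate = 6 * QRSCount`, and the axes / QRS duration
#' copied from `params`.
#'
#' @param params a [subject_params()].
#' @param morph a [beat_morphology()]; defaults to
#'   `beat_morphology(params$qrs_duration)`.
#' @param seed integer seed; required (reproducibility contract).
#' @param id record identifier.
#' @return An [ecg_record()] with ground-truth metadata and `params`.
#' @export
generate_record <- function(params, morph = NULL, seed, id = "rec") {
  stopifnot(inherits(params, "subject_params"))
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  if (is.null(morph)) morph <- beat_morphology(params$qrs_duration)
  fs <- params$fs
  n <- round(params$duration * fs)
  rr <- 60 / params$heart_rate
  if (params$duration < rr) stop("duration must cover at least one beat")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  # beat placement
  beat_times <- numeric(0)
  t_cur <- 0.42 * rr
  while (t_cur < params$duration) {
    beat_times <- c(beat_times, t_cur)
    jit <- 0
    if (params$rr_jitter > 0) {
      jit <- stats::rnorm(1, 0, params$rr_jitter)
      jit <- max(min(jit, 3 * params$rr_jitter), -3 * params$rr_jitter)
    }
    t_cur <- t_cur + rr * (1 + jit)
  }
  qrs_count <- length(beat_times)

  # per-wave-group scalar signals
  grp <- function(wn) {
    v <- numeric(n)
    for (w in wn) {
      row <- morph[morph$wave == w, ]
      v <- v + .add_bumps(n, fs, beat_times, row$center, row$amp, row$width)
    }
    v
  }
  s_p <- grp("P"); s_qrs <- grp(c("Q", "R", "S")); s_t <- grp("T")

  deg <- pi / 180
  dx <- s_qrs * cos(params$theta_r * deg) + s_t * cos(params$theta_t * deg) +
    s_p * cos(P_AXIS_DEG * deg)
  dy <- s_qrs * sin(params$theta_r * deg) + s_t * sin(params$theta_t * deg) +
    s_p * sin(P_AXIS_DEG * deg)
  if (params$baseline_amp > 0) {
    tt <- (seq_len(n) - 1) / fs
    wander <- params$baseline_amp * sin(2 * pi * 0.25 * tt +
                                        stats::runif(1, 0, 2 * pi))
    dx <- dx + wander; dy <- dy + 0.5 * wander
  }
  if (params$noise_amp > 0) {
    dx <- dx + stats::rnorm(n, 0, params$noise_amp)
    dy <- dy + stats::rnorm(n, 0, params$noise_amp)
  }
  limb <- project_frontal_leads(rbind(dx, dy), theta = 0)

  chest <- matrix(0, 6, n)
  for (k in 1:6) {
    phi <- PRECORDIAL_ANGLES[k] * deg
    chest[k, ] <- params$w_qrs[k] * s_qrs * cos(params$theta_r * deg - phi) +
      params$w_t[k] * s_t * cos(params$theta_t * deg - phi) +
      0.15 * s_p * cos(P_AXIS_DEG * deg - phi)
    if (params$noise_amp > 0)
      chest[k, ] <- chest[k, ] + stats::rnorm(n, 0, params$noise_amp)
  }
  signal <- rbind(limb, chest)
  rownames(signal) <- LEAD_NAMES

  meta <- list(RAxis = params$theta_r, TAxis = params$theta_t,
               VentricularRate = 6 * qrs_count, QRSCount = qrs_count,
               QRSDuration = params$qrs_duration)
  rec <- ecg_record(signal, fs, meta = meta, id = id, params = params)
  rec$beat_times <- beat_times
  rec
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# sample subject parameters; stratified mode cycles every Table-driven
# category and switches jitter/noise off so the targeted categories are hit
# exactly.
.sample_params <- function(i, stratified, fs, duration) {
  runifa <- function(lo, hi) stats::runif(1, lo, hi)
  axis_cats <- list(Normal = c(-30, 90), Left = c(-89, -31),
                    Right = c(91, 179), Extreme = c(-179, -91))
  if (stratified) {
    ra <- axis_cats[[(i - 1L) %% 4L + 1L]]
    ta <- axis_cats[[((i - 1L) %/% 4L) %% 4L + 1L]]
    qd <- if (((i - 1L) %/% 16L) %% 2L == 0L) c(75, 110) else c(125, 160)
    hr_rng <- switch(((i - 1L) %/% 32L) %% 3L + 1L,
                     c(62, 95), c(40, 54), c(105, 150))
    subject_params(theta_r = runifa(ra[1], ra[2]),
                   theta_t = runifa(ta[1], ta[2]),
                   heart_rate = runifa(hr_rng[1], hr_rng[2]),
                   qrs_duration = runifa(qd[1], qd[2]),
                   rr_jitter = 0, noise_amp = 0,
                   duration = duration, fs = fs)
  } else {
    subject_params(theta_r = runifa(-175, 175),
                   theta_t = runifa(-175, 175),
                   heart_rate = runifa(45, 140),
                   qrs_duration = min(max(stats::rnorm(1, 95, 20), 65), 175),
                   rr_jitter = 0.02, noise_amp = 0.02,
                   duration = duration, fs = fs)
  }
}

#' Generate a synthetic dataset with a 70/15/15 record-level split
#'
#' Per-record seeds are derived deterministically from the master seed.  The
#' default sampler draws both frontal axes uniformly over (-175, 175) deg,
#' heart rate uniformly in 45-140 bpm, QRS duration from a clipped normal
#' (95 +/- 20 ms), with 2% RR jitter and 0.02 mV noise; `stratified = TRUE`
#' instead cycles deterministically through every discretization category of
#' every feature (with jitter and noise off, so each record lands exactly in
#' its targeted category).
#'
#' @param n number of records (>= 10).
#' @param seed master integer seed (required).
#' @param stratified cycle through all metadata categories?
#' @param fs sampling rate (Hz), 500 or 100.
#' @param duration record duration (s).
#' @param param_sampler optional function `(i) -> subject_params` overriding
#'   the built-in sampler.
#' @return A list with `records` (list of [ecg_record()]) and `split`
#'   (factor with levels train/val/test, one per record).
#' @export
generate_dataset <- function(n, seed, stratified = FALSE, fs = 500,
                             duration = 10, param_sampler = NULL) {
  if (n < 10) stop("n must be >= 10")
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  rec_seeds <- sample.int(.Machine$integer.max - 1L, n)
  records <- vector("list", n)
  for (i in seq_len(n)) {
    p <- if (is.null(param_sampler)) .sample_params(i, stratified, fs, duration)
         else param_sampler(i)
    if (!inherits(p, "subject_params")) stop("param_sampler must return subject_params")
    records[[i]] <- generate_record(p, seed = rec_seeds[i],
                                    id = sprintf("synth%05d", i))
  }
  split <- split_dataset(n, seed = rec_seeds[1] %% 100000L + 1L)
  list(records = records, split = split)
}

#' Estimate the frontal QRS axis from leads I and aVF
#'
#' Signed areas of leads I and aVF over +/- `window_ms` around detected R
#' peaks are combined as `atan2(aVF * 2/sqrt(3), I)`; the 2/sqrt(3) factor
#' undoes the Goldberger amplitude of aVF so a pure dipole at angle theta is
#' recovered exactly.
#'
#' @param record an [ecg_record()].
#' @param window_ms half-window around each R peak (ms).
#' @return Estimated axis in degrees, in (-180, 180].
#' @export
estimate_frontal_axis <- function(record, window_ms = 60) {
  # detect beats on the frontal dipole magnitude, which is invariant to the
  # axis itself (lead II alone loses the QRS when theta is perpendicular)
  mag <- sqrt(record$signal["I", ]^2 +
              (2 / sqrt(3) * record$signal["aVF", ])^2)
  peaks <- detect_r_peaks(mag, record$fs)
  if (length(peaks) == 0) stop("no R peaks found")
  w <- round(window_ms / 1000 * record$fs)
  n <- ncol(record$signal)
  a_i <- 0; a_f <- 0
  for (p in peaks) {
    i0 <- max(1, p - w); i1 <- min(n, p + w)
    a_i <- a_i + sum(record$signal["I", i0:i1])
    a_f <- a_f + sum(record$signal["aVF", i0:i1])
  }
  th <- atan2(a_f * 2 / sqrt(3), a_i) * 180 / pi
  if (th <= -180) th <- th + 360
  th
}
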