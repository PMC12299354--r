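#' Parameters of the synthetic pronation-supination cohort generator
#'
#' The simulator emulates variable-length wrist-accelerometer recordings of
#' the alternating pronation-supination task (UPDRS 3.6). Each session is a
#' gravity vector rotated about the forearm axis by an oscillating wrist angle,
#' plus a tangential acceleration term proportional to the angular
#' acceleration, white sensor noise, and -- for dyskinesia-positive sessions --
#' an irregular band-limited choreiform overlay with slow amplitude modulation
#' and sporadic jerk transients.
#'
#' @param n_subjects Number of subjects (default 60).
#' @param sessions_per_subject Integer range `c(min, max)` (default 2-6).
#' @param prevalence Fraction of dyskinesia-positive sessions (default 0.3).
#' @param sample_rate Sampling rate, Hz (default 50).
#' @param duration Session duration range, seconds (default 10-30).
#' @param task_freq Alternating-rotation frequency range, Hz (default 0.8-2.0).
#' @param task_amplitude Tangential-acceleration amplitude range, g
#'   (default 0.3-0.8); the angular amplitude of the wrist rotation is tied to
#'   it (1.2 x amplitude, radians).
#' @param dysk_severity Dyskinesia severity dial in [0, 1]; 0 collapses the
#'   two classes (default 1).
#' @param dysk_band Frequency band of the choreiform overlay, Hz (default 1-4).
#' @param dysk_am_depth Amplitude-modulation depth of the overlay (default 0.3).
#' @param jerk_rate Poisson rate of jerk transients, events/s (default 0.5).
#' @param noise_sd White sensor-noise sd, g (default 0.02).
#' @param gravity_dir Unit 3-vector of gravity in the device frame
#'   (default +z).
#' @param dataset_tag Cohort label written to sessions and manifest.
#' @param seed Integer master seed.
#' @return Validated list of class `synth_params`.
#' @export
synth_params <- function(n_subjects = 60L,
                         sessions_per_subject = c(2L, 6L),
                         prevalence = 0.3,
                         sample_rate = 50,
                         duration = c(10, 30),
                         task_freq = c(0.8, 2.0),
                         task_amplitude = c(0.3, 0.8),
                         dysk_severity = 1.0,
                         dysk_band = c(1, 4),
                         dysk_am_depth = 0.3,
                         jerk_rate = 0.5,
                         noise_sd = 0.02,
                         gravity_dir = c(0, 0, 1),
                         dataset_tag = "synthetic_source",
                         seed = 1L) {
  p <- list(n_subjects = as.integer(n_subjects),
            sessions_per_subject = as.integer(sessions_per_subject),
            prevalence = prevalence, sample_rate = sample_rate,
            duration = duration, task_freq = task_freq,
            task_amplitude = task_amplitude, dysk_severity = dysk_severity,
            dysk_band = dysk_band, dysk_am_depth = dysk_am_depth,
            jerk_rate = jerk_rate, noise_sd = noise_sd,
            gravity_dir = gravity_dir / sqrt(sum(gravity_dir^2)),
            dataset_tag = dataset_tag, seed = as.integer(seed))
  stopifnot(p$n_subjects > 0,
            length(p$sessions_per_subject) == 2L,
            all(p$sessions_per_subject > 0),
            p$prevalence > 0, p$prevalence < 1,
            p$sample_rate > 0,
            all(p$duration > 0), all(p$task_freq > 0),
            all(p$task_amplitude > 0),
            p$dysk_severity >= 0, p$dysk_severity <= 1,
            all(p$dysk_band > 0), p$dysk_am_depth >= 0,
            p$jerk_rate >= 0, p$noise_sd >= 0)
  class(p) <- "synth_params"
  p
}

#' Shifted-site variant of a parameter set
#'
#' A transfer-target preset emulating a different collection site: doubled
#' sensor noise, 30 Hz sampling and a rotated device gravity direction.
#'
#' @param params A `synth_params` object.
#' @return Modified `synth_params`.
#' @export
shifted_site_params <- function(params = synth_params()) {
  params$noise_sd <- params$noise_sd * 2
  params$sample_rate <- 30
  ang <- 25 * pi / 180
  R <- matrix(c(cos(ang), 0, sin(ang), 0, 1, 0, -sin(ang), 0, cos(ang)),
              3, 3, byrow = TRUE)
  params$gravity_dir <- as.numeric(R %*% params$gravity_dir)
  params$dataset_tag <- "synthetic_shifted"
  params
}

# FFT band-pass of white noise, unit-RMS output (zero outside [lo, hi] Hz).
bandlimited_noise <- function(n, fs, lo, hi) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  freqs <- (seq_len(n) - 1) * fs / n
  freqs <- pmin(freqs, fs - freqs)       # two-sided
  W[freqs < lo | freqs > hi] <- 0
  b <- Re(stats::fft(W, inverse = TRUE)) / n
  s <- stats::sd(b)
  if (s == 0) rep(0, n) else b / s
}

#' Generate one synthetic session
#'
#' Signal model: wrist angle `theta(t) = theta_A * sin(2 pi f t + phi)` about
#' the forearm (x) axis; acceleration = rotated gravity + tangential term
#' proportional to `theta''(t)` (peak `task_amplitude` g, on the tangent axis)
#' + white noise. Dyskinesia-positive sessions additionally receive, on each
#' axis, band-limited stochastic oscillation in `dysk_band` with slow amplitude
#' modulation (overall scale `dysk_severity * task_amplitude`), plus Poisson
#' jerk transients. Fully determined by `seed`; a severity of 0 generates the
#' identical signal for either label.
#'
#' @param params A [synth_params()] object.
#' @param label Binary dyskinesia label.
#' @param seed Integer seed for this session.
#' @param session_id,subject_id Identifiers.
#' @param subject Optional list of per-subject random effects
#'   (`amp`, `freq`, `gravity_dir`) as drawn by [generate_cohort()].
#' @return An [accel_session()] with `sim` holding the drawn ground truth.
#' @export
generate_session <- function(params, label, seed,
                             session_id = "S000_01", subject_id = "SUBJ000",
                             subject = NULL) {
  stopifnot(inherits(params, "synth_params"), label %in% c(0, 1))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  dur <- stats::runif(1, params$duration[1], params$duration[2])
  f <- if (is.null(subject)) stats::runif(1, params$task_freq[1], params$task_freq[2])
       else subject$freq
  amp <- if (is.null(subject))
    stats::runif(1, params$task_amplitude[1], params$task_amplitude[2])
  else subject$amp
  gdir <- if (is.null(subject)) params$gravity_dir else subject$gravity_dir
  fs <- params$sample_rate
  n <- max(3L, round(dur * fs))
  t <- (seq_len(n) - 1) / fs
  phi <- stats::runif(1, 0, 2 * pi)

  theta_A <- 1.2 * amp
  theta <- theta_A * sin(2 * pi * f * t + phi)
  # gravity rotated about the forearm (x) axis
  gx <- rep(gdir[1], n)
  gy <- cos(theta) * gdir[2] + sin(theta) * gdir[3]
  gz <- -sin(theta) * gdir[2] + cos(theta) * gdir[3]
  # tangential acceleration, proportional to theta'' with peak task amplitude;
  # the sign (sensor mounting side) is chosen so it adds to, rather than
  # cancels, the gravity-rotation oscillation on the tangent axis
  a_tan <- amp * sin(2 * pi * f * t + phi)
  acc <- cbind(x = gx, y = gy + a_tan, z = gz)

  if (label == 1 && params$dysk_severity > 0) {
    scale <- params$dysk_severity * amp
    psi <- stats::runif(1, 0, 2 * pi)
    am <- 1 + params$dysk_am_depth * sin(2 * pi * 0.25 * t + psi)
    for (ax in 1:3) {
      b <- bandlimited_noise(n, fs, params$dysk_band[1], params$dysk_band[2])
      acc[, ax] <- acc[, ax] + 0.5 * scale * am * b
    }
    n_jerk <- stats::rpois(1, params$jerk_rate * dur)
    if (n_jerk > 0) for (j in seq_len(n_jerk)) {
      u <- stats::runif(1, 0, dur)
      w <- stats::runif(1, 0.08, 0.25)
      a <- scale * stats::runif(1, 0.8, 2.0)
      d <- stats::rnorm(3); d <- d / sqrt(sum(d^2))
      pulse <- a * exp(-((t - u) / (w / 2))^2) * sin(2 * pi * 6 * (t - u))
      acc <- acc + outer(pulse, d)
    }
  }
  if (params$noise_sd > 0)
    acc <- acc + matrix(stats::rnorm(3 * n, 0, params$noise_sd), n, 3)

  accel_session(
    session_id = session_id, subject_id = subject_id,
    dataset_tag = params$dataset_tag, task_tag = "UPDRS_3_6",
    timestamps = t, acc = acc, label = label,
    sim = list(duration = dur, freq = f, amplitude = amp, seed = seed,
               severity = if (label == 1) params$dysk_severity else 0)
  )
}

#' Generate a labelled synthetic cohort
#'
#' Per-subject random effects (own amplitude, rotation frequency and a small
#' perturbation of the device gravity direction) are shared across that
#' subject's sessions; session labels are Bernoulli(`prevalence`) draws. The
#' whole cohort is determined by `params$seed`.
#'
#' @param params A [synth_params()] object.
#' @return List with `manifest` (data.frame with columns file, session_id,
#'   subject_id, dataset_tag, label, task_tag) and `sessions` (named list).
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(params$seed)

  subjects <- lapply(seq_len(params$n_subjects), function(s) {
    gd <- params$gravity_dir + stats::rnorm(3, 0, 0.05)
    list(
      amp = stats::runif(1, params$task_amplitude[1], params$task_amplitude[2]),
      freq = stats::runif(1, params$task_freq[1], params$task_freq[2]),
      gravity_dir = gd / sqrt(sum(gd^2)),
      n_sessions = sample(params$sessions_per_subject[1]:params$sessions_per_subject[2], 1L)
    )
  })
  n_total <- sum(vapply(subjects, `[[`, 0L, "n_sessions"))
  labels <- stats::rbinom(n_total, 1L, params$prevalence)
  seeds <- sample.int(.Machine$integer.max - 1L, n_total)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  else if (exists(".Random.seed", globalenv(), inherits = FALSE))
    rm(".Random.seed", envir = globalenv())

  sessions <- list()
  rows <- list()
  i <- 0L
  for (s in seq_along(subjects)) {
    subj <- subjects[[s]]
    subject_id <- sprintf("SUBJ%03d", s)
    for (kk in seq_len(subj$n_sessions)) {
      i <- i + 1L
      session_id <- sprintf("S%03d_%02d", s, kk)
      sessions[[session_id]] <- generate_session(
        params, labels[i], seeds[i],
        session_id = session_id, subject_id = subject_id, subject = subj)
      rows[[i]] <- data.frame(
        file = paste0(session_id, ".csv"), session_id = session_id,
        subject_id = subject_id, dataset_tag = params$dataset_tag,
        label = labels[i], task_tag = "UPDRS_3_6")
    }
  }
  list(manifest = do.call(rbind, rows), sessions = sessions)
}

#' Write a cohort to disk
#'
#' One CSV (`t,x,y,z`) per session plus a `manifest.tsv`, round-trippable by
#' [read_manifest()] / [read_cohort()]. Refuses to overwrite an existing
#' manifest unless `force = TRUE`.
#'
#' @param manifest Cohort manifest data.frame.
#' @param sessions Named list of sessions.
#' @param dir Output directory (created if missing).
#' @param force Overwrite an existing cohort.
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(manifest, sessions, dir, force = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mpath <- file.path(dir, "manifest.tsv")
  if (file.exists(mpath) && !force)
    stop("cohort already exists at ", dir, " (use force = TRUE to overwrite)")
  if (nrow(manifest) > 0) for (i in seq_len(nrow(manifest))) {
    s <- sessions[[manifest$session_id[i]]]
    d <- data.frame(t = s$timestamps, x = s$acc[, 1], y = s$acc[, 2],
                    z = s$acc[, 3])
    utils::write.csv(format(d, digits = 12, trim = TRUE, scientific = FALSE),
                     file.path(dir, basename(manifest$file[i])),
                     row.names = FALSE, quote = FALSE)
  }
  out <- manifest
  out$file <- basename(out$file)
  utils::write.table(out, mpath, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(mpath)
}
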