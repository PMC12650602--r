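#' Synthetic ECG beat morphologies
#'
#' A beat morphology is a parametric description of one heartbeat as a sum
#' of Gaussian deflections (P, Q, R, S, T), plus the mean and jitter of the
#' RR interval that separates consecutive beats of this class. The five
#' built-in morphologies mirror the clinical contrasts between the AAMI
#' classes without claiming physiological realism:
#' \itemize{
#'   \item N: full P-QRS-T complex, narrow QRS.
#'   \item S: P-wave amplitude reduced to 40\% and a shortened preceding RR
#'     interval (atrial/timing changes).
#'   \item V: QRS widened threefold, absent P wave, inverted T.
#'   \item F: the pointwise blend 0.5 * (N template + V template).
#'   \item Q: paced/unclassifiable morphology - a sharp pacing spike
#'     followed by a very wide, low-amplitude QRS and a flat T, carrying
#'     heavy-tailed distortion noise.
#' }
#'
#' @param class_label One of `"N"`, `"S"`, `"V"`, `"F"`, `"Q"`.
#' @param wave_params Data frame with columns `wave`, `amplitude` (mV),
#'   `center` (seconds relative to the R peak) and `width` (seconds).
#' @param rr_interval_mean Mean RR interval in seconds (> 0).
#' @param rr_interval_jitter Standard deviation of RR jitter in seconds.
#' @param distortion_sd Scale (mV) of heavy-tailed (t, 3 df) sample noise
#'   added to every beat of this class; non-zero only for Q by default.
#' @return An object of class `beat_morphology`.
#' @export
beat_morphology <- function(class_label, wave_params, rr_interval_mean,
                            rr_interval_jitter, distortion_sd = 0) {
  if (!is.character(class_label) || length(class_label) != 1L ||
      !(class_label %in% aami_classes())) {
    stop("unknown beat class label: ", deparse(class_label))
  }
  stopifnot(is.data.frame(wave_params),
            all(c("wave", "amplitude", "center", "width") %in% names(wave_params)))
  if (any(wave_params$width <= 0)) stop("wave widths must be > 0")
  if (rr_interval_mean <= 0) stop("rr_interval_mean must be > 0")
  # exactly one dominant R deflection
  r <- wave_params[wave_params$wave == "R", , drop = FALSE]
  if (nrow(r) != 1L) stop("morphology must contain exactly one R wave")
  if (abs(r$amplitude) < max(abs(wave_params$amplitude[wave_params$wave != "R"]), 0)) {
    stop("R must be the dominant deflection")
  }
  structure(list(class_label = class_label, wave_params = wave_params,
                 rr_interval_mean = rr_interval_mean,
                 rr_interval_jitter = rr_interval_jitter,
                 distortion_sd = distortion_sd),
            class = "beat_morphology")
}

wave_df <- function(wave, amplitude, center, width) {
  data.frame(wave = wave, amplitude = amplitude, center = center,
             width = width, stringsAsFactors = FALSE)
}

#' Default morphologies for the five AAMI classes
#'
#' @return Named list of [beat_morphology()] objects (`N`, `S`, `V`, `F`, `Q`).
#' @export
default_morphologies <- function() {
  n_waves <- wave_df(c("P", "Q", "R", "S", "T"),
                     amplitude = c(0.15, -0.12, 1.10, -0.22, 0.32),
                     center    = c(-0.20, -0.030, 0.0, 0.030, 0.22),
                     width     = c(0.028, 0.010, 0.014, 0.010, 0.055))
  # V: QRS width x3, no P, inverted T
  v_waves <- wave_df(c("Q", "R", "S", "T"),
                     amplitude = c(-0.15, 1.30, -0.35, -0.35),
                     center    = c(-0.055, 0.0, 0.060, 0.30),
                     width     = c(0.030, 0.042, 0.030, 0.065))
  # S: attenuated P, shortened preceding RR interval
  s_waves <- n_waves
  s_waves$amplitude[s_waves$wave == "P"] <- 0.15 * 0.4
  s_waves$center[s_waves$wave == "P"] <- -0.16
  # F: 0.5 * (N template + V template), realized as the union of both wave
  # sets at half amplitude (pointwise signal blend); the two co-located R
  # bumps are merged into one entry so the R-dominance invariant holds
  f_waves <- rbind(transform(n_waves, amplitude = amplitude * 0.5,
                             wave = paste0(wave, ".n")),
                   transform(v_waves, amplitude = amplitude * 0.5,
                             wave = paste0(wave, ".v")))
  is_r <- f_waves$wave %in% c("R.n", "R.v")
  f_r <- wave_df("R", sum(f_waves$amplitude[is_r]), 0.0,
                 mean(f_waves$width[is_r]))
  f_waves <- rbind(f_waves[!is_r, ], f_r)
  # Q: pacing-spike + very wide low QRS + flat T ("unclassifiable" beats);
  # purely additive noise on an N template is not 1-NN separable (a noised
  # beat always lies closer to a clean template than to another noised one)
  q_waves <- wave_df(c("spike", "R", "T"),
                     amplitude = c(0.6, 0.75, 0.12),
                     center    = c(-0.08, 0.0, 0.30),
                     width     = c(0.006, 0.09, 0.07))
  list(
    N = beat_morphology("N", n_waves, 0.80, 0.040),
    S = beat_morphology("S", s_waves, 0.58, 0.050),
    V = beat_morphology("V", v_waves, 0.85, 0.060),
    F = beat_morphology("F", f_waves, 0.80, 0.050),
    Q = beat_morphology("Q", q_waves, 0.75, 0.080, distortion_sd = 0.12)
  )
}

#' Noise model for synthetic records
#'
#' @param baseline_wander_amplitude Amplitude of sinusoidal baseline wander (mV).
#' @param baseline_wander_freq Wander frequency in Hz; must be < 1 Hz.
#' @param hf_noise_sd Standard deviation of additive Gaussian noise (mV).
#' @param seed Integer seed for the noise realization.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(baseline_wander_amplitude = 0.1,
                        baseline_wander_freq = 0.3,
                        hf_noise_sd = 0.03, seed = 1L) {
  if (baseline_wander_amplitude < 0 || hf_noise_sd < 0) {
    stop("noise amplitudes must be >= 0")
  }
  if (baseline_wander_freq >= 1) stop("baseline_wander_freq must be < 1 Hz")
  structure(list(baseline_wander_amplitude = baseline_wander_amplitude,
                 baseline_wander_freq = baseline_wander_freq,
                 hf_noise_sd = hf_noise_sd, seed = as.integer(seed)),
            class = "noise_model")
}

# Offset (0-based) of the R sample within a window of length L, matching the
# 90/188 position of the segmentation layout.
r_offset <- function(len) round(len * 90 / 188)

# Evaluate the sum-of-Gaussians template of `morph` at times `t` (seconds,
# relative to the R peak), with per-wave amplitude scaling factors `amp_scale`.
eval_template <- function(morph, t, amp_scale = 1) {
  w <- morph$wave_params
  amp <- w$amplitude * amp_scale
  y <- numeric(length(t))
  for (i in seq_len(nrow(w))) {
    y <- y + amp[i] * exp(-(t - w$center[i])^2 / (2 * w$width[i]^2))
  }
  y
}

#' Generate one synthetic heartbeat
#'
#' Produces a window of `round(1.5 * fs)` samples centred on the R
#' deflection, as a sum of Gaussian bumps given by the morphology. With
#' `neighbors = TRUE` the adjacent beats (one RR interval away on either
#' side) are also rendered, as they would appear inside a segmentation
#' window cut from a continuous recording.
#'
#' @param morph A [beat_morphology()].
#' @param fs Sampling rate in Hz (360 or 125).
#' @param rng_seed Integer seed; identical seeds give identical beats.
#' @param amplitude_jitter_sd Relative SD of per-wave amplitude jitter.
#' @param neighbors Render the neighbouring beats inside the window?
#' @return Numeric vector of length `round(1.5 * fs)` (mV).
#' @export
generate_beat <- function(morph, fs = 125, rng_seed = 1L,
                          amplitude_jitter_sd = 0.05, neighbors = FALSE) {
  if (!inherits(morph, "beat_morphology")) {
    stop("morph must be a beat_morphology")
  }
  if (!fs %in% c(360, 125)) stop("fs must be 360 or 125 Hz")
  len <- round(1.5 * fs)
  r0 <- r_offset(len)
  t <- (seq_len(len) - 1L - r0) / fs
  with_seed(rng_seed, {
    scale <- 1 + rnorm(nrow(morph$wave_params), 0, amplitude_jitter_sd)
    y <- eval_template(morph, t, scale)
    if (neighbors) {
      for (side in c(-1, 1)) {
        rr <- morph$rr_interval_mean +
          rnorm(1, 0, morph$rr_interval_jitter)
        y <- y + eval_template(morph, t - side * rr,
                               1 + rnorm(nrow(morph$wave_params), 0,
                                         amplitude_jitter_sd))
      }
    }
    if (morph$distortion_sd > 0) {
      y <- y + morph$distortion_sd * rt(len, df = 3)
    }
    y
  })
}

# MIT-BIH beat symbols associated with each AAMI class (used when drawing
# annotation symbols for synthetic records).
class_symbol_pool <- function() {
  list(N = c("N", "L", "R", "e", "j"),
       S = c("A", "a", "J", "S"),
       V = c("V", "E"),
       F = "F",
       Q = c("Q", "?", "/", "f"))
}

#' Generate a synthetic annotated single-lead ECG record
#'
#' Emulates an MIT-BIH-style recording: beats of the five AAMI classes are
#' drawn from `class_probs`, placed at RR intervals given by their
#' morphologies, and summed onto a continuous trace; sinusoidal baseline
#' wander and Gaussian high-frequency noise are then injected according to
#' `noise`. Each beat is annotated at its R-peak sample (0-based index)
#' with an MIT-BIH symbol that maps to the drawn class.
#'
#' @param n_beats Number of beats (>= 1).
#' @param class_probs Probability 5-vector over (N, S, V, F, Q); must sum
#'   to 1 within 1e-9.
#' @param fs Sampling rate in Hz.
#' @param noise A [noise_model()], or `NULL` for a noise-free record.
#' @param rng_seed Integer seed.
#' @param morphologies Named list of morphologies (default
#'   [default_morphologies()]).
#' @param record_id Record identifier stored with the trace.
#' @return An object of class `ecg_record`: list with `samples` (mV), `fs`,
#'   `lead_name`, `annotations` (data frame `sample` 0-based, `symbol`),
#'   `record_id`, `provenance`.
#' @export
generate_record <- function(n_beats, class_probs = c(0.7, 0.1, 0.1, 0.05, 0.05),
                            fs = 360, noise = noise_model(), rng_seed = 1L,
                            morphologies = default_morphologies(),
                            record_id = "synth") {
  if (n_beats < 1) stop("n_beats must be >= 1")
  if (length(class_probs) != 5L || abs(sum(class_probs) - 1) > 1e-9) {
    stop("class_probs must be a 5-vector summing to 1")
  }
  classes <- aami_classes()
  pool <- class_symbol_pool()
  with_seed(rng_seed, {
    cls <- sample(classes, n_beats, replace = TRUE, prob = class_probs)
    rr <- vapply(cls, function(k) {
      m <- morphologies[[k]]
      max(0.35, m$rr_interval_mean + rnorm(1, 0, m$rr_interval_jitter))
    }, numeric(1))
    r_times <- 0.5 + cumsum(c(0, rr[-n_beats]))
    n <- round((r_times[n_beats] + 0.8) * fs)
    y <- numeric(n)
    tgrid <- (seq_len(n) - 1L) / fs
    for (i in seq_len(n_beats)) {
      m <- morphologies[[cls[i]]]
      lo <- max(1L, round((r_times[i] - 0.75) * fs))
      hi <- min(n, round((r_times[i] + 0.75) * fs))
      idx <- lo:hi
      scale <- 1 + rnorm(nrow(m$wave_params), 0, 0.05)
      y[idx] <- y[idx] + eval_template(m, tgrid[idx] - r_times[i], scale)
      if (m$distortion_sd > 0) {
        y[idx] <- y[idx] + m$distortion_sd * rt(length(idx), df = 3)
      }
    }
    if (!is.null(noise)) {
      phase <- runif(1, 0, 2 * pi)
      y <- y + noise$baseline_wander_amplitude *
        sin(2 * pi * noise$baseline_wander_freq * tgrid + phase)
      if (noise$hf_noise_sd > 0) y <- y + rnorm(n, 0, noise$hf_noise_sd)
    }
    sym <- vapply(cls, function(k) {
      p <- pool[[k]]
      p[sample.int(length(p), 1L)]
    }, character(1))
    ann <- data.frame(sample = as.integer(round(r_times * fs)),
                      symbol = sym, stringsAsFactors = FALSE)
    ecg_record(samples = y, fs = fs, lead_name = "MLII", annotations = ann,
               record_id = record_id,
               provenance = list(prov_step("synth_record", n_beats = n_beats,
                                           seed = rng_seed)))
  })
}

#' Construct an ECG record object
#'
#' @param samples Numeric vector of the trace (mV).
#' @param fs Sampling rate (Hz), > 0.
#' @param lead_name Lead name, e.g. `"MLII"`.
#' @param annotations Data frame with integer `sample` (0-based index into
#'   `samples`, strictly increasing) and single-character `symbol`.
#' @param record_id Identifier.
#' @param provenance List of processing-step descriptors.
#' @return An `ecg_record` object.
#' @export
ecg_record <- function(samples, fs, lead_name = "MLII",
                       annotations = data.frame(sample = integer(),
                                                symbol = character()),
                       record_id = "record", provenance = list()) {
  stopifnot(is.numeric(samples), fs > 0)
  ann <- annotations[order(annotations$sample), , drop = FALSE]
  rownames(ann) <- NULL
  if (nrow(ann)) {
    if (any(ann$sample < 0 | ann$sample >= length(samples))) {
      stop("annotation sample index outside the signal")
    }
    if (any(duplicated(ann$sample))) stop("annotation indices must be strictly increasing")
  }
  structure(list(samples = as.numeric(samples), fs = fs,
                 lead_name = lead_name, annotations = ann,
                 record_id = record_id, provenance = provenance),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record %s> lead %s, %.1f s at %g Hz, %d annotations\n",
              x$record_id, x$lead_name, length(x$samples) / x$fs, x$fs,
              nrow(x$annotations)))
  invisible(x)
}

#' Generate a labeled, normalized synthetic beat dataset
#'
#' Directly generates `n_per_class` beats per AAMI class at 125 Hz, each
#' already 188 samples long and z-score normalized: the form the
#' preprocessing chain would produce. Neighbouring beats are rendered
#' inside each window (at the class's RR interval), so classes differ both
#' in morphology and in local timing structure, making the dataset
#' class-separable by construction.
#'
#' @param n_per_class Beats per class (>= 1).
#' @param rng_seed Integer master seed.
#' @param morphologies Named list of morphologies.
#' @return A [beat_dataset()] with `5 * n_per_class` rows of length 188.
#' @export
generate_dataset <- function(n_per_class, rng_seed = 1L,
                             morphologies = default_morphologies()) {
  if (n_per_class < 1) stop("n_per_class must be >= 1")
  classes <- aami_classes()
  n <- 5L * n_per_class
  beats <- matrix(0, n, 188L)
  labels <- character(n)
  row <- 0L
  for (k in seq_along(classes)) {
    for (i in seq_len(n_per_class)) {
      row <- row + 1L
      b <- generate_beat(morphologies[[classes[k]]], fs = 125,
                         rng_seed = child_seed(rng_seed, row),
                         neighbors = TRUE)
      beats[row, ] <- zscore(b)
      labels[row] <- classes[k]
    }
  }
  beat_dataset(beats, labels,
               provenance = list(prov_step("synth_dataset",
                                           n_per_class = n_per_class,
                                           seed = rng_seed)))
}
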