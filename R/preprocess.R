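# Preprocessing chain: zero-phase denoising, Fourier resampling to 125 Hz,
# 188-sample beat segmentation around annotated R peaks (90 before / 98
# after), and per-window z-score normalization.

#' Zero-phase band-pass denoising
#'
#' Removes baseline wander and high-frequency noise while preserving the
#' P-QRS-T morphology: a 4th-order Butterworth high-pass at `low` Hz and a
#' 3rd-order Butterworth low-pass at `high` Hz, both applied forward and
#' backward (`signal::filtfilt`) so the filter is zero-phase and R peaks
#' are not shifted. The input is reflection-padded before filtering to
#' suppress edge transients. The squared (zero-phase) response attenuates
#' content below 0.5 Hz by more than 20 dB while keeping the 1-35 Hz band
#' within 1 dB.
#'
#' @param x Numeric signal (mV).
#' @param fs Sampling rate in Hz.
#' @param low High-pass corner frequency (Hz).
#' @param high Low-pass corner frequency (Hz); skipped if >= Nyquist.
#' @return Filtered signal, same length as `x`.
#' @export
denoise <- function(x, fs, low = 0.7, high = 55) {
  if (fs <= 0) stop("fs must be > 0")
  min_len <- ceiling(2 * fs)
  if (length(x) < min_len) {
    stop(sprintf("signal too short for denoising: need at least %d samples (2 s at %g Hz)",
                 min_len, fs))
  }
  n <- length(x)
  pad <- min(n - 1L, round(fs))
  xp <- c(2 * x[1] - rev(x[2:(pad + 1)]), x,
          2 * x[n] - rev(x[(n - pad):(n - 1)]))
  hp <- signal::butter(4, low / (fs / 2), type = "high")
  y <- signal::filtfilt(hp, xp)
  if (high < 0.95 * fs / 2) {
    lp <- signal::butter(3, high / (fs / 2), type = "low")
    y <- signal::filtfilt(lp, y)
  }
  y[(pad + 1):(pad + n)]
}

#' Fourier-method resampling
#'
#' Resamples a signal by spectral truncation: the FFT is computed, the
#' spectrum is cut at the output Nyquist frequency (ideal anti-aliasing),
#' and the inverse transform is evaluated on the new grid. Band-limited
#' content below the output Nyquist is preserved exactly up to edge
#' effects. Output length is `round(length(x) * fs_out / fs_in)`.
#'
#' @param x Numeric signal.
#' @param fs_in Input sampling rate (Hz).
#' @param fs_out Output sampling rate (Hz); must not exceed `fs_in`
#'   (upsampling is out of scope).
#' @return List with `samples` (the resampled signal) and `scale`
#'   (`fs_out / fs_in`, the factor that maps annotation indices).
#' @export
resample_signal <- function(x, fs_in, fs_out) {
  if (fs_in <= 0 || fs_out <= 0) stop("sampling rates must be > 0")
  if (fs_out > fs_in) stop("upsampling (fs_out > fs_in) is not supported")
  n <- length(x)
  n_out <- round(n * fs_out / fs_in)
  if (n_out == n) return(list(samples = x, scale = fs_out / fs_in))
  X <- fft(x)
  Y <- complex(length.out = n_out)
  nh <- n_out %/% 2L
  Y[1] <- X[1]
  if (nh >= 2L) {
    k <- 2:nh
    Y[k] <- X[k]
    Y[n_out - k + 2L] <- X[n - k + 2L]
  }
  if (n_out %% 2L == 0L) {
    # output Nyquist bin: fold the conjugate pair so Y stays Hermitian
    Y[nh + 1L] <- X[nh + 1L] + Conj(X[nh + 1L])
  } else if (nh >= 1L) {
    Y[nh + 1L] <- X[nh + 1L]
    Y[n_out - nh + 1L] <- X[n - nh + 1L]
  }
  y <- Re(fft(Y, inverse = TRUE)) / n
  list(samples = y, scale = fs_out / fs_in)
}

#' Rescale an annotation index between sampling rates
#'
#' @param sample_index Non-negative integer sample index (0-based) at the
#'   original rate.
#' @param scale Rational scale factor `fs_out / fs_in`.
#' @return Integer index at the new rate, `round(sample_index * scale)`
#'   (half-up rounding).
#' @export
rescale_annotation <- function(sample_index, scale) {
  if (any(sample_index < 0)) stop("sample_index must be >= 0")
  as.integer(floor(sample_index * scale + 0.5))
}

#' Per-window z-score normalization
#'
#' Standardizes a beat window as `(x - mu) / (sigma + 1e-6)`, with `mu` the
#' arithmetic mean and `sigma` the population (uncorrected) standard
#' deviation; the `1e-6` guard keeps constant windows finite (they map to
#' all zeros).
#'
#' @param x Non-empty numeric vector.
#' @return Normalized vector of the same length.
#' @export
zscore <- function(x) {
  if (!length(x)) stop("window must be non-empty")
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))
  (x - mu) / (sigma + 1e-6)
}

#' Segment heartbeats around annotated R peaks
#'
#' Cuts a fixed window of 188 samples for every beat annotation: 90 samples
#' before the R index and 98 from the R index on (half-open interval
#' `[r - 90, r + 98)` in 0-based coordinates, the R sample sitting at
#' offset 90). Annotations whose class is `"EXCLUDED"`, or with
#' insufficient context on either side, are skipped and counted.
#'
#' @param x Numeric signal (typically at 125 Hz).
#' @param annotations Data frame with `sample` (0-based index) and `class`
#'   (AAMI class or `"EXCLUDED"`), sorted ascending by `sample`.
#' @param before,after Window extent around R (defaults 90 and 98).
#' @return List with `segments` (matrix, one row per beat), `labels`,
#'   `r_index` (0-based R index per row), `n_skipped_bounds`,
#'   `n_excluded`.
#' @export
segment_beats <- function(x, annotations, before = 90L, after = 98L) {
  n <- length(x)
  win <- before + after
  keep <- annotations$class %in% aami_classes()
  n_excluded <- sum(!keep)
  ann <- annotations[keep, , drop = FALSE]
  ok <- ann$sample - before >= 0L & ann$sample + after <= n
  n_skipped <- sum(!ok)
  ann <- ann[ok, , drop = FALSE]
  segs <- matrix(0, nrow(ann), win)
  for (i in seq_len(nrow(ann))) {
    r <- ann$sample[i]
    segs[i, ] <- x[(r - before + 1L):(r + after)]
  }
  list(segments = segs, labels = ann$class, r_index = ann$sample,
       n_skipped_bounds = n_skipped, n_excluded = n_excluded)
}

#' Beat dataset container
#'
#' The unit of exchange between preprocessing, class balancing, training
#' and evaluation: a beat matrix (one 188-sample normalized window per
#' row), its AAMI labels, per-class counts, a provenance trail of the
#' processing steps applied, and the split role the dataset plays.
#'
#' @param beats Numeric matrix `[n_beats x 188]`.
#' @param labels Vector of AAMI class labels, length `n_beats`.
#' @param provenance List of processing-step descriptors.
#' @param role One of `"unsplit"`, `"train"`, `"val"`, `"test"`.
#' @return A `beat_dataset` object.
#' @export
beat_dataset <- function(beats, labels, provenance = list(),
                         role = "unsplit") {
  beats <- as.matrix(beats)
  labels <- factor(as.character(labels), levels = aami_classes())
  if (anyNA(labels)) stop("labels must be drawn from {N,S,V,F,Q}")
  if (nrow(beats) != length(labels)) stop("beats/labels length mismatch")
  structure(list(beats = beats, labels = labels,
                 class_counts = table(labels), provenance = provenance,
                 role = role),
            class = "beat_dataset")
}

#' @export
print.beat_dataset <- function(x, ...) {
  cat(sprintf("<beat_dataset> %d beats x %d samples (%s)\n",
              nrow(x$beats), ncol(x$beats), x$role))
  print(x$class_counts)
  invisible(x)
}

#' Preprocessing configuration
#'
#' @param denoise Apply the band-pass denoiser first?
#' @param fs_out Target sampling rate (Hz) for the downsampling stage.
#' @param before,after Segmentation window extents around R.
#' @param low,high Denoiser corner frequencies (Hz).
#' @return A list of preprocessing parameters.
#' @export
preprocess_config <- function(denoise = TRUE, fs_out = 125, before = 90L,
                              after = 98L, low = 0.7, high = 55) {
  list(denoise = denoise, fs_out = fs_out, before = as.integer(before),
       after = as.integer(after), low = low, high = high)
}

#' Run the full preprocessing chain on one record
#'
#' Composition: denoise -> resample to 125 Hz -> rescale annotation indices
#' -> map symbols to AAMI classes -> segment 188-sample windows -> z-score
#' each window. The returned dataset's provenance lists every step with
#' its parameters and skip counts.
#'
#' @param record An [ecg_record()].
#' @param config A [preprocess_config()].
#' @return A [beat_dataset()].
#' @export
preprocess_record <- function(record, config = preprocess_config()) {
  stopifnot(inherits(record, "ecg_record"))
  prov <- record$provenance
  x <- record$samples
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("preprocess stage '%s' failed for record %s: %s",
                   name, record$record_id, conditionMessage(e)), call. = FALSE)
    })
  }
  if (isTRUE(config$denoise)) {
    x <- stage("denoise", denoise(x, record$fs, config$low, config$high))
    prov <- c(prov, list(prov_step("denoise", low = config$low,
                                   high = config$high, fs = record$fs)))
  }
  if (config$fs_out != record$fs) {
    rs <- stage("resample", resample_signal(x, record$fs, config$fs_out))
    x <- rs$samples
    scale <- rs$scale
    prov <- c(prov, list(prov_step("resample", fs_in = record$fs,
                                   fs_out = config$fs_out)))
  } else {
    scale <- 1
  }
  ann <- record$annotations
  ann125 <- data.frame(sample = if (nrow(ann)) rescale_annotation(ann$sample, scale) else integer(),
                       class = map_annotation_symbol(ann$symbol),
                       stringsAsFactors = FALSE)
  seg <- stage("segment", segment_beats(x, ann125, config$before, config$after))
  prov <- c(prov, list(prov_step("segment", before = config$before,
                                 after = config$after,
                                 n_skipped_bounds = seg$n_skipped_bounds,
                                 n_excluded = seg$n_excluded)))
  segs <- seg$segments
  if (nrow(segs)) segs <- t(apply(segs, 1L, zscore))
  prov <- c(prov, list(prov_step("zscore", epsilon = 1e-6)))
  if (!nrow(segs)) {
    segs <- matrix(0, 0L, config$before + config$after)
  }
  ds <- beat_dataset(segs, seg$labels, provenance = prov)
  ds
}

#' Write / read a beat dataset as CSV (+ JSON provenance sidecar)
#'
#' The CSV holds the 188 feature columns (`V1..V188`) plus a `label`
#' column; provenance and role are written to `<path>.provenance.json`.
#'
#' @param dataset A [beat_dataset()].
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_beat_dataset <- function(dataset, path) {
  df <- as.data.frame(dataset$beats)
  names(df) <- paste0("V", seq_len(ncol(df)))
  df$label <- as.character(dataset$labels)
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(role = dataset$role,
                            provenance = dataset$provenance),
                       paste0(path, ".provenance.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_beat_dataset
#' @export
read_beat_dataset <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  lab <- df$label
  beats <- as.matrix(df[, setdiff(names(df), "label"), drop = FALSE])
  side <- paste0(path, ".provenance.json")
  prov <- list(); role <- "unsplit"
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = FALSE)
    prov <- meta$provenance %||% list()
    role <- meta$role %||% "unsplit"
  }
  beat_dataset(beats, lab, provenance = prov, role = role)
}
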