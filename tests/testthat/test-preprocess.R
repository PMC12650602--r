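test_that("denoiser meets its stop-band and pass-band specifications", {
  fs <- 360
  t <- (0:(30 * fs - 1)) / fs
  rms <- function(x) sqrt(mean(x^2))
  drift <- sin(2 * pi * 0.2 * t)
  expect_lt(rms(denoise(drift, fs)) / rms(drift), 0.1)
  tone10 <- sin(2 * pi * 10 * t)
  expect_lt(abs(rms(denoise(tone10, fs)) / rms(tone10) - 1), 0.11)
  expect_error(denoise(rnorm(100), fs), "at least")
})

test_that("denoising is zero-phase: R peaks move by at most one sample", {
  m <- default_morphologies()
  beat <- generate_beat(m$N, fs = 360, rng_seed = 5, amplitude_jitter_sd = 0)
  clean <- c(numeric(720), beat, numeric(720))
  t <- (seq_along(clean) - 1) / 360
  noisy <- clean + 0.4 * sin(2 * pi * 0.3 * t + 1)
  filtered <- denoise(noisy, 360)
  expect_lte(abs(which.max(filtered) - which.max(clean)), 1L)
})

test_that("Fourier resampling preserves band-limited content and length", {
  rs <- resample_signal(numeric(3600) + 1, 360, 125)
  expect_length(rs$samples, 1250L)
  expect_equal(rs$scale, 125 / 360)
  expect_lt(max(abs(rs$samples - 1)), 1e-9)  # constant stays constant
  t <- (0:3599) / 360
  tone <- sin(2 * pi * 5 * t)
  y <- resample_signal(tone, 360, 125)$samples
  sp <- Mod(fft(y))
  peak_hz <- (which.max(sp[2:625])) * 125 / 1250
  expect_equal(peak_hz, 5)
  expect_lt(abs(max(abs(y[100:1150])) - 1), 0.02)
  expect_error(resample_signal(tone, 125, 360), "upsampling")
})

test_that("annotation rescaling rounds to the mapped rate", {
  expect_equal(rescale_annotation(360L, 125 / 360), 125L)
  expect_equal(rescale_annotation(0L, 125 / 360), 0L)
  expect_equal(rescale_annotation(1000L, 125 / 360), 347L)
  expect_error(rescale_annotation(-1L, 0.5), ">= 0")
})

test_that("z-score normalization matches direct mean/SD arithmetic", {
  expect_equal(zscore(c(5, 5, 5, 5)), rep(0, 4))
  z <- zscore(c(-1, 0, 1))
  expect_equal(z, c(-1.224744, 0, 1.224744), tolerance = 1e-4)
  set.seed(11)
  for (i in 1:10) {
    x <- rnorm(50, sd = runif(1, 0.1, 5))
    z <- zscore(x)
    expect_lt(abs(mean(z)), 1e-9)
    expect_equal(z, (x - mean(x)) / (sd_pop(x) + 1e-6), tolerance = 1e-12)
    # idempotence up to the epsilon guard
    expect_equal(zscore(z), z, tolerance = 1e-4)
  }
  expect_error(zscore(numeric(0)), "non-empty")
})

test_that("segmentation cuts the 90/98 window and skips boundary beats", {
  x <- seq_len(1250) - 1  # value == 0-based index
  ann <- data.frame(sample = 600L, class = "N")
  seg <- segment_beats(x, ann)
  expect_equal(dim(seg$segments), c(1L, 188L))
  expect_equal(seg$segments[1, ], as.numeric(510:697))
  expect_equal(seg$segments[1, 91], 600)  # R sample at 0-based offset 90
  seg2 <- segment_beats(x, data.frame(sample = 80L, class = "N"))
  expect_equal(nrow(seg2$segments), 0L)
  expect_equal(seg2$n_skipped_bounds, 1L)
  ann3 <- data.frame(sample = c(200L, 400L, 450L, 600L),
                     class = c("N", "V", "EXCLUDED", "F"))
  seg3 <- segment_beats(x, ann3)
  expect_equal(nrow(seg3$segments), 3L)
  expect_equal(seg3$labels, c("N", "V", "F"))
  expect_equal(seg3$n_excluded, 1L)
})

test_that("segmentation never reads outside the signal", {
  set.seed(404)
  for (i in 1:50) {
    n <- sample(150:2000, 1)
    x <- rnorm(n)
    ann <- data.frame(sample = sort(sample(0:(n - 1), 10)), class = "N")
    ann <- ann[!duplicated(ann$sample), , drop = FALSE]
    seg <- segment_beats(x, ann)
    expect_true(all(is.finite(seg$segments)))
    expect_equal(nrow(seg$segments) + seg$n_skipped_bounds, nrow(ann))
    if (nrow(seg$segments)) expect_equal(ncol(seg$segments), 188L)
  }
})

test_that("the full chain keeps one labeled window per valid annotation", {
  rec <- fix_record_n()
  ds <- preprocess_record(rec)
  seg_step <- Filter(function(p) p$step == "segment", ds$provenance)[[1]]
  expect_equal(nrow(ds$beats) + seg_step$n_skipped_bounds,
               nrow(rec$annotations))
  expect_true(all(ds$labels == "N"))
  expect_equal(ncol(ds$beats), 188L)
  mus <- rowMeans(ds$beats)
  expect_lt(max(abs(mus)), 1e-3)
})

test_that("segment labels equal the classes that generated the beats", {
  rec <- generate_record(60, class_probs = c(0.4, 0.2, 0.2, 0.1, 0.1),
                         fs = 360, rng_seed = 88)
  truth <- map_annotation_symbol(rec$annotations$symbol)
  ds <- preprocess_record(rec)
  # align: drop boundary-skipped annotations
  ann125 <- rescale_annotation(rec$annotations$sample, 125 / 360)
  n125 <- round(length(rec$samples) * 125 / 360)
  ok <- ann125 - 90 >= 0 & ann125 + 98 <= n125
  expect_equal(as.character(ds$labels), truth[ok])
})

test_that("an annotation-free record preprocesses to an empty dataset", {
  rec <- ecg_record(rnorm(3600), 360, record_id = "empty")
  ds <- preprocess_record(rec)
  expect_equal(nrow(ds$beats), 0L)
})

test_that("beat datasets round-trip through CSV with provenance", {
  ds <- fix_dataset()
  path <- file.path(tempdir(), "beats.csv")
  write_beat_dataset(ds, path)
  back <- read_beat_dataset(path)
  expect_equal(back$beats, ds$beats, ignore_attr = TRUE,
               tolerance = 1e-10)
  expect_equal(as.character(back$labels), as.character(ds$labels))
  expect_equal(back$role, ds$role)
})
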