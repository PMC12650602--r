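test_that("AAMI symbol mapping is total, correct and idempotent", {
  expect_equal(map_annotation_symbol("L"), "N")
  expect_equal(map_annotation_symbol("V"), "V")
  expect_equal(map_annotation_symbol("+"), "EXCLUDED")
  expect_equal(map_annotation_symbol(c("N", "L", "R", "e", "j")),
               rep("N", 5))
  expect_equal(map_annotation_symbol(c("A", "a", "J", "S")), rep("S", 4))
  expect_equal(map_annotation_symbol(c("V", "E")), rep("V", 2))
  expect_equal(map_annotation_symbol("F"), "F")
  expect_equal(map_annotation_symbol(c("Q", "?", "/", "f")), rep("Q", 4))
  # every MIT-BIH non-beat annotation code is excluded
  non_beat <- c("~", "|", "s", "T", "*", "D", "\"", "=", "p", "^", "t",
                "+", "u", "!", "[", "]", "@", "x", "(", ")")
  expect_true(all(map_annotation_symbol(non_beat) == "EXCLUDED"))
  # idempotent on its own outputs
  out <- map_annotation_symbol(c("L", "+", "V"))
  expect_equal(map_annotation_symbol(out), c("N", "EXCLUDED", "V"))
})

test_that("WFDB write/read round-trips samples and annotations (formats 16 and 212)", {
  rec <- fix_record_n()
  for (fmt in c("16", "212")) {
    dir <- file.path(tempdir(), paste0("wfdb", fmt))
    write_wfdb_record(rec, dir, fmt = fmt, gain = 200)
    back <- read_wfdb_record(file.path(dir, rec$record_id))
    expect_equal(back$fs, rec$fs)
    expect_equal(back$lead_name, "MLII")
    expect_lt(max(abs(back$samples - rec$samples)), 1 / (2 * 200) + 1e-9)
    expect_equal(back$annotations$sample, rec$annotations$sample)
    expect_equal(back$annotations$symbol, rec$annotations$symbol)
  }
})

test_that("212 round trip survives an odd sample count", {
  rec <- fix_record_n()
  odd <- ecg_record(rec$samples[1:1001], rec$fs, record_id = "odd")
  dir <- file.path(tempdir(), "wfdb_odd")
  write_wfdb_record(odd, dir, fmt = "212")
  back <- read_wfdb_record(file.path(dir, "odd"))
  expect_length(back$samples, 1001L)
  expect_lt(max(abs(back$samples - odd$samples)), 1 / 400 + 1e-9)
})

test_that("annotation gaps beyond the 10-bit interval field use SKIP words", {
  n <- 30000
  rec <- ecg_record(sin(seq_len(n) / 40), fs = 360,
                    annotations = data.frame(sample = c(100L, 25000L, 28000L),
                                             symbol = c("N", "V", "N")),
                    record_id = "skiprec")
  dir <- file.path(tempdir(), "wfdb_skip")
  write_wfdb_record(rec, dir)
  back <- read_wfdb_record(file.path(dir, "skiprec"))
  expect_equal(back$annotations$sample, c(100L, 25000L, 28000L))
  expect_equal(back$annotations$symbol, c("N", "V", "N"))
})

test_that("the preferred lead is selected from multi-channel records", {
  # hand-build a two-channel format-16 record: channel 1 = V1, channel 2 = MLII
  dir <- file.path(tempdir(), "wfdb_2ch")
  dir.create(dir, showWarnings = FALSE)
  n <- 1000
  v1 <- as.integer(round(100 * sin(seq_len(n) / 7)))
  mlii <- as.integer(round(200 * cos(seq_len(n) / 9)))
  inter <- as.integer(rbind(v1, mlii))
  writeBin(inter, file.path(dir, "twoch.dat"), size = 2L, endian = "little")
  writeLines(c(sprintf("twoch 2 360 %d", n),
               "twoch.dat 16 200 16 0 0 0 0 V1",
               "twoch.dat 16 200 16 0 0 0 0 MLII"),
             file.path(dir, "twoch.hea"))
  rec <- read_wfdb_record(file.path(dir, "twoch"))
  expect_equal(rec$lead_name, "MLII")
  expect_equal(rec$samples, mlii / 200)
  # absent preferred lead: falls back to channel 1 with a recorded warning
  expect_warning(rec2 <- read_wfdb_record(file.path(dir, "twoch"),
                                          preferred_lead = "V5"),
                 "V5")
  expect_equal(rec2$lead_name, "V1")
  expect_true(any(vapply(rec2$provenance,
                         function(p) identical(p$step, "lead_fallback"),
                         logical(1))))
})

test_that("ecg_record enforces ordered in-range annotations", {
  x <- rnorm(100)
  unsorted <- data.frame(sample = c(50L, 10L), symbol = c("V", "N"))
  rec <- ecg_record(x, 360, annotations = unsorted)
  expect_equal(rec$annotations$sample, c(10L, 50L))
  expect_equal(rec$annotations$symbol, c("N", "V"))
  expect_error(ecg_record(x, 360,
                          annotations = data.frame(sample = 100L, symbol = "N")),
               "outside")
  expect_error(read_wfdb_record(file.path(tempdir(), "missing_rec")),
               "missing_rec")
})

test_that("the paced-record exclusion list is available to preprocessing drivers", {
  expect_setequal(paced_records(), c("102", "104", "107", "217"))
})
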