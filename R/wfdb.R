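# Minimal WFDB subset: .hea headers, .dat signal formats 212 and 16, and
# MIT-format .atr annotation files. Covers what is needed to read MIT-BIH
# Arrhythmia Database records and to round-trip records written by the
# synthetic generator. Annotation sample indices are 0-based (WFDB native).

# MIT annotation code table (code -> display symbol), wfdb ecgcodes order.
mit_ann_codes <- function() {
  c(`1` = "N", `2` = "L", `3` = "R", `4` = "a", `5` = "V", `6` = "F",
    `7` = "J", `8` = "A", `9` = "S", `10` = "E", `11` = "j", `12` = "/",
    `13` = "Q", `14` = "~", `16` = "|", `18` = "s", `19` = "T", `20` = "*",
    `21` = "D", `22` = "\"", `23` = "=", `24` = "p", `25` = "B", `26` = "^",
    `27` = "t", `28` = "+", `29` = "u", `30` = "?", `31` = "!", `32` = "[",
    `33` = "]", `34` = "e", `35` = "n", `36` = "@", `37` = "x", `38` = "f",
    `39` = "(", `40` = ")", `41` = "r")
}

#' Map an MIT-BIH annotation symbol to its AAMI class
#'
#' Implements the standard AAMI five-class merge: `{N,L,R,e,j} -> N`,
#' `{A,a,J,S} -> S`, `{V,E} -> V`, `{F} -> F`, `{Q,?,/,f} -> Q` (paced and
#' fusion-of-paced beats go to the unknown class). Every other symbol
#' (rhythm changes, artifacts, non-beat markers) maps to `"EXCLUDED"`.
#' The mapping is total and idempotent on its own outputs' symbols.
#'
#' @param symbol Character vector of single-character annotation symbols.
#' @return Character vector over `{N, S, V, F, Q, EXCLUDED}`.
#' @export
map_annotation_symbol <- function(symbol) {
  map <- c(N = "N", L = "N", R = "N", e = "N", j = "N",
           A = "S", a = "S", J = "S", S = "S",
           V = "V", E = "V",
           F = "F",
           Q = "Q", `?` = "Q", `/` = "Q", f = "Q")
  out <- unname(map[symbol])
  out[is.na(out)] <- "EXCLUDED"
  out
}

#' MIT-BIH records with paced rhythms
#'
#' The four records dominated by paced beats, commonly excluded in the
#' literature. Kept by default; pass to the `exclude` argument of
#' preprocessing drivers to drop them.
#'
#' @return Character vector of record names.
#' @export
paced_records <- function() c("102", "104", "107", "217")

parse_header <- function(hea_path) {
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rec <- sub("/.*$", "", top[1])
  nsig <- as.integer(top[2])
  fs <- if (length(top) >= 3) as.numeric(sub("/.*$", "", top[3])) else 250
  nsamp <- if (length(top) >= 4) as.integer(top[4]) else NA_integer_
  sig <- lapply(lines[1 + seq_len(nsig)], function(l) {
    tok <- strsplit(trimws(l), "\\s+")[[1]]
    gain_tok <- tok[3]
    gain <- as.numeric(sub("^([-0-9.]+).*$", "\\1", gain_tok))
    if (is.na(gain) || gain == 0) gain <- 200
    baseline <- if (grepl("\\(", gain_tok)) {
      as.numeric(sub("^[^(]*\\(([-0-9]+)\\).*$", "\\1", gain_tok))
    } else NA_real_
    adc_zero <- if (length(tok) >= 5) suppressWarnings(as.numeric(tok[5])) else 0
    if (is.na(baseline)) baseline <- if (is.na(adc_zero)) 0 else adc_zero
    desc <- if (length(tok) >= 9) paste(tok[9:length(tok)], collapse = " ") else ""
    list(file = tok[1], fmt = sub("x.*$", "", tok[2]), gain = gain,
         baseline = baseline, desc = desc)
  })
  list(record = rec, nsig = nsig, fs = fs, nsamp = nsamp, signals = sig)
}

read_dat_212 <- function(path, nsig, nsamp) {
  raw <- readBin(path, "raw", file.info(path)$size)
  n_vals <- (length(raw) %/% 3L) * 2L
  b <- as.integer(raw)
  i1 <- seq(1L, by = 3L, length.out = n_vals %/% 2L)
  lo <- b[i1]; mid <- b[i1 + 1L]; hi <- b[i1 + 2L]
  s1 <- lo + bitwShiftL(bitwAnd(mid, 0x0FL), 8L)
  s2 <- hi + bitwShiftL(bitwAnd(mid, 0xF0L), 4L)
  s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
  s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
  vals <- as.vector(rbind(s1, s2))
  total <- nsig * nsamp
  if (!is.na(total) && total <= length(vals)) vals <- vals[seq_len(total)]
  matrix(vals, ncol = nsig, byrow = TRUE)
}

read_dat_16 <- function(path, nsig, nsamp) {
  n <- file.info(path)$size %/% 2L
  vals <- readBin(path, "integer", n = n, size = 2L, signed = TRUE,
                  endian = "little")
  total <- nsig * nsamp
  if (!is.na(total) && total <= length(vals)) vals <- vals[seq_len(total)]
  matrix(vals, ncol = nsig, byrow = TRUE)
}

# Read an MIT-format annotation file. Returns data frame (sample, symbol),
# sample indices 0-based.
read_mit_annotations <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  words <- function(i) {
    as.integer(raw[i]) + bitwShiftL(as.integer(raw[i + 1L]), 8L)
  }
  i <- 1L
  t_cur <- 0
  samples <- integer(0)
  symbols <- character(0)
  codes <- mit_ann_codes()
  while (i + 1L <= length(raw)) {
    a <- words(i); i <- i + 2L
    code <- bitwShiftR(a, 10L)
    field <- bitwAnd(a, 1023L)
    if (a == 0L) break
    if (code == 59L && field == 0L) {           # SKIP: 4-byte interval, high word first
      hi <- words(i); lo <- words(i + 2L); i <- i + 4L
      t_cur <- t_cur + hi * 65536 + lo
    } else if (code %in% c(60L, 61L, 62L)) {    # NUM / SUB / CHN: value only
      next
    } else if (code == 63L) {                   # AUX: skip field bytes (+pad)
      i <- i + field + (field %% 2L)
    } else if (code >= 1L && code <= 49L) {
      t_cur <- t_cur + field
      sym <- codes[as.character(code)]
      if (!is.na(sym)) {
        samples <- c(samples, t_cur)
        symbols <- c(symbols, unname(sym))
      }
    } else {
      t_cur <- t_cur + field
    }
  }
  data.frame(sample = as.integer(samples), symbol = symbols,
             stringsAsFactors = FALSE)
}

#' Read a WFDB record (MIT-BIH style) into an ECG record object
#'
#' Parses the `.hea` header, reads the signal file (formats 212 and 16 are
#' supported) and, when present, the MIT-format `.atr` annotation file.
#' The channel whose description equals `preferred_lead` is selected; if
#' absent, the first channel is returned and a warning is recorded in the
#' result's provenance (and raised as an R warning).
#'
#' @param path Path to the record: either the `.hea` file or the extension-less
#'   record path.
#' @param preferred_lead Lead description to select (default `"MLII"`).
#' @return An [ecg_record()] with samples in mV and 0-based annotation
#'   indices sorted ascending.
#' @export
read_wfdb_record <- function(path, preferred_lead = "MLII") {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) stop("cannot read WFDB header: ", hea)
  h <- parse_header(hea)
  if (h$nsig < 1) stop("record has no signal channels: ", hea)
  dir <- dirname(hea)
  dat <- file.path(dir, h$signals[[1]]$file)
  if (!file.exists(dat)) stop("cannot read WFDB signal file: ", dat)
  fmt <- h$signals[[1]]$fmt
  adus <- switch(fmt,
                 "212" = read_dat_212(dat, h$nsig, h$nsamp),
                 "16"  = read_dat_16(dat, h$nsig, h$nsamp),
                 stop("unsupported WFDB signal format: ", fmt))
  leads <- vapply(h$signals, `[[`, character(1), "desc")
  prov <- list(prov_step("wfdb_read", path = hea, format = fmt))
  ch <- match(preferred_lead, leads)
  if (is.na(ch)) {
    ch <- 1L
    msg <- sprintf("lead %s not found in record %s (have: %s); using %s",
                   preferred_lead, h$record, paste(leads, collapse = ", "),
                   leads[1])
    warning(msg)
    prov <- c(prov, list(prov_step("lead_fallback", message = msg)))
  }
  gain <- h$signals[[ch]]$gain
  baseline <- h$signals[[ch]]$baseline
  samples <- (adus[, ch] - baseline) / gain
  atr <- file.path(dir, paste0(h$record, ".atr"))
  ann <- if (file.exists(atr)) read_mit_annotations(atr) else
    data.frame(sample = integer(), symbol = character())
  ann <- ann[ann$sample >= 0 & ann$sample < length(samples), , drop = FALSE]
  ecg_record(samples = samples, fs = h$fs, lead_name = leads[ch],
             annotations = ann, record_id = h$record, provenance = prov)
}

write_dat_212 <- function(path, adus) {
  # adus: integer matrix [n x nsig]; values must fit 12-bit two's complement
  v <- as.integer(t(adus))
  if (length(v) %% 2L == 1L) v <- c(v, 0L)
  if (any(v < -2048L | v > 2047L)) stop("sample out of 12-bit range for format 212")
  v[v < 0L] <- v[v < 0L] + 4096L
  s1 <- v[seq(1L, length(v), by = 2L)]
  s2 <- v[seq(2L, length(v), by = 2L)]
  bytes <- as.raw(rbind(bitwAnd(s1, 255L),
                        bitwOr(bitwShiftR(s1, 8L),
                               bitwShiftL(bitwShiftR(s2, 8L), 4L)),
                        bitwAnd(s2, 255L)))
  writeBin(bytes, path)
}

write_mit_annotations <- function(path, ann) {
  words <- integer(0)
  codes <- mit_ann_codes()
  sym_to_code <- stats::setNames(as.integer(names(codes)), unname(codes))
  t_prev <- 0
  for (i in seq_len(nrow(ann))) {
    code <- sym_to_code[[ann$symbol[i]]]
    if (is.null(code) || is.na(code)) stop("no MIT code for symbol ", ann$symbol[i])
    delta <- ann$sample[i] - t_prev
    if (delta > 1023 || delta < 0) {
      words <- c(words, bitwShiftL(59L, 10L),                 # SKIP
                 bitwAnd(bitwShiftR(as.integer(delta), 16L), 65535L),
                 bitwAnd(as.integer(delta), 65535L))
      delta <- 0
    }
    words <- c(words, bitwOr(bitwShiftL(code, 10L), as.integer(delta)))
    t_prev <- ann$sample[i]
  }
  words <- c(words, 0L)
  bytes <- as.raw(rbind(bitwAnd(words, 255L), bitwShiftR(words, 8L)))
  writeBin(bytes, path)
}

#' Write an ECG record in WFDB-compatible layout
#'
#' Emits `<id>.hea`, `<id>.dat` (format 16 by default, or the MIT-BIH
#' format 212) and, when the record carries annotations, an MIT-format
#' `<id>.atr`. Samples are quantized with the given ADC gain
#' (adu = round(mV * gain)), so a read-back reproduces them within
#' `1/(2*gain)` mV.
#'
#' @param record An [ecg_record()].
#' @param dir Output directory (created if missing).
#' @param fmt Signal format, `"16"` or `"212"`.
#' @param gain ADC gain in adu/mV.
#' @return The header path, invisibly.
#' @export
write_wfdb_record <- function(record, dir, fmt = c("16", "212"), gain = 200) {
  fmt <- match.arg(fmt)
  stopifnot(inherits(record, "ecg_record"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  id <- record$record_id
  adus <- matrix(as.integer(round(record$samples * gain)), ncol = 1L)
  datf <- paste0(id, ".dat")
  if (fmt == "212") write_dat_212(file.path(dir, datf), adus)
  else writeBin(as.integer(adus[, 1]), file.path(dir, datf), size = 2L,
                endian = "little")
  hea <- file.path(dir, paste0(id, ".hea"))
  writeLines(c(sprintf("%s 1 %g %d", id, record$fs, length(record$samples)),
               sprintf("%s %s %g 16 0 %d 0 0 %s", datf, fmt, gain,
                       adus[1, 1], record$lead_name)),
             hea)
  if (nrow(record$annotations)) {
    write_mit_annotations(file.path(dir, paste0(id, ".atr")),
                          record$annotations)
  }
  invisible(hea)
}
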