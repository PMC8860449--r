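# Minimal EDF/EDF+ support: fixed-layout ASCII header + 16-bit little-endian
# samples, one signal per channel role, common sampling rate. Covers what the
# pipeline needs (continuous synchronized channels); no annotations channel.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

edf_num <- function(x, width = 8) {
  s <- format(x, digits = width - 1, trim = TRUE, scientific = FALSE)
  if (nchar(s) > width) s <- formatC(x, digits = width - 4, format = "g")
  if (nchar(s) > width) stop("cannot encode ", x, " in ", width, " chars")
  edf_pad(s, width)
}

edf_units <- function(role) {
  switch(role, ecog = "uV", emg = "uV", resp = "a.u.",
         gas_o2 = "%", gas_co2 = "%", laser = "", "")
}

write_edf <- function(rec, path) {
  chn <- rec$channels
  ns <- length(chn)
  n <- length(chn[[1]])
  fs <- rec$fs
  if (abs(fs - round(fs)) < 1e-9 && n %% round(fs) == 0) {
    spr <- round(fs); nrec <- n %/% spr; rec_dur <- 1
  } else {
    spr <- n; nrec <- 1L; rec_dur <- n / fs
  }
  pmin <- vapply(chn, min, numeric(1))
  pmax <- vapply(chn, max, numeric(1))
  flat <- pmax <= pmin
  pmax[flat] <- pmin[flat] + 1
  # quantize against the limits as stored in the 8-char ASCII header
  # fields, so that reading back inverts the scaling exactly
  pmin <- vapply(pmin, function(v) as.numeric(edf_num(v, 8)), numeric(1))
  pmax <- vapply(pmax, function(v) as.numeric(edf_num(v, 8)), numeric(1))
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeBin(charToRaw(s), con)
  wr(edf_pad("0", 8))
  wr(edf_pad("X X X X", 80))
  wr(edf_pad("Startdate X X X X", 80))
  wr(edf_pad("01.01.00", 8))
  wr(edf_pad("00.00.00", 8))
  wr(edf_pad(as.character(256 + ns * 256), 8))
  wr(edf_pad("", 44))
  wr(edf_pad(as.character(nrec), 8))
  wr(edf_num(rec_dur, 8))
  wr(edf_pad(as.character(ns), 4))
  roles <- names(chn)
  for (r in roles) wr(edf_pad(r, 16))
  for (r in roles) wr(edf_pad("", 80))
  for (r in roles) wr(edf_pad(edf_units(r), 8))
  for (i in seq_len(ns)) wr(edf_num(pmin[i], 8))
  for (i in seq_len(ns)) wr(edf_num(pmax[i], 8))
  for (i in seq_len(ns)) wr(edf_pad(as.character(dmin), 8))
  for (i in seq_len(ns)) wr(edf_pad(as.character(dmax), 8))
  for (r in roles) wr(edf_pad("", 80))
  for (i in seq_len(ns)) wr(edf_pad(as.character(spr), 8))
  for (r in roles) wr(edf_pad("", 32))
  gain <- (pmax - pmin) / (dmax - dmin)
  dig <- lapply(seq_len(ns), function(i) {
    as.integer(pmin(pmax(round((chn[[i]] - pmin[i]) / gain[i]) + dmin,
                         dmin), dmax))
  })
  for (r in seq_len(nrec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    for (i in seq_len(ns)) {
      writeBin(dig[[i]][idx], con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nchars) {
    trimws(rawToChar(readBin(con, "raw", nchars)))
  }
  rd(8)                                  # version
  rd(80); rd(80); rd(8); rd(8)           # ids, date, time
  rd(8)                                  # header bytes
  rd(44)
  nrec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)          # transducer
  for (i in seq_len(ns)) rd(8)           # units
  pmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  pmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(ns)) rd(80)          # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1L) {
    stop("EDF signals have different sampling rates; resampling not supported")
  }
  gain <- (pmax - pmin) / (dmax - dmin)
  chn <- stats::setNames(
    lapply(seq_len(ns), function(i) numeric(nrec * spr[i])), labels)
  for (r in seq_len(nrec)) {
    for (i in seq_len(ns)) {
      d <- readBin(con, "integer", spr[i], size = 2, signed = TRUE,
                   endian = "little")
      chn[[i]][((r - 1) * spr[i] + 1):(r * spr[i])] <-
        (d - dmin[i]) * gain[i] + pmin[i]
    }
  }
  list(channels = chn, fs = spr[1] / rec_dur, start_time = 0)
}
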