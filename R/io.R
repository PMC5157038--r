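#' Read a continuous EEG recording with triggers
#'
#' Reads a BrainVision header (`.vhdr`, with its `.eeg`/`.vmrk` companions)
#' or an EDF file and returns a [recording()]. Movement-onset triggers are
#' taken from the embedded marker track (BrainVision) and/or a plain-text
#' sidecar file with one onset time in seconds per line; when both are
#' present they are merged and sorted. Signal values are returned in
#' microvolts.
#'
#' For EDF files, a sidecar named `<stem>.events.txt` next to the data file
#' is picked up automatically when `events` is not given.
#'
#' @param path path to a `.vhdr` or `.edf` file
#' @param events optional path to a sidecar event file (one float per line,
#'   seconds from recording start)
#' @return a [recording()]
#' @export
load_recording <- function(path, events = NULL) {
  if (!file.exists(path)) stop("missing file: ", path)
  ext <- tolower(tools::file_ext(path))
  rec <- switch(ext,
    vhdr = read_brainvision(path),
    edf = read_edf(path),
    stop("unknown extension: .", ext, " (expected .vhdr or .edf)")
  )
  trig <- rec$triggers
  if (is.null(events) && ext == "edf") {
    side <- paste0(tools::file_path_sans_ext(path), ".events.txt")
    if (file.exists(side)) events <- side
  }
  if (!is.null(events)) {
    if (!file.exists(events)) stop("missing events file: ", events)
    trig <- c(trig, read_event_sidecar(events))
  }
  trig <- sort(unique(trig))
  if (length(trig) == 0L)
    stop("no triggers: neither embedded markers nor a sidecar event file found")
  recording(rec$data, fs = rec$fs, channels = rec$channels,
            triggers = trig, meta = rec$meta)
}

#' Write a recording to disk
#'
#' BrainVision output is the `.vhdr`/`.eeg`/`.vmrk` triplet with triggers
#' encoded as stimulus markers and signal data as IEEE float32. EDF output
#' is 16-bit with per-channel physical scaling chosen from the data range;
#' triggers go to a `<stem>.events.txt` sidecar. Run metadata is embedded
#' (a comment section in the header, or the EDF recording-id field) so that
#' [load_recording()] round-trips it.
#'
#' @param rec a [recording()]
#' @param path output path; extension is forced to match `format`
#' @param format `"brainvision"` or `"edf"`
#' @return (invisibly) character vector of the files written
#' @export
save_recording <- function(rec, path, format = c("brainvision", "edf")) {
  format <- match.arg(format)
  stopifnot(inherits(rec, "recording"))
  if (nrow(rec$data) == 0L) stop("empty recording")
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("unwritable path: ", dir)
  stem <- tools::file_path_sans_ext(path)
  files <- switch(format,
    brainvision = write_brainvision(rec, stem),
    edf = write_edf(rec, stem)
  )
  invisible(files)
}

read_event_sidecar <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  as.numeric(lines)
}

write_event_sidecar <- function(triggers, path) {
  writeLines(sprintf("%.6f", triggers), path)
  path
}

# serialize scalar meta fields as "key=value" tokens (no spaces in values)
meta_to_string <- function(meta) {
  keep <- c("subject", "hand", "hand_status", "imi", "session")
  meta <- meta[intersect(keep, names(meta))]
  if (!length(meta)) return("")
  paste(names(meta), vapply(meta, function(v) format(v, digits = 10), ""),
        sep = "=", collapse = " ")
}

meta_from_string <- function(s) {
  s <- trimws(s)
  if (!nzchar(s)) return(list())
  toks <- strsplit(strsplit(s, "[[:space:]]+")[[1]], "=", fixed = TRUE)
  toks <- toks[lengths(toks) == 2L]
  meta <- lapply(toks, function(kv) {
    v <- kv[2]
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(meta) <- vapply(toks, `[`, "", 1L)
  meta
}

## ---- BrainVision ----------------------------------------------------------

write_brainvision <- function(rec, stem) {
  base <- basename(stem)
  vhdr <- paste0(stem, ".vhdr")
  vmrk <- paste0(stem, ".vmrk")
  eeg <- paste0(stem, ".eeg")
  nch <- length(rec$channels)

  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", base, ".eeg"),
    paste0("MarkerFile=", base, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nch),
    paste0("SamplingInterval=", format(1e6 / rec$fs, digits = 15)),
    "",
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(nch), rec$channels)
  )
  ms <- meta_to_string(rec$meta)
  if (nzchar(ms)) hdr <- c(hdr, "", "[Comment]", paste0("muresp-meta: ", ms))
  con <- file(vhdr, open = "w", encoding = "UTF-8")
  writeLines(hdr, con)
  close(con)

  pos <- round(rec$triggers * rec$fs) + 1L  # 1-based data points
  mrk <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", base, ".eeg"),
    "",
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0,00000000000000000000",
    if (length(pos))
      sprintf("Mk%d=Stimulus,S  1,%d,1,0", seq_along(pos) + 1L, pos)
  )
  con <- file(vmrk, open = "w", encoding = "UTF-8")
  writeLines(mrk, con)
  close(con)

  con <- file(eeg, open = "wb")
  writeBin(as.vector(t(rec$data)), con, size = 4L, endian = "little")
  close(con)
  c(vhdr, eeg, vmrk)
}

# minimal INI-style parser: returns list(section -> named character vector)
parse_vhdr_ini <- function(lines) {
  lines <- sub(";.*$", "", lines)  # strip comments outside [Comment]
  out <- list(); section <- ""
  for (ln in lines) {
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      if (is.null(out[[section]])) out[[section]] <- character(0)
    } else if (grepl("=", ln, fixed = TRUE)) {
      kv <- regmatches(ln, regexpr("=", ln, fixed = TRUE), invert = TRUE)[[1]]
      out[[section]][trimws(kv[1])] <- trimws(kv[2])
    }
  }
  out
}

read_brainvision <- function(vhdr_path) {
  raw_lines <- readLines(vhdr_path, warn = FALSE, encoding = "UTF-8")
  ini <- parse_vhdr_ini(raw_lines)
  ci <- ini[["Common Infos"]]
  bi <- ini[["Binary Infos"]]
  if (is.null(ci)) stop("not a BrainVision header: ", vhdr_path)
  if (!is.null(ci["DataOrientation"]) && !is.na(ci["DataOrientation"]) &&
      toupper(ci["DataOrientation"]) != "MULTIPLEXED")
    stop("only MULTIPLEXED BrainVision data is supported")
  nch <- as.integer(ci["NumberOfChannels"])
  fs <- 1e6 / as.numeric(ci["SamplingInterval"])

  chinfo <- ini[["Channel Infos"]]
  labels <- character(nch); res <- rep(1, nch)
  for (i in seq_len(nch)) {
    parts <- strsplit(chinfo[paste0("Ch", i)], ",", fixed = TRUE)[[1]]
    labels[i] <- parts[1]
    if (length(parts) >= 3 && nzchar(parts[3]))
      res[i] <- as.numeric(parts[3])
  }

  dirn <- dirname(vhdr_path)
  eeg_path <- file.path(dirn, ci["DataFile"])
  fmt <- toupper(if (!is.null(bi)) bi["BinaryFormat"] else "IEEE_FLOAT_32")
  sz <- file.info(eeg_path)$size
  con <- file(eeg_path, open = "rb")
  on.exit(close(con), add = TRUE)
  if (identical(unname(fmt), "INT_16")) {
    n <- sz %/% 2L
    v <- readBin(con, "integer", n = n, size = 2L, signed = TRUE,
                 endian = "little")
  } else {
    n <- sz %/% 4L
    v <- readBin(con, "numeric", n = n, size = 4L, endian = "little")
  }
  nsamp <- length(v) %/% nch
  data <- t(matrix(v[seq_len(nsamp * nch)], nrow = nch))  # multiplexed
  data <- sweep(data, 2, res, `*`)

  triggers <- numeric(0)
  vmrk_path <- file.path(dirn, ci["MarkerFile"])
  if (!is.na(ci["MarkerFile"]) && file.exists(vmrk_path)) {
    mlines <- readLines(vmrk_path, warn = FALSE, encoding = "UTF-8")
    mk <- grep("^Mk[0-9]+=Stimulus,", mlines, value = TRUE)
    if (length(mk)) {
      pos <- vapply(strsplit(mk, ",", fixed = TRUE),
                    function(p) as.numeric(p[3]), 0)
      triggers <- sort((pos - 1) / fs)
    }
  }

  meta <- list()
  mline <- grep("muresp-meta:", raw_lines, value = TRUE, fixed = TRUE)
  if (length(mline))
    meta <- meta_from_string(sub(".*muresp-meta:", "", mline[1]))

  list(data = data, fs = fs, channels = labels, triggers = triggers,
       meta = meta)
}

## ---- EDF ------------------------------------------------------------------

pad_field <- function(x, width) {
  x <- as.character(x)
  x <- substr(x, 1L, width)
  formatC(x, width = -width)  # left-justified, space-padded
}

write_edf <- function(rec, stem) {
  path <- paste0(stem, ".edf")
  data <- rec$data
  nch <- ncol(data)
  n <- nrow(data)
  fs <- rec$fs

  if (abs(fs - round(fs)) < 1e-9 && n %% round(fs) == 0L) {
    spr <- as.integer(round(fs)); rec_dur <- 1
  } else {
    spr <- 1L; rec_dur <- 1 / fs
  }
  nrec <- n %/% spr

  # symmetric physical range per channel; header stores the printed value
  pmax <- vapply(seq_len(nch), function(j) {
    m <- max(abs(data[, j]), 1e-6)
    as.numeric(trimws(fmt8(m * 1.0000001)))
  }, 0)
  if (any(pmax > 32767))
    warning("EDF quantization step exceeds 1 uV for channels: ",
            paste(rec$channels[pmax > 32767], collapse = ", "))
  dmax <- 32767
  ints <- round(sweep(data, 2, pmax / dmax, `/`))
  ints[ints > dmax] <- dmax; ints[ints < -dmax] <- -dmax
  storage.mode(ints) <- "integer"

  hdr <- paste0(
    pad_field("0", 8),
    pad_field("X X X X", 80),
    pad_field(paste("muresp", meta_to_string(rec$meta)), 80),
    pad_field("01.01.00", 8),
    pad_field("00.00.00", 8),
    pad_field(256 * (1 + nch), 8),
    pad_field("", 44),
    pad_field(nrec, 8),
    pad_field(format(rec_dur, digits = 8), 8),
    pad_field(nch, 4),
    paste(pad_field(rec$channels, 16), collapse = ""),
    paste(rep(pad_field("", 80), nch), collapse = ""),
    paste(rep(pad_field("uV", 8), nch), collapse = ""),
    paste(vapply(-pmax, fmt8, ""), collapse = ""),
    paste(vapply(pmax, fmt8, ""), collapse = ""),
    paste(rep(fmt8(-dmax), nch), collapse = ""),
    paste(rep(fmt8(dmax), nch), collapse = ""),
    paste(rep(pad_field("", 80), nch), collapse = ""),
    paste(rep(pad_field(spr, 8), nch), collapse = ""),
    paste(rep(pad_field("", 32), nch), collapse = "")
  )
  con <- file(path, open = "wb")
  writeBin(charToRaw(hdr), con)
  # record-major: all samples of signal 1, then signal 2, ... per record
  a <- array(ints, dim = c(spr, nrec, nch))
  writeBin(as.integer(aperm(a, c(1, 3, 2))), con, size = 2L,
           endian = "little")
  close(con)

  ev <- write_event_sidecar(rec$triggers, paste0(stem, ".events.txt"))
  c(path, ev)
}

# format a number into an 8-char ASCII EDF header field
fmt8 <- function(x) {
  for (d in 7:1) {
    s <- formatC(x, digits = d, width = 8, format = "g")
    if (nchar(s) <= 8) return(formatC(s, width = -8))
  }
  stop("cannot format ", x, " into 8 characters")
}

read_edf <- function(path) {
  con <- file(path, open = "rb")
  on.exit(close(con), add = TRUE)
  rd <- function(width) trimws(rawToChar(readBin(con, "raw", width)))
  rd(8)                          # version
  rd(80)                         # patient id
  rec_id <- rd(80)
  rd(8); rd(8)                   # date, time
  rd(8)                          # header bytes
  rd(44)                         # reserved
  nrec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  nch <- as.integer(rd(4))
  fld <- function(width) vapply(seq_len(nch), function(i) rd(width), "")
  labels <- fld(16)
  fld(80)                        # transducer
  fld(8)                         # dimension
  pmin <- as.numeric(fld(8))
  pmax <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8))
  dmax <- as.numeric(fld(8))
  fld(80)                        # prefiltering
  spr <- as.integer(fld(8))
  fld(32)                        # reserved
  if (length(unique(spr)) != 1L)
    stop("EDF with per-signal sampling rates is not supported")
  spr <- spr[1]
  fs <- spr / rec_dur

  v <- readBin(con, "integer", n = nrec * nch * spr, size = 2L,
               signed = TRUE, endian = "little")
  a <- array(v, dim = c(spr, nch, nrec))
  data <- aperm(a, c(1, 3, 2))
  dim(data) <- c(spr * nrec, nch)
  scale <- (pmax - pmin) / (dmax - dmin)
  data <- sweep(sweep(data, 2, scale, `*`), 2, pmin - dmin * scale, `+`)

  meta <- list()
  if (startsWith(rec_id, "muresp"))
    meta <- meta_from_string(sub("^muresp", "", rec_id))

  list(data = data, fs = fs, channels = labels, triggers = numeric(0),
       meta = meta)
}
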