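#' Decode a Physionet-style run number
#'
#' The motor movement/imagery layout stores 14 runs per subject:
#' R01 = eyes open (EO), R02 = eyes closed (EC), and then the four tasks
#' cycling three times: R03/R07/R11 = T1 runs 1-3, R04/R08/R12 = T2,
#' R05/R09/R13 = T3, R06/R10/R14 = T4.
#'
#' @param run_number Integer in 1..14.
#' @return List with elements `task` and `run`.
#' @export
decode_run_number <- function(run_number) {
  rn <- as.integer(run_number)
  if (is.na(rn) || rn < 1 || rn > 14) {
    abort(paste0("unknown run number: ", run_number, " (expected 1..14)"))
  }
  if (rn == 1L) return(list(task = "EO", run = "R1"))
  if (rn == 2L) return(list(task = "EC", run = "R1"))
  task <- paste0("T", ((rn - 3L) %% 4L) + 1L)
  run <- paste0("R", ((rn - 3L) %/% 4L) + 1L)
  list(task = task, run = run)
}

#' Encode (task, run) as a Physionet-style run number
#'
#' Inverse of [decode_run_number()].
#'
#' @param task Task label.
#' @param run Run label (ignored for baselines, which have a single run).
#' @return Integer run number in 1..14.
#' @export
run_number <- function(task, run = "R1") {
  if (task == "EO") return(1L)
  if (task == "EC") return(2L)
  k <- task_index(task) - 2L  # T1..T4 -> 1..4
  j <- run_index(run)
  2L + (j - 1L) * 4L + k
}

pad_field <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording as a 16-bit EDF file
#'
#' Minimal EDF (European Data Format) writer: fixed-width ASCII header plus
#' little-endian int16 data records of one second each. Physical values are
#' scaled symmetrically per signal onto the digital range -32767..32767, so
#' the round-trip error is bounded by half a quantization step.
#'
#' @param rec An [eeg_recording()]; its length is truncated to whole seconds.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$sample_rate
  if (fs != round(fs)) abort("EDF writer requires an integer sample rate")
  ns <- nrow(rec$data)
  n_rec <- floor(ncol(rec$data) / fs)
  if (n_rec < 1) abort("recording shorter than one EDF data record (1 s)")
  data <- rec$data[, seq_len(n_rec * fs), drop = FALSE]

  pmax_ <- max(abs(data), 1e-6)
  phys_max <- signif(pmax_ * 1.0001, 6)
  dig_max <- 32767
  scaled <- round(data / phys_max * dig_max)
  storage.mode(scaled) <- "integer"

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(pad_field(x, width), con, nchars = width, eos = NULL)
  wr("0", 8)
  wr(sprintf("subject %d", rec$subject_id), 80)
  wr(sprintf("task %s run %s synthetic", rec$task, rec$run), 80)
  wr("01.01.00", 8)
  wr("00.00.00", 8)
  wr(256 * (ns + 1), 8)
  wr("", 44)
  wr(n_rec, 8)
  wr(1, 8)
  wr(ns, 4)
  for (lab in rec$channel_labels) wr(lab, 16)
  for (i in seq_len(ns)) wr("synthetic", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(format(-phys_max), 8)
  for (i in seq_len(ns)) wr(format(phys_max), 8)
  for (i in seq_len(ns)) wr(-dig_max, 8)
  for (i in seq_len(ns)) wr(dig_max, 8)
  for (i in seq_len(ns)) wr("none", 80)
  for (i in seq_len(ns)) wr(fs, 8)
  for (i in seq_len(ns)) wr("", 32)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    for (sig in seq_len(ns)) {
      writeBin(scaled[sig, cols], con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

read_edf_header <- function(con) {
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  h <- list(
    version = rd(8), patient = rd(80), recording = rd(80),
    startdate = rd(8), starttime = rd(8),
    header_bytes = as.integer(rd(8)), reserved = rd(44),
    n_records = as.integer(rd(8)), record_duration = as.numeric(rd(8)),
    n_signals = as.integer(rd(4))
  )
  ns <- h$n_signals
  if (is.na(ns) || ns < 1) abort("unreadable EDF file: bad signal count in header")
  rdn <- function(width) vapply(seq_len(ns), function(i) rd(width), character(1))
  h$labels <- rdn(16)
  h$transducer <- rdn(80)
  h$phys_dim <- rdn(8)
  h$phys_min <- as.numeric(rdn(8))
  h$phys_max <- as.numeric(rdn(8))
  h$dig_min <- as.numeric(rdn(8))
  h$dig_max <- as.numeric(rdn(8))
  h$prefilter <- rdn(80)
  h$samples_per_record <- as.integer(rdn(8))
  h$sig_reserved <- rdn(32)
  h
}

#' Read a 16-bit EDF file
#'
#' Returns the signal matrix and header metadata; use [read_record()] to also
#' decode subject/task/run from a Physionet-style filename.
#'
#' @param path EDF file path.
#' @return List with `data` (channels x samples, physical units), `labels`,
#'   `sample_rate` and the parsed `header`.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) abort(paste0("unreadable file: ", path))
  con <- file(path, "rb")
  on.exit(close(con))
  h <- tryCatch(read_edf_header(con), error = function(e) {
    abort(paste0("unreadable EDF file: ", path, " (", conditionMessage(e), ")"))
  })
  spr <- h$samples_per_record
  if (length(unique(spr)) != 1) {
    abort("inconsistent per-channel sampling rates in EDF file")
  }
  ns <- h$n_signals
  fs <- spr[1] / h$record_duration
  gain <- (h$phys_max - h$phys_min) / (h$dig_max - h$dig_min)
  offset <- h$phys_min - h$dig_min * gain
  data <- matrix(0, ns, h$n_records * spr[1])
  for (r in seq_len(h$n_records)) {
    raw <- readBin(con, "integer", n = ns * spr[1], size = 2,
                   endian = "little", signed = TRUE)
    if (length(raw) < ns * spr[1]) abort("unreadable EDF file: truncated data records")
    block <- matrix(raw, nrow = spr[1], ncol = ns)  # per-signal contiguous
    cols <- ((r - 1) * spr[1] + 1):(r * spr[1])
    data[, cols] <- t(block) * gain + offset
  }
  list(data = data, labels = h$labels, sample_rate = fs, header = h)
}

#' Read one Physionet-style recording
#'
#' Reads an EDF file named `S{subject:03d}R{run:02d}.edf` and decodes the
#' subject id and (task, run) labels from the filename via the 14-run mapping
#' (see [decode_run_number()]).
#'
#' @param path Path to an EDF file following the naming convention.
#' @return An [eeg_recording()].
#' @export
read_record <- function(path) {
  base <- basename(path)
  m <- regmatches(base, regexec("^S(\\d{3})R(\\d{2})\\.edf$", base))[[1]]
  if (length(m) != 3) {
    abort(paste0("filename does not follow S###R##.edf convention: ", base))
  }
  subject <- as.integer(m[2])
  tr <- decode_run_number(as.integer(m[3]))
  edf <- read_edf(path)
  eeg_recording(
    subject_id = subject, task = tr$task, run = tr$run,
    sample_rate = edf$sample_rate, channel_labels = edf$labels,
    data = edf$data
  )
}
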