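#' Build a segment set tibble
#'
#' A segment set is a tibble with one row per fixed-length window: columns
#' `subject_id`, `task`, `run`, `start_sample` (0-based index into the source
#' recording) and `data` (list-column of channels x window matrices), ordered
#' by (subject_id, start_sample). Provenance (window length, sample rate,
#' stride, filter band, augmentation flag) travels in attributes.
#'
#' @param rows Tibble with the columns above.
#' @param window_samples Window length in samples.
#' @param sample_rate Sampling rate in Hz.
#' @param stride Stride in samples (NA for non-overlapping cuts).
#' @param band Optional [bandpass_spec()] recorded as provenance.
#' @param augmented Logical, whether the set came from sliding-window
#'   augmentation.
#' @return A tibble of class `segment_set`.
#' @export
segment_set <- function(rows, window_samples, sample_rate, stride = NA_real_,
                        band = NULL, augmented = FALSE) {
  out <- arrange(as_tibble(rows), .data$subject_id, .data$start_sample)
  structure(
    out,
    window_samples = as.integer(window_samples),
    sample_rate = sample_rate,
    stride = stride,
    band = band,
    augmented = augmented,
    class = c("segment_set", class(out))
  )
}

segment_meta <- function(segs) {
  list(
    window_samples = attr(segs, "window_samples"),
    sample_rate = attr(segs, "sample_rate"),
    stride = attr(segs, "stride"),
    band = attr(segs, "band"),
    augmented = attr(segs, "augmented")
  )
}

#' Number of sliding windows over a signal
#'
#' With window `W`, stride `s` and signal length `L` (all in samples), windows
#' start at 0, s, 2s, ... and the count is `floor((L - W) / s) + 1`; no
#' partial window is emitted. A 123-s recording at 160 Hz (19,680 samples)
#' with W = 1,920 and s = 20 gives 889 windows; 125 s gives 905.
#'
#' @param n_samples Signal length L in samples.
#' @param window_samples Window length W in samples.
#' @param stride_samples Stride s in samples.
#' @return Integer window count.
#' @export
sliding_count <- function(n_samples, window_samples, stride_samples) {
  if (stride_samples < 1) abort("stride must be >= 1 sample")
  if (window_samples > n_samples) abort("window longer than signal")
  as.integer((n_samples - window_samples) %/% stride_samples + 1)
}

segments_from_starts <- function(rec, starts0, window_samples) {
  mats <- lapply(starts0, function(s0) {
    rec$data[, (s0 + 1):(s0 + window_samples), drop = FALSE]
  })
  tibble(
    subject_id = rec$subject_id, task = rec$task, run = rec$run,
    start_sample = as.integer(starts0), data = mats
  )
}

#' Cut a recording into non-overlapping windows
#'
#' Test-time segmentation: consecutive windows at starts 0, W, 2W, ...; the
#' trailing remainder is discarded. A 60-s baseline at 160 Hz with 12-s
#' windows yields 5 segments; a 120-s task yields 10.
#'
#' @param rec An [eeg_recording()].
#' @param window_s Window length in seconds (default 12).
#' @return A [segment_set()].
#' @export
cut_nonoverlap <- function(rec, window_s = 12) {
  stopifnot(inherits(rec, "eeg_recording"))
  w <- as.integer(round(window_s * rec$sample_rate))
  L <- n_samples(rec)
  if (L < w) abort("recording shorter than one window")
  k <- L %/% w
  starts0 <- (seq_len(k) - 1) * w
  segment_set(segments_from_starts(rec, starts0, w),
              window_samples = w, sample_rate = rec$sample_rate,
              stride = w, band = rec$band, augmented = FALSE)
}

#' Sliding-window augmentation
#'
#' Training-time augmentation: a window of `window_samples` slides by a
#' constant `stride_samples`, producing heavily overlapping segments (starts
#' 0, s, 2s, ...; count per [sliding_count()]); the window stops at the end
#' of the signal and partial windows are never emitted.
#'
#' @param rec An [eeg_recording()].
#' @param window_samples Window length in samples (default 1,920 = 12 s at
#'   160 Hz).
#' @param stride_samples Stride in samples; 20 corresponds to 125 ms at
#'   160 Hz, and 40 is the standard choice for training.
#' @return A [segment_set()] with `augmented = TRUE`.
#' @export
augment_sliding <- function(rec, window_samples = 1920, stride_samples = 40) {
  stopifnot(inherits(rec, "eeg_recording"))
  L <- n_samples(rec)
  k <- sliding_count(L, window_samples, stride_samples)
  starts0 <- (seq_len(k) - 1) * stride_samples
  segment_set(segments_from_starts(rec, starts0, window_samples),
              window_samples = window_samples, sample_rate = rec$sample_rate,
              stride = stride_samples, band = rec$band, augmented = TRUE)
}

#' Combine segment sets
#'
#' Row-binds segment sets sharing window length and channel count (e.g. the
#' per-session outputs of [augment_sliding()] for a multi-session training
#' set).
#'
#' @param ... Segment sets.
#' @return A [segment_set()].
#' @export
bind_segments <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) && !inherits(sets[[1]], "segment_set")) {
    sets <- sets[[1]]
  }
  w <- unique(vapply(sets, function(s) attr(s, "window_samples"), integer(1)))
  if (length(w) != 1) abort("segment sets have differing window lengths")
  meta <- segment_meta(sets[[1]])
  rows <- bind_rows(lapply(sets, as_tibble))
  segment_set(rows, w, meta$sample_rate, meta$stride, meta$band, meta$augmented)
}

#' Chronological train/validation split
#'
#' Splits each subject's chronologically ordered segment list: the first
#' `ceil(fraction * n)` go to training, the rest to validation (e.g. 500
#' augmented segments at fraction 0.9 give the first 450 for training and the
#' last 50 for validation). No segment appears in both sets.
#'
#' @param segs A [segment_set()].
#' @param train_fraction Proportion in (0, 1); default 0.9.
#' @return List with elements `train` and `validation`, both segment sets.
#' @export
chronological_split <- function(segs, train_fraction = 0.9) {
  stopifnot(inherits(segs, "segment_set"))
  if (!(train_fraction > 0 && train_fraction < 1)) {
    abort("train_fraction must lie strictly between 0 and 1")
  }
  if (nrow(segs) == 0) abort("empty segment set")
  meta <- segment_meta(segs)
  tb <- as_tibble(segs)
  # preserve per-(subject, session) chronological order as listed
  tb <- mutate(group_by(tb, .data$subject_id), .rank = seq_len(n()),
               .ntot = n())
  tb <- ungroup(tb)
  take <- tb$.rank <= ceiling(train_fraction * tb$.ntot)
  mk <- function(rows) {
    rows$.rank <- NULL; rows$.ntot <- NULL
    segment_set(rows, meta$window_samples, meta$sample_rate, meta$stride,
                meta$band, meta$augmented)
  }
  list(train = mk(tb[take, , drop = FALSE]),
       validation = mk(tb[!take, , drop = FALSE]))
}

#' Per-segment z-score normalization (optional, off by default in pipelines)
#'
#' Standardizes each channel of each segment to zero mean and unit variance.
#' Raw filtered microvolts are the standard network input; this is provided
#' for experimentation only.
#'
#' @param segs A [segment_set()].
#' @return A [segment_set()] with standardized data.
#' @export
zscore_segments <- function(segs) {
  stopifnot(inherits(segs, "segment_set"))
  meta <- segment_meta(segs)
  rows <- as_tibble(segs)
  rows$data <- lapply(rows$data, function(m) {
    mu <- rowMeans(m)
    s <- apply(m, 1, sd)
    s[s == 0] <- 1
    (m - mu) / s
  })
  segment_set(rows, meta$window_samples, meta$sample_rate, meta$stride,
              meta$band, meta$augmented)
}

#' Stack a segment set into a 3-D array
#'
#' @param segs A [segment_set()].
#' @return Numeric array of dim (channels, window_samples, n_segments).
#' @export
segments_array <- function(segs) {
  stopifnot(inherits(segs, "segment_set"), nrow(segs) > 0)
  C <- nrow(segs$data[[1]])
  W <- ncol(segs$data[[1]])
  arr <- array(0, c(C, W, nrow(segs)))
  for (i in seq_len(nrow(segs))) arr[, , i] <- segs$data[[i]]
  arr
}

#' Checkpoint a segment set to disk
#'
#' Writes a simple binary container: a float32 payload of the stacked
#' segments plus a JSON sidecar (`<path>.json`) recording shape, subject and
#' session labels, start samples and provenance.
#'
#' @param segs A [segment_set()].
#' @param path Output path for the payload; sidecar goes to `<path>.json`.
#' @return Invisibly, `path`.
#' @export
write_segments <- function(segs, path) {
  arr <- segments_array(segs)
  con <- file(path, "wb")
  writeBin(as.numeric(arr), con, size = 4)
  close(con)
  meta <- segment_meta(segs)
  side <- list(
    shape = dim(arr), subject_id = segs$subject_id, task = segs$task,
    run = segs$run, start_sample = segs$start_sample,
    window_samples = meta$window_samples, sample_rate = meta$sample_rate,
    stride = meta$stride, augmented = meta$augmented,
    band = if (!is.null(meta$band)) unclass(meta$band)
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a segment-set checkpoint written by [write_segments()]
#'
#' @param path Payload path (sidecar expected at `<path>.json`).
#' @return A [segment_set()] (float32 precision).
#' @export
read_segments <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  shape <- as.integer(side$shape)
  con <- file(path, "rb")
  vals <- readBin(con, "numeric", n = prod(shape), size = 4)
  close(con)
  arr <- array(vals, shape)
  rows <- tibble(
    subject_id = as.integer(side$subject_id), task = side$task, run = side$run,
    start_sample = as.integer(side$start_sample),
    data = lapply(seq_len(shape[3]), function(i) arr[, , i, drop = TRUE])
  )
  rows$data <- lapply(rows$data, function(m) matrix(m, shape[1], shape[2]))
  band <- if (length(side$band) >= 2) {
    bandpass_spec(side$band$low_hz, side$band$high_hz)
  }
  segment_set(rows, side$window_samples, side$sample_rate, side$stride,
              band, side$augmented)
}
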