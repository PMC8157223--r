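#' The 64-electrode 10-10 montage used by the Physionet motor movement/imagery
#' recordings
#'
#' Channel labels in acquisition order. The nine-electrode subset used by the
#' region protocols is the union of the frontal (AF3, AFz, AF4), motor-cortex
#' (C1, Cz, C2) and occipital (O1, Oz, O2) triplets.
#'
#' @return Character vector of 64 electrode labels.
#' @export
montage_64 <- function() {
  c(
    "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6",
    "C5", "C3", "C1", "Cz", "C2", "C4", "C6",
    "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6",
    "Fp1", "Fpz", "Fp2",
    "AF7", "AF3", "AFz", "AF4", "AF8",
    "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
    "FT7", "FT8", "T7", "T8", "T9", "T10", "TP7", "TP8",
    "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
    "PO7", "PO3", "POz", "PO4", "PO8",
    "O1", "Oz", "O2", "Iz"
  )
}

#' Electrode region sets for the scalp-region protocols
#'
#' @param region One of `"F"` (frontal), `"M"` (motor cortex), `"O"`
#'   (occipital), `"nine"` (their union) or `"all64"`.
#' @return Character vector of electrode labels.
#' @export
electrode_set <- function(region = c("nine", "F", "M", "O", "all64")) {
  region <- match.arg(region)
  sets <- list(
    F = c("AF3", "AFz", "AF4"),
    M = c("C1", "Cz", "C2"),
    O = c("O1", "Oz", "O2")
  )
  switch(region,
    F = sets$F, M = sets$M, O = sets$O,
    nine = c(sets$F, sets$M, sets$O),
    all64 = montage_64()
  )
}

#' Stride duration in milliseconds
#'
#' Converts a sliding-window stride expressed in samples to milliseconds at a
#' given sampling rate (e.g. 20 samples at 160 Hz is 125 ms).
#'
#' @param stride_samples Stride in samples.
#' @param sample_rate Sampling rate in Hz.
#' @return Stride in milliseconds.
#' @export
stride_ms <- function(stride_samples, sample_rate = 160) {
  stopifnot(stride_samples >= 1, sample_rate > 0)
  1000 * stride_samples / sample_rate
}

# Deterministic substream seed for (seed, subject, task, run) so that adding
# subjects or tasks never shifts another substream. Plain integer hashing kept
# below 2^31.
substream_seed <- function(seed, subject = 0L, task_idx = 0L, run_idx = 0L) {
  s <- (as.double(seed) %% 2147483647)
  for (k in c(subject, task_idx, run_idx)) {
    s <- (s * 69069 + as.double(k) * 12345 + 1) %% 2147483647
  }
  as.integer(s)
}

task_levels <- function() c("EO", "EC", "T1", "T2", "T3", "T4")

task_index <- function(task) {
  i <- match(task, task_levels())
  if (anyNA(i)) {
    abort(paste0("unknown task label: ", paste(task[is.na(i)], collapse = ", ")))
  }
  i
}

run_index <- function(run) {
  i <- match(run, c("R1", "R2", "R3"))
  if (anyNA(i)) abort(paste0("unknown run label: ", paste(run[is.na(i)], collapse = ", ")))
  i
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

sigmoid <- function(x) 1 / (1 + exp(-x))
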