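#' Configuration for the synthetic EEG generator
#'
#' Defines the shape of a synthetic multi-subject, multi-task EEG study. Each
#' subject receives a stable spectral fingerprint: per-channel sinusoid
#' amplitudes in three frequency bands (1-50 Hz, 10-30 Hz and the gamma band
#' 30-50 Hz). Task-dependent multiplicative perturbations and additive white
#' noise are layered on top, so the discriminative signal downstream is band
#' power, and its strength is controlled by `separability`.
#'
#' @param n_subjects Number of subjects.
#' @param n_channels Number of EEG channels (9 and 64 get standard 10-10
#'   montage labels).
#' @param sample_rate Sampling rate in Hz; must exceed twice the highest
#'   synthesized frequency (50 Hz).
#' @param session_lengths Named numeric vector, seconds of recording per task
#'   label. Defaults mirror the motor movement/imagery layout: 60 s baselines
#'   (EO, EC), 120 s tasks (T1-T4). All lengths must be at least 12 s.
#' @param seed Integer master seed; every signal is a deterministic function
#'   of `(seed, subject, task, run)`.
#' @param separability Dimensionless, >= 0. Scales the between-subject spread
#'   of band amplitudes; 0 makes all subjects spectrally identical.
#' @param base_amplitude Median per-band sinusoid amplitude in microvolts;
#'   the ~1 uV default matches the scale of narrow-band (notably gamma)
#'   scalp rhythms.
#' @param noise_sd Standard deviation of the additive Gaussian noise
#'   (microvolts).
#' @param task_shift_sd Log-scale SD of the per-(subject, task) multiplicative
#'   band perturbation; baselines and tasks all get their own draw.
#' @param n_sinusoids Sinusoids summed per band and channel.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 10, n_channels = 9, sample_rate = 160,
                         session_lengths = c(EO = 60, EC = 60, T1 = 120,
                                             T2 = 120, T3 = 120, T4 = 120),
                         seed = 1L, separability = 1,
                         base_amplitude = 1, noise_sd = 0.2,
                         task_shift_sd = 0.02, n_sinusoids = 3) {
  if (length(n_subjects) != 1 || n_subjects < 1) {
    abort("invalid config: n_subjects must be a positive count")
  }
  if (n_channels < 1) abort("invalid config: n_channels must be a positive count")
  if (separability < 0) abort("invalid config: separability must be >= 0")
  if (sample_rate <= 2 * 50) {
    abort("invalid config: sample_rate must exceed twice the highest synthesized frequency (50 Hz)")
  }
  if (any(session_lengths < 12)) abort("invalid config: session lengths must be >= 12 s")
  if (is.null(names(session_lengths)) || any(!nzchar(names(session_lengths)))) {
    abort("invalid config: session_lengths must be named by task label")
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects), n_channels = as.integer(n_channels),
      sample_rate = sample_rate, session_lengths = session_lengths,
      seed = as.integer(seed), separability = separability,
      base_amplitude = base_amplitude, noise_sd = noise_sd,
      task_shift_sd = task_shift_sd, n_sinusoids = as.integer(n_sinusoids),
      bands = list(broad = c(1, 50), beta = c(10, 30), gamma = c(30, 50))
    ),
    class = "synth_config"
  )
}

default_channel_labels <- function(n_channels) {
  if (n_channels == 64) {
    montage_64()
  } else if (n_channels == 9) {
    electrode_set("nine")
  } else {
    paste0("CH", seq_len(n_channels))
  }
}

#' Build a single subject's spectral fingerprint
#'
#' The fingerprint has two stable components, both scaled by the study's
#' `separability`: per-channel band amplitudes, log-normal around
#' `base_amplitude` with log-scale spread `0.15 * separability` (a realistic
#' tens-of-percent inter-individual band-power spread at separability ~3), and
#' per-band spectral peak positions, jittered around a study-wide base set
#' of frequencies with SD `separability` Hz (individual spectral peak
#' frequencies are a stable trait of real EEG). At `separability = 0` every
#' subject has identical amplitudes and identical peak frequencies. Profiles
#' are drawn from a subject-specific substream so that the same
#' `(seed, subject_id)` always regenerates an identical profile and adding
#' subjects never shifts existing ones.
#'
#' @param subject_id Positive integer identity.
#' @param config A [synth_config()].
#' @return An object of class `subject_profile` with fields `subject_id`,
#'   `band_amplitudes` (bands x channels matrix, microvolts), `band_freqs`
#'   (bands x n_sinusoids matrix, Hz, on the 1/60 Hz grid), `noise_sd` and
#'   `task_shift` (task -> per-band multiplier).
#' @export
subject_profile <- function(subject_id, config) {
  stopifnot(inherits(config, "synth_config"), subject_id >= 1)
  n_bands <- length(config$bands)
  grid <- 60  # frequency grid of 1/60 Hz: exact bins for 60 s and 120 s sessions
  # study-wide base peak set, shared by all subjects
  set.seed(substream_seed(config$seed, 0L, 0L, 0L))
  base_k <- lapply(config$bands, function(band) {
    sample(seq(ceiling(band[1] * grid), floor(band[2] * grid)),
           config$n_sinusoids, replace = TRUE)
  })
  tasks <- names(config$session_lengths)
  # study-wide task effect: the same task perturbs every subject's bands alike
  study_shift_z <- matrix(rnorm(n_bands * length(tasks)), n_bands,
                          dimnames = list(NULL, tasks))
  set.seed(substream_seed(config$seed, subject_id, 0L, 0L))
  z <- matrix(rnorm(n_bands * config$n_channels), n_bands, config$n_channels)
  amps <- config$base_amplitude * exp(0.15 * config$separability * z)
  dimnames(amps) <- list(names(config$bands), default_channel_labels(config$n_channels))
  freqs <- matrix(0, n_bands, config$n_sinusoids,
                  dimnames = list(names(config$bands), NULL))
  for (b in seq_len(n_bands)) {
    band <- config$bands[[b]]
    k_lo <- ceiling(band[1] * grid)
    k_hi <- floor(band[2] * grid)
    jitter <- round(config$separability * rnorm(config$n_sinusoids, 0, grid))
    # wrap jitter around the band so peaks never pile up at the edges
    k <- k_lo + ((base_k[[b]] + jitter - k_lo) %% (k_hi - k_lo + 1L))
    freqs[b, ] <- k / grid
  }
  # task perturbation: shared study-wide effect plus a subject-specific
  # idiosyncrasy that vanishes at separability 0 (no identity leak there)
  shifts <- lapply(seq_along(tasks), function(i) {
    exp(config$task_shift_sd *
          (study_shift_z[, i] + config$separability * rnorm(n_bands)))
  })
  names(shifts) <- tasks
  structure(
    list(subject_id = as.integer(subject_id), band_amplitudes = amps,
         band_freqs = freqs, noise_sd = config$noise_sd, task_shift = shifts),
    class = "subject_profile"
  )
}

#' Generate all subject fingerprints for a study
#'
#' @param config A [synth_config()].
#' @return A list of [subject_profile()] objects, one per subject.
#' @export
generate_profiles <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  lapply(seq_len(config$n_subjects), subject_profile, config = config)
}

#' Synthesize one recording session
#'
#' The signal of each channel is a sum over the three bands of `n_sinusoids`
#' sinusoids at the subject's stable peak frequencies (on the 1/60 Hz grid,
#' so a full-record periodogram of a 60 s or 120 s session concentrates each
#' component in a single bin), scaled by the subject's band amplitude times
#' the task perturbation, plus white Gaussian noise. Phases are redrawn per
#' (subject, task, run, channel) from a dedicated substream; amplitudes and
#' frequencies are not, so band power and peak placement are the stable
#' identity signals across runs.
#'
#' @param profile A [subject_profile()].
#' @param task Task label with a defined session length in `config`.
#' @param run Run label `"R1"`, `"R2"` or `"R3"`.
#' @param config The [synth_config()] the profile was built from.
#' @return An [eeg_recording()].
#' @export
synthesize_recording <- function(profile, task, run = "R1", config) {
  stopifnot(inherits(profile, "subject_profile"), inherits(config, "synth_config"))
  if (!task %in% names(config$session_lengths)) {
    abort(paste0("unknown task label: ", task, " (no session length defined)"))
  }
  len_s <- config$session_lengths[[task]]
  fs <- config$sample_rate
  n <- round(len_s * fs)
  tt <- (seq_len(n) - 1) / fs
  n_ch <- config$n_channels
  shift <- profile$task_shift[[task]] %||% rep(1, length(config$bands))

  set.seed(substream_seed(config$seed, profile$subject_id,
                          task_index(task), run_index(run)))
  data <- matrix(0, n_ch, n)
  n_sub <- 5L          # sub-components per spectral peak
  half_bw <- 0.5       # half-bandwidth of a peak in Hz (EEG peaks are ~1-2 Hz wide)
  for (b in seq_along(config$bands)) {
    band <- config$bands[[b]]
    for (ch in seq_len(n_ch)) {
      amp <- profile$band_amplitudes[b, ch] * shift[b] /
        sqrt(config$n_sinusoids * n_sub)
      for (j in seq_len(config$n_sinusoids)) {
        # each peak is a narrow cluster of grid sinusoids, so the rhythm
        # decoheres within a few seconds as real band-limited EEG does
        f0 <- profile$band_freqs[b, j]
        k_lo <- max(ceiling((f0 - half_bw) * len_s), ceiling(band[1] * len_s))
        k_hi <- min(floor((f0 + half_bw) * len_s), floor(band[2] * len_s))
        ks <- sample(seq(k_lo, k_hi), n_sub, replace = TRUE)
        phases <- runif(n_sub, 0, 2 * pi)
        for (q in seq_len(n_sub)) {
          data[ch, ] <- data[ch, ] +
            amp * sin(2 * pi * (ks[q] / len_s) * tt + phases[q])
        }
      }
    }
  }
  if (config$noise_sd > 0) {
    data <- data + matrix(rnorm(n_ch * n, 0, config$noise_sd), n_ch, n)
  }
  eeg_recording(
    subject_id = profile$subject_id, task = task, run = run,
    sample_rate = fs, channel_labels = default_channel_labels(n_ch),
    data = data
  )
}

#' Synthesize a full study
#'
#' Convenience wrapper generating recordings for every subject and every
#' requested (task, run) session.
#'
#' @param config A [synth_config()].
#' @param sessions Tibble or data frame with columns `task` and `run`; default
#'   is every task in `config$session_lengths` with a single run (baselines)
#'   or three runs (T1-T4).
#' @param subjects Integer vector of subject ids; default all.
#' @return A list of [eeg_recording()] objects.
#' @export
synthesize_study <- function(config, sessions = default_sessions(config),
                             subjects = seq_len(config$n_subjects)) {
  profiles <- lapply(subjects, subject_profile, config = config)
  out <- list()
  for (p in profiles) {
    for (i in seq_len(nrow(sessions))) {
      rec <- synthesize_recording(p, sessions$task[i], sessions$run[i], config)
      out[[length(out) + 1]] <- rec
    }
  }
  out
}

#' Default session plan for a synthetic study
#'
#' Baselines (EO, EC) have one run; motor/imagery tasks have three.
#'
#' @param config A [synth_config()].
#' @return Tibble with columns `task`, `run`.
#' @export
default_sessions <- function(config) {
  tasks <- names(config$session_lengths)
  rows <- lapply(tasks, function(tk) {
    runs <- if (tk %in% c("EO", "EC")) "R1" else c("R1", "R2", "R3")
    tibble(task = tk, run = runs)
  })
  bind_rows(rows)
}

#' Write a synthetic study as EDF files
#'
#' Emits one EDF file per (subject, task, run) using the
#' `S{subject:03d}R{run:02d}.edf` naming convention of the Physionet motor
#' movement/imagery layout, so the real-data reading path can be exercised
#' without external data.
#'
#' @param config A [synth_config()].
#' @param dir Output directory (created if missing).
#' @param sessions Session plan as in [synthesize_study()].
#' @param subjects Subject ids to write.
#' @return Invisibly, a tibble of written paths with subject/task/run columns.
#' @export
synth_write_edf <- function(config, dir, sessions = default_sessions(config),
                            subjects = seq_len(config$n_subjects)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (s in subjects) {
    p <- subject_profile(s, config)
    for (i in seq_len(nrow(sessions))) {
      task <- sessions$task[i]; run <- sessions$run[i]
      rec <- synthesize_recording(p, task, run, config)
      rn <- run_number(task, run)
      path <- file.path(dir, sprintf("S%03dR%02d.edf", s, rn))
      write_edf(rec, path)
      rows[[length(rows) + 1]] <- tibble(
        subject_id = s, task = task, run = run, path = path
      )
    }
  }
  invisible(bind_rows(rows))
}
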