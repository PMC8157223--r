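# Shared fixture builders. Everything is generated in code at test time.

# A pure-tone recording for filter tests.
tone_recording <- function(freq_hz, seconds = 60, fs = 160, amplitude = 1,
                           n_channels = 1) {
  tt <- (seq_len(seconds * fs) - 1) / fs
  x <- amplitude * sin(2 * pi * freq_hz * tt)
  eeg_recording(
    subject_id = 1, task = "EO", run = "R1", sample_rate = fs,
    channel_labels = paste0("CH", seq_len(n_channels)),
    data = matrix(rep(x, n_channels), nrow = n_channels, byrow = TRUE)
  )
}

# A flat (constant-zero) recording of given length in samples.
zero_recording <- function(n_samples, fs = 160, n_channels = 1) {
  eeg_recording(
    subject_id = 1, task = "EO", run = "R1", sample_rate = fs,
    channel_labels = paste0("CH", seq_len(n_channels)),
    data = matrix(0, n_channels, n_samples)
  )
}

# Small custom descriptor with architecture-A layer geometry but few filters;
# fast enough for training tests.
tiny_arch_A <- function(n_channels = 9, window = 1920, n_classes = 10,
                        n_filters = c(8, 12, 16), fc_hidden = c(64, 32),
                        embedding_dim = 32) {
  architecture_spec(
    "custom", input_shape = c(n_channels, window), n_classes = n_classes,
    conv_kernels = c(11, 9, 9), conv_strides = c(1, 1, 1),
    pool_sizes = c(2, 2, 2), pool_strides = c(4, 2, 2),
    n_filters = n_filters, fc_hidden = fc_hidden,
    embedding_dim = embedding_dim
  )
}

# Even smaller: 3-second windows for fast optimization tests.
micro_arch <- function(n_channels = 9, window = 480, n_classes = 6,
                       embedding_dim = 16) {
  architecture_spec(
    "custom", input_shape = c(n_channels, window), n_classes = n_classes,
    conv_kernels = c(11, 9, 9), conv_strides = c(1, 1, 1),
    pool_sizes = c(2, 2, 2), pool_strides = c(4, 2, 2),
    n_filters = c(6, 8, 10), fc_hidden = c(32, 24),
    embedding_dim = embedding_dim
  )
}

# Band power of each channel in [lo, hi] Hz from a full-record periodogram.
band_power <- function(data, fs, lo, hi) {
  n <- ncol(data)
  freqs <- (seq_len(n) - 1) * fs / n
  apply(data, 1, function(x) {
    p <- Mod(stats::fft(x))^2 / n
    sum(p[freqs >= lo & freqs <= hi & freqs <= fs / 2])
  })
}

# Independent EER oracle: explicit threshold sweep with counting loops plus
# the same linear-interpolation rule at the FAR/FRR crossing.
oracle_eer <- function(gen, imp) {
  thr <- sort(unique(c(gen, imp)))
  far <- vapply(thr, function(t) sum(imp <= t) / length(imp), numeric(1))
  frr <- vapply(thr, function(t) sum(gen > t) / length(gen), numeric(1))
  d <- far - frr
  i <- which(d >= 0)[1]
  if (i == 1 || d[i] == 0) {
    (far[i] + frr[i]) / 2
  } else {
    a <- (0 - d[i - 1]) / (d[i] - d[i - 1])
    (1 - a) * (far[i - 1] + frr[i - 1]) / 2 + a * (far[i] + frr[i]) / 2
  }
}

# Scored-pairs tibble straight from distance vectors.
pairs_from_scores <- function(gen, imp) {
  tibble::tibble(
    distance = c(gen, imp),
    genuine = rep(c(TRUE, FALSE), c(length(gen), length(imp)))
  )
}
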