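#' Build one evaluation-scenario specification
#'
#' A scenario names the train and test sessions (task/run pairs), the
#' electrode set, the filter band, the augmentation stride and, for the
#' cross-individual protocol, a disjoint subject split.
#'
#' @param name Scenario identifier.
#' @param train_sessions,test_sessions Data frames with columns `task`,
#'   `run`.
#' @param channel_set One of `"all64"`, `"nine"`, `"F"`, `"M"`, `"O"`.
#' @param band A [bandpass_spec()]; default the gamma band 30-50 Hz (the
#'   best-performing one).
#' @param stride Augmentation stride in samples; default 40.
#' @param subject_split Optional list with `train_ids` and `test_ids`
#'   (disjoint subject id vectors) for cross-individual evaluation.
#' @return Object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, train_sessions, test_sessions,
                          channel_set = "nine", band = analysis_band("30-50"),
                          stride = 40, subject_split = NULL) {
  train_sessions <- as_tibble(train_sessions)
  test_sessions <- as_tibble(test_sessions)
  key <- function(s) paste(s$task, s$run)
  if (is.null(subject_split) &&
      length(intersect(key(train_sessions), key(test_sessions))) > 0) {
    abort("train and test sessions overlap without a subject split")
  }
  if (!is.null(subject_split) &&
      length(intersect(subject_split$train_ids, subject_split$test_ids)) > 0) {
    abort("subject split must be disjoint")
  }
  structure(
    list(name = name, train_sessions = train_sessions,
         test_sessions = test_sessions, channel_set = channel_set,
         band = band, stride = stride, subject_split = subject_split),
    class = "scenario_spec"
  )
}

sessions_tb <- function(spec_str) {
  # "T1R1" / "EO" style session strings -> tibble(task, run)
  rows <- lapply(spec_str, function(s) {
    if (s %in% c("EO", "EC")) {
      tibble(task = s, run = "R1")
    } else {
      tibble(task = substr(s, 1, 2), run = substr(s, 3, 4))
    }
  })
  bind_rows(rows)
}

#' The catalog of evaluation scenarios
#'
#' Encodes the four evaluation families as runnable configurations:
#'
#' * `baseline`: train on eyes-open (EO), test on eyes-closed (EC), 64
#'   electrodes.
#' * `P1.<region>.<task>`: region protocol; train R1+R3 of one task on one
#'   electrode triplet (F, M or O, or their nine-electrode union), test R2 of
#'   the same task.
#' * `P2.<task>.<test>`: train R1+R3 of one task, test the second run of
#'   every task plus both baselines (4 x 6 matrix), nine electrodes.
#' * `P3.1` .. `P3.11`: accumulating heterogeneous training sets, test fixed
#'   at T1R2, nine electrodes.
#' * `cross_task.<session>`: one single session for training (the 11 task
#'   runs other than T1R2), test T1R2.
#' * `cross_individual.<train>.<test>`: train on subjects 1-55, test on
#'   subjects 56-109, with EO/EC crossings.
#'
#' @param n_subjects Total subjects (only used for the cross-individual
#'   split; default 109 giving the 55/54 split).
#' @return Named list of [scenario_spec()] objects.
#' @export
scenario_catalog <- function(n_subjects = 109) {
  cat_ <- list()
  add <- function(spec) {
    cat_[[spec$name]] <<- spec
  }
  tasks <- paste0("T", 1:4)

  add(scenario_spec("baseline", sessions_tb("EO"), sessions_tb("EC"),
                    channel_set = "all64"))

  # P1: region x task, train R1+R3, test R2 of the same task
  for (region in c("F", "M", "O", "nine")) {
    for (tk in tasks) {
      add(scenario_spec(
        paste0("P1.", region, ".", tk),
        sessions_tb(paste0(tk, c("R1", "R3"))),
        sessions_tb(paste0(tk, "R2")),
        channel_set = region
      ))
    }
  }

  # P2: train R1+R3 of one task; test second run of every task + baselines
  p2_tests <- c(paste0(tasks, "R2"), "EO", "EC")
  for (tk in tasks) {
    for (te in p2_tests) {
      add(scenario_spec(
        paste0("P2.", tk, ".", te),
        sessions_tb(paste0(tk, c("R1", "R3"))),
        sessions_tb(te),
        channel_set = "nine"
      ))
    }
  }

  # P3: accumulating training sets, test fixed at T1R2
  p3_trains <- list(
    "P3.1" = "T1R1",
    "P3.2" = "T1R3",
    "P3.3" = c("T1R1", "T1R3"),
    "P3.4" = c("T2R1", "T2R2", "T2R3"),
    "P3.5" = c("T1R1", "T1R3", "T2R1"),
    "P3.6" = c("T1R1", "T2R1", "T2R2", "T2R3"),
    "P3.7" = c("T1R1", "T1R3", "T2R1", "T2R2"),
    "P3.8" = c("T1R1", "T1R3", "T2R1", "T2R2", "T2R3"),
    "P3.9" = c("T1R1", "T1R3", "T2R1", "T2R2", "T2R3", "T3R1"),
    "P3.10" = c("T1R1", "T1R3", "T2R1", "T2R2", "T2R3", "T3R1", "T4R1"),
    "P3.11" = c("T1R1", "T1R3", "T2R1", "T2R2", "T2R3", "T3R1", "T4R1", "T4R2")
  )
  for (nm in names(p3_trains)) {
    add(scenario_spec(nm, sessions_tb(p3_trains[[nm]]), sessions_tb("T1R2"),
                      channel_set = "nine"))
  }

  # cross-task: each single session except T1R2 trains a model tested on T1R2
  all_sessions <- as.vector(outer(tasks, paste0("R", 1:3), paste0))
  for (s in setdiff(all_sessions, "T1R2")) {
    add(scenario_spec(paste0("cross_task.", s), sessions_tb(s),
                      sessions_tb("T1R2"), channel_set = "nine"))
  }

  # cross-individual: disjoint subject halves, EO/EC crossings.
  # With the full 109-subject gallery this is the canonical 55/54 split;
  # smaller synthetic studies split at ceiling(n/2).
  half <- if (n_subjects >= 109L) 55L else as.integer(ceiling(n_subjects / 2))
  if (half >= n_subjects) abort("cross-individual split needs at least 2 subjects")
  split <- list(train_ids = seq_len(half),
                test_ids = seq(half + 1L, n_subjects))
  for (tr in c("EO", "EC")) {
    for (te in c("EO", "EC")) {
      add(scenario_spec(
        paste0("cross_individual.", tr, ".", te),
        sessions_tb(tr), sessions_tb(te),
        channel_set = "all64", subject_split = split
      ))
    }
  }
  cat_
}

#' Catalog overview as a tibble
#'
#' @param catalog Output of [scenario_catalog()].
#' @return Tibble with one row per scenario.
#' @export
catalog_summary <- function(catalog = scenario_catalog()) {
  bind_rows(lapply(catalog, function(s) {
    tibble(
      name = s$name,
      train = paste(paste0(s$train_sessions$task, s$train_sessions$run),
                    collapse = ","),
      test = paste(paste0(s$test_sessions$task, s$test_sessions$run),
                   collapse = ","),
      channels = s$channel_set,
      band = paste0(s$band$low_hz, "-", s$band$high_hz),
      stride = s$stride,
      subject_split = !is.null(s$subject_split)
    )
  }))
}

#' Round-trip a scenario through its flat configuration document
#'
#' @param spec A [scenario_spec()].
#' @return A list (JSON-serializable flat document).
#' @export
scenario_to_config <- function(spec) {
  list(
    name = spec$name,
    train_sessions = paste0(spec$train_sessions$task, "_", spec$train_sessions$run),
    test_sessions = paste0(spec$test_sessions$task, "_", spec$test_sessions$run),
    channel_set = spec$channel_set,
    band_low = spec$band$low_hz, band_high = spec$band$high_hz,
    stride = spec$stride,
    train_ids = spec$subject_split$train_ids,
    test_ids = spec$subject_split$test_ids
  )
}

#' @rdname scenario_to_config
#' @param config A list as produced by [scenario_to_config()].
#' @export
scenario_from_config <- function(config) {
  parse_sess <- function(v) {
    bind_rows(lapply(v, function(s) {
      parts <- strsplit(s, "_", fixed = TRUE)[[1]]
      tibble(task = parts[1], run = parts[2])
    }))
  }
  split <- NULL
  if (!is.null(config$train_ids)) {
    split <- list(train_ids = as.integer(config$train_ids),
                  test_ids = as.integer(config$test_ids))
  }
  scenario_spec(
    config$name, parse_sess(config$train_sessions),
    parse_sess(config$test_sessions), channel_set = config$channel_set,
    band = bandpass_spec(config$band_low, config$band_high),
    stride = config$stride, subject_split = split
  )
}

recording_provider <- function(data, config = NULL) {
  if (is.character(data) && length(data) == 1 && dir.exists(data)) {
    function(subject, task, run) {
      path <- file.path(data, sprintf("S%03dR%02d.edf", subject,
                                      run_number(task, run)))
      if (!file.exists(path)) {
        abort(paste0("missing session: subject ", subject, " ", task, run,
                     " (", path, ")"))
      }
      read_record(path)
    }
  } else if (inherits(data, "synth_config")) {
    function(subject, task, run) {
      synthesize_recording(subject_profile(subject, data), task, run, data)
    }
  } else {
    abort("data must be an EDF directory path or a synth_config")
  }
}

#' Run one evaluation scenario end to end
#'
#' Executes the full pipeline: load (or synthesize) each required session,
#' select the scenario's electrodes, band-pass filter the whole recording,
#' sliding-window augment the training sessions, split 90/10
#' chronologically, train the classifier, embed the non-overlapping test
#' segments through the truncated network, and score genuine/impostor pairs.
#'
#' @param spec A [scenario_spec()] (e.g. from [scenario_catalog()]).
#' @param data Either a directory of `S###R##.edf` files or a
#'   [synth_config()] whose recordings are generated on the fly.
#' @param subjects Subject ids (gallery) when no subject split is given.
#' @param model_spec An [architecture_spec()] sized for the scenario's
#'   channels and gallery, or NULL to build the standard architecture A.
#' @param train_cfg A [train_config()].
#' @param se Optional [se_variant_spec()].
#' @param metric Distance for pair scoring: `"euclidean"` (default) or
#'   `"cosine"`.
#' @param seed Seed for weight initialization (training shuffling is seeded
#'   by `train_cfg$seed`).
#' @return List of class `scenario_result`: `result` (a
#'   `verification_result`), `training` (history), `report` (configuration,
#'   seeds, counts).
#' @export
run_scenario <- function(spec, data, subjects = NULL, model_spec = NULL,
                         train_cfg = train_config(), se = NULL,
                         metric = c("euclidean", "cosine"), seed = 1L) {
  metric <- match.arg(metric)
  stopifnot(inherits(spec, "scenario_spec"))
  provider <- recording_provider(data)
  if (!is.null(spec$subject_split)) {
    train_ids <- spec$subject_split$train_ids
    test_ids <- spec$subject_split$test_ids
  } else {
    if (is.null(subjects)) {
      subjects <- if (inherits(data, "synth_config")) seq_len(data$n_subjects)
                  else abort("subjects must be given for a directory data source")
    }
    train_ids <- test_ids <- subjects
  }
  channels <- electrode_set(spec$channel_set)

  prep <- function(subject, task, run) {
    rec <- provider(subject, task, run)
    rec <- select_channels(rec, channels)
    bandpass(rec, spec$band)
  }

  train_sets <- list()
  for (s in train_ids) {
    for (i in seq_len(nrow(spec$train_sessions))) {
      rec <- prep(s, spec$train_sessions$task[i], spec$train_sessions$run[i])
      train_sets[[length(train_sets) + 1]] <-
        augment_sliding(rec, stride_samples = spec$stride)
    }
  }
  train_all <- bind_segments(train_sets)
  split <- chronological_split(train_all, 0.9)

  if (is.null(model_spec)) {
    model_spec <- architecture_spec(
      "A", input_shape = c(length(channels), attr(train_all, "window_samples")),
      n_classes = length(train_ids)
    )
  }
  stopifnot(model_spec$n_classes == length(train_ids))
  model <- build_network(model_spec, se = se, seed = seed)
  val <- if (nrow(split$validation) > 0) split$validation
  fit <- train_classifier(model, split$train, val, train_cfg)

  test_sets <- list()
  for (s in test_ids) {
    for (i in seq_len(nrow(spec$test_sessions))) {
      rec <- prep(s, spec$test_sessions$task[i], spec$test_sessions$run[i])
      test_sets[[length(test_sets) + 1]] <- cut_nonoverlap(rec, 12)
    }
  }
  test_all <- bind_segments(test_sets)
  embs <- embed_segments(fit$model, test_all)
  pairs <- score_all_pairs(embs, metric = metric)
  result <- det_and_eer(pairs)

  report <- list(
    scenario = scenario_to_config(spec),
    seed = seed, train_seed = train_cfg$seed,
    stride = spec$stride,
    band = c(spec$band$low_hz, spec$band$high_hz),
    channel_set = spec$channel_set, n_channels = length(channels),
    architecture = model_spec$name, metric = metric,
    se_variant = if (!is.null(se)) se$variant, se_r = if (!is.null(se)) se$r,
    n_train_segments = nrow(split$train),
    n_val_segments = nrow(split$validation),
    n_test_segments = nrow(test_all),
    n_genuine = result$n_genuine, n_impostor = result$n_impostor,
    train_subjects = train_ids, test_subjects = test_ids
  )
  structure(
    list(result = result, training = fit$history, report = report,
         model = fit$model, embeddings = embs),
    class = "scenario_result"
  )
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> %s\n", x$report$scenario$name))
  print(x$result)
  invisible(x)
}

#' @method glance scenario_result
#' @export
glance.scenario_result <- function(x, ...) {
  mutate(glance(x$result), scenario = x$report$scenario$name, .before = 1)
}
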