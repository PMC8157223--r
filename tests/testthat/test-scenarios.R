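test_that("the scenario catalog encodes the published protocol tables", {
  cat_ <- scenario_catalog()

  # baseline: EO train, EC test, all 64 electrodes
  expect_equal(cat_$baseline$train_sessions$task, "EO")
  expect_equal(cat_$baseline$test_sessions$task, "EC")
  expect_equal(cat_$baseline$channel_set, "all64")

  # P3.11 accumulates exactly the eight published sessions
  p311 <- cat_$P3.11$train_sessions
  expect_equal(nrow(p311), 8)
  expect_setequal(paste0(p311$task, p311$run),
                  c("T1R1", "T1R3", "T2R1", "T2R2", "T2R3",
                    "T3R1", "T4R1", "T4R2"))
  expect_equal(length(grep("^P3\\.", names(cat_))), 11)

  # P2 is a 4 x 6 train/test matrix
  p2 <- grep("^P2\\.", names(cat_), value = TRUE)
  expect_length(p2, 24)

  # cross-task: 11 single-session trainings, all tested on T1R2
  ct <- cat_[grep("^cross_task\\.", names(cat_))]
  expect_length(ct, 11)
  for (s in ct) {
    expect_equal(nrow(s$train_sessions), 1)
    expect_equal(paste0(s$test_sessions$task, s$test_sessions$run), "T1R2")
  }

  # region protocol: 4 tasks x (3 regions + union)
  expect_length(grep("^P1\\.", names(cat_)), 16)

  # cross-individual: subjects 1-55 train, 56-109 test
  ci <- cat_$cross_individual.EO.EC
  expect_equal(ci$subject_split$train_ids, 1:55)
  expect_equal(ci$subject_split$test_ids, 56:109)
  expect_length(grep("^cross_individual\\.", names(cat_)), 4)
})

test_that("no scenario shares a session between train and test without a subject split", {
  for (s in scenario_catalog()) {
    if (is.null(s$subject_split)) {
      tr <- paste(s$train_sessions$task, s$train_sessions$run)
      te <- paste(s$test_sessions$task, s$test_sessions$run)
      expect_length(intersect(tr, te), 0)
    } else {
      expect_length(intersect(s$subject_split$train_ids,
                              s$subject_split$test_ids), 0)
    }
  }
})

test_that("every scenario round-trips through its flat config document", {
  for (s in scenario_catalog()) {
    back <- scenario_from_config(scenario_to_config(s))
    expect_equal(back$train_sessions, s$train_sessions, info = s$name)
    expect_equal(back$test_sessions, s$test_sessions, info = s$name)
    expect_equal(back$channel_set, s$channel_set)
    expect_equal(back$band, s$band)
    expect_equal(back$stride, s$stride)
    expect_equal(back$subject_split, s$subject_split)
  }
})

test_that("a scenario run is deterministic and reports its configuration", {
  cfg <- synth_config(n_subjects = 3, n_channels = 9, seed = 41,
                      separability = 2,
                      session_lengths = c(EO = 60, EC = 60))
  spec <- scenario_spec("baseline", data.frame(task = "EO", run = "R1"),
                        data.frame(task = "EC", run = "R1"),
                        channel_set = "nine", stride = 400)
  ms <- tiny_arch_A(n_classes = 3, n_filters = c(4, 6, 8),
                    fc_hidden = c(24, 16), embedding_dim = 16)
  tc <- train_config(lr_schedule = data.frame(lr = 0.01, epochs = 2),
                     batch_size = 20, seed = 5)
  r1 <- run_scenario(spec, cfg, model_spec = ms, train_cfg = tc, seed = 6)
  r2 <- run_scenario(spec, cfg, model_spec = ms, train_cfg = tc, seed = 6)
  expect_identical(r1$result$eer, r2$result$eer)

  rep <- r1$report
  expect_equal(rep$stride, 400)
  expect_equal(rep$band, c(30, 50))
  expect_equal(rep$n_channels, 9)
  expect_equal(rep$n_test_segments, 15)           # 3 subjects x 5 segments
  expect_equal(rep$n_genuine, r1$result$n_genuine)
  expect_gt(rep$n_train_segments, 0)
  g <- glance(r1)
  expect_named(g, c("scenario", "eer", "decidability",
                    "n_genuine", "n_impostor"))
})

test_that("a missing session in a directory source is reported", {
  spec <- scenario_spec("baseline", data.frame(task = "EO", run = "R1"),
                        data.frame(task = "EC", run = "R1"),
                        channel_set = "nine")
  dir <- withr::local_tempdir()
  expect_error(
    run_scenario(spec, dir, subjects = 1,
                 model_spec = tiny_arch_A(n_classes = 1)),
    "missing session"
  )
})

test_that("scenario runs work from EDF directories written by the generator", {
  cfg <- synth_config(n_subjects = 2, n_channels = 9, seed = 43,
                      separability = 2,
                      session_lengths = c(EO = 24, EC = 24))
  dir <- withr::local_tempdir()
  synth_write_edf(cfg, dir, sessions = tibble::tibble(task = c("EO", "EC"),
                                                      run = c("R1", "R1")))
  spec <- scenario_spec("baseline", data.frame(task = "EO", run = "R1"),
                        data.frame(task = "EC", run = "R1"),
                        channel_set = "nine", stride = 192)
  ms <- tiny_arch_A(n_classes = 2, n_filters = c(4, 6, 8),
                    fc_hidden = c(16, 12), embedding_dim = 8)
  tc <- train_config(lr_schedule = data.frame(lr = 0.01, epochs = 1),
                     batch_size = 10, seed = 3)
  res <- run_scenario(spec, dir, subjects = 1:2, model_spec = ms,
                      train_cfg = tc, seed = 4)
  expect_s3_class(res$result, "verification_result")
  expect_equal(res$report$n_test_segments, 4)     # 2 subjects x 2 segments
})
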