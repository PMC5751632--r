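test_that("simulate -> train -> recognize pipeline runs from config files", {
  dir <- withr::local_tempdir()
  cfg <- list(seed = 42, n_subjects = 2, minutes_per_subject = 2,
              sensor_file = file.path(dir, "sensors.csv"),
              annotations_file = file.path(dir, "annotations.csv"),
              model_file = file.path(dir, "model.json"),
              output_file = file.path(dir, "decisions.csv"))
  ds <- cli_simulate(cfg, quiet = TRUE)
  # seed echoed into the output header comment
  expect_match(readLines(cfg$sensor_file, n = 1), "seed: 42")
  # files parse back through the windowing layer
  recs <- read_sensor_csv(cfg$sensor_file)
  w <- segment_windows(recs)
  expect_gt(nrow(w), 100)
  ann <- read_annotations_csv(cfg$annotations_file)
  expect_true(all(c("eating", "subject_property") %in% names(ann)))

  model <- cli_train(cfg, quiet = TRUE)
  expect_s3_class(model, "mbn_model")
  out <- cli_recognize(cfg, quiet = TRUE)
  expect_equal(nrow(out), nrow(w))
  expect_true(all(out$decision %in% c("eating", "non-eating")))
  expect_true(all(out$posterior >= 0 & out$posterior <= 1))
})

test_that("retraining identical inputs yields an identical model file", {
  dir <- withr::local_tempdir()
  cfg <- list(seed = 7, n_subjects = 2, minutes_per_subject = 2,
              sensor_file = file.path(dir, "s.csv"),
              annotations_file = file.path(dir, "a.csv"),
              model_file = file.path(dir, "m1.json"))
  cli_simulate(cfg, quiet = TRUE)
  cli_train(cfg, quiet = TRUE)
  h1 <- readLines(cfg$model_file)
  cfg$model_file <- file.path(dir, "m2.json")
  cli_train(cfg, quiet = TRUE)
  expect_identical(h1, readLines(cfg$model_file))
})

test_that("model JSON round-trips and reproduces posteriors exactly", {
  d <- small_dataset()
  model <- train_model(d$windows[1:200, ], d$contexts[1:200, ])
  path <- withr::local_tempfile(fileext = ".json")
  save_model(model, path)
  back <- load_model(path)
  expect_equal(back$threshold, model$threshold)
  expect_equal(back$cpts$eating, model$cpts$eating, tolerance = 1e-14)
  w <- d$windows[201:230, ]
  expect_equal(predict_windows(back, w)$posterior,
               predict_windows(model, w)$posterior, tolerance = 1e-12)
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(cpts = list()), bad, auto_unbox = TRUE)
  expect_error(load_model(bad), "structure")
})

test_that("training evaluated on its own data beats the class prior", {
  dir <- withr::local_tempdir()
  cfg <- list(seed = 11, n_subjects = 2, minutes_per_subject = 3,
              sensor_file = file.path(dir, "s.csv"),
              annotations_file = file.path(dir, "a.csv"),
              model_file = file.path(dir, "m.json"),
              output_file = file.path(dir, "metrics.json"),
              roc_file = file.path(dir, "roc.csv"))
  cli_simulate(cfg, quiet = TRUE)
  cli_train(cfg, quiet = TRUE)
  res <- cli_evaluate(cfg, quiet = TRUE)
  w <- segment_windows(read_sensor_csv(cfg$sensor_file))
  prior <- max(mean(w$is_eating), 1 - mean(w$is_eating))
  expect_gt(res$metrics$accuracy, 100 * prior)
  js <- jsonlite::read_json(cfg$output_file)
  expect_equal(js$metrics$accuracy, res$metrics$accuracy, tolerance = 1e-9)
  expect_true(file.exists(cfg$roc_file))
})

test_that("recognition tolerates a channel missing from the whole stream", {
  dir <- withr::local_tempdir()
  cfg <- list(seed = 13, n_subjects = 2, minutes_per_subject = 2,
              sensor_file = file.path(dir, "s.csv"),
              annotations_file = file.path(dir, "a.csv"),
              model_file = file.path(dir, "m.json"),
              output_file = file.path(dir, "d.csv"))
  ds <- cli_simulate(cfg, quiet = TRUE)
  cli_train(cfg, quiet = TRUE)
  # drop h_lux entirely from the stream to be recognized
  recs <- ds$records[ds$records$channel != "h_lux", ]
  write_sensor_csv(recs, cfg$sensor_file)
  expect_warning(out <- cli_recognize(cfg, quiet = TRUE), "h_lux")
  expect_gt(nrow(out), 0)
  expect_true(all(is.finite(out$posterior)))
  expect_true(all(out$posterior > 0 & out$posterior < 1))

  # empty input produces an empty decisions file with a header
  write_sensor_csv(ds$records[0, ], cfg$sensor_file)
  suppressWarnings(out0 <- cli_recognize(cfg, quiet = TRUE))
  expect_equal(nrow(out0), 0L)
  expect_true(file.exists(cfg$output_file))
})

test_that("run configs validate and fill defaults", {
  cfg <- read_run_config(list(seed = 1))
  expect_equal(cfg$threshold, 0.6)
  expect_equal(cfg$alpha, 1)
  expect_equal(cfg$window_s, 1)
  expect_error(read_run_config(list(threshold = 1.5)))
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines("seed: 9\nthreshold: 0.5", path)
  cfg2 <- read_run_config(path)
  expect_equal(cfg2$seed, 9)
  expect_equal(cfg2$threshold, 0.5)
})
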