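#' End-to-end pipeline configuration
#'
#' Settings for [run_pipeline()]: simulation scale, preprocessing,
#' grading, labeling, the toy-width model and training, and evaluation.
#' Defaults are sized so the whole flow (simulate, align, preprocess,
#' grade, label, train, evaluate) runs in minutes on one CPU.
#'
#' @param n_patients Number of simulated patients.
#' @param n_measurements Glucose measurements per patient.
#' @param spacing_minutes Mean spacing between measurements.
#' @param value_range Glucose range (mg/dL) for simulated measurements.
#' @param heart_rate_range Heart-rate range sampled per patient (bpm).
#' @param noise_sd,artifact_burst_rate Degradation levels passed to the
#'   generator.
#' @param max_segments_per_measurement Cap on segments kept per
#'   measurement window.
#' @param filter A [filter_spec()].
#' @param thresholds A [threshold_config()].
#' @param clamp A [step_clamp()].
#' @param grades Quality grades admitted to training (default `"A"`).
#' @param soft_label_radius Soft-label neighbour radius.
#' @param width_multiplier Model width multiplier (default 1/8 toy width).
#' @param train A [train_config()].
#' @param eval_mode Clarke zoning mode, `"banded"` or `"canonical"`.
#' @param seed Global pipeline seed; every stage seed derives from it.
#' @param out_dir Output directory for artifacts (`NULL` for a tempdir).
#'
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_patients = 4, n_measurements = 3,
                            spacing_minutes = 20, value_range = c(90, 220),
                            heart_rate_range = c(55, 100),
                            noise_sd = 0, artifact_burst_rate = 0,
                            max_segments_per_measurement = 12,
                            filter = filter_spec(),
                            thresholds = threshold_config(),
                            clamp = step_clamp(),
                            grades = "A", soft_label_radius = 2,
                            width_multiplier = 1 / 8,
                            train = train_config(max_epochs = 10),
                            eval_mode = "banded",
                            seed = 1L, out_dir = NULL) {
  structure(
    list(n_patients = n_patients, n_measurements = n_measurements,
         spacing_minutes = spacing_minutes, value_range = value_range,
         heart_rate_range = heart_rate_range, noise_sd = noise_sd,
         artifact_burst_rate = artifact_burst_rate,
         max_segments_per_measurement = max_segments_per_measurement,
         filter = filter, thresholds = thresholds, clamp = clamp,
         grades = grades, soft_label_radius = soft_label_radius,
         width_multiplier = width_multiplier, train = train,
         eval_mode = eval_mode, seed = as.integer(seed), out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Simulate a labeled multi-patient dataset
#'
#' Generates, for each simulated patient, a sparse glucose timeline and a
#' continuous PPG record covering it, extracts glucose-aligned 10-s
#' segments, preprocesses them, grades them, and attaches glucose labels
#' and auxiliary history features.
#'
#' @param config A [pipeline_config()].
#' @return A tibble with one row per surviving segment (grading columns,
#'   `segment` list-column, label and auxiliary columns) plus stage counts
#'   in attribute `stage_counts`.
#' @export
simulate_dataset <- function(config = pipeline_config()) {
  all_rows <- list()
  counts <- c(extracted = 0L, preprocessed = 0L, graded = 0L)
  for (pt in seq_len(config$n_patients)) {
    pt_seed <- config$seed * 1000L + pt
    pid <- sprintf("sim-%03d", pt)
    glucose <- generate_glucose_timeline(
      config$n_measurements, config$value_range,
      config$spacing_minutes, seed = pt_seed, patient_id = pid,
      start_time = 600
    )
    span_end <- max(glucose$time) + 9 * 60
    duration <- ceiling(span_end + 10)
    hr <- with_seed(pt_seed + 1L, {
      round(runif(1, config$heart_rate_range[1], config$heart_rate_range[2]))
    })
    rec <- generate_segment(synth_config(
      duration_s = duration, heart_rate_bpm = hr,
      noise_sd = config$noise_sd,
      artifact_burst_rate = config$artifact_burst_rate,
      baseline_amplitude = 0.1, seed = pt_seed + 2L
    ))$segment
    rec$patient_id <- pid

    windows <- extract_windows(rec, glucose)
    if (nrow(windows) == 0) next
    windows <- windows |>
      dplyr::group_by(.data$measurement_time) |>
      dplyr::slice_head(n = config$max_segments_per_measurement) |>
      dplyr::ungroup()
    counts["extracted"] <- counts["extracted"] + nrow(windows)

    prep <- preprocess_segments(windows, config$filter)
    counts["preprocessed"] <- counts["preprocessed"] + nrow(prep)
    if (nrow(prep) == 0) next

    graded <- grade_segments(prep, config$thresholds, config$clamp)
    counts["graded"] <- counts["graded"] + nrow(graded)
    if (nrow(graded) == 0) next

    # history features use strictly prior measurements; segments of a
    # patient's first measurement have no history and are dropped
    graded <- graded[graded$measurement_time > min(glucose$time), ,
                     drop = FALSE]
    if (nrow(graded) == 0) next
    aux <- purrr::map_dfr(seq_len(nrow(graded)), function(i) {
      aux_features(glucose, graded$measurement_time[i])
    })
    all_rows[[pt]] <- dplyr::bind_cols(graded, aux)
  }
  out <- dplyr::bind_rows(all_rows)
  attr(out, "stage_counts") <- counts
  out
}

#' Run the full PPG-to-glucose pipeline on synthetic data
#'
#' Simulates records and glucose timelines, aligns and preprocesses
#' segments, grades signal quality, keeps the configured grades, builds
#' soft labels and auxiliary features, balances classes, trains the
#' (toy-width) ResNet-Transformer classifier, evaluates MARD and Clarke
#' zone occupancy on the held-out validation split, and writes artifacts
#' plus a manifest with per-stage counts and file hashes.
#'
#' @param config A [pipeline_config()].
#' @return A `ppg_run` list: `manifest`, `report` (a `ppg_eval`), `fit`
#'   (a `glucose_fit`), `data` (the labeled segment table), `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  out_dir <- config$out_dir %||% file.path(tempdir(), "ppglucose-run")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  dataset <- simulate_dataset(config)
  if (nrow(dataset) == 0) stop("pipeline stage 'simulate' produced no segments")
  counts <- attr(dataset, "stage_counts")

  kept <- dataset[as.character(dataset$grade) %in% config$grades, ,
                  drop = FALSE]
  if (nrow(kept) == 0) {
    stop("pipeline stage 'grade-filter' removed every segment (grades: ",
         paste(config$grades, collapse = ","), ")")
  }

  kept$class <- suppressWarnings(discretize_glucose(kept$glucose_mgdl))
  balanced <- balance_classes(kept, seed = config$seed + 17L)

  data <- build_training_data(balanced, radius = config$soft_label_radius)
  mcfg <- model_config(
    input_length = ncol(data$x),
    width_multiplier = config$width_multiplier
  )
  model <- build_model(mcfg, seed = config$seed + 23L)
  fit <- train_model(model, data, config$train)

  tcfg <- config$train
  n <- nrow(data$x)
  val_idx <- with_seed(tcfg$seed, {
    sample.int(n)[seq_len(max(1, floor(tcfg$val_fraction * n)))]
  })
  pred <- predict_glucose(fit, data$x[val_idx, , drop = FALSE],
                          data$aux[val_idx, , drop = FALSE])
  report <- eval_report(pred, data$glucose[val_idx], config$eval_mode)

  files <- list(
    glucose = file.path(out_dir, "labels.csv"),
    grades = file.path(out_dir, "grades.csv"),
    predictions = file.path(out_dir, "predictions.csv"),
    log = file.path(out_dir, "training_log.csv"),
    report = file.path(out_dir, "report.json")
  )
  utils::write.csv(
    dplyr::select(balanced, -dplyr::any_of(c("segment", "fiducials"))),
    files$glucose, row.names = FALSE
  )
  utils::write.csv(
    dplyr::count(dataset, .data$grade, .drop = FALSE),
    files$grades, row.names = FALSE
  )
  utils::write.csv(
    data.frame(reference = data$glucose[val_idx], predicted = pred),
    files$predictions, row.names = FALSE
  )
  utils::write.csv(fit$log, files$log, row.names = FALSE)
  jsonlite::write_json(glance(report), files$report, auto_unbox = TRUE,
                       digits = NA)

  manifest <- list(
    seed = config$seed,
    stage_counts = c(
      as.list(counts),
      list(grade_kept = nrow(kept), balanced = nrow(balanced),
           trained_on = nrow(data$x) - length(val_idx),
           evaluated = length(val_idx))
    ),
    grades_kept = config$grades,
    file_hashes = as.list(tools::md5sum(unlist(files))),
    mard_percent = report$mard_percent
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  structure(
    list(manifest = manifest, report = report, fit = fit, data = balanced,
         out_dir = out_dir),
    class = "ppg_run"
  )
}

#' @export
print.ppg_run <- function(x, ...) {
  cat("<ppg_run>\n seed:", x$manifest$seed, "\n counts:",
      paste(names(x$manifest$stage_counts),
            unlist(x$manifest$stage_counts), sep = "=", collapse = " "),
      "\n")
  print(x$report)
  invisible(x)
}

#' Build a small labeled grade-A dataset for training sanity checks
#'
#' Draws a grade-A training set with the same structure the full pipeline
#' produces: several simulated patients, sparse glucose measurements, and
#' many 10-s segments per measurement window sharing that measurement's
#' label and history features. A little measurement noise keeps every
#' waveform distinct, as real grade-A PPG is. Used by the toy overfit run
#' that validates the loss machinery, gradients and optimizer end to end.
#'
#' @param n_segments Number of grade-A segments to return.
#' @param seed Integer seed.
#' @param noise_sd Gaussian noise level for the generator (default 0.03,
#'   small enough that most segments remain grade A).
#' @return A tibble with `segment`, `glucose_mgdl`, auxiliary feature
#'   columns, `grade`, and `class`.
#' @export
make_toy_dataset <- function(n_segments = 200, seed = 1L, noise_sd = 0.03) {
  cfg <- pipeline_config(
    n_patients = ceiling(n_segments / 36) + 1, n_measurements = 5,
    spacing_minutes = 30, max_segments_per_measurement = 12,
    noise_sd = noise_sd, seed = seed
  )
  ds <- simulate_dataset(cfg)
  out <- utils::head(ds[ds$grade == "A", , drop = FALSE], n_segments)
  out$class <- suppressWarnings(discretize_glucose(out$glucose_mgdl))
  out
}
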