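# End-to-end orchestration: cohort in (synthetic or logged), per-recording
# metrics report + group summaries + classification out.

#' Default analysis parameters
#'
#' The parameter block driving [run_pipeline()] and [analyze_recording()]:
#' 200 ms minimum dwell, 60 Hz gaze rate, 14,000-frame common duration,
#' n-gram lengths 3..6, 5-fold cross-validation with 35 principal
#' components and 10 cosine-KNN neighbours, 0.1 Nm callout tolerance, and
#' the instructed flight targets (130 kt, vertical speed in
#' (-800, +500) ft/min, heading 143 deg).
#'
#' @return Named list of parameters.
#' @export
pipeline_defaults <- function() {
  list(
    min_dwell = 0.2,
    rate = 60,
    n_frames = 14000,
    ngram_lengths = 3:6,
    k_folds = 5,
    n_components = 35,
    neighbors = 10,
    k_scope = "pooled",
    callout_tolerance = 0.1,
    targets = list(
      speed = target_spec("point", value = 130, units = "kt"),
      vertical_speed = target_spec("band", low = -800, high = 500,
                                   units = "ft/min"),
      heading = target_spec("point", value = 143, units = "deg")
    )
  )
}

#' Compute the scanning-metric report for one recording
#'
#' Runs the eye-tracking pipeline on one gaze stream: trim to the common
#' duration (when the stream is long enough), segment, clean, derive
#' transitions, and compute dwell statistics, matrix density, gaze
#' transition entropy and Lempel-Ziv complexity. Flight RMSEs and callout
#' omissions are added when traces/calls are supplied. The coefficient K
#' under pooled standardization is a cohort-level quantity and is filled in
#' by [run_pipeline()]; here `k` is `NA` unless `k_scope =
#' "per-recording"`.
#'
#' @param stream A [gaze_stream()].
#' @param model A [world_model()].
#' @param params Parameter list as from [pipeline_defaults()].
#' @param traces Optional named list of flight traces (`list(time,
#'   values)`), matched by name to `params$targets`.
#' @param calls,marks Optional callout distances and expected marks (Nm).
#' @param id Recording identifier for the report.
#' @return A list with `report` (the metrics list), `seq` (cleaned
#'   `dwell_sequence`), `transitions`, and `tm` (the
#'   [transition_matrix()]).
#' @export
analyze_recording <- function(stream, model, params = pipeline_defaults(),
                              traces = NULL, calls = NULL, marks = NULL,
                              id = stream$source_id %||% "recording") {
  params <- utils::modifyList(pipeline_defaults(), params)
  if (length(stream$aoi) > params$n_frames)
    stream <- trim_to_duration(stream, params$n_frames)
  seq <- clean_sequence(segment_dwells(stream), min_dwell = params$min_dwell)
  trans <- build_transitions(seq, model)
  tm <- transition_matrix(trans, m = model$m, labels = aoi_labels(model))
  stats <- scanning_statistics(seq, m = model$m)
  gte <- if (nrow(seq) >= 2L)
    gaze_transition_entropy(tm, stationary_distribution(seq, m = model$m))
  else NA_real_
  lzc <- if (nrow(seq) >= 1L) lempel_ziv_complexity(seq$aoi) else NA_integer_
  k <- NA_real_
  if (identical(params$k_scope, "per-recording") && nrow(trans) >= 2L)
    k <- coefficient_k(k_input(seq, model),
                       scope = "per-recording")[[1]]$k_mean
  rmse <- list()
  if (!is.null(traces)) {
    for (p in intersect(names(traces), names(params$targets)))
      rmse[[p]] <- rmse_deviation(traces[[p]], params$targets[[p]])
  }
  omissions <- if (!is.null(calls) && !is.null(marks))
    count_omissions(marks, calls, tolerance = params$callout_tolerance)
  else NA_integer_
  report <- list(
    id = id,
    n_dwells = stats$n_dwells,
    mean_dwell_time = stats$mean_dwell_time,
    outside_share = stats$outside_share,
    matrix_density = matrix_density(tm),
    gte = gte,
    lzc = lzc,
    k = k,
    k_scope = params$k_scope,
    rmse = rmse,
    omissions = omissions
  )
  list(report = report, seq = seq, transitions = trans, tm = tm)
}

#' Run the full cohort analysis
#'
#' Obtains a cohort — either simulated from the configuration's `synthesis`
#' block or read from `input_dir` (gaze_*.csv / flight_*.csv / manifest.csv
#' as written by [write_cohort()]) — analyses every recording, computes the
#' pooled-scope coefficient K across the cohort, mines group-common
#' n-grams for each gram length, and (when every group has at least
#' `k_folds` members) cross-validates the cosine-KNN expertise classifier
#' on the flattened transition matrices. Reports are returned and, when
#' `out_dir` is given, written as per-recording JSON files, a summary CSV,
#' and a classification JSON.
#'
#' @param config A list, or path to a JSON file, with optional elements
#'   `synthesis` (`profiles` — preset names or profile lists —,
#'   `n_per_group`, `n_frames`, `seed`), `input_dir`, `world_model` (path;
#'   default bundled model), and `params` (overrides of
#'   [pipeline_defaults()]).
#' @param out_dir Optional output directory.
#' @param seed Optional master-seed override for the synthesis block.
#' @return A list of class `"pipeline_result"`: `reports` (per recording),
#'   `summary` (data frame), `groups` (per-group common n-gram counts and
#'   ranked tables), `classification` (a
#'   [crossvalidated_knn()] report or `NULL`), `provenance`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL, seed = NULL) {
  if (is.character(config))
    config <- jsonlite::fromJSON(config, simplifyVector = FALSE)
  params <- utils::modifyList(pipeline_defaults(), config$params %||% list())
  model <- if (is.null(config$world_model)) default_world_model()
           else load_world_model(config$world_model)

  labels <- NULL
  traces_list <- list(); calls_list <- list(); marks_list <- list()
  if (!is.null(config$synthesis)) {
    syn <- config$synthesis
    syn_seed <- seed %||% syn$seed %||% 1
    profs <- lapply(syn$profiles %||% c("expert-like", "novice-like"),
                    function(p) if (inherits(p, "group_profile")) p
                                else make_profile(p, m = model$m))
    cohort <- simulate_cohort(profs, n_per_group = syn$n_per_group %||% 16,
                              n_frames = syn$n_frames %||% params$n_frames,
                              seed = syn_seed)
    streams <- lapply(cohort$recordings, `[[`, "stream")
    traces_list <- lapply(cohort$recordings, `[[`, "traces")
    calls_list <- lapply(cohort$recordings, `[[`, "calls")
    marks_list <- lapply(cohort$recordings, `[[`, "marks")
    labels <- cohort$manifest$profile
    used_seed <- syn_seed
  } else if (!is.null(config$input_dir)) {
    files <- sort(list.files(config$input_dir, pattern = "^gaze_.*\\.csv$",
                             full.names = TRUE))
    if (length(files) == 0L)
      stop_input("no gaze logs (gaze_*.csv) found in ", config$input_dir)
    streams <- lapply(files, read_gaze_log, model = model,
                      rate = params$rate)
    flight_files <- sub("gaze_", "flight_", files)
    traces_list <- lapply(flight_files, function(f)
      if (file.exists(f)) read_flight_log(f) else NULL)
    manifest_path <- file.path(config$input_dir, "manifest.csv")
    if (file.exists(manifest_path))
      labels <- utils::read.csv(manifest_path)$profile
    used_seed <- seed %||% NA_integer_
  } else {
    stop_input("config needs either a 'synthesis' block or an 'input_dir'")
  }

  n <- length(streams)
  analyses <- vector("list", n)
  for (i in seq_len(n)) {
    analyses[[i]] <- analyze_recording(
      streams[[i]], model, params,
      traces = if (length(traces_list)) traces_list[[i]] else NULL,
      calls = if (length(calls_list)) calls_list[[i]] else NULL,
      marks = if (length(marks_list)) marks_list[[i]] else NULL,
      id = streams[[i]]$source_id %||% sprintf("recording_%03d", i)
    )
  }

  # pooled-scope coefficient K across the whole cohort
  if (identical(params$k_scope, "pooled")) {
    usable <- which(vapply(analyses, function(a) nrow(a$transitions) >= 1L,
                           logical(1)))
    if (length(usable) >= 1L) {
      kres <- coefficient_k(lapply(analyses[usable], function(a)
        k_input(a$seq, model)), scope = "pooled")
      for (j in seq_along(usable))
        analyses[[usable[j]]]$report$k <- kres[[j]]$k_mean
    }
  }

  reports <- lapply(analyses, `[[`, "report")
  summary_df <- data.frame(
    id = vapply(reports, `[[`, character(1), "id"),
    group = if (is.null(labels)) NA_character_ else as.character(labels),
    n_dwells = vapply(reports, `[[`, numeric(1), "n_dwells"),
    mean_dwell_time = vapply(reports, `[[`, numeric(1), "mean_dwell_time"),
    outside_share = vapply(reports, `[[`, numeric(1), "outside_share"),
    matrix_density = vapply(reports, `[[`, numeric(1), "matrix_density"),
    gte = vapply(reports, `[[`, numeric(1), "gte"),
    lzc = vapply(reports, function(r) as.numeric(r$lzc), numeric(1)),
    k = vapply(reports, `[[`, numeric(1), "k"),
    omissions = vapply(reports, function(r) as.numeric(r$omissions),
                       numeric(1))
  )
  for (p in names(params$targets))
    summary_df[[paste0("rmse_", p)]] <- vapply(reports, function(r)
      r$rmse[[p]] %||% NA_real_, numeric(1))

  groups <- NULL
  classification <- NULL
  if (!is.null(labels)) {
    groups <- lapply(split(seq_len(n), labels), function(idx) {
      per_n <- lapply(params$ngram_lengths, function(g) {
        tabs <- lapply(idx, function(i)
          suppressWarnings(ngram_counts(analyses[[i]]$seq$aoi, g)))
        ok <- vapply(tabs, length, integer(1)) > 0
        res <- if (sum(ok) >= 2L) common_ngrams(tabs[ok]) else
          list(ngrams = character(0), count = 0L)
        list(n = g, common_count = res$count, common = res$ngrams,
             report = write_ngram_report(tabs))
      })
      names(per_n) <- paste0("n", params$ngram_lengths)
      list(n_recordings = length(idx), common_ngrams = per_n)
    })
    class_sizes <- table(labels)
    if (length(class_sizes) >= 2L && all(class_sizes >= params$k_folds)) {
      ft <- build_feature_table(lapply(analyses, `[[`, "tm"), labels)
      classification <- crossvalidated_knn(
        ft, k_folds = params$k_folds, neighbors = params$neighbors,
        n_components = params$n_components,
        seed = derive_seed(if (is.na(used_seed)) 0 else used_seed, 999))
    }
  }

  provenance <- list(
    package_version = as.character(utils::packageVersion("aoiscan")),
    seed = used_seed,
    config_hash = config_hash(list(params = params, config_names =
                                     sort(names(config))))
  )
  result <- structure(
    list(reports = reports, summary = summary_df, groups = groups,
         classification = classification, provenance = provenance,
         params = params),
    class = "pipeline_result"
  )
  if (!is.null(out_dir)) write_pipeline_result(result, out_dir)
  result
}

# Stable content hash without external dependencies: sum of bit-rotated
# byte values of the canonical JSON serialization.
config_hash <- function(x) {
  bytes <- as.integer(charToRaw(jsonlite::toJSON(x, auto_unbox = TRUE,
                                                 force = TRUE)))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result:", nrow(x$summary), "recordings\n")
  print(utils::head(x$summary))
  if (!is.null(x$classification)) {
    cat("\n")
    print(x$classification)
  }
  invisible(x)
}

write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (r in result$reports) {
    validate_report(r)
    jsonlite::write_json(
      r, file.path(out_dir, paste0("report_", gsub("[^A-Za-z0-9._-]", "_",
                                                   r$id), ".json")),
      auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  }
  utils::write.csv(result$summary, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  if (!is.null(result$groups)) {
    for (g in names(result$groups)) {
      counts <- vapply(result$groups[[g]]$common_ngrams, `[[`, numeric(1),
                       "common_count")
      utils::write.csv(
        data.frame(n = as.integer(sub("^n", "", names(counts))),
                   common_count = counts),
        file.path(out_dir, paste0("common_ngrams_",
                                  gsub("[^A-Za-z0-9._-]", "_", g), ".csv")),
        row.names = FALSE)
    }
  }
  if (!is.null(result$classification)) {
    cl <- result$classification
    jsonlite::write_json(
      list(fold_accuracies = cl$fold_accuracies,
           overall_accuracy = cl$overall_accuracy,
           confusion = as.data.frame(cl$confusion),
           chance_level = cl$chance_level,
           n_components = cl$n_components,
           neighbors = cl$neighbors, k_folds = cl$k_folds,
           seed = cl$seed, pca_within_fold = cl$pca_within_fold),
      file.path(out_dir, "classification.json"),
      auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(result$provenance,
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Validate a per-recording metrics report against the bundled schema
#'
#' Checks that every required field of the report schema is present;
#' metrics may be `NA` (explicitly skipped) but not absent.
#'
#' @param report A per-recording report list (see [analyze_recording()]).
#' @return `TRUE` invisibly; errors when a required field is missing.
#' @export
validate_report <- function(report) {
  schema <- jsonlite::fromJSON(system.file("extdata", "report_schema.json",
                                           package = "aoiscan",
                                           mustWork = TRUE))
  missing <- setdiff(schema$per_recording_required, names(report))
  if (length(missing))
    stop_input("report is missing required field(s): ",
               paste(missing, collapse = ", "))
  invisible(TRUE)
}
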