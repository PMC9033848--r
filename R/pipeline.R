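# Orchestration: resolved run configuration, the generate / frp / train /
# evaluate stages, and the combined evaluation report (metric suite + BHS +
# AAMI + Bland-Altman). Every run writes its resolved config next to its
# outputs and logs stage lines stamped with time, seed and config hash.

#' Resolve a run configuration
#'
#' Merges user overrides into the package defaults for every stage. The
#' defaults mirror the reference study setup: 125 Hz signals split 70/10/20
#' chronologically within each record, delay embedding (m = 3, tau = 5), fuzzy
#' c-means with c = 3 and omega = 2, an 88 x 88 fuzzy recurrence plot, and
#' training with batch 100, Adam, learning rate 0.001.
#'
#' @param ... overrides of the default fields (see the returned list), or a
#'   single list of overrides.
#' @return a `run_config` list with components `generator`, `window`, `stride`,
#'   `embed` (`m`, `tau`), `fcm` (`c`, `omega`, `alpha`, `max_iter`), `frp_side`,
#'   `model` (`type`, `fusion`, `stream_1d`, `stream_2d`), `hyper`, `fractions`,
#'   `seed`.
#' @export
run_config <- function(...) {
  defaults <- list(
    generator = list(n_records = 4L, duration = 120),
    window = 1024L,
    stride = 1024L,
    embed = list(m = 3L, tau = 5L),
    fcm = list(c = 3L, omega = 2, alpha = 1e-5, max_iter = 300L),
    frp_side = 88L,
    model = list(type = "concat", fusion = "concat",
                 stream_1d = list(), stream_2d = list()),
    hyper = list(batch = 100L, lr = 0.001, max_epochs = 300L, patience = 30L),
    fractions = c(0.7, 0.1, 0.2),
    seed = 1L
  )
  dots <- list(...)
  if (length(dots) == 1L && is.list(dots[[1]]) && is.null(names(dots))) {
    dots <- dots[[1]]
  }
  cfg <- modifyList(defaults, dots)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose top-level keys override [run_config()] defaults.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  run_config(yaml::read_yaml(path))
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".rds")
  on.exit(unlink(tmp))
  saveRDS(unclass(cfg), tmp, version = 2)
  unname(tools::md5sum(tmp))
}

log_stage <- function(stage, cfg, msg) {
  message(sprintf("[%s] %s seed=%d cfg=%s | %s",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"), stage,
                  cfg$seed, substr(config_hash(cfg), 1, 8), msg))
}

write_config <- function(cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(cfg), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Generate a set of synthetic records
#'
#' Stage 1 of the pipeline: draws `n_records` independent records (seeds
#' `seed + 1, seed + 2, ...`), optionally writing one CSV per record plus a
#' manifest.
#'
#' @param cfg a [run_config()].
#' @param out_dir output directory, or `NULL` to skip writing.
#' @return list of `signal_record`s, invisibly carrying the manifest as
#'   attribute `manifest` when written.
#' @export
cmd_generate <- function(cfg = run_config(), out_dir = NULL) {
  gen_over <- cfg$generator
  n_records <- gen_over$n_records %||% 4L
  gen_over$n_records <- NULL
  records <- lapply(seq_len(n_records), function(i) {
    gc <- do.call(generator_config, c(gen_over, list(seed = cfg$seed + i)))
    generate_record(gc)
  })
  if (!is.null(out_dir)) {
    write_config(cfg, out_dir)
    paths <- file.path(out_dir, sprintf("record_%03d.csv", seq_len(n_records)))
    for (i in seq_len(n_records)) write_signal_csv(records[[i]], paths[i])
    manifest <- data.frame(record = seq_len(n_records), path = paths,
                           samples = vapply(records, function(r) length(r$ppg), numeric(1)),
                           fs = vapply(records, function(r) r$fs, numeric(1)))
    write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
    attr(records, "manifest") <- manifest
    log_stage("generate", cfg, sprintf("%d records -> %s", n_records, out_dir))
  }
  invisible(records)
}

#' Segment records and compute their fuzzy recurrence plots
#'
#' Stage 2: windows every record, splits chronologically per record, and
#' computes the FRP tensor for each split.
#'
#' @param records list of `signal_record`s.
#' @param cfg a [run_config()].
#' @param target `"sbp"` or `"dbp"` (selects which label becomes `y`).
#' @return list with `train`, `val`, `test` datasets (each as in
#'   [build_dataset()]) and the `split` bookkeeping.
#' @export
cmd_frp <- function(records, cfg = run_config(), target = "sbp") {
  segs <- lapply(records, segment_record, window = cfg$window, stride = cfg$stride)
  split <- split_segments(segs, cfg$fractions)
  side <- if (cfg$model$type == "cnn1d") NULL else cfg$frp_side
  mk <- function(sgs) build_dataset(sgs, target = target, side = side,
                                    m = cfg$embed$m, tau = cfg$embed$tau,
                                    c = cfg$fcm$c, omega = cfg$fcm$omega,
                                    alpha = cfg$fcm$alpha,
                                    max_iter = cfg$fcm$max_iter,
                                    seed = cfg$seed)
  log_stage("frp", cfg, sprintf("%d/%d/%d train/val/test segments (side %s)",
                                length(split$train), length(split$val),
                                length(split$test),
                                if (is.null(side)) "-" else side))
  list(train = mk(split$train), val = mk(split$val), test = mk(split$test),
       split = split)
}

#' Train a model on a prepared dataset
#'
#' Stage 3: builds the model spec from the config and fits it.
#'
#' @param data output of [cmd_frp()].
#' @param cfg a [run_config()].
#' @param target `"sbp"` or `"dbp"`.
#' @param out_dir optional directory for the model artifact and history CSV.
#' @return a trained `bp_cnn_model`.
#' @export
cmd_train <- function(data, cfg = run_config(), target = "sbp", out_dir = NULL) {
  spec <- build_model_spec(cfg$model$type, list(
    window = cfg$window, side = cfg$frp_side, fusion = cfg$model$fusion,
    stream_1d = cfg$model$stream_1d, stream_2d = cfg$model$stream_2d,
    target = target))
  hyper <- modifyList(cfg$hyper, list(seed = cfg$seed))
  model <- train_model(spec, data$train, data$val, hyper)
  if (!is.null(out_dir)) {
    write_config(cfg, out_dir)
    save_model(model, file.path(out_dir, sprintf("model_%s_%s.rds",
                                                 cfg$model$type, target)))
    write.csv(model$history, file.path(out_dir, sprintf("history_%s.csv", target)),
              row.names = FALSE)
    log_stage("train", cfg, sprintf("%s/%s: %d epochs, best val loss %.4g",
                                    cfg$model$type, target, nrow(model$history),
                                    min(model$history$val_loss)))
  }
  model
}

#' Evaluate predictions against reference targets
#'
#' Composes the full evaluation report: the six-metric suite, the BHS
#' cumulative-error grade, the AAMI verdict, and Bland-Altman agreement.
#'
#' @param y reference blood pressures (mmHg).
#' @param yhat estimates (mmHg).
#' @param subjects number of subjects behind the samples (for the AAMI rule);
#'   defaults to `length(y)`.
#' @param target label carried into the report (e.g. `"sbp"`).
#' @return an `eval_report` list: `target`, `metrics`, `bhs` (`cum5`, `cum10`,
#'   `cum15`, `grade`), `aami`, `bland_altman`.
#' @export
evaluate_predictions <- function(y, yhat, subjects = length(y), target = "sbp") {
  metrics <- compute_metrics(y, yhat)
  cums <- bhs_cumulative(y - yhat)
  structure(list(
    target = target,
    metrics = metrics,
    bhs = list(cum5 = unname(cums[1]), cum10 = unname(cums[2]),
               cum15 = unname(cums[3]), grade = bhs_grade(cums)),
    aami = aami_check(metrics$me, metrics$std, subjects),
    bland_altman = bland_altman(y, yhat)
  ), class = "eval_report")
}

#' Evaluate a trained model on a test dataset
#'
#' Stage 4: predicts the held-out segments and writes the report as JSON and
#' readable text.
#'
#' @param model a trained `bp_cnn_model`.
#' @param test dataset list (`x1`, `x2`, `y`).
#' @param cfg a [run_config()] (for logging).
#' @param out_dir optional output directory.
#' @param subjects subject count for the AAMI rule (defaults to the number of
#'   test samples).
#' @return an `eval_report`.
#' @export
cmd_evaluate <- function(model, test, cfg = run_config(), out_dir = NULL,
                         subjects = length(test$y)) {
  yhat <- predict(model, test$x1, test$x2)
  report <- evaluate_predictions(test$y, yhat, subjects = subjects,
                                 target = model$spec$target)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report_to_list(report),
                         file.path(out_dir, sprintf("report_%s.json", report$target)),
                         auto_unbox = TRUE, digits = NA)
    writeLines(utils::capture.output(print(report)),
               file.path(out_dir, sprintf("report_%s.txt", report$target)))
    log_stage("evaluate", cfg, sprintf("%s: MAE %.2f mmHg, BHS %s, AAMI %s",
                                       report$target, report$metrics$mae,
                                       report$bhs$grade,
                                       if (report$aami$pass) "pass" else "fail"))
  }
  report
}

# plain-list view of a report for lossless JSON round-trips
report_to_list <- function(report) {
  m <- report$metrics
  list(
    target = report$target,
    n = m$n,
    metrics = list(mae = m$mae, mse = m$mse, me = m$me, r2 = m$r2, r = m$r,
                   std = m$std, r_defined = m$r_defined,
                   r2_defined = m$r2_defined),
    bhs = report$bhs,
    aami = list(me = report$aami$me, std = report$aami$std,
                subjects = report$aami$subjects, pass = report$aami$pass,
                reasons = as.list(report$aami$reasons)),
    bland_altman = list(bias = report$bland_altman$bias,
                        loa_low = report$bland_altman$loa_low,
                        loa_high = report$bland_altman$loa_high,
                        within_fraction = report$bland_altman$within_fraction)
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("== Evaluation report (%s, n = %d) ==\n", toupper(x$target),
              x$metrics$n))
  print(x$metrics)
  cat(sprintf("  BHS: %.2f%% / %.2f%% / %.2f%% within 5/10/15 mmHg -> grade %s\n",
              x$bhs$cum5, x$bhs$cum10, x$bhs$cum15, x$bhs$grade))
  print(x$aami)
  print(x$bland_altman)
  invisible(x)
}

#' Run the full pipeline
#'
#' generate -> segment/FRP -> train -> evaluate for one target, end to end and
#' fully seeded.
#'
#' @param cfg a [run_config()].
#' @param target `"sbp"` or `"dbp"`.
#' @param out_dir optional output directory (resolved config, model artifact,
#'   history, reports).
#' @return list with `model`, `report`, `data` (the split datasets) and `cfg`.
#' @export
run_pipeline <- function(cfg = run_config(), target = "sbp", out_dir = NULL) {
  records <- cmd_generate(cfg, out_dir = out_dir)
  data <- cmd_frp(records, cfg, target = target)
  model <- cmd_train(data, cfg, target = target, out_dir = out_dir)
  report <- cmd_evaluate(model, data$test, cfg, out_dir = out_dir)
  list(model = model, report = report, data = data, cfg = cfg)
}
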