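# YAML run configuration and the end-to-end smoke pipeline.

run_config_defaults <- function() {
  list(
    # architecture
    embed_dim = 64L, n_transformer_layers = 2L, n_heads = 4L,
    signal_encoder_dims = c(64L, 64L), gru_hidden = 64L, gru_dropout = 0.2,
    ablation = character(),
    # optimization
    epochs = 20L, batch_size = 64L, lr = 1e-3, lr_decay = 0.95,
    alpha = 0.8, margin = 2, freeze_schedule = "per_epoch",
    seed = 1L,
    # paths (optional, used by the command-line driver)
    features = NULL, validation = NULL, test = NULL, out = NULL,
    version = as.character(utils::packageVersion("nanocon"))
  )
}

#' Load and validate a YAML run configuration
#'
#' Reads a YAML file, fills defaults for absent keys and validates types
#' and ranges. Unknown keys are rejected so that typos fail loudly instead
#' of silently running with defaults. An empty (or `NULL`) file yields the
#' all-defaults configuration.
#'
#' @param path path to a YAML file, or `NULL` for defaults.
#' @return a `run_config` list; split into model and fit arguments by
#'   [as_model_config()].
#' @export
load_config <- function(path = NULL) {
  defaults <- run_config_defaults()
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
  }
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, user, keep.null = TRUE)
  for (key in c("embed_dim", "n_transformer_layers", "n_heads", "gru_hidden",
                "epochs", "batch_size", "seed"))
    if (!is.numeric(cfg[[key]]) || cfg[[key]] < 1)
      stop("config key '", key, "' must be a positive integer")
  if (!is.numeric(cfg$alpha) || cfg$alpha < 0 || cfg$alpha > 1)
    stop("config key 'alpha' must be in [0, 1]")
  if (!is.numeric(cfg$margin) || cfg$margin <= 0)
    stop("config key 'margin' must be > 0")
  if (!is.numeric(cfg$gru_dropout) || cfg$gru_dropout < 0 || cfg$gru_dropout >= 1)
    stop("config key 'gru_dropout' must be in [0, 1)")
  if (!is.numeric(cfg$lr) || cfg$lr <= 0) stop("config key 'lr' must be > 0")
  if (!cfg$freeze_schedule %in% c("per_epoch", "per_batch"))
    stop("config key 'freeze_schedule' must be per_epoch or per_batch")
  if (length(setdiff(cfg$ablation, ABLATION_FLAGS)))
    stop("config key 'ablation' contains an unknown flag")
  structure(cfg, class = "run_config")
}

#' @rdname load_config
#' @param cfg a `run_config`.
#' @export
save_config <- function(cfg, path) {
  keep <- !vapply(cfg, is.null, logical(1))
  yaml::write_yaml(unclass(cfg)[keep], path)
  invisible(path)
}

#' @rdname load_config
#' @export
as_model_config <- function(cfg) {
  nanocon_config(embed_dim = cfg$embed_dim,
                 n_transformer_layers = cfg$n_transformer_layers,
                 n_heads = cfg$n_heads,
                 signal_encoder_dims = cfg$signal_encoder_dims,
                 gru_hidden = cfg$gru_hidden,
                 gru_dropout = cfg$gru_dropout,
                 ablation = as.character(unlist(cfg$ablation)))
}

#' End-to-end smoke pipeline on simulated data
#'
#' Simulates a small separable dataset, splits it 8:1:1, trains for a few
#' epochs, predicts on the held-out test partition and writes the metric
#' suite as JSON. Exercises every stage of the pipeline in a few minutes on
#' one CPU; any stage failure propagates with the stage name.
#'
#' @param seed integer seed controlling all randomness.
#' @param out_dir directory for `metrics.json` and `manifest.json`.
#' @param n_instances,epochs pipeline size knobs.
#' @return list with `status` (0 on success), `metrics` (the
#'   `metric_report`) and `paths` of the written files.
#' @export
smoke_pipeline <- function(seed = 1L, out_dir = tempfile("smoke"),
                           n_instances = 600L, epochs = 4L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("smoke pipeline failed at stage '%s': %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  cfg <- sim_config(n_instances = n_instances, proportion = 0.25,
                    delta = 3, noise_sigma = 1, seed = seed)
  data <- stage("simulate", simulate_dataset(cfg))
  splits <- stage("split", split_dataset(data, seed = seed))
  fit <- stage("train", nanocon(splits$train, splits$validation,
                                epochs = epochs, seed = seed))
  metrics <- stage("evaluate", evaluate(fit, splits$test))
  metrics_path <- file.path(out_dir, "metrics.json")
  stage("report", write_metrics_json(metrics, metrics_path))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(list(seed = seed, n_instances = n_instances,
                            epochs = epochs,
                            sim = unclass(cfg),
                            version = as.character(utils::packageVersion("nanocon"))),
                       manifest_path, auto_unbox = TRUE, digits = NA)
  list(status = 0L, metrics = metrics,
       paths = c(metrics = metrics_path, manifest = manifest_path))
}
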