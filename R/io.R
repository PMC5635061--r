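# 32-bit FNV-1a hash of a string, hex-encoded; used to stamp artifacts with
# the configuration that produced them
config_hash <- function(config) {
  s <- paste(deparse(config[order(names(config))]), collapse = "")
  bytes <- utf8ToInt(s)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483629
  sprintf("%08x", as.integer(h))
}

#' Read a delimited feature table
#'
#' Reads a comma-separated table with a header row and a designated label
#' column, validating that every feature cell is a finite number; a
#' non-numeric or non-finite cell raises an error naming its row and column.
#' Lines starting with `#` (artifact provenance stamps) are skipped.
#'
#' @param path file path.
#' @param labels label column name (default `"class"`).
#' @return tibble with numeric feature columns and the label column.
#' @export
read_feature_table <- function(path, labels = "class") {
  df <- read.csv(path, header = TRUE, comment.char = "#",
                 colClasses = "character", check.names = FALSE)
  if (!labels %in% names(df)) {
    abort(sprintf("Label column '%s' missing from %s.", labels, path),
          class = "ckalign_validation_error")
  }
  for (col in setdiff(names(df), labels)) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(vals) | !is.finite(vals))
    if (length(bad)) {
      abort(sprintf("Non-numeric or non-finite value at row %d, column '%s'.",
                    bad[1L], col), class = "ckalign_validation_error")
    }
    df[[col]] <- vals
  }
  lab <- suppressWarnings(as.integer(df[[labels]]))
  df[[labels]] <- if (anyNA(lab)) df[[labels]] else lab
  tibble::as_tibble(df)
}

#' Write a feature table (with provenance stamp)
#'
#' @param data data frame to write.
#' @param path destination path.
#' @param stamp optional provenance line (config hash + seed) written as a
#'   leading `#` comment.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(data, path, stamp = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(stamp)) writeLines(paste0("# ", stamp), con)
  write.csv(data, con, row.names = FALSE)
  invisible(path)
}

default_pipeline_config <- function() {
  list(
    seed = 1,
    out_dir = NULL,
    simulate = list(kind = "tabular", n_samples = 200, n_features = 40,
                    n_informative = 6, n_classes = 2,
                    structure = "linear_means", class_sep = 5, noise_sd = 1),
    input = NULL,                       # feature CSV path (alternative to simulate)
    labels = "class",
    fit = list(tolerance = 1e-6, max_iterations = 300, learn_sigma = TRUE,
               step_rule = "backtracking", initial_step = 1),
    select = list(rule = "variance_explained", param = 0.95),
    embed = FALSE,
    evaluate = list(k_grid = c(1, 3, 5, 7, 9, 11), outer_folds = 10,
                    inner_folds = 10, curve = FALSE))
}

# recursive merge of user config into defaults, rejecting unknown keys
merge_config <- function(user, defaults, path = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    abort(sprintf("Unknown configuration key%s: %s.",
                  if (length(unknown) > 1) "s" else "",
                  paste0(path, unknown, collapse = ", ")),
          class = "ckalign_validation_error")
  }
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && is.list(user[[k]]) &&
                         !is.null(names(defaults[[k]]))) {
      merge_config(user[[k]], defaults[[k]], paste0(path, k, "."))
    } else {
      user[[k]]
    }
  }
  defaults
}

#' Run the full pipeline
#'
#' Executes simulate (or load) -> relevance fit + selection -> optional
#' embedding -> nested-CV evaluation of the selected features, persisting
#' every intermediate artifact when `out_dir` is set and returning a run
#' report. Reruns with the same configuration and seed reproduce the same
#' artifacts.
#'
#' @param config named list (see `default_pipeline_config` in the sources
#'   for the schema) or path to a YAML file with the same structure. Unknown
#'   keys are rejected before any computation.
#' @return list of class `run_report`: configuration echo (with hash and
#'   seed), selection summary, evaluation summary, artifact paths, and
#'   wall-clock time.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(config, default_pipeline_config())
  hash <- config_hash(cfg[setdiff(names(cfg), "out_dir")])  # path-independent
  stamp <- sprintf("ckalign config=%s seed=%d", hash, as.integer(cfg$seed))
  t0 <- Sys.time()
  artifacts <- list()

  if (!is.null(cfg$input)) {
    data <- read_feature_table(cfg$input, labels = cfg$labels)
    support <- NULL
  } else if (identical(cfg$simulate$kind, "tabular")) {
    sim <- simulate_tabular(
      n_samples = cfg$simulate$n_samples, n_features = cfg$simulate$n_features,
      n_informative = cfg$simulate$n_informative,
      n_classes = cfg$simulate$n_classes, structure = cfg$simulate$structure,
      class_sep = cfg$simulate$class_sep, noise_sd = cfg$simulate$noise_sd,
      seed = cfg$seed)
    data <- sim$data
    support <- sim$support
  } else {
    trials <- simulate_eeg(seed = cfg$seed)
    data <- eeg_feature_bank(trials)
    support <- NULL
  }

  control <- cka_control(
    tolerance = cfg$fit$tolerance, max_iterations = cfg$fit$max_iterations,
    learn_sigma = cfg$fit$learn_sigma, step_rule = cfg$fit$step_rule,
    initial_step = cfg$fit$initial_step)
  sel <- cka_select(data, labels = cfg$labels, rule = cfg$select$rule,
                    param = cfg$select$param, control = control)

  emb <- if (isTRUE(cfg$embed)) {
    cka_embed(data, labels = cfg$labels, rule = cfg$select$rule,
              param = cfg$select$param, control = control)
  } else NULL

  eval_data <- if (is.null(emb)) sel$data_selected else emb$Y
  cv <- knn_nested_cv(eval_data, labels = cfg$labels,
                      k_grid = cfg$evaluate$k_grid,
                      outer_folds = cfg$evaluate$outer_folds,
                      inner_folds = cfg$evaluate$inner_folds,
                      seed = cfg$seed)

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    p_feat <- file.path(cfg$out_dir, "features.csv")
    write_feature_table(data, p_feat, stamp)
    p_rel <- file.path(cfg$out_dir, "relevance.csv")
    write_feature_table(sel$relevance, p_rel, stamp)
    artifacts$features <- p_feat
    artifacts$relevance <- p_rel
    if (!is.null(emb)) {
      p_emb <- file.path(cfg$out_dir, "embedding.csv")
      write_feature_table(emb$Y, p_emb, stamp)
      artifacts$embedding <- p_emb
    }
  }

  report <- list(
    config = cfg, config_hash = hash, seed = cfg$seed,
    true_support = support,
    selection = as.list(glance(sel)),
    fit = as.list(glance(sel$fit)),
    embedding = if (!is.null(emb)) as.list(glance(emb)) else NULL,
    evaluation = list(accuracy_mean = cv$accuracy_mean,
                      accuracy_sd = cv$accuracy_sd,
                      chosen_k = cv$chosen_k,
                      stratified = cv$stratified, scaling = cv$scaling),
    artifacts = artifacts,
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  if (!is.null(cfg$out_dir)) {
    p_rep <- file.path(cfg$out_dir, "report.json")
    jsonlite::write_json(report, p_rep, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, null = "null")
    report$artifacts$report <- p_rep
  }
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report>  config %s, seed %d\n", x$config_hash, x$seed))
  cat(sprintf("  selected %d / %d features; accuracy %.2f%% +/- %.2f%%\n",
              x$selection$n_selected, x$selection$n_features,
              x$evaluation$accuracy_mean, x$evaluation$accuracy_sd))
  invisible(x)
}
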