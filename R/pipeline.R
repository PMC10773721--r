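# Pipeline orchestration: a structured config drives the staged workflow
# simulate -> windows -> encode -> resample -> train -> evaluate -> explain,
# each stage writing artifacts plus a JSON manifest so every run is
# reconstructible from its outputs.

pipeline_stages <- function() {
  c("simulate", "windows", "encode", "resample", "train", "evaluate", "explain")
}

#' Default pipeline configuration
#'
#' Returns the full configuration with every tunable pinned to its default:
#' cohort parameters, encoding method, resampling plan, architecture specs,
#' focal-loss parameters, split sizes, repeats and seed. Values can be
#' overridden via a YAML file ([read_run_config()]) or by supplying a
#' partial list to [pipeline_run()].
#'
#' @return A nested list of configuration sections.
#' @export
default_run_config <- function() {
  list(
    output_dir = "injurisk_run",
    seed = 1L,
    cohort = list(n_athletes = 74L, n_days = 400L, prevalence_target = 0.013,
                  risk_volume = 1.5, risk_spike = 1.0),
    split = list(n_test_athletes = 10L),
    windows = list(pad = "edge"),
    encoding = list(method = "gasf", Q = 5L, eps_fraction = 0.2),
    resampling = list(n_injured_target = 650L, ratio = 0.136, smote_k = 5L,
                      final_ratio = 1),
    autoencoder = list(latent_dim = 5L, conv_filters = c(32L, 64L),
                       dropout_rate = 0.1, epochs = 100L, batch = 512L,
                       lr = 1.0, rho = 0.95),
    classifier = list(hidden = rep(50L, 4L), dropout_rate = 0.1,
                      epochs = 100L, batch = 512L, lr = 1.0, rho = 0.95),
    focal = list(alpha = NULL, gamma = 3.5),
    evaluate = list(repeats = 5L, threshold = 0.5),
    explain = list(n_samples = 50L, n_background = 10L)
  )
}

#' Read a run configuration from YAML
#'
#' Unspecified keys fall back to [default_run_config()]; unknown keys are
#' rejected.
#'
#' @param path YAML file path.
#' @return Configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_injurisk("config file not found: %s", path)
  user <- yaml::read_yaml(path)
  merge_config(default_run_config(), user, "")
}

merge_config <- function(base, user, prefix) {
  if (is.null(user)) return(base)
  bad <- setdiff(names(user), names(base))
  if (length(bad) > 0) {
    stop_injurisk("unknown config key(s): %s",
                  paste0(prefix, bad, collapse = ", "))
  }
  for (nm in names(user)) {
    base[[nm]] <- if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      merge_config(base[[nm]], user[[nm]], paste0(prefix, nm, "."))
    } else user[[nm]]
  }
  base
}

artifact_path <- function(config, name) file.path(config$output_dir, name)

write_manifest <- function(config, stage, extra = list()) {
  hashed <- config
  hashed$output_dir <- NULL  # hash the scientific content, not the paths
  manifest <- c(list(stage = stage, config = config,
                     config_hash = config_hash(hashed),
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                     package_version = as.character(utils::packageVersion("injurisk")),
                     r_version = R.version.string),
                extra)
  jsonlite::write_json(manifest, artifact_path(config, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
}

require_stage <- function(config, stage, file) {
  p <- artifact_path(config, file)
  if (!file.exists(p)) {
    stop_injurisk("stage '%s' requires artifact '%s'; run the earlier stages first",
                  stage, file)
  }
  p
}

#' Run a pipeline stage
#'
#' Executes one stage of the workflow against the artifacts in
#' `config$output_dir` and writes its own outputs plus a JSON manifest
#' (config hash, seed, versions, per-stage counts). Stages must be run in
#' order; a missing prerequisite artifact raises an explicit error.
#'
#' @param stage One of `simulate`, `windows`, `encode`, `resample`, `train`,
#'   `evaluate`, `explain` (`evaluate` runs the repeated hold-out protocol
#'   end to end and does not require the single-shot `train` stage).
#' @param config Configuration list (partial lists are completed with
#'   defaults) or a path to a YAML config.
#' @param verbose Progress messages.
#' @return The stage's primary result, invisibly.
#' @export
pipeline_run <- function(stage, config = default_run_config(), verbose = FALSE) {
  if (!(stage %in% pipeline_stages())) {
    stop_injurisk("unknown stage '%s'; valid: %s", stage,
                  paste(pipeline_stages(), collapse = ", "))
  }
  if (is.character(config)) config <- read_run_config(config)
  config <- merge_config(default_run_config(), config, "")
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)

  result <- switch(stage,
    simulate = {
      co <- config$cohort
      rec <- generate_cohort(co$n_athletes, co$n_days, co$prevalence_target,
                             c(co$risk_volume, co$risk_spike), seed = seed)
      write_day_approach_csv(rec, artifact_path(config, "day_approach.csv"))
      saveRDS(rec, artifact_path(config, "records.rds"))
      write_manifest(config, "simulate",
                     list(n_records = nrow(rec), prevalence = mean(rec$injury)))
      rec
    },
    windows = {
      rec <- readRDS(require_stage(config, "windows", "records.rds"))
      test_ids <- utils::tail(sort(unique(rec$athlete_id)),
                              config$split$n_test_athletes)
      split_rec <- split(rec, rec$athlete_id %in% test_ids)
      sets <- lapply(list(train = split_rec$`FALSE`, test = split_rec$`TRUE`),
                     function(r) {
                       nm <- normalize_per_athlete(r)
                       ws <- build_windows(nm$records, pad = config$windows$pad,
                                           quiet = !verbose)
                       ws$normalization <- nm$state
                       ws
                     })
      saveRDS(sets, artifact_path(config, "windows.rds"))
      write_manifest(config, "windows",
                     list(train_windows = nrow(sets$train$meta),
                          test_windows = nrow(sets$test$meta),
                          test_athletes = test_ids))
      sets
    },
    encode = {
      sets <- readRDS(require_stage(config, "encode", "windows.rds"))
      enc <- lapply(sets, encode_windows, method = config$encoding$method,
                    rescale = TRUE, Q = config$encoding$Q,
                    eps_fraction = config$encoding$eps_fraction)
      saveRDS(enc, artifact_path(config, "stacks.rds"))
      write_manifest(config, "encode", list(method = config$encoding$method))
      enc
    },
    resample = {
      sets <- readRDS(require_stage(config, "resample", "windows.rds"))
      rs <- multiple_resample(flatten_windows(sets$train),
                              sets$train$meta$label, sets$train$meta$athlete_id,
                              plan = config_plan(config, seed))
      saveRDS(rs, artifact_path(config, "resampled.rds"))
      jsonlite::write_json(
        list(counts = as.data.frame(rs$provenance$counts),
             per_athlete_k = rs$provenance$per_athlete_k,
             excluded = rs$provenance$excluded_athletes,
             n_tomek_removed = length(rs$provenance$tomek_removed),
             seed = rs$provenance$seed),
        artifact_path(config, "resample_provenance.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
      write_manifest(config, "resample",
                     list(counts = as.data.frame(rs$provenance$counts)))
      rs
    },
    train = {
      sets <- readRDS(require_stage(config, "train", "windows.rds"))
      rs <- readRDS(require_stage(config, "train", "resampled.rds"))
      rs_ws <- new_window_set(unflatten_windows(clamp(rs$features, 0, 1), sets$train),
                              data.frame(athlete_id = NA, day_index = NA,
                                         label = rs$labels),
                              padded = TRUE, normalized = TRUE)
      stacks <- encode_windows(rs_ws, method = config$encoding$method,
                               rescale = TRUE, Q = config$encoding$Q,
                               eps_fraction = config$encoding$eps_fraction)
      ae <- config$autoencoder
      encoder <- dcae_fit(stacks, do.call(autoencoder_spec, ae),
                          seed = derive_seed(seed, 21), verbose = verbose)
      lat <- dcae_encode(encoder, stacks)
      focal <- config_focal(config, sets$train$meta$label)
      classifier <- dnn_fit(lat, rs$labels, do.call(classifier_spec, config$classifier),
                            focal = focal, seed = derive_seed(seed, 22))
      saveRDS(list(encoder = encoder, classifier = classifier),
              artifact_path(config, "models.rds"))
      utils::write.csv(encoder$history, artifact_path(config, "dcae_loss.csv"),
                       row.names = FALSE)
      utils::write.csv(classifier$history, artifact_path(config, "dnn_loss.csv"),
                       row.names = FALSE)
      write_manifest(config, "train",
                     list(dcae_final_loss = utils::tail(encoder$history$loss, 1),
                          dnn_final_loss = utils::tail(classifier$history$loss, 1),
                          focal = list(alpha = focal$alpha, gamma = focal$gamma)))
      list(encoder = encoder, classifier = classifier)
    },
    evaluate = {
      rec <- readRDS(require_stage(config, "evaluate", "records.rds"))
      test_ids <- utils::tail(sort(unique(rec$athlete_id)),
                              config$split$n_test_athletes)
      train_ids <- setdiff(unique(rec$athlete_id), test_ids)
      report <- holdout_protocol(
        rec, train_ids, test_ids, method = config$encoding$method,
        plan = config_plan(config, seed),
        ae_spec = do.call(autoencoder_spec, config$autoencoder),
        clf_spec = do.call(classifier_spec, config$classifier),
        focal = if (!is.null(config$focal$alpha))
          focal_loss_params(config$focal$alpha, config$focal$gamma),
        repeats = config$evaluate$repeats,
        threshold = config$evaluate$threshold, seed = seed, verbose = verbose)
      saveRDS(report, artifact_path(config, "run_report.rds"))
      tabs <- run_report_tables(report)
      utils::write.csv(tabs$per_repeat, artifact_path(config, "metrics_per_repeat.csv"),
                       row.names = FALSE)
      utils::write.csv(tabs$summary, artifact_path(config, "metrics_summary.csv"),
                       row.names = FALSE)
      jsonlite::write_json(tabs$summary, artifact_path(config, "metrics_summary.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      write_manifest(config, "evaluate",
                     list(test_mean = as.list(report$test$mean),
                          validation_mean = as.list(report$validation$mean)))
      report
    },
    explain = {
      report <- readRDS(require_stage(config, "explain", "run_report.rds"))
      stacks <- encode_windows(report$windows$train, method = config$encoding$method,
                               rescale = TRUE, Q = config$encoding$Q,
                               eps_fraction = config$encoding$eps_fraction)
      att <- latent_variable_importance(
        report$encoder, report$classifier, stacks, stacks,
        n_samples = config$explain$n_samples,
        n_background = config$explain$n_background,
        seed = derive_seed(seed, 31))
      utils::write.csv(as.data.frame(att$variable_importance),
                       artifact_path(config, "variable_importance.csv"))
      jsonlite::write_json(as.list(att$latent_relative_importance),
                           artifact_path(config, "latent_relative_importance.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      saveRDS(att, artifact_path(config, "attribution.rds"))
      write_manifest(config, "explain",
                     list(latent_relative_importance =
                            as.list(att$latent_relative_importance)))
      att
    })
  invisible(result)
}

config_plan <- function(config, seed) {
  rs <- config$resampling
  resampling_plan(n_injured_target = rs$n_injured_target, ratio = rs$ratio,
                  smote_k = rs$smote_k, final_ratio = rs$final_ratio,
                  seed = derive_seed(seed, 7))
}

config_focal <- function(config, labels) {
  alpha <- config$focal$alpha %||%
    compute_alpha(max(sum(labels == 1), 1), length(labels))
  focal_loss_params(alpha, config$focal$gamma)
}
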