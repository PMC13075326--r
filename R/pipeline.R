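# End-to-end pipeline driver: simulate -> folds -> pretrain/train ->
# external predictions -> ensemble/triage -> bootstrap -> saliency.
# Every stage is idempotent: finished outputs in the run directory are
# reused on rerun, so deleting a later stage's outputs reconstructs them
# from the cached earlier stages.

#' Assemble a run configuration
#'
#' Bundles every knob of the pipeline with its default: the simulation
#' config, architecture and training hyperparameters, augmentation
#' policy, triage thresholds (0.90, 0.95), bootstrap iterations (1000),
#' and the center held out for external testing. One root seed fans out
#' into named substreams per stage. The resolved configuration is
#' persisted verbatim into the run directory.
#'
#' @param seed root seed.
#' @param simulation a [simulation_config()].
#' @param model a [model_spec()].
#' @param train,pretrain [train_config()]s for the two phases.
#' @param augmentation an [augmentation_policy()].
#' @param thresholds triage probability thresholds.
#' @param bootstrap_B bootstrap iterations.
#' @param external_center center id held out as the external test set.
#' @param saliency_n number of external episodes rendered with saliency.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L,
                       simulation = simulation_config(seed =
                         derive_seed(seed, "simulate")),
                       model = model_spec(),
                       train = train_config(seed =
                         derive_seed(seed, "train")),
                       pretrain = train_config(seed =
                         derive_seed(seed, "pretrain")),
                       augmentation = augmentation_policy(),
                       thresholds = c(0.90, 0.95),
                       bootstrap_B = 1000L,
                       external_center = "center_E",
                       saliency_n = 3L) {
  structure(list(seed = as.integer(seed), simulation = simulation,
                 model = model, train = train, pretrain = pretrain,
                 augmentation = augmentation, thresholds = thresholds,
                 bootstrap_B = as.integer(bootstrap_B),
                 external_center = external_center,
                 saliency_n = as.integer(saliency_n)),
            class = "run_config")
}

#' Save / load a run configuration as YAML
#'
#' @param config a [run_config()].
#' @param path YAML file path.
#' @return `load_run_config` returns a `run_config`.
#' @export
save_run_config <- function(config, path) {
  # named atomic vectors must become YAML maps or their names are lost
  demote <- function(x) {
    if (is.list(x)) lapply(unclass(x), demote)
    else if (is.atomic(x) && !is.null(names(x))) as.list(x)
    else x
  }
  yaml::write_yaml(demote(unclass(config)), path)
  invisible(path)
}

#' @rdname save_run_config
#' @export
load_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- run_config(seed = raw$seed)
  rebuild <- function(proto, vals) {
    for (nm in names(vals)) proto[[nm]] <- if (is.list(proto[[nm]]) &&
      !is.list(vals[[nm]])) proto[[nm]] else vals[[nm]]
    proto
  }
  cfg$simulation <- structure(rebuild(unclass(simulation_config()),
                                      raw$simulation), class = "sim_config")
  cfg$simulation$centers <- unlist(raw$simulation$centers)
  cfg$simulation$class_mixture <- unlist(raw$simulation$class_mixture)
  cfg$model <- do.call(model_spec, raw$model)
  cfg$train <- do.call(train_config, raw$train)
  cfg$pretrain <- do.call(train_config, raw$pretrain)
  cfg$augmentation <- do.call(augmentation_policy, raw$augmentation)
  cfg$thresholds <- raw$thresholds
  cfg$bootstrap_B <- raw$bootstrap_B
  cfg$external_center <- raw$external_center
  cfg$saliency_n <- raw$saliency_n
  cfg
}

pipeline_log <- function(out_dir, stage, msg, t0 = NULL) {
  wall <- if (is.null(t0)) "" else
    sprintf(" [%.1f s]", as.numeric(Sys.time()) - t0)
  line <- sprintf("%s  stage=%-10s %s%s",
                  format(Sys.time(), "%H:%M:%S"), stage, msg, wall)
  message(line)
  cat(line, "\n", file = file.path(out_dir, "log.txt"), append = TRUE)
}

#' Run the full pipeline
#'
#' Executes simulate, cross-validation (pretrain + transfer + train per
#' fold), external prediction, soft-voting ensemble with threshold
#' triage, patient-level bootstrap, and saliency rendering, persisting
#' every stage under `out_dir`. Stages whose outputs already exist are
#' reused, so reruns are incremental and a deleted report directory is
#' reconstructed identically from the cached predictions.
#'
#' @param config a [run_config()].
#' @param out_dir run directory (created if needed).
#' @param verbose print stage progress.
#' @return list: `cohort`, `crossval`, `external` (prediction sets),
#'   `ensemble` (prediction set), `report` (workload table), `bootstrap`,
#'   invisibly.
#' @export
run_all <- function(config = run_config(), out_dir, verbose = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  save_run_config(config, file.path(out_dir, "config.yaml"))
  lg <- function(stage, msg, t0 = NULL)
    if (verbose) pipeline_log(out_dir, stage, msg, t0)

  # -- simulate -------------------------------------------------------
  cohort_dir <- file.path(out_dir, "cohort")
  t0 <- as.numeric(Sys.time())
  if (file.exists(file.path(cohort_dir, "manifest.csv"))) {
    cohort <- load_cohort(cohort_dir)
    lg("simulate", "reusing cached cohort", t0)
  } else {
    cohort <- simulate_cohort(config$simulation)
    save_cohort(cohort, cohort_dir)
    lg("simulate", sprintf("seed=%d: %d episodes, %d patients",
                           config$simulation$seed, length(cohort$episodes),
                           length(cohort$patient_to_center)), t0)
  }

  # -- cross-validation ----------------------------------------------
  plan <- make_fold_plan(cohort, external_center = config$external_center,
                         seed = derive_seed(config$seed, "plan"))
  n_folds <- length(plan$folds)
  fold_dirs <- file.path(out_dir, paste0("fold_", seq_len(n_folds)))
  t0 <- as.numeric(Sys.time())
  if (all(file.exists(file.path(fold_dirs, "checkpoint.rds")))) {
    cv <- list(models = lapply(file.path(fold_dirs, "checkpoint.rds"),
                               readRDS),
               predictions = lapply(file.path(fold_dirs, "predictions.csv"),
                                    utils::read.csv,
                                    stringsAsFactors = FALSE),
               plan = plan)
    lg("crossval", "reusing cached fold checkpoints", t0)
  } else {
    cv <- run_crossval(cohort, plan, config$model, config$train,
                       config$pretrain, config$augmentation,
                       seed = derive_seed(config$seed, "crossval"),
                       out_dir = out_dir, verbose = verbose)
    for (f in seq_len(n_folds))
      saveRDS(cv$models[[f]], file.path(fold_dirs[f], "checkpoint.rds"))
    lg("crossval", sprintf("%d folds trained", n_folds), t0)
  }

  # -- external predictions ------------------------------------------
  man <- manifest_table(cohort)
  ext_eps <- cohort$episodes[man$center_id == config$external_center &
                               man$label != "SINUS"]
  ext_files <- file.path(out_dir,
                         sprintf("external_fold_%d.csv", seq_len(n_folds)))
  t0 <- as.numeric(Sys.time())
  if (all(file.exists(ext_files))) {
    ext <- lapply(ext_files, utils::read.csv, stringsAsFactors = FALSE)
    lg("external", "reusing cached external predictions", t0)
  } else {
    ext <- predict_external(cv$models, ext_eps)
    for (f in seq_len(n_folds))
      utils::write.csv(ext[[f]], ext_files[f], row.names = FALSE)
    lg("external", sprintf("%d episodes x %d models",
                           length(ext_eps), n_folds), t0)
  }

  # -- ensemble, triage, bootstrap -----------------------------------
  report_dir <- file.path(out_dir, "report")
  dir.create(report_dir, showWarnings = FALSE)
  t0 <- as.numeric(Sys.time())
  ens <- soft_vote(ext)
  utils::write.csv(ens, file.path(report_dir, "ensemble_predictions.csv"),
                   row.names = FALSE)
  report <- workload_report(ens, config$thresholds,
                            out_csv = file.path(report_dir, "workload.csv"))
  pid_map <- stats::setNames(man$patient_id, man$episode_id)
  boot <- patient_bootstrap(ens, unname(pid_map[ens$episode_id]),
                            B = config$bootstrap_B,
                            seed = derive_seed(config$seed, "bootstrap"))
  boot_out <- list(B = boot$B, recall = boot$recall,
                   specificity = boot$specificity)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(boot_out, file.path(report_dir, "bootstrap.json"),
                         dataframe = "rows", digits = NA)
  } else {
    yaml::write_yaml(boot_out, file.path(report_dir, "bootstrap.yaml"))
  }
  lg("ensemble", sprintf("coverage at %.2f: %.1f%%, %d incorrect",
                         max(config$thresholds),
                         report$coverage[nrow(report)],
                         report$incorrect[nrow(report)]), t0)

  # -- saliency samples ----------------------------------------------
  t0 <- as.numeric(Sys.time())
  maps_dir <- file.path(out_dir, "maps")
  dir.create(maps_dir, showWarnings = FALSE)
  n_sal <- min(config$saliency_n, length(ext_eps))
  sal_idx <- with_seed(derive_seed(config$seed, "saliency"),
                       sample(length(ext_eps), n_sal))
  for (i in sal_idx) {
    ep <- ext_eps[[i]]
    maps <- lapply(cv$models, grad_cam_pp, episode = ep)
    em <- ensemble_map(maps)
    render_saliency(ep, em, file.path(maps_dir,
                                      paste0(ep$episode_id, ".png")))
    utils::write.csv(saliency_table(em),
                     file.path(maps_dir, paste0(ep$episode_id, ".csv")),
                     row.names = FALSE)
  }
  lg("saliency", sprintf("%d episodes rendered", n_sal), t0)

  invisible(list(cohort = cohort, crossval = cv, external = ext,
                 ensemble = ens, report = report, bootstrap = boot))
}
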