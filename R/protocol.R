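# Center-level fold construction, patient-level splitting, and
# cross-validation orchestration. Patients are atomic everywhere: no
# patient ever contributes episodes to both a training pool (including
# pretraining and augmentation sources) and the validation or test set of
# the same fold.

# per-patient class-count table for a set of episodes
patient_class_counts <- function(episodes) {
  pid <- vapply(episodes, `[[`, "", "patient_id")
  lab <- vapply(episodes, `[[`, "", "label")
  tab <- table(pid, factor(lab, levels = egm_labels()))
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab),
              dimnames = dimnames(tab))
  m
}

# greedy stratified bipartition of patients targeting per-class episode
# fractions; returns logical vector (TRUE -> side A) over rownames(counts)
greedy_bipartition <- function(counts, frac_a = 0.5, seed = 1L) {
  target <- colSums(counts) * frac_a
  ord <- with_seed(seed, {
    noise <- stats::runif(nrow(counts))      # random tie-break
    order(-rowSums(counts), noise)
  })
  got_a <- numeric(ncol(counts))
  tot_a <- 0; tot <- sum(counts); side <- logical(nrow(counts))
  for (i in ord) {
    ca <- sum(abs(got_a + counts[i, ] - target)) +
      abs((tot_a + sum(counts[i, ])) - frac_a * tot)
    cb <- sum(abs(got_a - target)) + abs(tot_a - frac_a * tot)
    if (ca <= cb) {
      side[i] <- TRUE
      got_a <- got_a + counts[i, ]
      tot_a <- tot_a + sum(counts[i, ])
    }
  }
  stats::setNames(side, rownames(counts))
}

#' Split one center's patients into two class-stratified halves
#'
#' Patients of the given center are partitioned into two patient-disjoint
#' halves whose per-class episode proportions are balanced by a greedy
#' assignment (patients are atomic, so balance is best-effort).
#'
#' @param cohort an `egm_cohort`.
#' @param center_id center to split.
#' @param seed tie-break seed.
#' @return list of two character vectors of patient ids (`half1`,
#'   `half2`).
#' @export
split_center <- function(cohort, center_id, seed = 1L) {
  man <- manifest_table(cohort)
  if (!center_id %in% man$center_id) stop("unknown center: ", center_id)
  eps <- cohort$episodes[man$center_id == center_id &
                           man$label != "SINUS"]
  counts <- patient_class_counts(eps)
  if (nrow(counts) < 2) stop("center ", center_id, " has < 2 patients")
  side <- greedy_bipartition(counts, 0.5, seed)
  list(half1 = names(side)[side], half2 = names(side)[!side])
}

#' Build the center-level fold plan
#'
#' Mirrors the multi-center design: among the cross-validation centers the
#' largest (by AHRE episode count) is split into two patient-stratified
#' halves and the two smallest are merged, yielding one center group per
#' fold; each group serves as the held-out test set exactly once. With
#' four cross-validation centers this produces the canonical fourfold
#' plan. Sinus-only patients belong to no group; they are used for
#' pretraining subject to the overlap guards.
#'
#' @param cohort an `egm_cohort`.
#' @param external_center optional center id excluded from the plan and
#'   reserved for external testing.
#' @param seed tie-break seed for the stratified split.
#' @return A `fold_plan`: list with `groups` (named list of patient-id
#'   vectors) and `folds` (list of `(test_group, trainval_groups)`).
#' @export
make_fold_plan <- function(cohort, external_center = NULL, seed = 1L) {
  man <- manifest_table(cohort)
  ahre <- man[man$label != "SINUS", ]
  centers <- sort(table(ahre$center_id), decreasing = TRUE)
  if (!is.null(external_center))
    centers <- centers[setdiff(names(centers), external_center)]
  if (length(centers) < 4)
    stop("need at least 4 cross-validation centers")
  cn <- names(centers)
  largest <- cn[1]
  smallest2 <- rev(cn)[1:2]
  middles <- setdiff(cn, c(largest, smallest2))
  halves <- split_center(cohort, largest, seed = seed)
  groups <- list()
  groups[[paste0(largest, "_1")]] <- halves$half1
  groups[[paste0(largest, "_2")]] <- halves$half2
  for (cc in middles)
    groups[[cc]] <- unique(ahre$patient_id[ahre$center_id == cc])
  groups[[paste(sort(smallest2), collapse = "+")]] <-
    unique(ahre$patient_id[ahre$center_id %in% smallest2])
  if (anyDuplicated(unlist(groups)))
    stop("patient assigned to more than one center group")
  folds <- lapply(names(groups), function(g)
    list(test_group = g, trainval_groups = setdiff(names(groups), g)))
  structure(list(groups = groups, folds = folds,
                 external_center = external_center),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat("<fold_plan> ", length(x$folds), " folds over groups: ",
      paste(names(x$groups), collapse = ", "), "\n", sep = "")
  if (!is.null(x$external_center))
    cat("  external test center:", x$external_center, "\n")
  invisible(x)
}

#' Patient-level train/validation split with class stratification
#'
#' Partitions episodes into a training (default 80%) and validation (20%)
#' set at the patient level: a patient's episodes all land on one side.
#' Greedy assignment balances per-class episode counts against the target
#' fractions; since patients carry unequal episode counts the split is
#' best-effort. A class carried by a single patient goes to the training
#' side with a warning.
#'
#' @param episodes list of `egm_episode`.
#' @param train_frac target training fraction by episode count.
#' @param seed tie-break seed.
#' @return list: `train_episodes`, `val_episodes`, `train_patients`,
#'   `val_patients`.
#' @export
trainval_split <- function(episodes, train_frac = 0.8, seed = 1L) {
  if (!length(episodes)) stop("no episodes to split")
  counts <- patient_class_counts(episodes)
  single <- colnames(counts)[colSums(counts > 0) == 1 & colSums(counts) > 0]
  if (length(single))
    warning("class(es) ", paste(single, collapse = ", "),
            " carried by a single patient; forced into the training set")
  side_train <- greedy_bipartition(counts, train_frac, seed)
  for (cl in single) {
    p <- rownames(counts)[counts[, cl] > 0]
    side_train[p] <- TRUE
  }
  pid <- vapply(episodes, `[[`, "", "patient_id")
  train_p <- names(side_train)[side_train]
  val_p <- names(side_train)[!side_train]
  list(train_episodes = episodes[pid %in% train_p],
       val_episodes = episodes[pid %in% val_p],
       train_patients = train_p, val_patients = val_p)
}

# hard guard: error if any patient appears on both sides
assert_patient_disjoint <- function(train_patients, heldout_patients,
                                    what = "test") {
  leak <- intersect(train_patients, heldout_patients)
  if (length(leak))
    stop("patient leakage between training pool and ", what, " set: ",
         paste(utils::head(leak, 5), collapse = ", "))
  invisible(TRUE)
}

#' Run the center-level cross-validation
#'
#' For every fold: pools the trainval groups' AHRE episodes, splits them
#' 80/20 at the patient level, pretrains a 2-class model on sinus + the
#' training split's AT/AF episodes (sinus episodes of validation/test
#' patients excluded), transfers the weights, augments the training split
#' per the policy, trains the 3-class model, and predicts the fold's
#' held-out center group. Patient leakage between a fold's training pool
#' and its validation/test sets is a hard error checked before any
#' training starts.
#'
#' @param cohort an `egm_cohort`.
#' @param plan a [make_fold_plan()] result.
#' @param spec a [model_spec()].
#' @param config a [train_config()] for 3-class training.
#' @param pretrain_config a [train_config()] for pretraining.
#' @param policy an [augmentation_policy()]; `NULL` disables augmentation.
#' @param seed root seed; folds derive substreams.
#' @param out_dir optional directory to persist per-fold predictions and
#'   training logs.
#' @param verbose print fold progress.
#' @return list: `models`, `predictions` (list of prediction sets),
#'   `histories`, `plan`.
#' @export
run_crossval <- function(cohort, plan, spec = model_spec(),
                         config = train_config(),
                         pretrain_config = config,
                         policy = augmentation_policy(),
                         seed = 1L, out_dir = NULL, verbose = FALSE) {
  man <- manifest_table(cohort)
  pid <- man$patient_id
  is_sinus <- man$label == "SINUS"
  is_ataf <- man$label == "ATAF"
  models <- list(); preds <- list(); hists <- list()
  for (f in seq_along(plan$folds)) {
    fold <- plan$folds[[f]]
    fseed <- derive_seed(seed, "fold", f)
    test_p <- plan$groups[[fold$test_group]]
    trainval_p <- unlist(plan$groups[fold$trainval_groups],
                         use.names = FALSE)
    assert_patient_disjoint(trainval_p, test_p)
    trainval <- cohort$episodes[pid %in% trainval_p & !is_sinus]
    sp <- trainval_split(trainval, 0.8, seed = derive_seed(fseed, "split"))
    assert_patient_disjoint(sp$train_patients, test_p)
    assert_patient_disjoint(sp$train_patients, sp$val_patients, "validation")
    # pretraining pool: sinus episodes of patients outside val/test, plus
    # the training split's AT/AF episodes (never augmented)
    excluded <- c(sp$val_patients, test_p)
    sinus_pool <- cohort$episodes[is_sinus & !(pid %in% excluded)]
    ataf_pool <- sp$train_episodes[
      vapply(sp$train_episodes, `[[`, "", "label") == "ATAF"]
    if (verbose)
      message("fold ", f, ": pretraining on ", length(sinus_pool),
              " sinus + ", length(ataf_pool), " AT/AF episodes")
    pre <- pretrain_then_transfer(c(sinus_pool, ataf_pool), spec,
                                  pretrain_config,
                                  seed = derive_seed(fseed, "pretrain"))
    train_aug <- if (is.null(policy)) sp$train_episodes else
      apply_augmentation(sp$train_episodes, policy,
                         seed = derive_seed(fseed, "augment"))
    if (verbose)
      message("fold ", f, ": training on ", length(train_aug),
              " episodes (incl. augmented), validating on ",
              length(sp$val_episodes))
    fit <- train_model(pre$model, train_aug, sp$val_episodes, config)
    fit$model$meta$train_patients <-
      union(sp$train_patients,
            unique(vapply(sinus_pool, `[[`, "", "patient_id")))
    fit$model$meta$fold <- f
    test_eps <- cohort$episodes[pid %in% test_p & !is_sinus]
    ps <- prediction_set(fit$model, test_eps,
                         provenance = paste0("fold", f))
    models[[f]] <- fit$model
    preds[[f]] <- ps
    hists[[f]] <- fit$history
    if (!is.null(out_dir)) {
      fd <- file.path(out_dir, paste0("fold_", f))
      dir.create(fd, recursive = TRUE, showWarnings = FALSE)
      utils::write.csv(ps, file.path(fd, "predictions.csv"),
                       row.names = FALSE)
      utils::write.csv(fit$history, file.path(fd, "log.csv"),
                       row.names = FALSE)
    }
  }
  list(models = models, predictions = preds, histories = hists,
       plan = plan)
}

#' Predict an external cohort with each cross-validation model
#'
#' Verifies that the external patients are disjoint from every model's
#' training patients, then produces one aligned prediction set per model
#' (identical episode ordering).
#'
#' @param models list of trained `resnet1d` models.
#' @param episodes external AHRE episodes (list of `egm_episode`).
#' @return list of prediction sets, one per model.
#' @export
predict_external <- function(models, episodes) {
  ext_p <- unique(vapply(episodes, `[[`, "", "patient_id"))
  for (m in models)
    if (!is.null(m$meta$train_patients))
      assert_patient_disjoint(m$meta$train_patients, ext_p, "external")
  sets <- lapply(seq_along(models), function(i)
    prediction_set(models[[i]], episodes, provenance = paste0("fold", i)))
  ids <- lapply(sets, `[[`, "episode_id")
  if (!all(vapply(ids, identical, NA, ids[[1]])))
    stop("episode-id mismatch across prediction sets")
  sets
}
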