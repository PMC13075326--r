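# cohort with realistic identity structure but trivial signals: built
# from the simulator's counts-only plan for speed
plan_cohort <- function(seed = 1, centers = c(cA = 14, cB = 8, cC = 8,
                                              cD = 6, cE = 5)) {
  plan <- simulate_patient_plan(simulation_config(seed = seed,
                                                  centers = centers))
  eps <- lapply(seq_len(nrow(plan)), function(i)
    flat_episode(id = plan$episode_id[i], patient = plan$patient_id[i],
                 center = plan$center_id[i], label = plan$label[i],
                 atrial = sin(seq_len(1280) / 15) * 0.7))
  cohort_manifest(eps)
}

test_that("center splitting partitions patients and balances classes", {
  co <- plan_cohort()
  sp <- split_center(co, "cA", seed = 2)
  expect_length(intersect(sp$half1, sp$half2), 0)
  man <- ahretriage:::manifest_table(co)
  cA_pat <- unique(man$patient_id[man$center_id == "cA" &
                                    man$label != "SINUS"])
  expect_setequal(c(sp$half1, sp$half2), cA_pat)
  # class proportions of the halves within 10 percentage points
  ahre <- man[man$center_id == "cA" & man$label != "SINUS", ]
  prop <- function(p) {
    tab <- table(factor(ahre$label[ahre$patient_id %in% p],
                        levels = ahre_classes()))
    as.numeric(tab) / sum(tab)
  }
  expect_true(all(abs(prop(sp$half1) - prop(sp$half2)) <= 0.10))
  expect_error(split_center(co, "nope"), "unknown center")
})

test_that("the fold plan covers every center group as test exactly once", {
  co <- plan_cohort()
  plan <- make_fold_plan(co, external_center = "cE", seed = 3)
  expect_length(plan$folds, 4)
  test_groups <- vapply(plan$folds, `[[`, "", "test_group")
  expect_setequal(test_groups, names(plan$groups))
  for (f in plan$folds) {
    expect_setequal(c(f$test_group, f$trainval_groups), names(plan$groups))
    expect_length(intersect(f$test_group, f$trainval_groups), 0)
  }
  # largest center split in two, two smallest (by episode count) merged
  expect_true(all(c("cA_1", "cA_2") %in% names(plan$groups)))
  merged <- grep("\\+", names(plan$groups), value = TRUE)
  expect_length(merged, 1)
  man <- ahretriage:::manifest_table(co)
  sizes <- sort(table(man$center_id[man$label != "SINUS"]))
  sizes <- sizes[names(sizes) != "cE"]
  expect_setequal(strsplit(merged, "\\+")[[1]], names(sizes)[1:2])
  # no patient in two groups; deterministic under the seed
  expect_equal(anyDuplicated(unlist(plan$groups)), 0)
  expect_identical(plan, make_fold_plan(co, external_center = "cE",
                                        seed = 3))
  expect_error(make_fold_plan(co, external_center = c("cC", "cD", "cE")),
               "at least 4")
})

test_that("train/validation split is patient-disjoint, near 80/20, and
           stratified", {
  co <- plan_cohort(seed = 4)
  man <- ahretriage:::manifest_table(co)
  ahre <- co$episodes[man$label != "SINUS"]
  sp <- trainval_split(ahre, seed = 5)
  expect_length(intersect(sp$train_patients, sp$val_patients), 0)
  frac <- length(sp$train_episodes) /
    (length(sp$train_episodes) + length(sp$val_episodes))
  expect_gte(frac, 0.75); expect_lte(frac, 0.85)
  for (cl in ahre_classes()) {
    carriers <- length(unique(vapply(ahre, `[[`, "", "patient_id")[
      vapply(ahre, `[[`, "", "label") == cl]))
    if (carriers >= 2) {
      expect_true(cl %in% vapply(sp$train_episodes, `[[`, "", "label"))
      expect_true(cl %in% vapply(sp$val_episodes, `[[`, "", "label"))
    }
  }
})

test_that("a class carried by one patient is forced into training with a
           warning", {
  eps <- c(
    lapply(1:6, function(i) flat_episode(id = paste0("a", i),
      patient = paste0("p", i), label = "ATAF")),
    lapply(1:3, function(i) flat_episode(id = paste0("f", i),
      patient = "pF", label = "FFO"))
  )
  expect_warning(sp <- trainval_split(eps, seed = 1), "FFO")
  expect_true("pF" %in% sp$train_patients)
})

test_that("cross-validation refuses to start on patient leakage", {
  co <- plan_cohort(seed = 6)
  plan <- make_fold_plan(co, external_center = "cE", seed = 1)
  # inject deliberate leakage: copy a test patient into a trainval group
  bad <- plan
  leak_pat <- bad$groups[[bad$folds[[1]]$test_group]][1]
  g2 <- bad$folds[[1]]$trainval_groups[1]
  bad$groups[[g2]] <- c(bad$groups[[g2]], leak_pat)
  expect_error(
    run_crossval(co, bad, tiny_spec(), train_config(max_epochs = 1)),
    "leakage")
})

test_that("external prediction enforces patient disjointness and aligned
           episode keys", {
  m <- build_resnet1d(tiny_spec(1280L), seed = 1)
  m$meta$train_patients <- c("p1", "p2")
  eps <- lapply(1:3, function(i) flat_episode(id = paste0("x", i),
    patient = paste0("q", i), label = "ATAF", seed = i))
  sets <- predict_external(list(m, m), eps)
  expect_identical(sets[[1]]$episode_id, sets[[2]]$episode_id)
  expect_equal(rowSums(as.matrix(sets[[1]][, c("p_ataf", "p_noise",
                                               "p_ffo")])),
               rep(1, 3), tolerance = 1e-6)
  leaky <- lapply(1:2, function(i) flat_episode(id = paste0("y", i),
    patient = "p1", label = "ATAF", seed = i))
  expect_error(predict_external(list(m), leaky), "leakage")
})
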