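nowhere_zero <- function(seed = 3) {
  set.seed(seed)
  x <- runif(1280, 0.1, 1) * sample(c(-1, 1), 1280, TRUE)
  flat_episode(atrial = x, vent = runif(1280, 0.1, 1))
}

test_that("blanking zeroes one shared 2 s window and nothing else", {
  e <- nowhere_zero()
  set.seed(9)
  for (i in 1:10) {
    b <- aug_blank(e)
    runs <- rle(b$atrial == 0)
    zero_runs <- runs$lengths[runs$values]
    expect_equal(zero_runs, 256)               # exactly one 2 s zero-run
    s <- b$blank_start + 1L
    expect_true(s >= 1 && s <= 1025)
    idx <- s:(s + 255L)
    expect_equal(b$atrial[-idx], e$atrial[-idx])   # locality
    expect_equal(b$ventricular[idx], rep(0, 256))  # same window, both ch.
    expect_equal(b$ventricular[-idx], e$ventricular[-idx])
  }
})

test_that("scaling draws per-channel factors in [0.4, 1.2] and preserves
           zero crossings", {
  e <- nowhere_zero()
  set.seed(4)
  fa <- numeric(0); fv <- numeric(0)
  for (i in 1:2000) {
    s <- aug_scale(e)
    fa <- c(fa, s$factor_atrial); fv <- c(fv, s$factor_ventricular)
  }
  expect_true(all(fa >= 0.4 & fa <= 1.2))
  expect_true(all(fv >= 0.4 & fv <= 1.2))
  expect_gt(stats::sd(fa - fv), 0)             # independent per channel
  s <- aug_scale(e)
  expect_equal(sign(s$atrial), sign(e$atrial))
  expect_equal(s$atrial, e$atrial * s$factor_atrial)
})

test_that("inversion is an involution that leaves markers and amplitude
           envelope unchanged", {
  e <- nowhere_zero()
  iv <- aug_invert(e)
  expect_equal(iv$atrial, -e$atrial)
  expect_identical(iv$markers, e$markers)
  expect_equal(max(abs(iv$atrial)), max(abs(e$atrial)))
  iv2 <- aug_invert(iv)
  expect_equal(iv2$atrial, e$atrial)
  expect_equal(iv2$ventricular, e$ventricular)
})

test_that("shifting moves both channels by 0.4-1.5 s and zero-fills", {
  e <- nowhere_zero()
  set.seed(5)
  for (i in 1:200) {
    s <- aug_shift(e)
    expect_true(abs(s$shift_samples) >= 51 && abs(s$shift_samples) <= 192)
    d <- s$shift_samples
    if (d > 0) {
      expect_equal(s$atrial[1:d], rep(0, d))
      expect_equal(s$atrial[(d + 1):1280], e$atrial[1:(1280 - d)])
    } else {
      expect_equal(s$atrial[(1280 + d + 1):1280], rep(0, -d))
      expect_equal(s$atrial[1:(1280 + d)], e$atrial[(1 - d):1280])
    }
    expect_lte(sum(s$atrial^2), sum(e$atrial^2))   # energy never grows
  }
  # direct index check at a positive half-second shift
  set.seed(123)
  repeat { s <- aug_shift(e); if (s$shift_samples == 64) break }
  expect_equal(s$atrial[65:1280], e$atrial[1:1216])
  expect_equal(s$atrial[1:64], rep(0, 64))
})

test_that("half swapping exchanges the 5 s halves and is an involution", {
  e <- nowhere_zero()
  sw <- aug_swap_halves(e)
  expect_equal(sw$atrial[1], e$atrial[641])
  expect_equal(sw$atrial[641:1280], e$atrial[1:640])
  expect_equal(sort(sw$atrial), sort(e$atrial))   # permutation
  sw2 <- aug_swap_halves(sw)
  expect_equal(sw2$atrial, e$atrial)
})

test_that("the policy augments all minority episodes five-fold and a
           disjoint 20% of AT/AF episodes", {
  eps <- c(
    lapply(1:100, function(i) flat_episode(id = paste0("a", i),
                                           label = "ATAF", seed = i)),
    lapply(1:10, function(i) flat_episode(id = paste0("n", i),
                                          label = "NOISE", seed = 100 + i)),
    lapply(1:4, function(i) flat_episode(id = paste0("f", i),
                                         label = "FFO", seed = 200 + i))
  )
  out <- apply_augmentation(eps, augmentation_policy(), seed = 7)
  labs <- vapply(out, function(e) e$label, "")
  # count bookkeeping oracle: 100+20 ATAF, 10+50 NOISE, 4+20 FFO
  expect_equal(sum(labs == "ATAF"), 120)
  expect_equal(sum(labs == "NOISE"), 60)
  expect_equal(sum(labs == "FFO"), 24)
  copies <- out[vapply(out, function(e) !is.null(e$technique), NA)]
  expect_equal(length(copies), 90)
  # ATAF sources are disjoint across techniques (4% each, 20% total)
  ataf_copies <- copies[vapply(copies, function(e) e$label == "ATAF", NA)]
  src <- vapply(ataf_copies, function(e) e$source_episode_id, "")
  expect_equal(length(unique(src)), 20)
  tech <- vapply(ataf_copies, function(e) e$technique, "")
  all_tech <- c("BLANK", "SCALE", "INVERT", "SHIFT", "SWAP_HALVES")
  expect_equal(unname(as.integer(table(tech)[all_tech])), rep(4L, 5))
  # identity fields are preserved on copies
  expect_true(all(vapply(copies, function(e)
    e$patient_id %in% vapply(eps, function(x) x$patient_id, ""), NA)))
})

test_that("sinus episodes and small AT/AF pools pass through the policy", {
  sinus <- lapply(1:5, function(i) flat_episode(id = paste0("s", i),
                                                label = "SINUS", seed = i))
  out <- apply_augmentation(sinus, augmentation_policy(), seed = 1)
  expect_identical(out, sinus)              # pretraining pool unchanged
  few <- lapply(1:10, function(i) flat_episode(id = paste0("a", i),
                                               label = "ATAF", seed = i))
  out2 <- apply_augmentation(few, augmentation_policy(), seed = 1)
  expect_identical(out2, few)               # floor(0.04 * 10) = 0 copies
})

test_that("augmentation is reproducible under a fixed seed", {
  eps <- lapply(1:30, function(i) flat_episode(id = paste0("e", i),
    label = c("ATAF", "NOISE")[1 + i %% 2], seed = i))
  a <- apply_augmentation(eps, augmentation_policy(), seed = 42)
  b <- apply_augmentation(eps, augmentation_policy(), seed = 42)
  expect_identical(a, b)
})

test_that("augmented cohorts persist with provenance columns", {
  eps <- lapply(1:8, function(i) flat_episode(id = paste0("e", i),
    label = c("ATAF", "NOISE")[1 + i %% 2], seed = i))
  aug <- apply_augmentation(eps, augmentation_policy(), seed = 3)
  co <- cohort_manifest(aug)
  d <- withr::local_tempdir()
  save_cohort(co, d)
  man <- utils::read.csv(file.path(d, "manifest.csv"))
  expect_true(all(c("source_episode_id", "technique") %in% names(man)))
  co2 <- load_cohort(d)
  i_cp <- which(vapply(co2$episodes, function(e)
    !is.null(e$technique), NA))
  expect_gt(length(i_cp), 0)
  for (i in i_cp) {
    orig <- co$episodes[[which(vapply(co$episodes, `[[`, "",
      "episode_id") == co2$episodes[[i]]$episode_id)]]
    expect_identical(co2$episodes[[i]]$atrial, orig$atrial)
    expect_identical(co2$episodes[[i]]$technique, orig$technique)
  }
})
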