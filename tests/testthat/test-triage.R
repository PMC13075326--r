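test_that("soft voting averages probabilities and preserves the simplex", {
  truth <- c("ATAF", "NOISE", "FFO")
  a <- pred_set(truth, rbind(c(1, 0, 0), c(0, 1, 0), c(0.2, 0.3, 0.5)))
  b <- pred_set(truth, rbind(c(0, 1, 0), c(0, 1, 0), c(0.6, 0.2, 0.2)))
  ens <- soft_vote(list(a, b))
  expect_equal(ens$p_ataf, c(0.5, 0, 0.4))
  expect_equal(ens$p_noise, c(0.5, 1, 0.25))
  expect_equal(rowSums(as.matrix(ens[, c("p_ataf", "p_noise", "p_ffo")])),
               rep(1, 3))
  expect_equal(attr(ens, "provenance"), "ensemble")
  # k identical members -> identity
  expect_equal(soft_vote(list(a, a, a))$p_ataf, a$p_ataf)
  # mismatched keys are rejected
  b2 <- b; b2$episode_id <- rev(b2$episode_id)
  expect_error(soft_vote(list(a, b2)), "keys differ")
})

test_that("threshold triage retains only confident predictions and breaks
           ties toward AT/AF", {
  s <- pred_set(c("ATAF", "ATAF", "NOISE"),
                rbind(c(0.98, 0.01, 0.01),
                      c(0.60, 0.30, 0.10),
                      c(0.40, 0.40, 0.20)))
  tc <- triage_classify(s, 0.95)
  expect_equal(tc$predicted, c("ATAF", "ATAF", "ATAF"))
  expect_equal(tc$retained, c(TRUE, FALSE, FALSE))
  expect_true(all(triage_classify(s, NULL)$retained))
  # tie at 0.40/0.40 resolved to the AT/AF class
  expect_equal(tc$predicted[3], "ATAF")
})

test_that("coverage is monotonically non-increasing in the threshold", {
  set.seed(8)
  for (i in 1:5) {
    z <- matrix(rexp(60), 20)
    p <- z / rowSums(z)
    s <- pred_set(sample(ahre_classes(), 20, TRUE), p)
    cov <- vapply(seq(0, 1, by = 0.05), function(tau)
      per_class_metrics(s, tau)$coverage, 0)
    expect_true(all(diff(cov) <= 1e-12))
  }
})

test_that("per-class metrics match hand-computed confusion counts", {
  # ATAF one-vs-rest: TP=3, FP=1, FN=1, TN=5
  truth <- c(rep("ATAF", 4), rep("NOISE", 4), rep("FFO", 2))
  pred <- c("ATAF", "ATAF", "ATAF", "NOISE",
            "ATAF", "NOISE", "NOISE", "NOISE", "FFO", "FFO")
  q <- 0.99
  p <- sharp_probs(pred, q)
  s <- pred_set(truth, p)
  rep_ <- per_class_metrics(s, NULL)
  at <- rep_$per_class[rep_$per_class$class == "ATAF", ]
  expect_equal(at$precision, 75)
  expect_equal(at$recall, 75)
  expect_equal(at$specificity, 100 * 5 / 6, tolerance = 1e-9)
  expect_equal(at$f2, 75)
  expect_equal(rep_$incorrect, 2)
  expect_equal(rep_$coverage, 100)
  # perfect predictions
  s2 <- pred_set(truth, sharp_probs(truth, 0.99))
  rep2 <- per_class_metrics(s2, NULL)
  expect_equal(rep2$incorrect, 0)
  expect_true(all(rep2$per_class[, c("precision", "recall",
                                     "specificity")] == 100))
})

test_that("undefined ratios surface as NA rather than silent zeros", {
  truth <- c("ATAF", "ATAF", "NOISE")
  s <- pred_set(truth, sharp_probs(c("ATAF", "ATAF", "ATAF"), 0.9))
  rep_ <- per_class_metrics(s, NULL)
  ffo <- rep_$per_class[rep_$per_class$class == "FFO", ]
  expect_true(is.na(ffo$precision))   # FFO never predicted
  expect_true(is.na(ffo$recall))      # FFO never true
  noise <- rep_$per_class[rep_$per_class$class == "NOISE", ]
  expect_true(is.na(noise$precision))
  expect_equal(noise$recall, 0)
})

test_that("the printed-formula variant of precision/recall differs from
           the standard definitions used here", {
  # with TP=3, FN=1, FP=2: standard precision = 3/5, recall = 3/4; the
  # swapped TP+FN / TP+FP reading would give 3/4 and 3/5 instead
  tp <- 3; fn <- 1; fp <- 2
  expect_equal(tp / (tp + fp), 0.6)          # standard precision
  expect_equal(tp / (tp + fn), 0.75)         # standard recall
  truth <- c(rep("ATAF", 4), rep("NOISE", 2))
  pred <- c("ATAF", "ATAF", "ATAF", "NOISE", "ATAF", "ATAF")
  rep_ <- per_class_metrics(pred_set(truth, sharp_probs(pred, 0.9)), NULL)
  at <- rep_$per_class[rep_$per_class$class == "ATAF", ]
  expect_equal(at$precision, 60)
  expect_equal(at$recall, 75)
})

test_that("workload report tracks coverage and error rate per threshold", {
  set.seed(3)
  truth <- sample(ahre_classes(), 200, TRUE, prob = c(0.7, 0.2, 0.1))
  pred <- truth
  flip <- sample(200, 20)
  pred[flip] <- sample(ahre_classes(), 20, TRUE)
  conf <- runif(200, 0.5, 1)
  p <- sharp_probs(pred, 1)          # start one-hot, then soften
  p <- p * conf + (1 - conf) / 3
  wr <- workload_report(pred_set(truth, p), c(0.90, 0.95))
  expect_equal(wr$threshold, c("none", "0.90", "0.95"))
  expect_equal(wr$coverage[1], 100)
  expect_equal(wr$error_rate, 100 * wr$incorrect / wr$retained)
  expect_true(all(diff(wr$retained) <= 0))
})

test_that("patient bootstrap degenerates correctly and is seeded", {
  # all correct -> recall 100 with zero-width CI
  truth <- rep(c("ATAF", "NOISE", "FFO"), each = 4)
  s <- pred_set(truth, sharp_probs(truth, 0.99))
  pats <- rep(sprintf("p%d", 1:4), times = 3)
  b <- patient_bootstrap(s, pats, B = 100, seed = 1)
  expect_equal(b$recall$point, rep(100, 3))
  expect_equal(b$recall$lower, b$recall$upper)
  # single patient, single episode -> every iteration identical
  s1 <- pred_set("ATAF", sharp_probs("ATAF", 0.9))
  b1 <- patient_bootstrap(s1, "p1", B = 50, seed = 2)
  at <- b1$recall[b1$recall$class == "ATAF", ]
  expect_equal(at$lower, at$upper)
  expect_equal(at$point, 100)
  # deterministic under seed
  b2 <- patient_bootstrap(s, pats, B = 100, seed = 1)
  expect_identical(b$draws, b2$draws)
  expect_error(patient_bootstrap(s, pats, B = 0), "B must be")
})

test_that("bootstrap CIs shrink with patient count", {
  make <- function(n_pat, seed) {
    set.seed(seed)
    pats <- character(0); truth <- character(0)
    for (i in seq_len(n_pat)) {
      k <- sample(1:4, 1)
      labs <- sample(ahre_classes(), k, TRUE, prob = c(0.6, 0.3, 0.1))
      pats <- c(pats, rep(sprintf("p%04d", i), k))
      truth <- c(truth, labs)
    }
    pred <- truth
    miss <- runif(length(truth)) < 0.15
    pred[miss] <- sample(ahre_classes(), sum(miss), TRUE)
    list(set = pred_set(truth, sharp_probs(pred, 0.9)), pats = pats)
  }
  small <- make(50, 1); big <- make(400, 1)
  bs <- patient_bootstrap(small$set, small$pats, B = 200, seed = 3)
  bb <- patient_bootstrap(big$set, big$pats, B = 200, seed = 3)
  width <- function(b) stats::median(b$recall$upper - b$recall$lower)
  expect_lt(width(bb), width(bs))
})
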