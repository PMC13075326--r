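test_that("the stem compresses 1280 samples to a 320-point feature map", {
  expect_equal(stem_feature_length(model_spec()), 320L)
  # scales with input length at the same /4 stride product
  expect_equal(stem_feature_length(tiny_spec(512L)), 128L)
  expect_error(model_spec(input_length = 1281L), "divisible")
})

test_that("forward passes emit probability-simplex rows, deterministically
           in evaluation mode", {
  m <- build_resnet1d(tiny_spec(), seed = 3)
  set.seed(10)
  X <- array(rnorm(8 * 256 * 2, sd = 5), c(8, 256, 2))
  p <- predict_proba(m, X)
  expect_equal(rowSums(p), rep(1, 8), tolerance = 1e-6)
  expect_true(all(p >= 0))
  # same input in a permuted batch gives identical probabilities
  ord <- c(5, 2, 8, 1, 3, 7, 4, 6)
  p2 <- predict_proba(m, X[ord, , , drop = FALSE])
  expect_equal(p2, p[ord, ], tolerance = 1e-12)
})

test_that("analytic gradients match numerical differentiation", {
  spec <- model_spec(input_length = 32L, input_channels = 2L, filters = 4L,
                     hidden = 8L)
  m <- build_resnet1d(spec, seed = 42)
  set.seed(7)
  X <- array(rnorm(6 * 32 * 2), c(6, 32, 2))
  y <- ahretriage:::onehot_matrix(sample(ahre_classes(), 6, TRUE),
                                  ahre_classes())
  lossfn <- function(model)
    focal_loss(ahretriage:::resnet_forward(model, X, TRUE)$probs, y, 2)
  fw <- ahretriage:::resnet_forward(m, X, TRUE)
  G <- ahretriage:::resnet_backward(
    m, fw$caches, ahretriage:::focal_grad_logits(fw$probs, y, 2))
  eps <- 1e-5
  for (nm in names(m$params)) {
    p <- m$params[[nm]]
    for (i in sample(length(p), min(2, length(p)))) {
      m2 <- m; m2$params[[nm]][i] <- p[i] + eps
      m3 <- m; m3$params[[nm]][i] <- p[i] - eps
      num <- (lossfn(m2) - lossfn(m3)) / (2 * eps)
      expect_equal(G[[nm]][i], num, tolerance = 1e-4,
                   label = paste("gradient of", nm))
    }
  }
})

test_that("focal loss reduces to cross-entropy at gamma = 0 and matches
           the closed form", {
  set.seed(2)
  for (i in 1:20) {
    z <- matrix(rnorm(15 * 3), 15)
    probs <- exp(z) / rowSums(exp(z))
    y <- ahretriage:::onehot_matrix(sample(ahre_classes(), 15, TRUE),
                                    ahre_classes())
    expect_equal(focal_loss(probs, y, gamma = 0), ce_oracle(probs, y),
                 tolerance = 1e-9)
  }
  # hand-evaluated batch of 2 with p_true = (0.5, 0.9), gamma = 2
  probs <- rbind(c(0.5, 0.3, 0.2), c(0.05, 0.9, 0.05))
  y <- rbind(c(1, 0, 0), c(0, 1, 0))
  expect_equal(focal_loss(probs, y, gamma = 2),
               mean(c(0.25 * log(2), 0.01 * log(10 / 9))),
               tolerance = 1e-12)
  # perfect prediction has zero loss; negative gamma is rejected
  expect_equal(focal_loss(rbind(c(1, 0, 0)), rbind(c(1, 0, 0)), 2), 0,
               tolerance = 1e-6)
  expect_error(focal_loss(probs, y, gamma = -1), "gamma")
})

test_that("class-weighted F2 follows the 5PR/(4P+R) closed form", {
  expect_equal(f2_score(0.5, 1.0), 5 / 6)
  expect_equal(weighted_f2(rep(0.8, 3), rep(0.8, 3), c(10, 5, 2)), 0.8)
  # single class present -> that class's F2
  expect_equal(weighted_f2(c(0.5, NA, NA), c(1, NA, NA), c(7, 0, 0)), 5 / 6)
  # support weighting
  expect_equal(weighted_f2(c(1, 0.5), c(1, 1), c(3, 1)),
               0.75 * 1 + 0.25 * (5 / 6))
})

test_that("pretraining transfers every layer except the output head", {
  spec <- tiny_spec()
  pool <- c(
    lapply(1:30, function(i) flat_episode(id = paste0("s", i),
      patient = paste0("sp", i %% 6), label = "SINUS",
      atrial = sin(seq_len(1280) / 10) * 0.9 + rnorm(1280, sd = 0.02))),
    lapply(1:30, function(i) flat_episode(id = paste0("a", i),
      patient = paste0("ap", i %% 6), label = "ATAF",
      atrial = sin(seq_len(1280) / 3) * 0.5 + rnorm(1280, sd = 0.02)))
  )
  res <- pretrain_then_transfer(pool, spec,
                                train_config(max_epochs = 2, seed = 1),
                                seed = 4)
  m3 <- res$model
  expect_equal(m3$n_classes, 3L)
  expect_identical(m3$params$stem.W, res$pretrained$params$stem.W)
  expect_identical(m3$params$L2B2.c2.W, res$pretrained$params$L2B2.c2.W)
  expect_equal(dim(res$pretrained$params$fc2.W), c(spec$hidden, 2L))
  expect_equal(dim(m3$params$fc2.W), c(spec$hidden, 3L))
  expect_false(identical(m3$params$fc2.b, res$pretrained$params$fc2.b))
  # valid simplex before any fine-tuning
  p <- predict_proba(m3, array(rnorm(4 * 256 * 2), c(4, 256, 2)))
  expect_equal(rowSums(p), rep(1, 4), tolerance = 1e-6)
  # pools containing non-pretraining classes are rejected
  bad <- c(pool, list(flat_episode(id = "x", label = "NOISE")))
  expect_error(pretrain_then_transfer(bad, spec), "SINUS and ATAF")
})

test_that("training learns an amplitude-coded toy task and reports
           history", {
  toy <- toy_task(n_per_class = 30, len = 256L, seed = 11)
  idx_val <- seq(1, 90, by = 3)
  tr <- list(X = toy$X[-idx_val, , , drop = FALSE], y = toy$y[-idx_val])
  va <- list(X = toy$X[idx_val, , , drop = FALSE], y = toy$y[idx_val])
  m <- build_resnet1d(tiny_spec(), seed = 2)
  fit <- train_model(m, tr, va, train_config(max_epochs = 50, patience = 10,
                                             batch_size = 16, seed = 3))
  expect_gte(max(fit$history$val_weighted_f2), 0.95)
  expect_lte(nrow(fit$history), 50)
  expect_true(all(c("epoch", "train_loss", "val_loss", "val_weighted_f2")
                  %in% names(fit$history)))
})

test_that("early stopping halts after the configured patience", {
  toy <- toy_task(n_per_class = 8, len = 256L, seed = 5)
  tr <- list(X = toy$X, y = toy$y)
  m <- build_resnet1d(tiny_spec(), seed = 2)
  # zero learning rate: only batch-norm statistics drift, so the score
  # plateaus quickly; training must stop `patience` epochs after the
  # last improvement
  fit <- train_model(m, tr, tr, train_config(learning_rate = 0,
                                             max_epochs = 50,
                                             patience = 3, seed = 1))
  expect_equal(nrow(fit$history), fit$model$meta$best_epoch + 3)
  expect_lt(nrow(fit$history), 50)
  expect_error(train_model(m, list(X = tr$X[0, , , drop = FALSE],
                                   y = character(0)), tr,
                           train_config()), "empty")
})
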