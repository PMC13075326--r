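#' Architecture specification for the 1D-ResNet10 classifier
#'
#' The network consumes two-channel (atrial, ventricular) 1280-sample
#' episodes. A stem (convolution with kernel `stem_kernel` and stride 2,
#' batch normalization, ReLU, max-pooling with window 3 and stride 2)
#' reduces the 1280 samples to a 320-point feature signal. Two residual
#' layers of two blocks each follow; the first keeps `filters` channels
#' with identity shortcuts, the second doubles the channels and halves the
#' temporal length via a strided convolution with a 1x1 projection
#' shortcut. A global average pooling layer and two dense layers (hidden
#' width `hidden`, then softmax) produce the class probabilities.
#'
#' @param input_length samples per channel (must be divisible by 4, the
#'   stem's total stride).
#' @param input_channels number of signal channels.
#' @param filters stem/first-layer filter count `F`; the second residual
#'   layer uses `2F`.
#' @param stem_kernel,block_kernel convolution kernel sizes.
#' @param hidden width of the penultimate dense layer.
#' @return A `model_spec` list.
#' @export
model_spec <- function(input_length = 1280L, input_channels = 2L,
                       filters = 32L, stem_kernel = 7L, block_kernel = 3L,
                       hidden = 64L) {
  if (input_length %% 4L != 0L)
    stop("input_length must be divisible by the stem stride product (4)")
  structure(list(input_length = as.integer(input_length),
                 input_channels = as.integer(input_channels),
                 filters = as.integer(filters),
                 stem_kernel = as.integer(stem_kernel),
                 block_kernel = as.integer(block_kernel),
                 hidden = as.integer(hidden)),
            class = "model_spec")
}

#' Training configuration
#'
#' Optimization defaults: Adam with learning rate 0.001, batch size 64,
#' categorical focal loss with focusing parameter `gamma = 2` and uniform
#' class weights, early stopping after 5 epochs without improvement of the
#' validation class-weighted F2-score, at most 50 epochs. The checkpoint
#' with the highest validation class-weighted F2 is kept.
#'
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param gamma focal-loss focusing parameter (>= 0).
#' @param alpha optional per-class focal weights (named, defaults uniform).
#' @param patience epochs without F2 improvement before stopping.
#' @param max_epochs epoch cap.
#' @param seed RNG seed for shuffling/initialization.
#' @param verbose print per-epoch progress.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 64L,
                         gamma = 2, alpha = NULL, patience = 5L,
                         max_epochs = 50L, seed = 1L, verbose = FALSE) {
  if (gamma < 0) stop("gamma must be >= 0")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), gamma = gamma,
                 alpha = alpha, patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "train_config")
}

bn_param_names <- function(prefix) paste0(prefix, c(".g", ".b"))
bn_stat_names <- function(prefix) paste0(prefix, c(".mean", ".var"))

block_prefixes <- c("L1B1", "L1B2", "L2B1", "L2B2")

#' Build a 1D-ResNet10 model
#'
#' Initializes all parameters (He initialization for convolutions and
#' dense layers, unit-gamma/zero-beta batch norms) for a given
#' architecture specification and class set.
#'
#' @param spec a [model_spec()].
#' @param n_classes 2 (pretraining: sinus vs AT/AF) or 3 (AT/AF, noise,
#'   FFO).
#' @param class_levels class label order for the output layer; defaults to
#'   `ahre_classes()` for 3 classes and `c("SINUS", "ATAF")` for 2.
#' @param seed initialization seed.
#' @return An object of class `resnet1d`.
#' @export
build_resnet1d <- function(spec = model_spec(), n_classes = 3L,
                           class_levels = NULL, seed = 1L) {
  stopifnot(n_classes %in% c(2L, 3L))
  if (is.null(class_levels))
    class_levels <- if (n_classes == 3L) ahre_classes() else
      c("SINUS", "ATAF")
  stopifnot(length(class_levels) == n_classes)
  F1 <- spec$filters; F2 <- 2L * spec$filters; kb <- spec$block_kernel
  P <- list(); S <- list()
  add_bn <- function(name, ch) {
    P[[paste0(name, ".g")]] <<- rep(1, ch)
    P[[paste0(name, ".b")]] <<- rep(0, ch)
    S[[paste0(name, ".mean")]] <<- rep(0, ch)
    S[[paste0(name, ".var")]] <<- rep(1, ch)
  }
  with_seed(seed, {
    P$stem.W <- he_conv(spec$stem_kernel, spec$input_channels, F1)
    add_bn("stem.bn", F1)
    for (pre in block_prefixes) {
      cin <- if (pre == "L2B1") F1 else if (startsWith(pre, "L2")) F2 else F1
      cout <- if (startsWith(pre, "L2")) F2 else F1
      P[[paste0(pre, ".c1.W")]] <- he_conv(kb, cin, cout)
      add_bn(paste0(pre, ".bn1"), cout)
      P[[paste0(pre, ".c2.W")]] <- he_conv(kb, cout, cout)
      add_bn(paste0(pre, ".bn2"), cout)
      if (pre == "L2B1") {
        P$L2B1.proj.W <- he_conv(1L, F1, F2)
        add_bn("L2B1.bnp", F2)
      }
    }
    P$fc1.W <- he_dense(F2, spec$hidden)
    P$fc1.b <- rep(0, spec$hidden)
    P$fc2.W <- he_dense(spec$hidden, n_classes)
    P$fc2.b <- rep(0, n_classes)
  })
  structure(list(spec = spec, n_classes = as.integer(n_classes),
                 class_levels = class_levels, params = P, stats = S,
                 meta = list(seed = seed)),
            class = "resnet1d")
}

#' @export
print.resnet1d <- function(x, ...) {
  npar <- sum(vapply(x$params, length, 0L))
  cat("<resnet1d> ", x$n_classes, "-class (",
      paste(x$class_levels, collapse = ", "), "), F=", x$spec$filters,
      ", ", format(npar, big.mark = ","), " parameters\n", sep = "")
  invisible(x)
}

# full forward pass; returns logits, probs, stem/feature activations,
# caches for backward (training) and updated BN running stats
resnet_forward <- function(model, X, training = FALSE) {
  P <- model$params; S <- model$stats
  kb <- model$spec$block_kernel
  pad_b <- (kb - 1L) %/% 2L
  cc <- list()
  bnf <- function(name, Z) {
    r <- bn_forward(Z, P[[paste0(name, ".g")]], P[[paste0(name, ".b")]],
                    S[[paste0(name, ".mean")]], S[[paste0(name, ".var")]],
                    training)
    S[[paste0(name, ".mean")]] <<- r$run_mean
    S[[paste0(name, ".var")]] <<- r$run_var
    cc[[name]] <<- r$cache
    r$Y
  }
  convf <- function(name, Z, stride, pad) {
    r <- conv1d_forward(Z, P[[paste0(name, ".W")]], stride, pad)
    cc[[name]] <<- r$cache
    r$Y
  }
  reluf <- function(name, Z) {
    r <- relu_forward(Z)
    cc[[name]] <<- r$cache
    r$Y
  }
  # stem: conv/2 -> BN -> ReLU -> maxpool/2  (1280 -> 320)
  Z <- convf("stem", X, 2L, (model$spec$stem_kernel - 1L) %/% 2L)
  Z <- bnf("stem.bn", Z)
  Z <- reluf("stem.relu", Z)
  mp <- maxpool_forward(Z, 3L, 2L, 1L)
  cc$maxpool <- mp$cache
  Z <- mp$Y
  stem_out <- Z
  # residual blocks
  for (pre in block_prefixes) {
    ds <- pre == "L2B1"
    shortcut <- Z
    Y <- convf(paste0(pre, ".c1"), Z, if (ds) 2L else 1L, pad_b)
    Y <- bnf(paste0(pre, ".bn1"), Y)
    Y <- reluf(paste0(pre, ".relu1"), Y)
    Y <- convf(paste0(pre, ".c2"), Y, 1L, pad_b)
    Y <- bnf(paste0(pre, ".bn2"), Y)
    if (ds) {
      Sc <- convf("L2B1.proj", shortcut, 2L, 0L)
      Sc <- bnf("L2B1.bnp", Sc)
      shortcut <- Sc
    }
    Y <- Y + shortcut
    Z <- reluf(paste0(pre, ".relu2"), Y)
  }
  feat <- Z                               # [N, L/8, 2F] final conv features
  g <- gap_forward(Z); cc$gap <- g$cache
  d1 <- dense_forward(g$Y, P$fc1.W, P$fc1.b); cc$fc1 <- d1$cache
  h <- relu_forward(d1$Y); cc$fc1.relu <- h$cache
  d2 <- dense_forward(h$Y, P$fc2.W, P$fc2.b); cc$fc2 <- d2$cache
  logits <- d2$Y
  list(logits = logits, probs = softmax_rows(logits), feat = feat,
       stem_out = stem_out, caches = cc, stats = S)
}

# backward pass from dlogits; returns gradients named like params
resnet_backward <- function(model, caches, dlogits) {
  P <- model$params
  G <- list()
  cc <- caches
  bnb <- function(name, dZ) {
    r <- bn_backward(dZ, P[[paste0(name, ".g")]], cc[[name]])
    G[[paste0(name, ".g")]] <<- r$dgamma
    G[[paste0(name, ".b")]] <<- r$dbeta
    r$dX
  }
  convb <- function(name, dZ, need_dx = TRUE) {
    r <- conv1d_backward(dZ, P[[paste0(name, ".W")]], cc[[name]], need_dx)
    G[[paste0(name, ".W")]] <<- r$dW
    r$dX
  }
  d2 <- dense_backward(dlogits, P$fc2.W, cc$fc2)
  G$fc2.W <- d2$dW; G$fc2.b <- d2$db
  dh <- relu_backward(d2$dX, cc$fc1.relu)
  d1 <- dense_backward(dh, P$fc1.W, cc$fc1)
  G$fc1.W <- d1$dW; G$fc1.b <- d1$db
  dZ <- gap_backward(d1$dX, cc$gap)
  for (pre in rev(block_prefixes)) {
    ds <- pre == "L2B1"
    dZ <- relu_backward(dZ, cc[[paste0(pre, ".relu2")]])
    d_short <- dZ                          # addition fans gradient out
    dY <- bnb(paste0(pre, ".bn2"), dZ)
    dY <- convb(paste0(pre, ".c2"), dY)
    dY <- relu_backward(dY, cc[[paste0(pre, ".relu1")]])
    dY <- bnb(paste0(pre, ".bn1"), dY)
    dY <- convb(paste0(pre, ".c1"), dY)
    if (ds) {
      dS <- bnb("L2B1.bnp", d_short)
      dS <- convb("L2B1.proj", dS)
      dZ <- dY + dS
    } else {
      dZ <- dY + d_short
    }
  }
  dZ <- maxpool_backward(dZ, cc$maxpool)
  dZ <- relu_backward(dZ, cc[["stem.relu"]])
  dZ <- bnb("stem.bn", dZ)
  convb("stem", dZ, need_dx = FALSE)   # input gradient never needed
  G
}

#' Temporal length of the stem feature map
#'
#' Builds the model and runs an actual forward pass, returning the
#' temporal dimension of the activation emitted by the stem (convolution,
#' batch norm, ReLU, max pooling). For the default specification this is
#' 320: the 1280-sample input halved by the strided convolution and halved
#' again by the pooling layer.
#'
#' @param spec a [model_spec()].
#' @param batch_size rows in the probe batch.
#' @return Integer feature-map length.
#' @export
stem_feature_length <- function(spec = model_spec(), batch_size = 2L) {
  model <- build_resnet1d(spec, seed = 1L)
  X <- array(stats::rnorm(batch_size * spec$input_length *
                            spec$input_channels),
             c(batch_size, spec$input_length, spec$input_channels))
  fw <- resnet_forward(model, X, training = FALSE)
  dim(fw$stem_out)[2]
}

PROB_EPS <- 1e-7

#' Categorical focal loss
#'
#' `FL = -mean( alpha_t * (1 - p_t)^gamma * log(p_t) )` over the batch,
#' where `p_t` is the predicted probability of the true class.
#' Probabilities are clipped to `[1e-7, 1]`. With `gamma = 0` and uniform
#' weights this reduces to categorical cross-entropy.
#'
#' @param probs matrix of probability rows (one per sample).
#' @param onehot matrix of one-hot labels, same shape.
#' @param gamma focusing parameter, >= 0.
#' @param alpha optional per-class weight vector (default 1 for each).
#' @return Scalar mean loss.
#' @export
focal_loss <- function(probs, onehot, gamma = 2, alpha = NULL) {
  if (gamma < 0) stop("gamma must be >= 0")
  if (is.null(alpha)) alpha <- rep(1, ncol(probs))
  p_t <- pmax(rowSums(probs * onehot), PROB_EPS)
  a_t <- as.numeric(onehot %*% alpha)
  mean(-a_t * (1 - p_t)^gamma * log(p_t))
}

# d(focal loss)/d(logits), averaged over the batch
focal_grad_logits <- function(probs, onehot, gamma, alpha = NULL) {
  n <- nrow(probs)
  if (is.null(alpha)) alpha <- rep(1, ncol(probs))
  p_t <- pmax(rowSums(probs * onehot), PROB_EPS)
  a_t <- as.numeric(onehot %*% alpha)
  if (gamma == 0) {
    g <- -a_t / p_t
  } else {
    om <- pmax(1 - p_t, PROB_EPS)
    g <- a_t * (gamma * om^(gamma - 1) * log(p_t) - om^gamma / p_t)
  }
  # dL/dz_j = g * p_t * (1[j = t] - p_j)
  (g * p_t / n) * (onehot - probs)
}

#' F-beta score with beta = 2
#'
#' `F2 = 5 P R / (4 P + R)`, the harmonic-style mean weighting recall four
#' times as much as precision.
#'
#' @param precision,recall values in `[0, 1]` (vectorized).
#' @return F2 in `[0, 1]`; `NA` where undefined (P = R = 0 or missing).
#' @export
f2_score <- function(precision, recall) {
  out <- 5 * precision * recall / (4 * precision + recall)
  out[is.nan(out)] <- NA_real_
  out
}

#' Class-weighted F2-score
#'
#' Support-weighted mean of per-class F2 scores: weights are the class
#' supports normalized to sum to one, so the score emphasizes the majority
#' AT/AF class. Classes with undefined F2 (no true or predicted positives)
#' contribute zero.
#'
#' @param precision,recall per-class vectors in `[0, 1]`.
#' @param support per-class true counts (same order).
#' @return Scalar in `[0, 1]`.
#' @export
weighted_f2 <- function(precision, recall, support) {
  stopifnot(length(precision) == length(recall),
            length(recall) == length(support))
  f2 <- f2_score(precision, recall)
  f2[is.na(f2)] <- 0
  w <- support / sum(support)
  sum(w * f2)
}

# one-vs-rest P/R per class, then support-weighted F2
classification_weighted_f2 <- function(truth, pred, levels) {
  truth <- factor(truth, levels = levels)
  pred <- factor(pred, levels = levels)
  tp <- vapply(levels, function(cl) sum(truth == cl & pred == cl), 0)
  fp <- vapply(levels, function(cl) sum(truth != cl & pred == cl), 0)
  fn <- vapply(levels, function(cl) sum(truth == cl & pred != cl), 0)
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  weighted_f2(precision, recall, support = tp + fn)
}

#' Convert episodes to a model input tensor
#'
#' Stacks episodes into the `[n, 1280, 2]` array the network consumes,
#' channel order (atrial, ventricular).
#'
#' @param episodes list of `egm_episode` objects.
#' @return list with `X` (array), `y` (character labels), `episode_id`,
#'   `patient_id`.
#' @export
episodes_to_tensor <- function(episodes) {
  n <- length(episodes)
  X <- array(0, c(n, EGM_LEN, 2L))
  for (i in seq_len(n)) {
    X[i, , 1L] <- episodes[[i]]$atrial
    X[i, , 2L] <- episodes[[i]]$ventricular
  }
  list(X = X,
       y = vapply(episodes, `[[`, "", "label"),
       episode_id = vapply(episodes, `[[`, "", "episode_id"),
       patient_id = vapply(episodes, `[[`, "", "patient_id"))
}

onehot_matrix <- function(y, levels) {
  m <- matrix(0, length(y), length(levels))
  m[cbind(seq_along(y), match(y, levels))] <- 1
  m
}

#' Predict class probabilities
#'
#' Runs the network in evaluation mode (batch-norm running statistics),
#' batch-wise.
#'
#' @param model a `resnet1d`.
#' @param X input array `[n, length, 2]` or a list of episodes.
#' @param batch_size evaluation batch size.
#' @return Matrix of probability rows, columns named by class.
#' @export
predict_proba <- function(model, X, batch_size = 256L) {
  if (is.list(X) && !is.array(X)) X <- episodes_to_tensor(X)$X
  n <- dim(X)[1]
  out <- matrix(0, n, model$n_classes,
                dimnames = list(NULL, model$class_levels))
  for (s in seq(1L, n, by = batch_size)) {
    e <- min(n, s + batch_size - 1L)
    fw <- resnet_forward(model, X[s:e, , , drop = FALSE], training = FALSE)
    out[s:e, ] <- fw$probs
  }
  out
}

#' Build a prediction set for a batch of episodes
#'
#' @param model a `resnet1d` (3-class).
#' @param episodes list of `egm_episode`.
#' @param provenance model identifier recorded on the set.
#' @return data.frame with columns `episode_id`, `true_label`, `p_ataf`,
#'   `p_noise`, `p_ffo` and attribute `provenance`.
#' @export
prediction_set <- function(model, episodes, provenance = "model") {
  te <- episodes_to_tensor(episodes)
  probs <- predict_proba(model, te$X)
  out <- data.frame(episode_id = te$episode_id, true_label = te$y,
                    p_ataf = probs[, "ATAF"], p_noise = probs[, "NOISE"],
                    p_ffo = probs[, "FFO"], stringsAsFactors = FALSE)
  attr(out, "provenance") <- provenance
  out
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Train a model with focal loss and F2-based checkpoint selection
#'
#' Minibatch Adam training on the categorical focal loss. After every
#' epoch the validation set is scored in evaluation mode; the checkpoint
#' with the highest class-weighted F2 is retained. Training stops when the
#' score has not improved for `patience` epochs or at `max_epochs`.
#'
#' @param model a `resnet1d`.
#' @param train,val lists of episodes, or tensors from
#'   [episodes_to_tensor()].
#' @param config a [train_config()].
#' @return list: `model` (best checkpoint), `history` (data.frame with
#'   epoch, train_loss, val_loss, val_weighted_f2).
#' @export
train_model <- function(model, train, val, config = train_config()) {
  if (is.list(train) && !is.null(train$X)) tr <- train else
    tr <- episodes_to_tensor(train)
  if (is.list(val) && !is.null(val$X)) va <- val else
    va <- episodes_to_tensor(val)
  n <- dim(tr$X)[1]
  if (n == 0 || dim(va$X)[1] == 0) stop("empty training or validation split")
  levels <- model$class_levels
  Y <- onehot_matrix(tr$y, levels)
  if (anyNA(match(tr$y, levels)) || anyNA(match(va$y, levels)))
    stop("labels outside the model's class set")
  opt <- adam_init(model$params)
  alpha <- config$alpha
  best <- list(f2 = -Inf, params = model$params, stats = model$stats,
               epoch = 0L)
  hist <- list()
  stale <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    ord <- with_seed(derive_seed(config$seed, "shuffle", epoch),
                     sample.int(n))
    losses <- numeric(0)
    for (s in seq(1L, n, by = config$batch_size)) {
      idx <- ord[s:min(n, s + config$batch_size - 1L)]
      Xb <- tr$X[idx, , , drop = FALSE]
      Yb <- Y[idx, , drop = FALSE]
      fw <- resnet_forward(model, Xb, training = TRUE)
      model$stats <- fw$stats
      losses <- c(losses, focal_loss(fw$probs, Yb, config$gamma, alpha))
      dlogits <- focal_grad_logits(fw$probs, Yb, config$gamma, alpha)
      grads <- resnet_backward(model, fw$caches, dlogits)
      upd <- adam_step(model$params, grads, opt, config$learning_rate)
      model$params <- upd$params
      opt <- upd$state
    }
    val_probs <- predict_proba(model, va$X)
    val_pred <- levels[max.col(val_probs, ties.method = "first")]
    val_f2 <- classification_weighted_f2(va$y, val_pred, levels)
    val_loss <- focal_loss(val_probs, onehot_matrix(va$y, levels),
                           config$gamma, alpha)
    hist[[epoch]] <- data.frame(epoch = epoch,
                                train_loss = mean(losses),
                                val_loss = val_loss,
                                val_weighted_f2 = val_f2)
    if (config$verbose)
      message(sprintf("epoch %2d  train %.4f  val %.4f  wF2 %.4f",
                      epoch, mean(losses), val_loss, val_f2))
    if (val_f2 > best$f2 + 1e-9) {
      best <- list(f2 = val_f2, params = model$params, stats = model$stats,
                   epoch = epoch)
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= config$patience) break
    }
  }
  model$params <- best$params
  model$stats <- best$stats
  model$meta$best_epoch <- best$epoch
  model$meta$best_f2 <- best$f2
  list(model = model, history = do.call(rbind, hist))
}

#' Pretrain on sinus vs AT/AF, then transfer to the 3-class task
#'
#' Pretraining distinguishes sinus rhythm from AT/AF on unaugmented
#' episodes. Afterwards, all weights except the final dense layer are
#' copied into a fresh 3-class model whose output layer is newly
#' initialized.
#'
#' @param pool list of episodes containing only `SINUS` and `ATAF` labels.
#' @param spec a [model_spec()].
#' @param config a [train_config()] for the pretraining phase.
#' @param seed seed for initialization and the internal patient-level
#'   80/20 split of the pool.
#' @return list: `model` (3-class, transferred weights), `pretrained`
#'   (2-class checkpoint), `history`.
#' @export
pretrain_then_transfer <- function(pool, spec = model_spec(),
                                   config = train_config(), seed = 1L) {
  labs <- vapply(pool, `[[`, "", "label")
  if (any(!labs %in% c("SINUS", "ATAF")))
    stop("pretraining pool must contain only SINUS and ATAF episodes")
  sp <- trainval_split(pool, seed = derive_seed(seed, "pretrain_split"))
  m2 <- build_resnet1d(spec, n_classes = 2L, seed = derive_seed(seed, "pre"))
  fit <- train_model(m2, sp$train_episodes, sp$val_episodes, config)
  m3 <- transfer_weights(fit$model, seed = derive_seed(seed, "head"))
  list(model = m3, pretrained = fit$model, history = fit$history)
}

#' Transfer pretrained weights into a fresh 3-class model
#'
#' Copies every parameter and batch-norm running statistic except the
#' final dense layer, which is re-initialized for the new class count.
#'
#' @param pretrained a 2-class `resnet1d`.
#' @param class_levels output classes, default `ahre_classes()`.
#' @param seed initialization seed for the new output layer.
#' @return A 3-class `resnet1d`.
#' @export
transfer_weights <- function(pretrained, class_levels = ahre_classes(),
                             seed = 1L) {
  m <- build_resnet1d(pretrained$spec, n_classes = length(class_levels),
                      class_levels = class_levels, seed = seed)
  keep <- setdiff(names(m$params), c("fc2.W", "fc2.b"))
  m$params[keep] <- pretrained$params[keep]
  m$stats <- pretrained$stats
  m$meta$pretrained <- TRUE
  m
}
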