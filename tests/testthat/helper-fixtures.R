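# Fixtures are built in code; nothing is read from disk.

# episode with prescribed raw signals (normalized on construction)
flat_episode <- function(id = "e1", patient = "p1", center = "c1",
                         label = "ATAF", atrial = NULL, vent = NULL,
                         seed = NULL) {
  if (is.null(atrial)) {
    if (!is.null(seed)) set.seed(seed)
    atrial <- stats::rnorm(1280, sd = 0.3)
  }
  preprocess_episode(atrial, vent, episode_id = id, patient_id = patient,
                     center_id = center, label = label)
}

# cohort of label-carrying episodes with trivial signals, one patient per
# `patients` entry; `labels_per_patient` is a list of label vectors
id_cohort <- function(patients, labels_per_patient, centers = NULL) {
  if (is.null(centers)) centers <- rep("c1", length(patients))
  eps <- list()
  for (i in seq_along(patients)) {
    labs <- labels_per_patient[[i]]
    for (j in seq_along(labs)) {
      eps[[length(eps) + 1L]] <- flat_episode(
        id = sprintf("%s_e%02d", patients[i], j),
        patient = patients[i], center = centers[i], label = labs[j],
        atrial = sin(seq_len(1280) / 20) * 0.8)
    }
  }
  cohort_manifest(eps)
}

# prediction set from explicit probability rows
pred_set <- function(truth, p, ids = NULL, patient = NULL) {
  n <- length(truth)
  if (is.null(ids)) ids <- sprintf("e%04d", seq_len(n))
  out <- data.frame(episode_id = ids, true_label = truth,
                    p_ataf = p[, 1], p_noise = p[, 2], p_ffo = p[, 3],
                    stringsAsFactors = FALSE)
  if (!is.null(patient)) attr(out, "patient_id") <- patient
  out
}

# one-hot rows placing probability q on the true class, rest split evenly
sharp_probs <- function(truth, q, classes = ahre_classes()) {
  p <- matrix((1 - q) / 2, length(truth), 3)
  p[cbind(seq_along(truth), match(truth, classes))] <- q
  p
}

# independent cross-entropy oracle for the focal-loss limit case
ce_oracle <- function(probs, onehot) {
  -mean(log(pmax(rowSums(probs * onehot), 1e-7)))
}

# small architecture for fast model tests
tiny_spec <- function(len = 256L)
  model_spec(input_length = len, input_channels = 2L, filters = 8L,
             stem_kernel = 7L, block_kernel = 3L, hidden = 16L)

# amplitude-coded separable toy task: class encoded by the amplitude of a
# regular spike train (plus a localized high-amplitude 2 s cue for ATAF,
# used by the saliency localization test)
toy_task <- function(n_per_class = 40, len = 1280L, cue = FALSE,
                     seed = 11) {
  set.seed(seed)
  classes <- ahre_classes()
  amps <- c(ATAF = 1.0, NOISE = 0.45, FFO = 0.12)
  X <- array(0, c(3 * n_per_class, len, 2))
  y <- character(3 * n_per_class)
  cue_start <- integer(3 * n_per_class)
  i <- 0
  for (cl in classes) for (r in seq_len(n_per_class)) {
    i <- i + 1
    base <- rep(0, len)
    at <- seq(10, len - 10, by = 64)
    base[at] <- amps[[cl]]
    sig <- base + stats::rnorm(len, sd = 0.02)
    if (cue) {
      # discriminative content is a dense oscillation confined to a
      # random 2 s (256-sample) window, present only for ATAF
      s <- sample(len - 256L, 1)
      cue_start[i] <- s
      if (cl == "ATAF")
        sig[s:(s + 255L)] <- sig[s:(s + 255L)] +
          sin(seq_len(256) / 2) * 1.5
      sig[at] <- 0.3   # identical spikes for every class in cue mode
      sig <- sig / max(abs(sig))
    } else {
      # amplitude coding must survive: clip instead of rescaling
      sig <- pmax(pmin(sig, 1), -1)
    }
    X[i, , 1] <- sig
    X[i, , 2] <- stats::rnorm(len, sd = 0.02)
    y[i] <- cl
  }
  list(X = X, y = y,
       episode_id = sprintf("toy%03d", seq_len(3 * n_per_class)),
       patient_id = sprintf("toypat%03d", seq_len(3 * n_per_class)),
       cue_start = cue_start)
}
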