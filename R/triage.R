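# Soft-voting ensemble, probability-threshold triage, per-class metrics,
# and patient-level bootstrap evaluation.
#
# Metric definitions are the standard one-vs-rest ones:
# precision = TP/(TP+FP), recall = TP/(TP+FN), specificity = TN/(TN+FP),
# F2 = 5PR/(4P+R), all expressed in percent. Undefined ratios (zero
# denominators) are reported as NA, never silently as 0.

prob_cols <- c(ATAF = "p_ataf", NOISE = "p_noise", FFO = "p_ffo")

check_prediction_set <- function(set) {
  need <- c("episode_id", "true_label", prob_cols)
  if (!all(need %in% names(set)))
    stop("prediction set must have columns ",
         paste(need, collapse = ", "))
  rs <- rowSums(set[, prob_cols])
  if (any(abs(rs - 1) > 1e-6))
    stop("probability rows must sum to 1")
  invisible(set)
}

#' Soft-voting ensemble of prediction sets
#'
#' Averages class probabilities element-wise across models; the ensemble
#' prediction is the class with the highest average probability.
#'
#' @param sets list of prediction sets (data.frames with `episode_id`,
#'   `true_label`, `p_ataf`, `p_noise`, `p_ffo`) sharing identical episode
#'   keys.
#' @return A prediction set with provenance `"ensemble"`.
#' @export
soft_vote <- function(sets) {
  stopifnot(length(sets) >= 1)
  lapply(sets, check_prediction_set)
  ids <- sets[[1]]$episode_id
  for (s in sets[-1])
    if (!identical(s$episode_id, ids))
      stop("episode keys differ across prediction sets")
  out <- sets[[1]]
  for (cl in prob_cols)
    out[[cl]] <- rowMeans(vapply(sets, `[[`, numeric(length(ids)), cl))
  attr(out, "provenance") <- "ensemble"
  out
}

#' Classify with an optional probability threshold
#'
#' Predicted label is the argmax of the probability row (ties broken in
#' the order AT/AF, noise, FFO — the clinically conservative priority).
#' An episode is retained iff its top probability is at least `tau`; with
#' `tau = NULL` all episodes are retained.
#'
#' @param set a prediction set.
#' @param tau probability threshold in `[0, 1]`, or `NULL` for none.
#' @return data.frame: `episode_id`, `true_label`, `predicted`,
#'   `max_prob`, `retained`.
#' @export
triage_classify <- function(set, tau = NULL) {
  check_prediction_set(set)
  P <- as.matrix(set[, prob_cols])        # columns in tie-break order
  top <- max.col(P, ties.method = "first")
  maxp <- P[cbind(seq_len(nrow(P)), top)]
  retained <- if (is.null(tau)) rep(TRUE, nrow(P)) else maxp >= tau
  data.frame(episode_id = set$episode_id, true_label = set$true_label,
             predicted = names(prob_cols)[top], max_prob = maxp,
             retained = retained, stringsAsFactors = FALSE)
}

#' Per-class triage metrics at one threshold
#'
#' One-vs-rest precision, recall, specificity and F2 (in percent) over the
#' retained episodes, plus the retained count, coverage (retained/total as
#' a percentage), the number of incorrect retained predictions, and the
#' confusion matrix.
#'
#' @param set a prediction set.
#' @param tau probability threshold or `NULL`.
#' @param classes class set (fixed to the three AHRE classes).
#' @return A `triage_report` list.
#' @export
per_class_metrics <- function(set, tau = NULL,
                              classes = ahre_classes()) {
  tc <- triage_classify(set, tau)
  r <- tc[tc$retained, , drop = FALSE]
  truth <- factor(r$true_label, levels = classes)
  pred <- factor(r$predicted, levels = classes)
  conf <- table(true = truth, predicted = pred)
  per <- do.call(rbind, lapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    tn <- sum(truth != cl & pred != cl)
    precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    specificity <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    data.frame(class = cl, support = tp + fn,
               precision = 100 * precision, recall = 100 * recall,
               specificity = 100 * specificity,
               f2 = 100 * f2_score(precision, recall),
               stringsAsFactors = FALSE)
  }))
  structure(list(
    threshold = if (is.null(tau)) NA_real_ else tau,
    total = nrow(tc), retained = nrow(r),
    coverage = 100 * nrow(r) / nrow(tc),
    incorrect = sum(r$true_label != r$predicted),
    per_class = per, confusion = conf
  ), class = "triage_report")
}

#' @export
print.triage_report <- function(x, ...) {
  tau <- if (is.na(x$threshold)) "none" else
    sprintf(">= %.0f%%", 100 * x$threshold)
  cat(sprintf("<triage_report> threshold %s: retained %d/%d (%.1f%%), %d incorrect\n",
              tau, x$retained, x$total, x$coverage, x$incorrect))
  pc <- x$per_class
  pc[, 3:6] <- round(pc[, 3:6], 2)
  print(pc, row.names = FALSE)
  invisible(x)
}

#' Workload-reduction summary across thresholds
#'
#' One row per threshold (including "none"): coverage (the fraction of
#' episodes auto-handled, i.e. the workload removed from human review),
#' the error rate among retained episodes, and the per-class metrics in
#' wide form.
#'
#' @param set a prediction set.
#' @param thresholds probability thresholds (default 0.90 and 0.95).
#' @param out_csv optional path for a machine-readable copy.
#' @return data.frame, one row per threshold; the `triage_report`s are
#'   attached as attribute `reports`.
#' @export
workload_report <- function(set, thresholds = c(0.90, 0.95),
                            out_csv = NULL) {
  taus <- c(list(NULL), as.list(thresholds))
  reports <- lapply(taus, function(t) per_class_metrics(set, t))
  rows <- lapply(reports, function(rep) {
    wide <- data.frame(threshold = ifelse(is.na(rep$threshold), "none",
                                          sprintf("%.2f", rep$threshold)),
                       retained = rep$retained, total = rep$total,
                       coverage = rep$coverage, incorrect = rep$incorrect,
                       error_rate = 100 * rep$incorrect /
                         max(rep$retained, 1L),
                       stringsAsFactors = FALSE)
    for (i in seq_len(nrow(rep$per_class))) {
      cl <- tolower(rep$per_class$class[i])
      wide[[paste0("precision_", cl)]] <- rep$per_class$precision[i]
      wide[[paste0("recall_", cl)]] <- rep$per_class$recall[i]
      wide[[paste0("specificity_", cl)]] <- rep$per_class$specificity[i]
    }
    wide
  })
  out <- do.call(rbind, rows)
  attr(out, "reports") <- reports
  if (!is.null(out_csv))
    utils::write.csv(out, out_csv, row.names = FALSE)
  out
}

#' Patient-level bootstrap of recall and specificity
#'
#' Patients are resampled with replacement `B` times; in each iteration
#' one episode of each class the patient possesses is drawn at random,
#' and one-vs-rest recall and specificity are computed per class on the
#' resampled episode set. This preserves class balance and yields enough
#' patients for the minority classes. Point estimates are the mean over
#' iterations (the plug-in estimate on the full set is also reported);
#' confidence intervals are the 2.5/97.5 percentiles.
#'
#' @param set a prediction set.
#' @param patient_ids character vector parallel to the rows of `set`.
#' @param B bootstrap iterations (>= 1).
#' @param seed RNG seed.
#' @param classes class set.
#' @return A `bootstrap_result`: per class, recall and specificity with
#'   point estimates and 95% CIs.
#' @export
patient_bootstrap <- function(set, patient_ids, B = 1000L, seed = 1L,
                              classes = ahre_classes()) {
  if (B < 1) stop("B must be >= 1")
  check_prediction_set(set)
  stopifnot(length(patient_ids) == nrow(set))
  tc <- triage_classify(set, NULL)
  truth <- tc$true_label
  pred <- tc$predicted
  # patient -> class -> row indices
  pats <- unique(patient_ids)
  by_pc <- lapply(pats, function(p) {
    rows <- which(patient_ids == p)
    split(rows, factor(truth[rows], levels = classes))
  })
  names(by_pc) <- pats
  measure <- function(rows) {
    tr <- truth[rows]; pr <- pred[rows]
    vapply(classes, function(cl) {
      tp <- sum(tr == cl & pr == cl); fn <- sum(tr == cl & pr != cl)
      fp <- sum(tr != cl & pr == cl); tn <- sum(tr != cl & pr != cl)
      c(recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
        specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
    }, c(recall = 0, specificity = 0))
  }
  draws <- with_seed(seed, {
    res <- array(NA_real_, c(2, length(classes), B),
                 dimnames = list(c("recall", "specificity"), classes, NULL))
    for (b in seq_len(B)) {
      chosen <- sample(length(pats), replace = TRUE)
      rows <- unlist(lapply(by_pc[chosen], function(cls)
        vapply(cls[lengths(cls) > 0], function(ix)
          if (length(ix) == 1L) ix else sample(ix, 1L), 0L)),
        use.names = FALSE)
      res[, , b] <- measure(rows)
    }
    res
  })
  plug_in <- measure(seq_along(truth))
  summarize <- function(metric) {
    do.call(rbind, lapply(classes, function(cl) {
      v <- draws[metric, cl, ]
      data.frame(class = cl,
                 point = 100 * mean(v, na.rm = TRUE),
                 lower = 100 * stats::quantile(v, 0.025, na.rm = TRUE,
                                               names = FALSE),
                 upper = 100 * stats::quantile(v, 0.975, na.rm = TRUE,
                                               names = FALSE),
                 plug_in = 100 * plug_in[metric, cl],
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(recall = summarize("recall"),
                 specificity = summarize("specificity"),
                 B = B, seed = seed, draws = draws),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat("<bootstrap_result> B =", x$B, "\n")
  fmt <- function(df, what) {
    for (i in seq_len(nrow(df)))
      cat(sprintf("  %-12s %-5s %.1f%% (95%% CI %.1f-%.1f)\n", what,
                  df$class[i], df$point[i], df$lower[i], df$upper[i]))
  }
  fmt(x$recall, "recall")
  fmt(x$specificity, "specificity")
  invisible(x)
}
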