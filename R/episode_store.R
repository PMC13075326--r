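#' @keywords internal
#' @useDynLib ahretriage, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Fixed signal geometry: 10 s at 128 Hz.
EGM_FS <- 128L
EGM_LEN <- 1280L

#' Episode class labels
#'
#' `ahre_classes()` returns the three AHRE classes the classifier
#' distinguishes (AT/AF, noise, far-field oversensing) in the canonical
#' column/tie-break order; `egm_labels()` additionally includes `SINUS`,
#' the sinus-rhythm class used only for pretraining.
#'
#' @return Character vector of class labels.
#' @export
ahre_classes <- function() c("ATAF", "NOISE", "FFO")

#' @rdname ahre_classes
#' @export
egm_labels <- function() c("ATAF", "NOISE", "FFO", "SINUS")

#' Construct an episode record
#'
#' The atomic data unit: one atrial high-rate episode with a 10 s atrial and
#' ventricular intracardiac electrogram (EGM) sampled at 128 Hz (1280
#' samples), a binarized device-marker train on the same grid, a class
#' label, and patient/center identity. Episodes missing the ventricular
#' channel carry an all-zero ventricular signal and `has_ventricular =
#' FALSE`.
#'
#' @param episode_id,patient_id,center_id opaque identifier strings.
#' @param label one of `egm_labels()`.
#' @param atrial,ventricular numeric vectors of length 1280, normalized to
#'   `[-1, 1]`.
#' @param has_ventricular logical; `FALSE` forces `ventricular` to zeros.
#' @param markers integer 0/1 vector of length 1280; 1 at marker samples.
#' @param marker_types optional data.frame with columns `sample_index`
#'   (0-based, in `[0, 1279]`) and `type` (`AS`, `TA`, `Vs`, `Vp`).
#' @param events optional ground-truth event log (data.frame with columns
#'   `event_time_s`, `event_kind`), attached by the simulator.
#' @param validate check the record invariants (disable for augmented
#'   copies, whose amplitudes may exceed the normalized range).
#' @return An object of class `egm_episode`.
#' @export
episode_record <- function(episode_id, patient_id, center_id, label,
                           atrial, ventricular = NULL,
                           has_ventricular = !is.null(ventricular),
                           markers = integer(EGM_LEN),
                           marker_types = NULL, events = NULL,
                           validate = TRUE) {
  if (is.null(ventricular) || !has_ventricular) {
    ventricular <- numeric(EGM_LEN)
    has_ventricular <- FALSE
  }
  e <- structure(list(
    episode_id = as.character(episode_id),
    patient_id = as.character(patient_id),
    center_id = as.character(center_id),
    label = as.character(label),
    atrial = as.numeric(atrial),
    ventricular = as.numeric(ventricular),
    has_ventricular = isTRUE(has_ventricular),
    markers = as.integer(markers),
    marker_types = marker_types
  ), class = "egm_episode")
  if (!is.null(events)) attr(e, "events") <- events
  if (validate) validate_episode(e)
  e
}

#' Validate an episode record
#'
#' Checks the structural invariants: 1280 samples per channel, normalized
#' amplitudes, all-zero ventricular channel when absent, and agreement
#' between the binary marker train and the typed marker list.
#'
#' @param e an `egm_episode`.
#' @return `e`, invisibly; errors with the episode id on violation.
#' @export
validate_episode <- function(e) {
  fail <- function(msg) stop("invalid episode '", e$episode_id, "': ", msg,
                             call. = FALSE)
  if (!e$label %in% egm_labels()) fail(paste("unknown label", e$label))
  if (length(e$atrial) != EGM_LEN) fail("atrial length != 1280")
  if (length(e$ventricular) != EGM_LEN) fail("ventricular length != 1280")
  if (length(e$markers) != EGM_LEN) fail("marker train length != 1280")
  if (anyNA(e$atrial) || !all(is.finite(e$atrial))) fail("non-finite atrial")
  if (anyNA(e$ventricular) || !all(is.finite(e$ventricular)))
    fail("non-finite ventricular")
  if (max(abs(e$atrial)) > 1 + 1e-9) fail("atrial not normalized")
  if (max(abs(e$ventricular)) > 1 + 1e-9) fail("ventricular not normalized")
  if (!e$has_ventricular && any(e$ventricular != 0))
    fail("ventricular must be all zeros when channel absent")
  if (!all(e$markers %in% c(0L, 1L))) fail("markers not binary")
  if (!is.null(e$marker_types)) {
    idx <- sort(unique(e$marker_types$sample_index))
    if (length(idx) && (min(idx) < 0L || max(idx) > EGM_LEN - 1L))
      fail("marker sample_index out of [0, 1279]")
    if (!identical(which(e$markers == 1L) - 1L, as.integer(idx)))
      fail("markers vector disagrees with marker_types")
  }
  invisible(e)
}

#' Max-absolute channel normalization
#'
#' Scales a signal by its maximum absolute value so the output lies in
#' `[-1, 1]` while preserving waveform shape. All-zero signals are returned
#' unchanged, and the operation is idempotent.
#'
#' @param x finite numeric vector.
#' @return Numeric vector of the same length with `max(|x|) <= 1`.
#' @export
#' @examples
#' normalize_channel(c(2, -4))  # 0.5 -1
normalize_channel <- function(x) {
  if (anyNA(x) || !all(is.finite(x))) stop("non-finite values in channel")
  m <- max(abs(x))
  if (m > 0) x / m else x
}

#' Preprocess raw episode signals to the fixed 10 s / 128 Hz grid
#'
#' Applies the acquisition contract: the last ten seconds of each channel
#' are retained (longer signals are truncated from the front, shorter ones
#' zero-padded at the beginning), an absent ventricular channel becomes a
#' ten-second signal of zeros, marker times are binarized onto the same
#' 1280-sample grid, and each channel is max-absolute normalized.
#'
#' Marker times are given in seconds from the start of the *raw* recording;
#' they are re-expressed relative to the retained window, rounded to the
#' nearest sample (`round(t * 128)`), clipped to the grid, and dropped when
#' they fall outside the retained window.
#'
#' @param raw_atrial numeric vector, any positive length.
#' @param raw_ventricular numeric vector or `NULL` when the channel is
#'   absent.
#' @param marker_times_s numeric vector of marker times in seconds.
#' @param marker_type_labels optional character vector parallel to
#'   `marker_times_s` (`AS`, `TA`, `Vs`, `Vp`).
#' @param fs sampling frequency; must be 128 Hz.
#' @inheritParams episode_record
#' @return An `egm_episode`.
#' @export
preprocess_episode <- function(raw_atrial, raw_ventricular = NULL,
                               marker_times_s = numeric(0),
                               marker_type_labels = NULL,
                               fs = 128,
                               episode_id = "episode",
                               patient_id = "patient",
                               center_id = "center",
                               label = "ATAF",
                               events = NULL) {
  if (fs != EGM_FS) stop("sampling frequency must be 128 Hz")
  if (length(raw_atrial) == 0) stop("invalid episode: empty atrial signal")
  if (anyNA(raw_atrial) || !all(is.finite(raw_atrial)))
    stop("invalid episode: non-finite atrial samples")
  has_v <- !is.null(raw_ventricular) && length(raw_ventricular) > 0
  if (has_v && (anyNA(raw_ventricular) || !all(is.finite(raw_ventricular))))
    stop("invalid episode: non-finite ventricular samples")

  fit_window <- function(x) {
    n <- length(x)
    if (n >= EGM_LEN) x[(n - EGM_LEN + 1L):n] else c(numeric(EGM_LEN - n), x)
  }
  n_raw <- length(raw_atrial)
  # offset (in samples) of the retained window start within the raw signal;
  # negative when the raw signal was front-padded
  offset <- n_raw - EGM_LEN

  atrial <- normalize_channel(fit_window(raw_atrial))
  ventricular <- if (has_v) normalize_channel(fit_window(raw_ventricular))
                 else numeric(EGM_LEN)

  markers <- integer(EGM_LEN)
  marker_types <- NULL
  if (length(marker_times_s)) {
    idx_raw <- round(marker_times_s * EGM_FS) - offset
    keep <- idx_raw >= 0 & idx_raw <= (EGM_LEN - 1L)
    idx <- pmin(pmax(as.integer(idx_raw[keep]), 0L), EGM_LEN - 1L)
    markers[idx + 1L] <- 1L
    if (!is.null(marker_type_labels)) {
      marker_types <- data.frame(
        sample_index = idx,
        type = as.character(marker_type_labels[keep]),
        stringsAsFactors = FALSE
      )
      marker_types <- marker_types[order(marker_types$sample_index), ,
                                   drop = FALSE]
      marker_types <- marker_types[!duplicated(marker_types$sample_index), ,
                                   drop = FALSE]
      rownames(marker_types) <- NULL
    }
  }
  episode_record(episode_id, patient_id, center_id, label,
                 atrial, ventricular, has_ventricular = has_v,
                 markers = markers, marker_types = marker_types,
                 events = events)
}

#' Assemble a cohort manifest
#'
#' A cohort is a set of episodes together with the patient-to-center map and
#' per-class episode tallies. Both derived fields are recomputed from the
#' episodes so the stated invariants hold by construction.
#'
#' @param episodes list of `egm_episode` objects.
#' @return An object of class `egm_cohort` with fields `episodes`,
#'   `patient_to_center` and `class_counts`.
#' @export
cohort_manifest <- function(episodes) {
  stopifnot(length(episodes) > 0)
  pid <- vapply(episodes, `[[`, "", "patient_id")
  cid <- vapply(episodes, `[[`, "", "center_id")
  lab <- vapply(episodes, `[[`, "", "label")
  p2c <- tapply(cid, pid, function(v) {
    u <- unique(v)
    if (length(u) > 1) stop("patient mapped to multiple centers")
    u
  })
  counts <- table(factor(lab, levels = egm_labels()))
  structure(list(
    episodes = episodes,
    patient_to_center = stats::setNames(as.character(p2c), names(p2c)),
    class_counts = stats::setNames(as.integer(counts), names(counts))
  ), class = "egm_cohort")
}

#' @export
print.egm_cohort <- function(x, ...) {
  cc <- x$class_counts[x$class_counts > 0]
  cat("<egm_cohort> ", length(x$episodes), " episodes, ",
      length(x$patient_to_center), " patients, ",
      length(unique(manifest_table(x)$center_id)), " centers\n", sep = "")
  cat("  classes:",
      paste(names(cc), cc, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# flat view of identity fields, one row per episode; augmentation
# provenance columns are appended only when any episode carries them
manifest_table <- function(cohort) {
  out <- data.frame(
    episode_id = vapply(cohort$episodes, `[[`, "", "episode_id"),
    patient_id = vapply(cohort$episodes, `[[`, "", "patient_id"),
    center_id = vapply(cohort$episodes, `[[`, "", "center_id"),
    label = vapply(cohort$episodes, `[[`, "", "label"),
    has_ventricular = vapply(cohort$episodes, `[[`, NA, "has_ventricular"),
    stringsAsFactors = FALSE
  )
  if (any(vapply(cohort$episodes, function(e)
    !is.null(e$technique), NA))) {
    grab <- function(f) vapply(cohort$episodes, function(e)
      if (is.null(e[[f]])) NA_character_ else as.character(e[[f]]), "")
    out$source_episode_id <- grab("source_episode_id")
    out$technique <- grab("technique")
  }
  out
}

#' Persist / restore a cohort
#'
#' Writes a cohort to a directory as a Parquet file of signal arrays
#' (`signals.parquet`, keyed by `episode_id`, with list columns for the
#' atrial and ventricular channels and markers), a plain-text manifest
#' (`manifest.csv` with columns `episode_id`, `patient_id`, `center_id`,
#' `label`, `has_ventricular`), and, when ground-truth event logs are
#' present, `events.csv` (`episode_id`, `event_time_s`, `event_kind`).
#' The round trip is lossless: doubles are stored at full precision.
#'
#' @param cohort an `egm_cohort`.
#' @param path directory to write to (created if needed).
#' @return `save_cohort`: `path`, invisibly. `load_cohort`: an
#'   `egm_cohort`.
#' @export
save_cohort <- function(cohort, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  man <- manifest_table(cohort)
  utils::write.csv(man, file.path(path, "manifest.csv"), row.names = FALSE)

  sig <- data.frame(episode_id = man$episode_id, stringsAsFactors = FALSE)
  sig$atrial <- lapply(cohort$episodes, `[[`, "atrial")
  sig$ventricular <- lapply(cohort$episodes, `[[`, "ventricular")
  sig$markers <- lapply(cohort$episodes, `[[`, "markers")
  sig$marker_index <- lapply(cohort$episodes, function(e)
    if (is.null(e$marker_types)) integer(0) else
      as.integer(e$marker_types$sample_index))
  sig$marker_type <- lapply(cohort$episodes, function(e)
    if (is.null(e$marker_types)) character(0) else e$marker_types$type)
  arrow::write_parquet(sig, file.path(path, "signals.parquet"))

  ev <- lapply(cohort$episodes, function(e) {
    log <- attr(e, "events")
    if (is.null(log) || nrow(log) == 0) return(NULL)
    cbind(episode_id = e$episode_id, log)
  })
  ev <- do.call(rbind, ev[!vapply(ev, is.null, NA)])
  if (!is.null(ev) && nrow(ev)) {
    ev$event_time_s <- sprintf("%.17g", ev$event_time_s)  # lossless doubles
    utils::write.csv(ev, file.path(path, "events.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' @rdname save_cohort
#' @export
load_cohort <- function(path) {
  man_file <- file.path(path, "manifest.csv")
  sig_file <- file.path(path, "signals.parquet")
  if (!file.exists(man_file)) stop("missing manifest.csv in ", path)
  if (!file.exists(sig_file)) stop("missing signals.parquet in ", path)
  man <- utils::read.csv(man_file, stringsAsFactors = FALSE)
  need <- c("episode_id", "patient_id", "center_id", "label",
            "has_ventricular")
  if (!all(need %in% names(man)))
    stop("malformed manifest: expected columns ",
         paste(need, collapse = ", "))
  sig <- as.data.frame(arrow::read_parquet(sig_file))
  rownames(sig) <- sig$episode_id

  ev_file <- file.path(path, "events.csv")
  ev <- if (file.exists(ev_file))
    utils::read.csv(ev_file, stringsAsFactors = FALSE) else NULL

  episodes <- lapply(seq_len(nrow(man)), function(i) {
    id <- man$episode_id[i]
    if (!id %in% sig$episode_id)
      stop("load error: episode '", id, "' has no signal row")
    row <- sig[id, ]
    atrial <- row$atrial[[1]]
    if (length(atrial) != EGM_LEN)
      stop("load error: episode '", id, "': atrial signal length ",
           length(atrial), " != 1280")
    vent <- row$ventricular[[1]]
    if (length(vent) != EGM_LEN)
      stop("load error: episode '", id, "': ventricular signal length ",
           length(vent), " != 1280")
    mt <- NULL
    if (length(row$marker_index[[1]]))
      mt <- data.frame(sample_index = as.integer(row$marker_index[[1]]),
                       type = as.character(row$marker_type[[1]]),
                       stringsAsFactors = FALSE)
    events <- NULL
    if (!is.null(ev) && id %in% ev$episode_id) {
      events <- ev[ev$episode_id == id, c("event_time_s", "event_kind")]
      rownames(events) <- NULL
    }
    augmented <- !is.null(man$technique) && !is.na(man$technique[i])
    ep <- episode_record(id, man$patient_id[i], man$center_id[i],
                         man$label[i], atrial, vent,
                         has_ventricular = man$has_ventricular[i],
                         markers = as.integer(row$markers[[1]]),
                         marker_types = mt, events = events,
                         validate = !augmented)
    if (augmented) {
      ep$source_episode_id <- man$source_episode_id[i]
      ep$technique <- man$technique[i]
    }
    ep
  })
  cohort_manifest(episodes)
}

# subset helper preserving cohort structure
cohort_subset <- function(cohort, keep) {
  cohort_manifest(cohort$episodes[keep])
}
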