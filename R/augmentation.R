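# Training-time signal augmentation: five operators and the application
# policy. Operators act on both EGM channels coherently (preserving A-V
# timing relations except where the transformation intends otherwise),
# leave the marker train untouched (markers are not a model input), and
# preserve episode identity fields. Augmented copies supplement their
# originals and are used only for 3-class training, never for
# pretraining, validation or testing.

AUG_TECHNIQUES <- c("BLANK", "SCALE", "INVERT", "SHIFT", "SWAP_HALVES")

aug_copy <- function(e, technique, atrial, ventricular) {
  out <- e
  out$atrial <- atrial
  out$ventricular <- ventricular
  out$episode_id <- paste0(e$episode_id, "_aug_", tolower(technique))
  out$source_episode_id <- e$episode_id
  out$technique <- technique
  out
}

#' Augmentation operators
#'
#' Five signal-level transformations applied to a whole episode:
#' \describe{
#'   \item{`aug_blank`}{zeroes a randomly placed contiguous 2 s
#'     (256-sample) window, the same window on both channels.}
#'   \item{`aug_scale`}{multiplies each channel by an independent factor
#'     drawn uniformly from `[0.4, 1.2]`.}
#'   \item{`aug_invert`}{multiplies both channels by -1 (an involution).}
#'   \item{`aug_shift`}{shifts both channels by a shared offset drawn
#'     uniformly from 0.4–1.5 s in a random direction; the vacated region
#'     is zero-filled.}
#'   \item{`aug_swap_halves`}{exchanges the first and second 5 s halves of
#'     both channels (an involution).}
#' }
#' Random draws use the current RNG state. Scale factors and shift
#' offsets are recorded on the returned copy (`factor_atrial`,
#' `factor_ventricular`, `shift_samples`).
#'
#' @param e an `egm_episode`.
#' @return An augmented copy with provenance fields `source_episode_id`
#'   and `technique`.
#' @export
aug_blank <- function(e) {
  start <- sample.int(EGM_LEN - 256L + 1L, 1L)   # start index 0..1024
  idx <- start:(start + 255L)
  a <- e$atrial; v <- e$ventricular
  a[idx] <- 0; v[idx] <- 0
  out <- aug_copy(e, "BLANK", a, v)
  out$blank_start <- start - 1L
  out
}

#' @rdname aug_blank
#' @export
aug_scale <- function(e) {
  fa <- stats::runif(1, 0.4, 1.2)
  fv <- stats::runif(1, 0.4, 1.2)
  out <- aug_copy(e, "SCALE", e$atrial * fa, e$ventricular * fv)
  out$factor_atrial <- fa
  out$factor_ventricular <- fv
  out
}

#' @rdname aug_blank
#' @export
aug_invert <- function(e) {
  aug_copy(e, "INVERT", -e$atrial, -e$ventricular)
}

#' @rdname aug_blank
#' @export
aug_shift <- function(e) {
  d <- round(stats::runif(1, 0.4, 1.5) * EGM_FS)
  if (stats::runif(1) < 0.5) d <- -d
  shift1 <- function(x) {
    y <- numeric(EGM_LEN)
    if (d > 0) y[(d + 1L):EGM_LEN] <- x[1L:(EGM_LEN - d)]
    else y[1L:(EGM_LEN + d)] <- x[(1L - d):EGM_LEN]
    y
  }
  out <- aug_copy(e, "SHIFT", shift1(e$atrial), shift1(e$ventricular))
  out$shift_samples <- d
  out
}

#' @rdname aug_blank
#' @export
aug_swap_halves <- function(e) {
  half <- EGM_LEN %/% 2L
  sw <- function(x) c(x[(half + 1L):EGM_LEN], x[1L:half])
  aug_copy(e, "SWAP_HALVES", sw(e$atrial), sw(e$ventricular))
}

aug_apply_one <- function(e, technique) {
  switch(technique,
         BLANK = aug_blank(e), SCALE = aug_scale(e),
         INVERT = aug_invert(e), SHIFT = aug_shift(e),
         SWAP_HALVES = aug_swap_halves(e),
         stop("unknown augmentation technique: ", technique))
}

#' Augmentation application policy
#'
#' Every noise and FFO episode receives one augmented copy per technique
#' (five copies each); a disjoint random 4% of the AT/AF episodes per
#' technique receives one copy (20% of AT/AF episodes in total); sinus
#' episodes are never augmented. Per-technique AT/AF subsets are sampled
#' without replacement and kept disjoint so the totals are exact.
#'
#' @param techniques ordered technique names.
#' @param ataf_fraction_per_technique fraction of AT/AF episodes augmented
#'   by each technique.
#' @return An `augmentation_policy` list.
#' @export
augmentation_policy <- function(techniques = AUG_TECHNIQUES,
                                ataf_fraction_per_technique = 0.04) {
  stopifnot(all(techniques %in% AUG_TECHNIQUES),
            ataf_fraction_per_technique >= 0,
            length(techniques) * ataf_fraction_per_technique <= 1)
  structure(list(techniques = techniques,
                 ataf_fraction_per_technique = ataf_fraction_per_technique),
            class = "augmentation_policy")
}

#' Apply the augmentation policy to a training pool
#'
#' Returns the original episodes plus the augmented copies mandated by the
#' policy. The per-technique AT/AF counts use `floor(fraction * n_ATAF)`
#' (so fewer than 25 AT/AF episodes can yield zero copies per technique).
#'
#' @param episodes training episodes (labels required).
#' @param policy an [augmentation_policy()].
#' @param seed RNG seed for window/factor/subset draws.
#' @return list of episodes: originals followed by augmented copies.
#' @export
apply_augmentation <- function(episodes, policy = augmentation_policy(),
                               seed = 1L) {
  labs <- vapply(episodes, `[[`, "", "label")
  minority <- which(labs %in% c("NOISE", "FFO"))
  ataf <- which(labs == "ATAF")
  k <- length(policy$techniques)
  n_per <- floor(policy$ataf_fraction_per_technique * length(ataf))
  copies <- with_seed(seed, {
    out <- list()
    for (i in minority)
      for (tech in policy$techniques)
        out[[length(out) + 1L]] <- aug_apply_one(episodes[[i]], tech)
    if (n_per > 0) {
      chosen <- sample(ataf, min(length(ataf), k * n_per))
      for (j in seq_len(k)) {
        block <- chosen[((j - 1L) * n_per + 1L):(j * n_per)]
        for (i in block)
          out[[length(out) + 1L]] <-
            aug_apply_one(episodes[[i]], policy$techniques[j])
      }
    }
    out
  })
  c(episodes, copies)
}
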