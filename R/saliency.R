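# Grad-CAM++ attribution for the 1D residual network, and the
# normalized-average ensemble map.
#
# The attribution target is the activation of the final residual block
# (the last convolutional stage). Because that layer is followed only by
# global average pooling and the dense head, the gradient of a class
# logit with respect to the feature map is exact and cheap to compute in
# closed form. Grad-CAM++ channel weights use the standard
# first/second/third-order gradient ratio with the piecewise-linear
# (exp-free) approximation; the weighted channel sum is ReLU-rectified,
# giving a nonnegative temporal map at feature resolution that is then
# linearly interpolated to the 1280-sample input grid. One temporal map
# is shared across both input channels.

#' Grad-CAM++ saliency map for one episode
#'
#' @param model a trained `resnet1d`.
#' @param episode an `egm_episode`, or a `[1, length, 2]` array.
#' @param class target class label or index; `"auto"` (default) uses the
#'   model's predicted class.
#' @return A `saliency_map`: list with `episode_id`, `class`, `values`
#'   (nonnegative, length 1280), `normalized = FALSE`, plus the model's
#'   predicted class and probability.
#' @export
grad_cam_pp <- function(model, episode, class = "auto") {
  if (inherits(episode, "egm_episode")) {
    X <- array(c(episode$atrial, episode$ventricular), c(1, EGM_LEN, 2))
    eid <- episode$episode_id
  } else {
    X <- episode
    eid <- "input"
  }
  fw <- resnet_forward(model, X, training = FALSE)
  probs <- fw$probs[1, ]
  pred_ix <- which.max(probs)
  cix <- if (identical(class, "auto")) pred_ix else if (is.character(class))
    match(class, model$class_levels) else as.integer(class)
  if (is.na(cix) || cix < 1 || cix > model$n_classes)
    stop("class index out of range")
  A <- fw$feat[1, , ]                       # [L', C'] final conv features
  Lf <- nrow(A)
  # closed-form gradient of the class logit w.r.t. A (head-only backprop)
  z1 <- colMeans(A)
  pre <- as.numeric(z1 %*% model$params$fc1.W) + model$params$fc1.b
  mask <- pre > 0
  dh <- model$params$fc2.W[, cix] * mask
  dz1 <- as.numeric(model$params$fc1.W %*% dh)
  g <- dz1 / Lf                             # time-constant per channel
  # Grad-CAM++ channel weights
  Asum <- colSums(A)
  denom <- 2 * g^2 + Asum * g^3
  alpha <- ifelse(abs(denom) > 1e-12, g^2 / denom, 0)
  w <- Lf * alpha * pmax(g, 0)
  map_lo <- pmax(as.numeric(A %*% w), 0)
  values <- stats::approx(seq_len(Lf), map_lo,
                          n = model$spec$input_length)$y
  structure(list(episode_id = eid,
                 class = model$class_levels[cix],
                 predicted = model$class_levels[pred_ix],
                 probability = unname(probs[pred_ix]),
                 values = values, normalized = FALSE),
            class = "saliency_map")
}

#' Min-max normalize a saliency map
#'
#' Maps values to `[0, 1]` with max 1 whenever any value is positive; a
#' constant map (max = min) normalizes to all zeros by convention.
#'
#' @param map a `saliency_map`.
#' @return The normalized map (`normalized = TRUE`).
#' @export
normalize_map <- function(map) {
  v <- map$values
  rng <- range(v)
  map$values <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else v * 0
  map$normalized <- TRUE
  map
}

#' Ensemble saliency map
#'
#' Min-max normalizes each member map, then averages element-wise. An
#' ensemble of one member equals that member's normalized map.
#'
#' @param maps list of `saliency_map`s sharing episode and class.
#' @return A `saliency_map` with provenance `"ensemble"`.
#' @export
ensemble_map <- function(maps) {
  stopifnot(length(maps) >= 1)
  lens <- vapply(maps, function(m) length(m$values), 0L)
  if (length(unique(lens)) != 1) stop("saliency map length mismatch")
  normed <- lapply(maps, normalize_map)
  out <- normed[[1]]
  out$values <- rowMeans(vapply(normed, `[[`, numeric(lens[1]), "values"))
  out$provenance <- "ensemble"
  out
}

#' Render an episode with its saliency map
#'
#' Draws the atrial and ventricular traces stacked, with the saliency map
#' as background shading (darker = more important), titled with the
#' predicted class and probability, and writes an image file.
#'
#' @param episode an `egm_episode`.
#' @param map a `saliency_map` for that episode.
#' @param file output path (extension selects the device, e.g. `.png`).
#' @param width,height figure size in inches.
#' @return `file`, invisibly.
#' @export
render_saliency <- function(episode, map, file, width = 9, height = 4) {
  m <- normalize_map(map)
  t_s <- (seq_len(EGM_LEN) - 1) / EGM_FS
  traces <- data.frame(
    t = rep(t_s, 2),
    value = c(episode$atrial, episode$ventricular),
    channel = rep(c("A-EGM", "V-EGM"), each = EGM_LEN)
  )
  shade <- data.frame(t = rep(t_s, 2), alpha = rep(m$values, 2),
                      channel = rep(c("A-EGM", "V-EGM"), each = EGM_LEN))
  ttl <- sprintf("%s  |  predicted %s (p = %.2f), map class %s",
                 episode$episode_id, map$predicted, map$probability,
                 map$class)
  p <- ggplot2::ggplot() +
    ggplot2::geom_tile(data = shade,
                       ggplot2::aes(x = t, y = 0, alpha = alpha),
                       height = Inf, fill = "firebrick", width = 1 / EGM_FS) +
    ggplot2::scale_alpha_identity() +
    ggplot2::geom_line(data = traces,
                       ggplot2::aes(x = t, y = value),
                       linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, ncol = 1) +
    ggplot2::labs(x = "time (s)", y = "normalized amplitude",
                  title = ttl) +
    ggplot2::theme_minimal(base_size = 9)
  ggplot2::ggsave(file, p, width = width, height = height, dpi = 110)
  invisible(file)
}

#' Saliency map values as a tidy table
#'
#' @param map a `saliency_map`.
#' @return data.frame: `episode_id`, `sample_index` (0-based), `value`.
#' @export
saliency_table <- function(map) {
  data.frame(episode_id = map$episode_id,
             sample_index = seq_along(map$values) - 1L,
             value = map$values, stringsAsFactors = FALSE)
}
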