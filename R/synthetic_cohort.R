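#' Simulation configuration for synthetic multi-center EGM cohorts
#'
#' Defines the study conditions the generator emulates: a handful of
#' centers with center-specific waveform morphology (the sampling bias the
#' ensemble is meant to absorb), heavy class imbalance with AT/AF as the
#' modal class, long-tailed per-patient episode counts (median 6 AT/AF
#' episodes among patients who have any), a pool of sinus-rhythm episodes
#' from dedicated patients for pretraining, and a small fraction of
#' episodes without a ventricular channel.
#'
#' Episode counts per patient are `1 + NegBin(size, mu)`; the defaults
#' (`size = 1.1`, `mu = 10`) put the median AT/AF burden at six episodes
#' per patient under the default class mixture. `hard_mode` narrows the
#' amplitude/frequency gaps between classes for robustness experiments.
#'
#' @param seed integer root seed; every stochastic draw descends from it.
#' @param centers named integer vector: AHRE patients per center.
#' @param class_mixture probabilities over `ATAF`, `NOISE`, `FFO`; must sum
#'   to 1 with `ATAF` modal.
#' @param episodes_per_patient list with `size`, `mu` (negative binomial) —
#'   per-patient AHRE episode counts are `1 + rnbinom(size, mu)`.
#' @param sinus_patients_frac dedicated sinus-rhythm patients per center,
#'   as a fraction of that center's AHRE patients.
#' @param sinus_mu mean extra sinus episodes per sinus patient (Poisson,
#'   shifted by 1).
#' @param no_ventricular_frac fraction of non-FFO episodes generated
#'   without a ventricular channel.
#' @param hard_mode logical; narrows class separability.
#' @return A `sim_config` list with all waveform parameter ranges
#'   (amplitudes, rates in bpm, kernel widths in ms, noise band in Hz).
#' @export
simulation_config <- function(seed = 1L,
                              centers = c(center_A = 40L, center_B = 25L,
                                          center_C = 25L, center_D = 18L,
                                          center_E = 12L),
                              class_mixture = c(ATAF = 0.70, NOISE = 0.22,
                                                FFO = 0.08),
                              episodes_per_patient = list(size = 1.1,
                                                          mu = 10),
                              sinus_patients_frac = 0.4,
                              sinus_mu = 12,
                              no_ventricular_frac = 0.05,
                              hard_mode = FALSE) {
  stopifnot(abs(sum(class_mixture) - 1) < 1e-8,
            names(which.max(class_mixture)) == "ATAF",
            all(centers >= 1))
  structure(list(
    seed = as.integer(seed),
    fs = EGM_FS, duration_s = 10,
    centers = centers,
    class_mixture = class_mixture[ahre_classes()],
    episodes_per_patient = episodes_per_patient,
    sinus_patients_frac = sinus_patients_frac,
    sinus_mu = sinus_mu,
    no_ventricular_frac = no_ventricular_frac,
    hard_mode = isTRUE(hard_mode),
    # waveform parameter ranges (stand-ins; no published waveform stats)
    sinus_bpm = c(50, 90),
    av_delay_ms = c(120, 200),
    ataf_bpm = if (hard_mode) c(140, 240) else c(180, 350),
    af_amp = c(0.3, 0.7),
    conduction_prob = 0.35,
    noise_band_hz = c(30, 60),
    noise_burst_s = c(1, 3),
    noise_bursts = 1:3,
    noise_amp = if (hard_mode) 0.45 else 0.9,
    ffo_lag_ms = c(0, 80),
    ffo_amp_frac = c(0.2, 0.6),
    spike_width_ms = c(8, 20),
    baseline_sd = if (hard_mode) 0.05 else 0.02,
    # per-center morphology jitter ranges
    center_amp_range = c(0.8, 1.25),
    center_width_factor = c(0.85, 1.2),
    center_noise_hz = c(35, 55)
  ), class = "sim_config")
}

# biphasic spike kernel: first derivative of a Gaussian, peak |amp| = 1;
# widths of 8-20 ms give 2-6 sample deflections at 128 Hz, matching the
# sharp biphasic look of near-field EGM spikes
spike_kernel <- function(width_ms, fs = EGM_FS) {
  sigma <- width_ms / 2000
  t <- seq(-2.5 * sigma, 2.5 * sigma, by = 1 / fs)
  k <- -t * exp(-t^2 / (2 * sigma^2))
  m <- max(abs(k))
  if (m == 0) return(1)               # degenerate sub-sample width
  k / m
}

# place kernel copies at event times (seconds) on a zero baseline
render_spikes <- function(times_s, amps, width_ms, n = EGM_LEN,
                          fs = EGM_FS) {
  x <- numeric(n)
  if (!length(times_s)) return(x)
  k <- spike_kernel(width_ms, fs)
  half <- (length(k) - 1L) %/% 2L
  centers <- round(times_s * fs) + 1L      # 1-based sample index
  for (i in seq_along(centers)) {
    lo <- centers[i] - half
    s0 <- max(1L, 1L - lo + 1L)
    s1 <- min(length(k), n - lo + 1L)
    if (s0 > s1) next
    dst <- lo + (s0:s1) - 1L
    x[dst] <- x[dst] + amps[i] * k[s0:s1]
  }
  x
}

# band-limited noise via FFT masking, unit max amplitude
band_noise <- function(n, band_hz, fs = EGM_FS) {
  z <- stats::rnorm(n)
  f <- stats::fft(z)
  freq <- (seq_len(n) - 1) * fs / n
  freq <- pmin(freq, fs - freq)                 # two-sided
  f[freq < band_hz[1] | freq > band_hz[2]] <- 0
  x <- Re(stats::fft(f, inverse = TRUE)) / n
  x / max(abs(x))
}

draw_center_morphology <- function(config) {
  list(
    amp = stats::runif(1, config$center_amp_range[1],
                       config$center_amp_range[2]),
    width_factor = stats::runif(1, config$center_width_factor[1],
                                config$center_width_factor[2]),
    noise_hz = stats::runif(1, config$center_noise_hz[1],
                            config$center_noise_hz[2])
  )
}

#' Simulate one episode
#'
#' Generates a preprocessed-format episode by class mechanism, using the
#' current RNG state:
#' \describe{
#'   \item{SINUS}{regular atrial activations at 50–90 bpm (biphasic
#'     Gaussian-derivative spikes), each conducted to a ventricular
#'     activation after a 120–200 ms AV delay; AS and Vs/Vp markers.}
#'   \item{ATAF}{atrial rate 180–350 bpm. AF mode: i.i.d. uniform cycle
#'     lengths and irregular low-amplitude fibrillatory deflections; AT
#'     mode: fast regular tachycardia. Ventricular response is a thinned,
#'     jittered, refractory-limited subsample of atrial events
#'     ("irregularly irregular"); TA/AS markers.}
#'   \item{NOISE}{an underlying sinus-like rhythm plus 1–3 bursts of
#'     band-limited 30–60 Hz contamination on the atrial channel with
#'     spurious AS/TA markers inside bursts.}
#'   \item{FFO}{sinus rhythm plus an attenuated, broader far-field R-wave
#'     deflection on the atrial channel time-locked to each ventricular
#'     activation (lag 0–80 ms, amplitude 20–60% of the atrial spike),
#'     yielding double-counted atrial markers.}
#' }
#' A ground-truth event log (activation times, far-field deflections,
#' burst windows) is attached as the `events` attribute and is consistent
#' with the marker train.
#'
#' @param label one of `egm_labels()`.
#' @param config a [simulation_config()].
#' @param morph per-center morphology (internal); default draws a fresh one.
#' @param episode_id,patient_id,center_id identity fields.
#' @param has_ventricular logical; `FALSE` zeroes the ventricular channel
#'   (the underlying ventricular event times are still logged).
#' @return An `egm_episode` with an `events` attribute.
#' @export
simulate_episode <- function(label, config = simulation_config(),
                             morph = NULL,
                             episode_id = "sim", patient_id = "p",
                             center_id = "c", has_ventricular = TRUE) {
  if (!label %in% egm_labels()) stop("unknown label: ", label)
  if (is.null(morph)) morph <- draw_center_morphology(config)
  dur <- config$duration_s
  width <- stats::runif(1, config$spike_width_ms[1],
                        config$spike_width_ms[2]) * morph$width_factor
  amp <- morph$amp
  ev <- list()
  add_ev <- function(t, kind) ev[[length(ev) + 1L]] <<-
    data.frame(event_time_s = t, event_kind = kind)

  sinus_rhythm <- function(amp_a = 1, amp_v = 1) {
    bpm <- stats::runif(1, config$sinus_bpm[1], config$sinus_bpm[2])
    period <- 60 / bpm
    t_a <- seq(stats::runif(1, 0, period), dur - 0.05, by = period)
    t_a <- t_a + stats::rnorm(length(t_a), 0, 0.01)
    t_a <- sort(t_a[t_a >= 0 & t_a <= dur - 1 / EGM_FS])
    av <- stats::runif(1, config$av_delay_ms[1], config$av_delay_ms[2]) / 1000
    t_v <- t_a + av
    t_v <- t_v[t_v <= dur - 1 / EGM_FS]
    a <- render_spikes(t_a, rep(amp_a * amp, length(t_a)), width)
    v <- render_spikes(t_v, rep(amp_v * amp, length(t_v)), width * 1.4)
    list(t_a = t_a, t_v = t_v, a = a, v = v)
  }

  if (label == "SINUS") {
    r <- sinus_rhythm()
    atr <- r$a; vnt <- r$v
    t_a <- r$t_a; t_v <- r$t_v
    m_a <- rep("AS", length(t_a)); m_v <- rep(
      sample(c("Vs", "Vp"), 1, prob = c(0.8, 0.2)), length(t_v))
  } else if (label == "ATAF") {
    af_mode <- stats::runif(1) < 0.6
    cl_range <- 60 / rev(config$ataf_bpm)      # cycle length range, s
    if (af_mode) {
      cls <- stats::runif(80, cl_range[1], cl_range[2])
      t_a <- cumsum(c(stats::runif(1, 0, cl_range[1]), cls))
      t_a <- t_a[t_a <= dur - 1 / EGM_FS]
      amps <- stats::runif(length(t_a), config$af_amp[1], config$af_amp[2])
      wid <- width * stats::runif(1, 0.6, 0.9)
    } else {
      cl <- stats::runif(1, cl_range[1], cl_range[2])
      t_a <- seq(stats::runif(1, 0, cl), dur - 1 / EGM_FS, by = cl)
      t_a <- t_a + stats::rnorm(length(t_a), 0, 0.004)
      t_a <- sort(t_a[t_a >= 0 & t_a <= dur - 1 / EGM_FS])
      amps <- rep(stats::runif(1, 0.7, 0.95), length(t_a))
      wid <- width * 0.8
    }
    atr <- render_spikes(t_a, amps * amp, wid)
    # irregular, slower ventricular response: thinned + refractory
    keep <- stats::runif(length(t_a)) < config$conduction_prob
    t_v <- t_a[keep] + stats::runif(sum(keep), 0.02, 0.08)
    if (length(t_v) > 1) {
      ok <- c(TRUE, diff(t_v) > 0.35)
      while (!all(ok)) { t_v <- t_v[ok]; ok <- c(TRUE, diff(t_v) > 0.35) }
    }
    t_v <- t_v[t_v <= dur - 1 / EGM_FS]
    vnt <- render_spikes(t_v, rep(amp, length(t_v)), width * 1.4)
    m_a <- rep("TA", length(t_a))
    m_a[stats::runif(length(t_a)) < 0.2] <- "AS"
    m_v <- rep("Vs", length(t_v))
  } else if (label == "NOISE") {
    r <- sinus_rhythm(amp_a = 0.8)
    atr <- r$a; vnt <- r$v; t_a <- r$t_a; t_v <- r$t_v
    m_a <- rep("AS", length(t_a)); m_v <- rep("Vs", length(t_v))
    band <- morph$noise_hz + c(-10, 10)
    band <- pmax(pmin(band, config$noise_band_hz[2]),
                 config$noise_band_hz[1])
    n_burst <- sample(config$noise_bursts, 1)
    for (b in seq_len(n_burst)) {
      len <- stats::runif(1, config$noise_burst_s[1], config$noise_burst_s[2])
      start <- stats::runif(1, 0, dur - len)
      i0 <- max(1L, round(start * EGM_FS)); i1 <- min(EGM_LEN,
                                                     round((start + len) * EGM_FS))
      seg <- band_noise(i1 - i0 + 1L, band) * config$noise_amp * amp
      # taper burst edges
      w <- length(seg)
      taper <- pmin(1, pmin(seq_len(w), rev(seq_len(w))) / (0.1 * w))
      atr[i0:i1] <- atr[i0:i1] + seg * taper
      add_ev(start, "noise_burst_start"); add_ev(start + len, "noise_burst_end")
      # spurious atrial markers inside the burst
      n_sp <- stats::rpois(1, 8 * len)
      if (n_sp > 0) {
        t_sp <- stats::runif(n_sp, start, start + len)
        t_a <- c(t_a, t_sp)
        m_a <- c(m_a, sample(c("AS", "TA"), n_sp, replace = TRUE))
      }
    }
  } else { # FFO
    r <- sinus_rhythm()
    t_a <- r$t_a; t_v <- r$t_v
    lag <- stats::runif(1, config$ffo_lag_ms[1], config$ffo_lag_ms[2]) / 1000
    frac <- stats::runif(1, config$ffo_amp_frac[1], config$ffo_amp_frac[2])
    t_ff <- t_v + lag
    t_ff <- t_ff[t_ff <= dur - 1 / EGM_FS]
    atr <- r$a + render_spikes(t_ff, rep(frac * amp, length(t_ff)),
                               width * 2)   # broader far-field R wave
    vnt <- r$v
    for (t in t_ff) add_ev(t, "farfield_deflection")
    m_a <- c(rep("AS", length(t_a)), rep("AS", length(t_ff)))
    t_a <- c(t_a, t_ff)
    m_v <- rep("Vs", length(t_v))
  }

  for (t in sort(t_a)) add_ev(t, "atrial_activation")
  for (t in t_v) add_ev(t, "ventricular_activation")

  atr <- atr + stats::rnorm(EGM_LEN, 0, config$baseline_sd)
  vnt <- vnt + stats::rnorm(EGM_LEN, 0, config$baseline_sd)
  if (!has_ventricular) { vnt <- NULL; m_v <- character(0); t_v <- numeric(0) }

  times <- c(t_a, t_v)
  types <- c(m_a, m_v)
  o <- order(times)
  events <- do.call(rbind, ev)
  events <- events[order(events$event_time_s), , drop = FALSE]
  rownames(events) <- NULL
  preprocess_episode(atr, vnt,
                     marker_times_s = times[o],
                     marker_type_labels = types[o],
                     episode_id = episode_id, patient_id = patient_id,
                     center_id = center_id, label = label,
                     events = events)
}

#' Counts-only patient plan
#'
#' Draws the patient rosters, per-patient episode counts and class
#' assignments of a cohort without rendering any signals. The same
#' substream seeds are used by [simulate_cohort()], so the plan is exactly
#' the roster of the full simulation. Useful for checking the per-patient
#' burden distribution at large n.
#'
#' @param config a [simulation_config()].
#' @return data.frame: `center_id`, `patient_id`, `label`, `episode_id`,
#'   `has_ventricular`.
#' @export
simulate_patient_plan <- function(config = simulation_config()) {
  rows <- list()
  for (center in names(config$centers)) {
    n_pat <- config$centers[[center]]
    for (i in seq_len(n_pat)) {
      pid <- sprintf("%s_p%03d", center, i)
      rows[[length(rows) + 1L]] <- with_seed(
        derive_seed(config$seed, "patient", center, i), {
          n_ep <- 1L + stats::rnbinom(1, size = config$episodes_per_patient$size,
                                      mu = config$episodes_per_patient$mu)
          labs <- sample(ahre_classes(), n_ep, replace = TRUE,
                         prob = config$class_mixture)
          no_v <- stats::runif(n_ep) < config$no_ventricular_frac &
            labs != "FFO"
          data.frame(center_id = center, patient_id = pid, label = labs,
                     episode_id = sprintf("%s_e%03d", pid, seq_len(n_ep)),
                     has_ventricular = !no_v, stringsAsFactors = FALSE)
        })
    }
    n_sin <- ceiling(config$sinus_patients_frac * n_pat)
    for (i in seq_len(n_sin)) {
      pid <- sprintf("%s_s%03d", center, i)
      rows[[length(rows) + 1L]] <- with_seed(
        derive_seed(config$seed, "sinus_patient", center, i), {
          n_ep <- 1L + stats::rpois(1, config$sinus_mu)
          data.frame(center_id = center, patient_id = pid, label = "SINUS",
                     episode_id = sprintf("%s_e%03d", pid, seq_len(n_ep)),
                     has_ventricular = TRUE, stringsAsFactors = FALSE)
        })
    }
  }
  do.call(rbind, rows)
}

#' Simulate a multi-center cohort
#'
#' Generates the full synthetic cohort: per-center patient rosters with
#' long-tailed episode counts, center-level morphology applied consistently
#' to all of a center's patients (center-specific sampling bias), dedicated
#' sinus-rhythm patients for pretraining, and per-episode ground-truth
#' event logs. Fully deterministic under the config seed via hierarchical
#' substreams.
#'
#' @param config a [simulation_config()].
#' @param progress print a line per center.
#' @return An `egm_cohort`; every episode carries an `events` attribute.
#' @export
simulate_cohort <- function(config = simulation_config(), progress = FALSE) {
  plan <- simulate_patient_plan(config)
  if (nrow(plan) == 0) stop("empty simulation plan")
  episodes <- vector("list", nrow(plan))
  for (center in names(config$centers)) {
    if (progress) message("simulating ", center)
    morph <- with_seed(derive_seed(config$seed, "center", center),
                       draw_center_morphology(config))
    idx <- which(plan$center_id == center)
    for (j in idx) {
      # small patient-level morphology jitter around the center's
      pmorph <- with_seed(derive_seed(config$seed, "pmorph",
                                      plan$patient_id[j]), list(
        amp = morph$amp * stats::runif(1, 0.9, 1.1),
        width_factor = morph$width_factor * stats::runif(1, 0.9, 1.1),
        noise_hz = morph$noise_hz
      ))
      episodes[[j]] <- with_seed(
        derive_seed(config$seed, "episode", plan$episode_id[j]),
        simulate_episode(plan$label[j], config, morph = pmorph,
                         episode_id = plan$episode_id[j],
                         patient_id = plan$patient_id[j],
                         center_id = center,
                         has_ventricular = plan$has_ventricular[j]))
    }
  }
  cohort_manifest(episodes)
}
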