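# Synthetic dual-task oddball EEG generator. Emulates the statistical
# structure the downstream analyses assume: a 32-channel 10-20 cap at 250 Hz,
# a 20% oddball stream with 2-2.4 s jittered ISIs, condition-dependent
# centroparietal P300 amplitudes (underload > overload > flow), a
# condition-independent early auditory N1/P2 complex, 1/f sensor noise with a
# shared low-rank spatial component, and stereotyped ocular/cardiac
# artifacts in the continuous record.

#' Simulation configuration
#'
#' Collects every generative parameter of the synthetic oddball session.
#' Amplitudes are single-trial peak values in uV; the per-condition P300
#' amplitudes encode the attentional-resource ordering the analyses probe
#' (largest under mental underload, intermediate under overload, smallest
#' during flow).
#'
#' @param n_subjects Number of simulated participants.
#' @param n_trials_per_condition Oddball trials per workload condition.
#' @param oddball_ratio Fraction of oddball events in the stream.
#' @param isi_range Interstimulus interval bounds in seconds.
#' @param fs Sampling rate in Hz.
#' @param epoch_window Epoch limits in seconds relative to sound onset.
#' @param p300_amplitude Named per-condition P300 peak amplitude (uV).
#' @param p300_latency,p300_width Gaussian P300 template peak time and SD (s).
#' @param noise_slope Exponent of the 1/f sensor-noise power spectrum.
#' @param noise_sd Single-trial noise SD per channel (uV).
#' @param shared_noise_rank,shared_noise_scale Rank and relative amplitude of
#'   the shared low-rank noise component (correlated sensors are what make
#'   covariance shrinkage worthwhile).
#' @param noise_smooth_sigma Spatial scale (radians of great-circle angle)
#'   of the volume-conduction-like correlated brain-noise background.
#' @param noise_white_frac Variance fraction of the spatially white
#'   electrode-noise floor.
#' @param subject_sd SD of the per-subject log-normal P300 amplitude factor.
#' @param blink_rate,ecg_rate Artifact events per minute in the continuous
#'   simulator.
#' @param behavior_means,behavior_sds Named lists (per measure: `score`,
#'   `nasa_tlx`, `fss`, `count_error`) of per-condition means and noise SDs.
#' @param seed Root random seed; all simulator randomness derives from it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_subjects = 13,
                              n_trials_per_condition = 100,
                              oddball_ratio = 0.20,
                              isi_range = c(2.0, 2.4),
                              fs = 250,
                              epoch_window = c(-0.2, 1.0),
                              p300_amplitude = c(underload = 8, overload = 4,
                                                 flow = 1),
                              p300_latency = 0.45,
                              p300_width = 0.1,
                              noise_slope = 1.0,
                              noise_sd = 8,
                              shared_noise_rank = 3,
                              shared_noise_scale = 0.5,
                              noise_smooth_sigma = 0.9,
                              noise_white_frac = 0.1,
                              subject_sd = 0.1,
                              blink_rate = 12,
                              ecg_rate = 70,
                              behavior_means = list(
                                score = c(underload = 0.85, flow = 0.92,
                                          overload = 0.35),
                                nasa_tlx = c(underload = 25, flow = 45,
                                             overload = 70),
                                fss = c(underload = 3.6, flow = 5.5,
                                        overload = 3.9),
                                count_error = c(underload = -0.02,
                                                flow = -0.15,
                                                overload = -0.03)),
                              behavior_sds = list(score = 0.05, nasa_tlx = 8,
                                                  fss = 0.6,
                                                  count_error = 0.07),
                              seed = 20251020) {
  stopifnot(oddball_ratio > 0, oddball_ratio < 1,
            length(isi_range) == 2, isi_range[1] <= isi_range[2],
            all(p300_amplitude >= 0), fs > 0,
            epoch_window[1] < epoch_window[2])
  if (!all(c("underload", "overload", "flow") %in% names(p300_amplitude))) {
    stop("p300_amplitude must name underload, overload and flow")
  }
  structure(as.list(environment()), class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    "<simulation_config> %d subjects, %d oddballs/condition, fs %g Hz\n",
    x$n_subjects, x$n_trials_per_condition, x$fs))
  cat(sprintf("  P300 uV: underload %g / overload %g / flow %g; noise sd %g\n",
              x$p300_amplitude["underload"], x$p300_amplitude["overload"],
              x$p300_amplitude["flow"], x$noise_sd))
  invisible(x)
}

.conditions <- c("underload", "flow", "overload")

#' Derive a deterministic child seed
#'
#' Mixes a root seed with integer offsets (multiplicative hashing), keeping
#' the result inside the 32-bit integer range, so every stochastic stage
#' can get an independent reproducible stream from one root seed.
#'
#' @param seed Root integer seed.
#' @param ... Integer offsets (stage / subject / condition indices).
#' @return An integer seed.
#' @export
derive_seed <- function(seed, ...) {
  offs <- c(...)
  s <- as.double(seed)
  for (i in seq_along(offs)) {
    s <- (s * 69069 + as.double(offs[i]) * 2654435761) %% 2147483647
  }
  as.integer(s)
}

#' Evaluate an expression under a local RNG state
#'
#' Seeds the RNG, evaluates, and restores the caller's random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Generate an oddball event schedule
#'
#' Onsets are cumulative sums of i.i.d. uniform ISIs on `config$isi_range`;
#' the oddball labels are an exact-count permutation: precisely
#' `round(oddball_ratio * n_events)` events are oddballs for every seed.
#'
#' @param n_events Number of auditory events.
#' @param config A [simulation_config()].
#' @param seed Optional seed override (defaults to the config root seed).
#' @return An `event_schedule`: list with `onsets` (s), `labels`
#'   (`"standard"`/`"oddball"`), and `target_frequency_hz` (350/650 Hz tone
#'   pair).
#' @export
generate_event_sequence <- function(n_events, config = simulation_config(),
                                    seed = NULL) {
  if (n_events < 1) stop("n_events must be at least 1")
  seed <- if (is.null(seed)) derive_seed(config$seed, 1) else seed
  with_seed(seed, {
    isis <- stats::runif(n_events, config$isi_range[1], config$isi_range[2])
    onsets <- cumsum(isis)
    n_odd <- round(config$oddball_ratio * n_events)
    labels <- rep("standard", n_events)
    labels[sample.int(n_events, n_odd)] <- "oddball"
    structure(list(onsets = onsets, labels = labels,
                   target_frequency_hz = c(standard = 350, oddball = 650)),
              class = "event_schedule")
  })
}

# Gaussian bump helper
.bump <- function(t, center, width) exp(-(t - center)^2 / (2 * width^2))

# Channel weight vector: gaussian falloff in great-circle angle from the
# normalized centroid of the named channels.
.scalp_pattern <- function(montage, channels, sigma) {
  ctr <- colMeans(montage$positions[channels, , drop = FALSE])
  ctr <- ctr / sqrt(sum(ctr^2))
  ang <- acos(pmin(1, pmax(-1, montage$positions %*% ctr)))
  w <- exp(-as.vector(ang)^2 / (2 * sigma^2))
  names(w) <- montage$labels
  w
}

#' Generative spatial topographies
#'
#' The P300 weight vector peaks over centroparietal sensors (CP1/CP2/Pz);
#' the early auditory N1/P2 weight vector peaks frontocentrally.
#'
#' @param montage An `eeg_montage` (defaults to the shipped 32-channel cap).
#' @return List with unit-peak weight vectors `p300` and `auditory`.
#' @export
generative_topographies <- function(montage = build_standard_montage()) {
  list(p300 = .scalp_pattern(montage, c("CP1", "CP2", "Pz"), 0.55),
       auditory = .scalp_pattern(montage, c("Cz", "FC1", "FC2"), 0.7))
}

# Per-subject multiplicative P300 amplitude factor (log-normal, seeded from
# the root seed only, so it is stable across conditions).
.subject_gain <- function(config, subject) {
  if (config$subject_sd <= 0) return(1)
  with_seed(derive_seed(config$seed, 7, subject),
            exp(stats::rnorm(1, 0, config$subject_sd)))
}

#' Noise-free single-trial ERP template
#'
#' The deterministic part of every simulated oddball trial: a Gaussian P300
#' bump scaled by the condition amplitude and the centroparietal topography,
#' plus a condition-independent auditory N1 (negative, 100 ms) / P2
#' (positive, 200 ms) complex on a frontocentral topography.
#'
#' @param config A [simulation_config()].
#' @param condition One of `"underload"`, `"flow"`, `"overload"`.
#' @param subject Optional subject index; applies the per-subject amplitude
#'   gain. `NULL` gives the group-level template.
#' @param montage Montage defining the channel order.
#' @param oddball If `FALSE`, the P300 bump is omitted (standard tones).
#' @return channels x time matrix (uV); times follow `config$epoch_window`.
#' @export
erp_template <- function(config, condition, subject = NULL,
                         montage = build_standard_montage(),
                         oddball = TRUE) {
  condition <- match.arg(condition, .conditions)
  times <- epoch_times(config)
  topo <- generative_topographies(montage)
  n1 <- -4 * .bump(times, 0.10, 0.025)
  p2 <- 3 * .bump(times, 0.20, 0.035)
  out <- outer(topo$auditory, n1 + p2)
  if (oddball) {
    amp <- unname(config$p300_amplitude[condition])
    if (!is.null(subject)) amp <- amp * .subject_gain(config, subject)
    out <- out + outer(topo$p300,
                       amp * .bump(times, config$p300_latency,
                                   config$p300_width))
  }
  dimnames(out) <- list(montage$labels, NULL)
  out
}

#' Epoch time axis implied by a configuration
#' @param config A [simulation_config()].
#' @return Numeric vector of sample times (half-open window).
#' @export
epoch_times <- function(config) {
  n <- round((config$epoch_window[2] - config$epoch_window[1]) * config$fs)
  config$epoch_window[1] + (seq_len(n) - 1) / config$fs
}

# 1/f-shaped noise: white Gaussian spectrum rescaled by f^(-slope/2),
# DC removed, standardized to unit SD per column. n x p matrix.
.pink_noise <- function(n, p, slope, fs) {
  wh <- matrix(stats::rnorm(n * p), n, p)
  sp <- stats::mvfft(wh)
  freq <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1))) * fs / n
  scale <- c(0, freq[-1]^(-slope / 2))
  x <- Re(stats::mvfft(sp * scale, inverse = TRUE)) / n
  x <- sweep(x, 2, colMeans(x))
  sdx <- apply(x, 2, stats::sd)
  sdx[sdx == 0] <- 1
  sweep(x, 2, sdx, "/")
}

# Full sensor-noise sample for one trial (or continuous block): 1/f brain
# noise made spatially smooth (volume-conduction-like correlations between
# neighbouring sensors), a small spatially white electrode-noise floor, and
# a shared low-rank 1/f component. Per-channel SD is config$noise_sd.
# Returns channels x n.
.sensor_noise <- function(n, montage, config, ops) {
  p <- length(montage$labels)
  smooth_part <- ops$smooth %*%
    t(.pink_noise(n, p, config$noise_slope, config$fs))
  white_part <- t(.pink_noise(n, p, config$noise_slope, config$fs))
  wf <- config$noise_white_frac
  out <- config$noise_sd * (sqrt(1 - wf) * smooth_part +
                              sqrt(wf) * white_part)
  if (config$shared_noise_rank > 0 && config$shared_noise_scale > 0) {
    src <- t(.pink_noise(n, config$shared_noise_rank, config$noise_slope,
                         config$fs))
    out <- out + (ops$mixing %*% src) *
      (config$noise_sd * config$shared_noise_scale)
  }
  out
}

# Noise structure operators, fixed by the root seed (the same correlated
# structure for all subjects and conditions): a unit-power spatial
# smoothing kernel (gaussian in great-circle angle, sigma 0.5 rad) and the
# low-rank mixing matrix. The smoothing width (radians) sets the spatial
# scale of the correlated brain-noise background.
.noise_operators <- function(config, montage) {
  p <- length(montage$labels)
  ang <- channel_angles(montage)
  W <- exp(-ang^2 / (2 * config$noise_smooth_sigma^2))
  W <- W / sqrt(rowSums(W^2))             # unit output variance per channel
  k <- config$shared_noise_rank
  mixing <- if (k == 0) matrix(0, p, 0) else {
    with_seed(derive_seed(config$seed, 3), {
      m <- matrix(stats::rnorm(p * k), p, k)
      sweep(m, 2, sqrt(colSums(m^2)), "/") * sqrt(p / 4)
    })
  }
  list(smooth = W, mixing = mixing)
}

#' Simulate oddball-locked epochs for one subject and condition
#'
#' Each trial is the noise-free [erp_template()] plus 1/f sensor noise.
#' Condition differences live only in the P300 window and topography; the
#' pre-stimulus baseline is zero-mean in expectation.
#'
#' @inheritParams erp_template
#' @param subject Subject index (seeds the noise stream and amplitude gain).
#' @return An [eeg_epochs] object with `labels` set to the condition.
#' @export
simulate_epochs <- function(config, condition, subject = 1,
                            montage = build_standard_montage()) {
  condition <- match.arg(condition, .conditions)
  times <- epoch_times(config)
  tmpl <- erp_template(config, condition, subject = subject,
                       montage = montage)
  p <- length(montage$labels)
  nt <- config$n_trials_per_condition
  ops <- .noise_operators(config, montage)
  data <- array(0, dim = c(nt, p, length(times)))
  ci <- match(condition, .conditions)
  with_seed(derive_seed(config$seed, 11, subject, ci), {
    for (tr in seq_len(nt)) {
      noise <- if (config$noise_sd > 0) {
        .sensor_noise(length(times), montage, config, ops)
      } else 0
      data[tr, , ] <- tmpl + noise
    }
  })
  new_eeg_epochs(data, times, config$fs, montage$labels,
                 labels = rep(condition, nt),
                 history = c("simulated"))
}

#' Simulate a continuous dual-task session block
#'
#' Embeds event-locked templates (oddballs carry the condition's P300,
#' standards only the auditory complex) in continuous 1/f sensor noise, with
#' optional stereotyped blink (frontal) and cardiac (broad, low-amplitude)
#' artifacts, plus EOG/ECG reference traces for artifact-metric testing.
#'
#' @inheritParams simulate_epochs
#' @param n_events Number of auditory events; defaults to the count whose
#'   oddball subset matches `n_trials_per_condition`.
#' @return List with `signal` (channels x samples, uV), `fs`, `times`,
#'   `schedule` (onsets shifted into the recording), `eog`, `ecg`,
#'   `condition`, `subject`, `channels`.
#' @export
simulate_continuous_session <- function(config, condition, subject = 1,
                                        n_events = NULL,
                                        montage = build_standard_montage()) {
  condition <- match.arg(condition, .conditions)
  if (is.null(n_events)) {
    n_events <- round(config$n_trials_per_condition / config$oddball_ratio)
  }
  ci <- match(condition, .conditions)
  schedule <- generate_event_sequence(
    n_events, config, seed = derive_seed(config$seed, 21, subject, ci))
  lead <- 2.0
  schedule$onsets <- schedule$onsets + lead
  fs <- config$fs
  n <- ceiling((max(schedule$onsets) + 2.0) * fs)
  p <- length(montage$labels)
  ops <- .noise_operators(config, montage)
  with_seed(derive_seed(config$seed, 23, subject, ci), {
    signal <- if (config$noise_sd > 0) {
      .sensor_noise(n, montage, config, ops)
    } else matrix(0, p, n)
    tmpl_odd <- erp_template(config, condition, subject = subject,
                             montage = montage, oddball = TRUE)
    tmpl_std <- erp_template(config, condition, subject = subject,
                             montage = montage, oddball = FALSE)
    w0 <- round(config$epoch_window[1] * fs)
    nw <- ncol(tmpl_odd)
    for (e in seq_along(schedule$onsets)) {
      s0 <- round(schedule$onsets[e] * fs) + w0
      idx <- (s0 + 1):(s0 + nw)
      ok <- idx >= 1 & idx <= n
      tm <- if (schedule$labels[e] == "oddball") tmpl_odd else tmpl_std
      signal[, idx[ok]] <- signal[, idx[ok]] + tm[, ok]
    }
    eog <- stats::rnorm(n, 0, 2)
    ecg <- stats::rnorm(n, 0, 1)
    # blinks: ~300 ms squared-sine bump, frontal-dominant topography
    if (config$blink_rate > 0) {
      n_blink <- stats::rpois(1, config$blink_rate * n / fs / 60)
      if (n_blink > 0) {
        btopo <- .scalp_pattern(montage, c("Fp1", "Fp2"), 0.45)
        blen <- round(0.3 * fs)
        bwave <- sin(pi * seq_len(blen) / blen)^2
        for (b in seq_len(n_blink)) {
          s0 <- sample.int(n - blen, 1)
          idx <- s0:(s0 + blen - 1)
          signal[, idx] <- signal[, idx] + outer(btopo, 100 * bwave)
          eog[idx] <- eog[idx] + 300 * bwave
        }
      }
    }
    # cardiac field: sharp biphasic spikes, broad shallow gradient topography
    if (config$ecg_rate > 0) {
      beat <- round(60 / config$ecg_rate * fs)
      qlen <- round(0.06 * fs)
      qt <- seq_len(qlen) / qlen
      qwave <- sin(2 * pi * qt) * exp(-((qt - 0.5) / 0.2)^2)
      ctopo <- 0.5 + 0.5 * (montage$positions[, 2] + 1) / 2
      for (s0 in seq(beat, n - qlen, by = beat)) {
        idx <- s0:(s0 + qlen - 1)
        signal[, idx] <- signal[, idx] + outer(ctopo, 6 * qwave)
        ecg[idx] <- ecg[idx] + 800 * qwave
      }
    }
    list(signal = signal, fs = fs, times = (seq_len(n) - 1) / fs,
         schedule = schedule, eog = eog, ecg = ecg, condition = condition,
         subject = subject, channels = montage$labels)
  })
}

#' Simulate the behavioral/subjective table
#'
#' One row per subject x difficulty x ergonomic position x measure, Gaussian
#' noise around the configured per-condition means with a per-subject random
#' intercept (half the measure's noise SD). Position has no generative
#' effect; it exists so the two-factor analysis has a true-null factor.
#'
#' @param config A [simulation_config()].
#' @param seed Optional seed override.
#' @return Long `data.frame` with columns `subject`, `difficulty`,
#'   `position`, `measure`, `value`.
#' @export
simulate_behavior <- function(config, seed = NULL) {
  seed <- if (is.null(seed)) derive_seed(config$seed, 31) else seed
  positions <- c("sitting", "standing")
  measures <- names(config$behavior_means)
  with_seed(seed, {
    rows <- expand.grid(subject = seq_len(config$n_subjects),
                        difficulty = .conditions, position = positions,
                        measure = measures, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
    val <- numeric(nrow(rows))
    for (ms in measures) {
      sdm <- config$behavior_sds[[ms]]
      intercept <- stats::rnorm(config$n_subjects, 0, sdm * 0.5)
      sel <- rows$measure == ms
      mu <- config$behavior_means[[ms]][rows$difficulty[sel]]
      val[sel] <- mu + intercept[rows$subject[sel]] +
        stats::rnorm(sum(sel), 0, sdm)
    }
    rows$value <- val
    rows
  })
}

#' Simulate a full multi-subject epoch study
#'
#' Convenience wrapper returning, per subject, one [eeg_epochs] object per
#' workload condition (oddball-locked, balanced by design).
#'
#' @inheritParams simulate_epochs
#' @return Nested list `[[subject]][[condition]]` of [eeg_epochs].
#' @export
simulate_study <- function(config, montage = build_standard_montage()) {
  lapply(seq_len(config$n_subjects), function(s) {
    out <- lapply(.conditions, function(cond) {
      simulate_epochs(config, cond, subject = s, montage = montage)
    })
    names(out) <- .conditions
    out
  })
}
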