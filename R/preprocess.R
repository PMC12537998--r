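# Continuous-to-clean-epochs chain: linear detrend, zero-phase Butterworth
# band-pass, epoch segmentation, SD-threshold channel/epoch rejection,
# FASTER-style component metrics, and baseline correction. Stage order
# follows the standard ERP chain: detrend > filter > segment > reject >
# (component hook) > baseline > per-epoch interpolation > CSD.

#' Remove per-channel linear trends
#'
#' @param signal Numeric channels x time matrix.
#' @return Matrix of the same shape with the least-squares line removed from
#'   each row.
#' @export
detrend_linear <- function(signal) {
  signal <- as.matrix(signal)
  n <- ncol(signal)
  if (n < 2) stop("need at least 2 samples to detrend")
  t0 <- seq_len(n) - (n + 1) / 2           # centered time axis
  denom <- sum(t0^2)
  slope <- (signal %*% t0) / denom
  rowm <- rowMeans(signal)
  signal - outer(as.vector(slope), t0) - rowm
}

#' Zero-phase Butterworth band-pass filter
#'
#' Designs a Butterworth band-pass of the given order and applies it
#' forward-backward (`signal::filtfilt`), so the effective magnitude response
#' is the squared single-pass response and phase distortion is zero --
#' preserving ERP latencies.
#'
#' @param x Numeric channels x time matrix (or vector).
#' @param fs Sampling rate (Hz).
#' @param low,high Band edges in Hz (defaults 0.2 and 20).
#' @param order Butterworth design order (default 4).
#' @return Filtered data, same shape as `x`.
#' @export
bandpass_filter <- function(x, fs, low = 0.2, high = 20, order = 4) {
  if (!(low > 0 && low < high && high < fs / 2)) {
    stop("band edges must satisfy 0 < low < high < fs/2")
  }
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, nrow = 1) else as.matrix(x)
  out <- t(apply(xm, 1, function(row) signal::filtfilt(bf, row)))
  if (vec) as.vector(out) else out
}

#' Segment a continuous recording into stimulus-locked epochs
#'
#' Sample windows are half-open: `[round((onset+tmin) fs), round((onset+tmax)
#' fs))`, so a 250 Hz recording cut at \[-0.2, 1.0) yields 300 samples per
#' epoch. Events whose window leaves the recording are dropped with a
#' warning.
#'
#' @param continuous Either the list returned by
#'   [simulate_continuous_session()] or a channels x time matrix (then `fs`
#'   and `channels` must be given).
#' @param events An `event_schedule` (onsets in seconds).
#' @param tmin,tmax Epoch window in seconds relative to onset.
#' @param fs,channels Required when `continuous` is a bare matrix.
#' @return An [eeg_epochs] with per-trial `labels` from the schedule.
#' @export
segment_epochs <- function(continuous, events, tmin = -0.2, tmax = 1.0,
                           fs = NULL, channels = NULL) {
  if (is.list(continuous) && !is.null(continuous$signal)) {
    sig <- continuous$signal
    fs <- continuous$fs
    channels <- continuous$channels
  } else {
    sig <- as.matrix(continuous)
    if (is.null(fs)) stop("fs required for matrix input")
    if (is.null(channels)) channels <- paste0("ch", seq_len(nrow(sig)))
  }
  nwin <- round((tmax - tmin) * fs)
  if (nwin < 1) stop("empty epoch window")
  start <- round((events$onsets + tmin) * fs)          # 0-based
  ok <- start >= 0 & (start + nwin) <= ncol(sig)
  if (!any(ok)) stop("no events fall inside the recording")
  if (any(!ok)) {
    warning(sprintf("dropped %d event(s) outside the recording bounds",
                    sum(!ok)))
  }
  idx <- which(ok)
  data <- array(0, dim = c(length(idx), nrow(sig), nwin))
  for (i in seq_along(idx)) {
    data[i, , ] <- sig[, (start[idx[i]] + 1):(start[idx[i]] + nwin)]
  }
  times <- tmin + (seq_len(nwin) - 1) / fs
  new_eeg_epochs(data, times, fs, channels,
                 labels = events$labels[idx], history = "segmented")
}

#' Flag outlier channels by variance
#'
#' A channel is flagged when the robust z-score (median/MAD) of its
#' log-variance, pooled over trials and time, exceeds `z_thresh`. With zero
#' spread across channels nothing is flagged. Decisions are scale-free
#' (z-scores) and invariant to channel ordering.
#'
#' @param epochs An [eeg_epochs].
#' @param z_thresh Threshold in robust SD units (default 5).
#' @return Character vector of flagged channel labels.
#' @export
reject_channels <- function(epochs, z_thresh = 5) {
  d <- epochs$data
  if (dim(d)[2] < 3) stop("need at least 3 channels")
  v <- apply(d, 2, function(m) stats::var(as.vector(m)))  # pooled per channel
  lv <- log(v + .Machine$double.xmin)
  md <- stats::median(lv)
  s <- stats::mad(lv)
  if (s < 1e-12) return(character(0))
  z <- (lv - md) / s
  epochs$channels[z > z_thresh]
}

#' Reject outlier epochs
#'
#' Epoch metrics are the maximum peak-to-peak amplitude over channels and
#' the mean log-variance; an epoch is removed when the robust z-score of
#' either exceeds `z_thresh`. Trial count is conserved:
#' `n_trials(retained) + length(dropped) == n_trials(input)`.
#'
#' @param epochs An [eeg_epochs].
#' @param z_thresh Threshold in robust SD units (default 3).
#' @return List with `epochs` (retained) and `dropped` (integer indices).
#' @export
reject_epochs <- function(epochs, z_thresh = 3) {
  d <- epochs$data
  nt <- dim(d)[1]
  if (nt < 3) stop("need at least 3 epochs")
  ptp <- apply(d, 1, function(ep) max(apply(ep, 1, function(r)
    diff(range(r)))))
  lv <- apply(d, 1, function(ep) mean(log(apply(ep, 1, stats::var) +
                                            .Machine$double.xmin)))
  rz <- function(x) {
    s <- stats::mad(x)
    if (s < 1e-12) return(rep(0, length(x)))
    (x - stats::median(x)) / s
  }
  bad <- rz(ptp) > z_thresh | rz(lv) > z_thresh
  if (all(bad)) stop("all epochs rejected")
  keep <- which(!bad)
  out <- epochs
  out$data <- d[keep, , , drop = FALSE]
  if (!is.null(out$labels)) out$labels <- out$labels[keep]
  out$history <- c(out$history, "epoch_rejection")
  list(epochs = out, dropped = which(bad))
}

# Rescaled-range Hurst exponent with the Anis-Lloyd small-sample correction:
# slope of log(R/S) - log(E[R/S]) against log(n) over log-spaced window
# sizes, plus 0.5.
.hurst_rs <- function(x, n_scales = 8) {
  n <- length(x)
  sizes <- unique(round(exp(seq(log(16), log(floor(n / 2)),
                                length.out = n_scales))))
  sizes <- sizes[sizes >= 8]
  rs <- ers <- numeric(length(sizes))
  for (i in seq_along(sizes)) {
    w <- sizes[i]
    nseg <- floor(n / w)
    seg <- matrix(x[seq_len(nseg * w)], nrow = w)
    vals <- apply(seg, 2, function(s) {
      s <- s - mean(s)
      cs <- cumsum(s)
      r <- max(cs) - min(cs)
      sd0 <- sqrt(mean(s^2))
      if (sd0 == 0) NA_real_ else r / sd0
    })
    rs[i] <- mean(vals, na.rm = TRUE)
    k <- seq_len(w - 1)
    corr <- if (w <= 340) {
      gamma((w - 1) / 2) / (sqrt(pi) * gamma(w / 2))
    } else 1 / sqrt(w * pi / 2)
    ers[i] <- (w - 0.5) / w * corr * sum(sqrt((w - k) / k))
  }
  ok <- is.finite(rs) & rs > 0
  if (sum(ok) < 2) return(NA_real_)
  unname(0.5 + stats::coef(stats::lm(I(log(rs[ok]) - log(ers[ok])) ~
                                       log(sizes[ok])))[2])
}

#' FASTER-style component artifact metrics
#'
#' Computes, per component: maximum absolute Pearson correlation with the
#' EOG/ECG reference traces (ocular/cardiac artifacts), excess kurtosis
#' (high-amplitude offsets), rescaled-range Hurst exponent (non-biological
#' signals deviate from ~0.7 typical of EEG; white noise sits near 0.5),
#' the high-band/low-band log power gradient (residual white noise), and
#' the median absolute first difference (muscle activity). A component is
#' flagged when any metric's robust z-score across components exceeds
#' `z_thresh`. Constant components get all-zero metrics and a warning.
#'
#' @param components Numeric comps x time matrix (e.g. ICA sources).
#' @param eog,ecg Reference traces, same length as the component rows;
#'   either may be `NULL`.
#' @param fs Sampling rate (Hz), for the power-gradient bands.
#' @param z_thresh Flagging threshold in robust SD units (default 3).
#' @return `data.frame` with columns `component`, `max_ref_cor`,
#'   `kurtosis`, `hurst`, `power_gradient`, `median_gradient`, `flagged`.
#' @export
faster_component_metrics <- function(components, eog = NULL, ecg = NULL,
                                     fs = 250, z_thresh = 3) {
  components <- as.matrix(components)
  n <- ncol(components)
  refs <- Filter(Negate(is.null), list(eog = eog, ecg = ecg))
  if (length(refs) && any(vapply(refs, length, 1L) != n)) {
    stop("reference traces must match component length")
  }
  met <- t(apply(components, 1, function(cp) {
    if (stats::sd(cp) < 1e-14) {
      warning("constant component: metrics set to 0")
      return(c(0, 0, 0, 0, 0))
    }
    mrc <- if (length(refs)) {
      max(vapply(refs, function(r) abs(stats::cor(cp, r)), 1.0))
    } else 0
    m2 <- mean((cp - mean(cp))^2)
    kur <- mean((cp - mean(cp))^4) / m2^2 - 3
    hst <- .hurst_rs(cp)
    ps <- Mod(stats::fft(cp - mean(cp)))^2
    freq <- (seq_along(ps) - 1) * fs / length(ps)
    lowb <- freq >= 1 & freq <= 10
    highb <- freq >= 25 & freq <= fs * 0.45
    pg <- log(mean(ps[highb]) + 1e-300) - log(mean(ps[lowb]) + 1e-300)
    mg <- stats::median(abs(diff(cp))) / stats::sd(cp)
    c(mrc, kur, hst, pg, mg)
  }))
  colnames(met) <- c("max_ref_cor", "kurtosis", "hurst", "power_gradient",
                     "median_gradient")
  rz <- function(x) {
    s <- stats::mad(x, na.rm = TRUE)
    if (!is.finite(s) || s < 1e-12) return(rep(0, length(x)))
    (x - stats::median(x, na.rm = TRUE)) / s
  }
  zmat <- apply(met, 2, rz)
  flagged <- apply(abs(zmat) > z_thresh, 1, any, na.rm = TRUE)
  data.frame(component = seq_len(nrow(met)), met, flagged = flagged,
             row.names = NULL)
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean over the baseline window.
#' Idempotent: applying twice equals applying once.
#'
#' @param epochs An [eeg_epochs].
#' @param window Baseline window in seconds (default the 200 ms before
#'   onset).
#' @return Baseline-corrected [eeg_epochs].
#' @export
baseline_correct <- function(epochs, window = c(-0.2, 0)) {
  sel <- epochs$times >= window[1] - 1e-12 & epochs$times < window[2] - 1e-12
  if (!any(sel)) stop("baseline window outside epoch times")
  bl <- apply(epochs$data[, , sel, drop = FALSE], c(1, 2), mean)
  epochs$data <- sweep(epochs$data, c(1, 2), bl)
  epochs$history <- c(epochs$history, "baseline")
  epochs
}

#' Run the full continuous-to-clean-epochs chain
#'
#' Applies, in order: linear detrend, zero-phase Butterworth band-pass,
#' segmentation, channel rejection (bad channels interpolated per epoch via
#' spherical splines), epoch rejection, baseline correction, and optionally
#' the surface-Laplacian CSD transform. An ICA hook may be supplied: a
#' function `continuous_matrix -> list(unmixing, mixing)`; flagged
#' components (FASTER metrics) are zeroed before back-projection.
#'
#' @param session List from [simulate_continuous_session()] (or compatible).
#' @param montage An `eeg_montage` matching the session channels.
#' @param low,high,order Band-pass settings.
#' @param tmin,tmax Epoch window (s).
#' @param channel_z,epoch_z Rejection thresholds in SD units.
#' @param ica Optional ICA provider (see Details); `NULL` skips the
#'   component stage.
#' @param csd Apply the surface-Laplacian transform at the end?
#' @param only Keep only epochs with this label (default `"oddball"`);
#'   `NULL` keeps all.
#' @return List with `epochs` (clean [eeg_epochs]), and a `log` list of
#'   dropped channels/epochs and applied thresholds.
#' @export
preprocess_session <- function(session, montage, low = 0.2, high = 20,
                               order = 4, tmin = -0.2, tmax = 1.0,
                               channel_z = 5, epoch_z = 3, ica = NULL,
                               csd = TRUE, only = "oddball") {
  sig <- detrend_linear(session$signal)
  sig <- bandpass_filter(sig, session$fs, low = low, high = high,
                         order = order)
  if (!is.null(ica)) {
    dec <- ica(sig)
    comps <- dec$unmixing %*% sig
    met <- faster_component_metrics(comps, eog = session$eog,
                                    ecg = session$ecg, fs = session$fs)
    comps[met$flagged, ] <- 0
    sig <- dec$mixing %*% comps
  } else {
    met <- NULL
  }
  session$signal <- sig
  ep <- segment_epochs(session, session$schedule, tmin = tmin, tmax = tmax)
  if (!is.null(only)) {
    keep <- ep$labels == only
    ep$data <- ep$data[keep, , , drop = FALSE]
    ep$labels <- ep$labels[keep]
  }
  bad <- reject_channels(ep, z_thresh = channel_z)
  rej <- reject_epochs(ep, z_thresh = epoch_z)
  ep <- baseline_correct(rej$epochs)
  if (length(bad)) {
    for (tr in seq_len(n_trials(ep))) {
      ep$data[tr, , ] <- spline_interpolate(ep$data[tr, , ], bad, montage)
    }
    ep$history <- c(ep$history, "interpolated")
  }
  if (csd) ep <- surface_laplacian_csd(ep, montage)
  list(epochs = ep,
       log = list(bad_channels = bad, dropped_epochs = rej$dropped,
                  channel_z = channel_z, epoch_z = epoch_z,
                  band = c(low, high), order = order,
                  component_metrics = met))
}
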