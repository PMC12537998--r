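# The epoched-EEG container shared by the simulator, the preprocessing chain
# and the statistics/decoding stages.

#' Construct an epoched EEG container
#'
#' @param data Numeric trials x channels x time array.
#' @param times Numeric vector of sample times in seconds relative to
#'   stimulus onset; must be strictly increasing with uniform spacing `1/fs`.
#' @param fs Sampling rate in Hz.
#' @param channels Character vector of channel labels (length = dim 2).
#' @param labels Optional per-trial tags (condition or stimulus), length =
#'   dim 1.
#' @param units `"potential"` (uV) or `"csd"` (uV/m^2).
#' @param bad_channels Optional list (per trial) of bad channel labels.
#' @param history Character vector of processing stages already applied.
#' @return An object of class `eeg_epochs`.
#' @export
new_eeg_epochs <- function(data, times, fs, channels, labels = NULL,
                           units = "potential", bad_channels = NULL,
                           history = character()) {
  data <- as.array(data)
  if (length(dim(data)) != 3) stop("data must be trials x channels x time")
  if (dim(data)[2] != length(channels)) {
    stop("channel labels do not match data")
  }
  if (dim(data)[3] != length(times)) stop("times do not match data")
  dt <- diff(times)
  if (length(dt) && (any(dt <= 0) || max(abs(dt - 1 / fs)) > 1e-6 / fs)) {
    stop("times must be strictly increasing with spacing 1/fs")
  }
  if (!is.null(labels) && length(labels) != dim(data)[1]) {
    stop("labels must have one entry per trial")
  }
  units <- match.arg(units, c("potential", "csd"))
  structure(list(data = data, times = as.numeric(times), fs = fs,
                 channels = as.character(channels), labels = labels,
                 units = units, bad_channels = bad_channels,
                 history = history),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<eeg_epochs> %d trials x %d channels x %d samples @ %g Hz [%s]\n",
    d[1], d[2], d[3], x$fs, x$units))
  cat(sprintf("  time %.3f .. %.3f s; stages: %s\n", x$times[1],
              x$times[length(x$times)],
              if (length(x$history)) paste(x$history, collapse = " > ")
              else "(raw)"))
  invisible(x)
}

#' Number of trials in an epoch set
#' @param epochs An `eeg_epochs` object.
#' @return Integer count.
#' @export
n_trials <- function(epochs) dim(epochs$data)[1]

#' Trial-average evoked response
#'
#' @param epochs An `eeg_epochs` object.
#' @param trials Optional trial subset (indices or logical).
#' @return channels x time matrix.
#' @export
evoked <- function(epochs, trials = NULL) {
  d <- epochs$data
  if (!is.null(trials)) d <- d[trials, , , drop = FALSE]
  out <- apply(d, c(2, 3), mean)
  dimnames(out) <- list(epochs$channels, NULL)
  out
}

#' Write / read an epoch set as plain text
#'
#' The on-disk container is a pair of files: `<stem>.json` with the metadata
#' (times, fs, channels, labels, units, history) and `<stem>.tsv` with the
#' flattened data, one row per (trial, channel), one column per sample.
#'
#' @param epochs An `eeg_epochs` object.
#' @param stem Path stem (without extension).
#' @return `read_epochs` returns an `eeg_epochs` object.
#' @export
write_epochs <- function(epochs, stem) {
  meta <- list(times = epochs$times, fs = epochs$fs,
               channels = epochs$channels, labels = epochs$labels,
               units = epochs$units, history = epochs$history,
               n_trials = dim(epochs$data)[1])
  jsonlite::write_json(meta, paste0(stem, ".json"), digits = NA,
                       auto_unbox = TRUE, null = "null")
  d <- dim(epochs$data)
  flat <- matrix(aperm(epochs$data, c(3, 2, 1)), ncol = d[3], byrow = TRUE)
  utils::write.table(flat, paste0(stem, ".tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(stem)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  flat <- as.matrix(utils::read.table(paste0(stem, ".tsv"), sep = "\t",
                                      header = FALSE))
  nt <- meta$n_trials
  p <- length(meta$channels)
  arr <- aperm(array(t(flat), dim = c(length(meta$times), p, nt)),
               c(3, 2, 1))
  new_eeg_epochs(arr, meta$times, meta$fs, meta$channels,
                 labels = meta$labels, units = meta$units,
                 history = as.character(meta$history))
}
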