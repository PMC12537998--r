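# Shared fixtures: tiny montages and epoch sets built in code.

std_montage <- build_standard_montage()

# n channels spread on a polar-angle ring (plus Cz apex for n >= 5)
ring_montage <- function(n, polar = 0.8) {
  az <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  pos <- cbind(sin(polar) * cos(az), sin(polar) * sin(az),
               rep(cos(polar), n))
  new_montage(paste0("ch", seq_len(n)), pos)
}

# single-channel montage (for 1-channel cluster maps)
mono_montage <- new_montage("ch1", matrix(c(0, 0, 1), 1))

toy_epochs <- function(n_trials = 5, n_ch = 4, n_t = 50, fs = 250,
                       labels = NULL, data = NULL, tmin = -0.2) {
  if (is.null(data)) {
    data <- array(stats::rnorm(n_trials * n_ch * n_t), c(n_trials, n_ch, n_t))
  } else {
    n_t <- dim(data)[3]
  }
  new_eeg_epochs(data, tmin + (seq_len(n_t) - 1) / fs, fs,
                 paste0("ch", seq_len(dim(data)[2])), labels = labels)
}

# finite-difference Laplace-Beltrami of an axisymmetric field f(theta) on the
# unit sphere: f'' + cot(theta) f', evaluated at the given polar angles
axisym_laplacian <- function(f, theta, h = 1e-4) {
  d1 <- (f(theta + h) - f(theta - h)) / (2 * h)
  d2 <- (f(theta + h) - 2 * f(theta) + f(theta - h)) / h^2
  d2 + d1 / tan(theta)
}
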