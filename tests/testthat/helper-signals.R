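# Signal-level helpers shared across test files.

# mu-band coupled two-channel epochs from the subject generator
coupled_pair_epochs <- function(coupling, seed, impf = 10, fs = 500,
                                duration = 30, n_epochs = 5) {
  spec <- sim_spec(n_channels = 2, duration = duration, impf = impf,
                   fs = fs, coupling = coupling, suppression = 1,
                   noise_sd = 1, n_events = 0, seed = seed)
  rec <- simulate_subject(spec)$recording
  band <- select_band(impf)
  mu <- bandpass(rec, band$low, band$high)
  ep <- extract_epochs(mu, data.frame(onset = numeric(0),
                                      condition = character(0)), "rest")
  ep$epochs[seq_len(min(n_epochs, length(ep$epochs)))]
}

# amplitude envelope via the analytic signal (FFT Hilbert transform)
envelope <- function(x) {
  n <- length(x)
  h <- rep(0, n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(stats::fft(x) * h, inverse = TRUE) / n)
}

# dominant frequency by Welch averaging of 4-s half-overlapping segments
peak_freq <- function(x, fs, seg_s = 4) {
  len <- seg_s * fs
  starts <- seq(1, length(x) - len + 1, by = len / 2)
  specs <- sapply(starts, function(s) {
    stats::spec.pgram(stats::ts(x[s:(s + len - 1)], frequency = fs),
                      taper = 0.1, plot = FALSE, detrend = TRUE)$spec
  })
  freq <- stats::spec.pgram(stats::ts(x[1:len], frequency = fs),
                            taper = 0.1, plot = FALSE)$freq
  s <- rowMeans(specs)
  top <- s >= max(s) / 2           # centroid of the half-power band
  sum(freq[top] * s[top]) / sum(s[top])
}
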