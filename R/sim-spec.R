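#' Simulation specification for one synthetic subject
#'
#' Describes a multichannel MEG-like recording: narrowband mu-like
#' oscillations centred at the subject's individual mu peak frequency
#' (IMPF) with a controllable pairwise coupling structure, broadband
#' sensor noise, and event-locked mu-amplitude suppression in prehension
#' windows.
#'
#' Channels are generated as jointly Gaussian narrowband processes whose
#' pairwise correlations equal the `coupling` entries (the "shared
#' fraction" of two channels' mu components), i.e. channel k is
#' sqrt(1 - c) * private + sqrt(c) * shared with respect to any channel
#' it is coupled to at level c.
#'
#' @param n_channels number of sensors (default 76, a hemispheric
#'   gradiometer array).
#' @param spacing target inter-sensor pitch in mm (default 13).
#' @param fs sampling rate in Hz (default 500).
#' @param duration recording length in seconds.
#' @param impf individual mu peak frequency in Hz.
#' @param coupling symmetric `n_channels x n_channels` matrix with zero
#'   diagonal and entries in [0, 1): pairwise shared-signal fractions.
#'   A scalar is recycled to all off-diagonal pairs.
#' @param suppression multiplicative mu-amplitude factor in [0, 1]
#'   applied during the 3 s following each prehension onset (1 = no
#'   suppression).
#' @param noise_sd standard deviation of the additive broadband noise,
#'   relative to the unit-variance mu component.
#' @param n_events number of prehension (movement) onsets.
#' @param seed integer seed; identical specs with identical seeds
#'   reproduce recordings exactly.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(n_channels = 76, spacing = 13, fs = 500,
                     duration = 120, impf = 10, coupling = 0,
                     suppression = 0.5, noise_sd = 1,
                     n_events = 6, seed = 1) {
  if (fs <= 0 || duration <= 0 || n_events < 0) {
    stop("`fs` and `duration` must be positive, `n_events` non-negative",
         call. = FALSE)
  }
  if (impf <= 0) stop("`impf` must be positive (Hz)", call. = FALSE)
  if (impf + 1 >= fs / 2) {
    stop("`impf` too close to the Nyquist frequency", call. = FALSE)
  }
  if (length(coupling) == 1L) {
    c0 <- coupling
    coupling <- matrix(c0, n_channels, n_channels)
    diag(coupling) <- 0
  }
  coupling <- as.matrix(coupling)
  if (!isTRUE(all.equal(coupling, t(coupling))) ||
      any(diag(coupling) != 0) ||
      any(coupling < 0) || any(coupling >= 1)) {
    stop("`coupling` must be symmetric with zero diagonal and entries in [0, 1)",
         call. = FALSE)
  }
  if (nrow(coupling) != n_channels) {
    stop("`coupling` dimension must equal `n_channels`", call. = FALSE)
  }
  if (suppression < 0 || suppression > 1) {
    stop("`suppression` must lie in [0, 1]", call. = FALSE)
  }
  if (n_events > 0 && n_events * 4 > duration) {
    stop("`n_events` x 4 s epochs exceed the recording duration",
         call. = FALSE)
  }
  structure(list(n_channels = as.integer(n_channels), spacing = spacing,
                 fs = fs, duration = duration, impf = impf,
                 coupling = coupling, suppression = suppression,
                 noise_sd = noise_sd, n_events = as.integer(n_events),
                 seed = as.integer(seed)),
            class = "sim_spec")
}

#' Build a block-modular coupling matrix
#'
#' Convenience constructor for planted-module coupling structure:
#' `within` coupling inside each of `n_modules` contiguous channel
#' blocks, `between` coupling across blocks.
#'
#' @param n_channels total channels.
#' @param n_modules number of equal-sized modules.
#' @param within,between shared-signal fractions in [0, 1).
#' @return symmetric coupling matrix with zero diagonal.
#' @export
modular_coupling <- function(n_channels, n_modules = 2, within = 0.7,
                             between = 0.3) {
  block <- rep(seq_len(n_modules), length.out = n_channels)
  block <- sort(block)
  cc <- ifelse(outer(block, block, "=="), within, between)
  diag(cc) <- 0
  cc
}
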