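#' Zero-phase Butterworth band-pass filter
#'
#' Applies a forward-reverse (zero-phase) Butterworth band-pass of the
#' given order to every channel of a recording.  The default pass band
#' (0.5-40 Hz, third order) is the wideband pre-processing stage;
#' the same design is reused for the individual mu band.
#'
#' @param rec a `recording`.
#' @param low,high band edges in Hz; must satisfy 0 < low < high < fs/2.
#' @param order filter order (default 3).
#' @return the recording with filtered `data`.
#' @export
bandpass <- function(rec, low = 0.5, high = 40, order = 3L) {
  stopifnot(inherits(rec, "recording"))
  if (!(low > 0 && high > low)) {
    stop("band edges must satisfy 0 < low < high", call. = FALSE)
  }
  if (high >= rec$fs / 2) {
    stop("`high` must be below the Nyquist frequency", call. = FALSE)
  }
  rec$data <- filter_matrix(rec$data, low, high, rec$fs, order)
  rec
}

# forward-reverse Butterworth over the rows of a channels x samples
# matrix; odd-reflection padding (~2 low-frequency periods) suppresses
# the start/end transients of the IIR filter
filter_matrix <- function(x, low, high, fs, order = 3L) {
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  n <- ncol(x)
  np <- min(n - 1L, as.integer(round(2 * fs / low)))
  out <- t(apply(x, 1L, function(ch) {
    padded <- c(2 * ch[1L] - ch[(np + 1L):2L], ch,
                2 * ch[n] - ch[(n - 1L):(n - np)])
    signal::filtfilt(bf, padded)[(np + 1L):(np + n)]
  }))
  dimnames(out) <- dimnames(x)
  out
}

#' Individual mu-band specification
#'
#' The analysis band is centred on the subject's individual mu peak
#' frequency (IMPF): cut-offs at IMPF - 2 Hz and IMPF + 2 Hz, with the
#' low edge clamped at the 0.5 Hz wideband floor (relevant for very
#' young infants whose IMPF can sit below 2.5 Hz).
#'
#' @param impf individual mu peak frequency, Hz (> 0).
#' @param half_width half band width in Hz (default 2).
#' @return object of class `band_spec` with fields `impf`, `low`, `high`.
#' @examples
#' select_band(9.5)  # 7.5 - 11.5 Hz
#' @export
select_band <- function(impf, half_width = 2) {
  if (!is.numeric(impf) || length(impf) != 1L || impf <= 0) {
    stop("`impf` must be a positive scalar (Hz)", call. = FALSE)
  }
  low <- max(0.5, impf - half_width)
  structure(list(impf = impf, low = low, high = impf + half_width),
            class = "band_spec")
}

#' Re-project retained independent components onto the sensors
#'
#' Reconstructs sensor signals from an externally computed ICA
#' decomposition, keeping only the retained components.  Component
#' selection itself (topography / mu-peak inspection) is performed
#' outside this package.
#'
#' @param mixing channels x ICs mixing matrix.
#' @param sources ICs x samples source matrix.
#' @param retained indices of the components to keep.
#' @param fs sampling rate of the reconstructed recording.
#' @param subject_id label for the reconstructed recording.
#' @return a `recording` with `data = mixing[, retained] %*%
#'   sources[retained, ]`.
#' @export
reproject_ics <- function(mixing, sources, retained, fs,
                          subject_id = "reprojected") {
  mixing <- as.matrix(mixing)
  sources <- as.matrix(sources)
  if (ncol(mixing) != nrow(sources)) {
    stop("`mixing` columns must match `sources` rows", call. = FALSE)
  }
  if (length(retained) == 0L) {
    stop("`retained` must name at least one component", call. = FALSE)
  }
  if (any(retained < 1) || any(retained > ncol(mixing)) ||
      any(retained != round(retained))) {
    stop("`retained` contains out-of-range component indices", call. = FALSE)
  }
  data <- mixing[, retained, drop = FALSE] %*%
    sources[retained, , drop = FALSE]
  ids <- rownames(mixing)
  if (is.null(ids)) ids <- sprintf("ch%02d", seq_len(nrow(data)))
  rownames(data) <- ids
  structure(list(subject_id = subject_id, fs = fs, data = data,
                 channel_ids = ids, channel_mask = rep(TRUE, nrow(data))),
            class = "recording")
}

#' Extract 4-s analysis epochs
#'
#' Prehension epochs span `[onset - pre_onset_s, onset - pre_onset_s +
#' epoch_s)` (by default 1 s of anticipatory activity followed by 3 s of
#' movement).  Rest epochs are non-overlapping `epoch_s` windows tiled
#' from the start of the recording in which every sample lies at least
#' `rest_margin_s` away from all movement onsets.  Epochs are always cut
#' from the already-filtered continuous recording; partial windows at
#' the edges are discarded, and a prehension epoch overlapping the
#' previous one is dropped.
#'
#' @param rec a `recording` (already band-limited).
#' @param events event table with `onset` (s) for the movement onsets.
#' @param condition `"rest"` or `"prehension"`.
#' @param epoch_s epoch length in seconds (default 4).
#' @param pre_onset_s anticipatory lead before each onset (default 1).
#' @param rest_margin_s minimal distance of rest samples from any onset
#'   (default 5).
#' @return object of class `epoch_set`: list with `condition`, `epochs`
#'   (list of channels x L matrices, L = epoch_s * fs), `start` (first
#'   sample of each epoch, 1-based), `fs`.
#' @export
extract_epochs <- function(rec, events, condition = c("rest", "prehension"),
                           epoch_s = 4, pre_onset_s = 1,
                           rest_margin_s = 5) {
  stopifnot(inherits(rec, "recording"))
  condition <- match.arg(condition)
  fs <- rec$fs
  len <- round(epoch_s * fs)
  n_samp <- ncol(rec$data)
  onsets <- events$onset[events$condition == "prehension"]

  starts <- integer(0)
  if (condition == "prehension") {
    if (length(onsets) == 0L) {
      stop("no prehension onsets available", call. = FALSE)
    }
    cand <- floor((onsets - pre_onset_s) * fs) + 1L
    cand <- cand[cand >= 1L & cand + len - 1L <= n_samp]
    for (s in cand) { # drop overlaps with an already accepted epoch
      if (length(starts) == 0L || s >= starts[length(starts)] + len) {
        starts <- c(starts, s)
      }
    }
  } else {
    cand <- seq(1L, n_samp - len + 1L, by = len)
    if (length(onsets) > 0L) {
      ok <- vapply(cand, function(s) {
        t0 <- (s - 1) / fs
        t1 <- (s + len - 1) / fs
        all(t0 >= onsets + rest_margin_s | t1 <= onsets - rest_margin_s)
      }, logical(1))
      cand <- cand[ok]
    }
    starts <- cand
  }
  if (length(starts) == 0L) {
    stop(sprintf("no complete %s epoch available", condition),
         call. = FALSE)
  }
  epochs <- lapply(starts, function(s) rec$data[, s:(s + len - 1L),
                                                drop = FALSE])
  structure(list(condition = condition, epochs = epochs,
                 start = starts, fs = fs),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d %s epochs of %d samples\n",
              length(x$epochs), x$condition, ncol(x$epochs[[1]])))
  invisible(x)
}
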