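#' Choose synchronization-likelihood embedding parameters
#'
#' Band-adapted parameter scheme for recurrence-based synchronization
#' estimation on a band-limited epoch: the embedding lag tracks the
#' highest frequency of interest, the embedding dimension covers the
#' slowest cycle, the Theiler window `w1` excludes autocorrelated
#' neighbours, and the outer window `w2` is sized so roughly
#' `90 / p_ref` candidate vectors fall inside the recurrence window
#' (capped by the epoch length).
#'
#' * lag `l = round(fs / (3 * high))`
#' * dimension `m = ceiling(3 * high / low) + 1`
#' * `w1 = 2 * l * (m - 1)`
#' * `w2 = min(w1 + round(90 / p_ref), n_embedded - 1)`
#'
#' @param band a [select_band()] object (or list with `low`, `high`).
#' @param fs sampling rate, Hz.
#' @param epoch_samples epoch length in samples.
#' @param p_ref target recurrence fraction (default 0.01).
#' @return object of class `sl_params` with fields `p_ref`, `l`, `m`,
#'   `w1`, `w2`, `n_embedded`.
#' @examples
#' choose_sl_params(select_band(7.41), fs = 500, epoch_samples = 2000)
#' @export
choose_sl_params <- function(band, fs, epoch_samples, p_ref = 0.01) {
  if (!(p_ref > 0 && p_ref < 1)) {
    stop("`p_ref` must lie in (0, 1)", call. = FALSE)
  }
  low <- band$low
  high <- band$high
  stopifnot(low > 0, high > low)
  l <- max(1L, as.integer(round(fs / (3 * high))))
  m <- as.integer(ceiling(3 * high / low)) + 1L
  if (m < 2L) m <- 2L
  n_emb <- as.integer(epoch_samples) - (m - 1L) * l
  w1 <- 2L * l * (m - 1L)
  if (n_emb <= w1 + 1L) {
    stop("epoch too short for the required embedding window", call. = FALSE)
  }
  w2 <- min(w1 + as.integer(round(90 / p_ref)), n_emb - 1L)
  structure(list(p_ref = p_ref, l = l, m = m, w1 = w1, w2 = w2,
                 n_embedded = n_emb),
            class = "sl_params")
}

#' @export
print.sl_params <- function(x, ...) {
  cat(sprintf("<sl_params> m=%d l=%d w1=%d w2=%d p_ref=%g (%d embedded vectors)\n",
              x$m, x$l, x$w1, x$w2, x$p_ref, x$n_embedded))
  invisible(x)
}

#' Time-delay embedding of a signal
#'
#' @param x numeric vector.
#' @param m embedding dimension (>= 1).
#' @param l lag in samples (>= 1).
#' @return matrix with `length(x) - (m - 1) * l` rows; row i is
#'   `x[i], x[i + l], ..., x[i + (m - 1) l]`.
#' @export
delay_embed <- function(x, m, l) {
  m <- as.integer(m)
  l <- as.integer(l)
  stopifnot(m >= 1L, l >= 1L)
  n_emb <- length(x) - (m - 1L) * l
  if (n_emb < 1L) stop("signal too short for this embedding", call. = FALSE)
  sapply(seq_len(m), function(k) x[seq.int((k - 1L) * l + 1L,
                                           length.out = n_emb)])
}

#' Per-time critical recurrence distances
#'
#' For each embedded vector i, the critical distance is the empirical
#' `p_ref`-quantile of Euclidean distances to the vectors j in the
#' two-sided window `w1 < |i - j| < w2`, so the realised in-window
#' recurrence fraction equals `p_ref` up to `1 / N_w(i)` (ties at the
#' boundary are included).  A constant signal yields all-zero critical
#' distances, with a warning.
#'
#' @param x numeric signal vector.
#' @param params an [choose_sl_params()] object.
#' @return list with `eps` (critical distances), `n_w` (window sizes)
#'   and `hits` (realised in-window recurrence counts).
#' @export
critical_distances <- function(x, params) {
  stopifnot(inherits(params, "sl_params"))
  rs <- recsets_channel(as.numeric(x), params)
  if (all(rs$eps == 0)) {
    warning("degenerate (constant) signal: all critical distances are 0",
            call. = FALSE)
  }
  list(eps = rs$eps, n_w = rs$n_w, hits = diff(rs$off))
}

# per-channel recurrence sets: delay embedding, BLAS Gram matrix,
# windowed quantile + set extraction in compiled code
recsets_channel <- function(x, params) {
  e <- delay_embed(x, params$m, params$l)
  recsets_from_gram(tcrossprod(e), params$w1, params$w2, params$p_ref)
}

#' Pairwise synchronization likelihood of one epoch
#'
#' SL between channels k and q is the time average of the normalised
#' simultaneous-recurrence count
#' `SL_kq = mean_i [ H_i * p_ref * N_w(i) / (n_k(i) * n_q(i)) ]`,
#' clipped to `[0, 1]`, where `H_i` counts window indices recurrent for
#' both channels and `n_k(i)` is channel k's realised recurrence count
#' (`~ p_ref * N_w(i)` by construction of the critical distances).
#' Normalising by the realised counts rather than the nominal
#' `p_ref * N_w(i)` removes the integer-rounding bias of the recurrence
#' quantile: independent signals give SL = `p_ref` in expectation,
#' identical signals give SL near 1.
#'
#' @param epoch channels x samples numeric matrix (band-limited).
#' @param params an [choose_sl_params()] object.
#' @return object of class `sl_matrix`: symmetric channels x channels
#'   matrix in `[0, 1]` with zero diagonal; attribute `n_epochs = 1`.
#' @export
sl_pairwise <- function(epoch, params) {
  stopifnot(inherits(params, "sl_params"))
  epoch <- as.matrix(epoch)
  if (nrow(epoch) < 2L) stop("need at least 2 channels", call. = FALSE)
  if (ncol(epoch) - (params$m - 1L) * params$l <= params$w1 + 1L) {
    stop("epoch too short for the required embedding window", call. = FALSE)
  }
  csd <- apply(epoch, 1L, sd)
  if (any(csd == 0)) {
    warning("degenerate (constant) channel(s) in epoch", call. = FALSE)
  }
  sets <- lapply(seq_len(nrow(epoch)),
                 function(k) recsets_channel(epoch[k, ], params))
  sl <- sl_from_recsets(sets, params$p_ref)
  dimnames(sl) <- list(rownames(epoch), rownames(epoch))
  structure(sl, class = c("sl_matrix", "matrix"), n_epochs = 1L)
}

#' Average SL matrices across epochs
#'
#' @param mats list of `sl_matrix` objects of identical dimension.
#' @return `sl_matrix` holding the element-wise mean, with attribute
#'   `n_epochs` set to the number of matrices averaged.
#' @export
sl_average <- function(mats) {
  if (length(mats) == 0L) stop("no SL matrices to average", call. = FALSE)
  dims <- vapply(mats, function(m) dim(m), integer(2))
  if (any(dims != dims[, 1])) {
    stop("SL matrices have mismatched dimensions", call. = FALSE)
  }
  avg <- Reduce(`+`, lapply(mats, unclass)) / length(mats)
  structure(avg, class = c("sl_matrix", "matrix"),
            n_epochs = length(mats))
}

#' SL connectivity of an epoch set
#'
#' Computes one SL matrix per epoch and averages them into the
#' per-condition average SL matrix.
#'
#' @param eps an [extract_epochs()] `epoch_set`.
#' @param params an [choose_sl_params()] object.
#' @return averaged `sl_matrix`.
#' @export
sl_condition <- function(eps, params) {
  stopifnot(inherits(eps, "epoch_set"))
  sl_average(lapply(eps$epochs, sl_pairwise, params = params))
}
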