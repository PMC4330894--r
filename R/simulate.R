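#' Simulate one synthetic subject
#'
#' Generates a multichannel recording plus its movement-onset event
#' table from a [sim_spec()].  Channels are jointly Gaussian narrowband
#' processes: white noise with the requested inter-channel correlation
#' structure is band-pass filtered at IMPF +/- 1 Hz (third-order
#' forward-reverse Butterworth), scaled to unit variance, multiplied by
#' `suppression` during the 3 s following every prehension onset, and
#' summed with independent broadband sensor noise.
#'
#' @param spec a [sim_spec()].
#' @return list with elements `recording` (class `recording`: fields
#'   `subject_id`, `fs`, `data` channels x samples, `channel_ids`,
#'   `channel_mask`) and `events` (data.frame `onset`, `condition`).
#' @examples
#' sub <- simulate_subject(sim_spec(n_channels = 4, duration = 30,
#'                                  n_events = 2, seed = 7))
#' dim(sub$recording$data)
#' @export
simulate_subject <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  n <- spec$n_channels
  n_samp <- round(spec$fs * spec$duration)

  # correlated white-noise drivers: Cov = coupling with unit diagonal
  cc <- spec$coupling
  diag(cc) <- 1
  ev <- eigen(cc, symmetric = TRUE)
  lmat <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), n)
  z <- matrix(rnorm(n * n_samp), n, n_samp)
  drivers <- lmat %*% z

  lo <- max(0.25, spec$impf - 1)
  hi <- spec$impf + 1
  mu <- filter_matrix(drivers, lo, hi, spec$fs, order = 3L)
  mu <- mu / apply(mu, 1L, sd)

  events <- place_events(spec, n_samp)
  if (nrow(events) > 0L && spec$suppression < 1) {
    for (t0 in events$onset) {
      idx <- seq(floor(t0 * spec$fs) + 1L,
                 min(n_samp, floor((t0 + 3) * spec$fs)))
      mu[, idx] <- mu[, idx] * spec$suppression
    }
  }

  noise <- matrix(rnorm(n * n_samp, sd = spec$noise_sd), n, n_samp)
  data <- mu + noise
  ids <- sprintf("ch%02d", seq_len(n))
  rownames(data) <- ids

  rec <- structure(list(subject_id = paste0("sub", spec$seed),
                        fs = spec$fs, data = data, channel_ids = ids,
                        channel_mask = rep(TRUE, n)),
                   class = "recording")
  list(recording = rec, events = events)
}

# evenly spaced onsets with small deterministic-seeded jitter, kept
# >= 1 s pre-onset and >= 3 s post-onset inside the recording
place_events <- function(spec, n_samp) {
  if (spec$n_events == 0L) {
    return(data.frame(onset = numeric(0), condition = character(0)))
  }
  dur <- n_samp / spec$fs
  lead <- 6          # leaves room for a leading rest window
  tail_t <- dur - 4  # room for the 3 s post-onset segment + slack
  if (tail_t <= lead) {
    stop("recording too short to place prehension events", call. = FALSE)
  }
  if (spec$n_events > 1 && (tail_t - lead) / (spec$n_events - 1) <= 4.6) {
    stop("prehension onsets too dense for 4-s epochs", call. = FALSE)
  }
  slots <- seq(lead, tail_t, length.out = spec$n_events)
  jit <- runif(spec$n_events, -0.3, 0.3)
  onsets <- sort(slots + jit)
  data.frame(onset = onsets,
             condition = rep("prehension", spec$n_events))
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %s: %d channels x %d samples @ %g Hz\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$fs))
  invisible(x)
}

#' Simulate a cohort of synthetic subjects
#'
#' @param specs list of per-subject entries, each a list with fields
#'   `subject_id` (unique label), `group`, `age` (months), and `spec`
#'   (a [sim_spec()] with its own seed).
#' @return list of subjects, each a list with `meta` (subject_id, group,
#'   age, impf, seed), `recording` and `events`.
#' @export
simulate_cohort <- function(specs) {
  if (length(specs) == 0L) stop("empty cohort specification", call. = FALSE)
  ids <- vapply(specs, function(s) s$subject_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate subject_id", call. = FALSE)
  lapply(specs, function(s) {
    sim <- simulate_subject(s$spec)
    sim$recording$subject_id <- s$subject_id
    list(meta = list(subject_id = s$subject_id, group = s$group,
                     age = s$age, impf = s$spec$impf,
                     seed = s$spec$seed),
         recording = sim$recording, events = sim$events)
  })
}
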