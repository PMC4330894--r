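make_rec <- function(data, fs = 500) {
  structure(list(subject_id = "t", fs = fs, data = data,
                 channel_ids = rownames(data),
                 channel_mask = rep(TRUE, nrow(data))),
            class = "recording")
}

test_that("wideband filter passes 20 Hz, rejects 60 Hz and DC", {
  fs <- 500
  t <- seq(0, 10, by = 1 / fs)[-1]
  mid <- seq(fs, length(t) - fs) # avoid edge transients
  s20 <- sin(2 * pi * 20 * t)
  out <- bandpass(make_rec(rbind(s20)), 0.5, 40)$data[1, ]
  gain <- sqrt(mean(out[mid]^2) / mean(s20[mid]^2))
  expect_gte(gain, 0.95)
  expect_lte(gain, 1.0)
  lag <- which.max(ccf(out[mid], s20[mid], lag.max = 10,
                       plot = FALSE)$acf) - 11
  expect_equal(lag, 0)

  s60 <- sin(2 * pi * 60 * t)
  out60 <- bandpass(make_rec(rbind(s60)), 0.5, 40)$data[1, ]
  expect_lt(sqrt(mean(out60[mid]^2)), 0.1 * sqrt(mean(s60^2)))

  dc <- rep(5, length(t))
  outdc <- bandpass(make_rec(rbind(dc)), 0.5, 40)$data[1, ]
  expect_lt(sqrt(mean(outdc[mid]^2)), 1e-3 * 5)
})

test_that("filtering is idempotent on in-band content", {
  fs <- 500
  t <- seq(0, 10, by = 1 / fs)[-1]
  mid <- seq(fs, length(t) - fs)
  x <- sin(2 * pi * 10 * t) + 0.5 * sin(2 * pi * 25 * t)
  once <- bandpass(make_rec(rbind(x)), 0.5, 40)$data[1, ]
  twice <- bandpass(make_rec(rbind(once)), 0.5, 40)$data[1, ]
  rms1 <- sqrt(mean(once[mid]^2))
  rms2 <- sqrt(mean(twice[mid]^2))
  expect_lt(abs(rms2 - rms1) / rms1, 0.05)
})

test_that("band edges are validated against Nyquist", {
  rec <- make_rec(matrix(rnorm(1000), 1), fs = 100)
  expect_error(bandpass(rec, 0.5, 60), "Nyquist")
  expect_error(bandpass(rec, 10, 5), "low < high")
})

test_that("the individual mu band is IMPF +/- 2 Hz with a 0.5 Hz floor", {
  b <- select_band(9.5)
  expect_equal(c(b$low, b$high), c(7.5, 11.5))
  b <- select_band(4.46)
  expect_equal(c(b$low, b$high), c(2.46, 6.46))
  b <- select_band(2.0)
  expect_equal(c(b$low, b$high), c(0.5, 4.0))
  expect_error(select_band(-1), "positive")
})

test_that("IC re-projection reconstructs and bounds rank", {
  set.seed(5)
  mixing <- matrix(rnorm(10 * 6), 10, 6)
  sources <- matrix(rnorm(6 * 200), 6, 200)
  full <- reproject_ics(mixing, sources, 1:6, fs = 500)
  expect_equal(full$data, mixing %*% sources, ignore_attr = TRUE)
  sub <- reproject_ics(mixing, sources, c(1, 3, 5), fs = 500)
  expect_lte(qr(sub$data)$rank, 3)
  expect_error(reproject_ics(mixing, sources, integer(0)), "at least one")
  expect_error(reproject_ics(mixing, sources, c(1, 9)), "out-of-range")
})

test_that("prehension epochs start 1 s before onset and span 4 s", {
  rec <- make_rec(matrix(seq_len(2 * 15000), nrow = 2, byrow = TRUE))
  ev <- data.frame(onset = 10, condition = "prehension")
  ep <- extract_epochs(rec, ev, "prehension")
  expect_length(ep$epochs, 1)
  expect_equal(ep$start, 4501)                     # sample index of t = 9 s
  expect_equal(ncol(ep$epochs[[1]]), 2000)
  expect_equal(ep$epochs[[1]][1, 1], 4501)         # data are sample indices
})

test_that("rest epochs respect the onset margin and tile the record", {
  rec <- make_rec(matrix(rnorm(2 * 150000), nrow = 2))
  no_ev <- data.frame(onset = numeric(0), condition = character(0))
  ep <- extract_epochs(rec, no_ev, "rest")
  expect_length(ep$epochs, 75)                     # 300 s / 4 s

  dense <- data.frame(onset = seq(6, 294, by = 6),
                      condition = "prehension")
  expect_error(extract_epochs(rec, dense, "rest", rest_margin_s = 5),
               "no complete rest epoch")
})

test_that("epoch bookkeeping is disjoint and onset-mapped", {
  set.seed(7)
  sub <- simulate_subject(sim_spec(n_channels = 2, duration = 90,
                                   n_events = 5, seed = 13))
  for (cond in c("rest", "prehension")) {
    ep <- extract_epochs(sub$recording, sub$events, cond)
    idx <- unlist(lapply(ep$start, function(s) s:(s + 1999)))
    expect_false(anyDuplicated(idx) > 0)
  }
  ep <- extract_epochs(sub$recording, sub$events, "prehension")
  onset_samples <- floor((sub$events$onset - 1) * 500) + 1
  expect_true(all(ep$start %in% onset_samples))
  expect_equal(length(ep$start), length(unique(ep$start)))
})
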