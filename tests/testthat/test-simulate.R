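test_that("recordings have fs x duration samples and are finite", {
  sub <- simulate_subject(sim_spec(n_channels = 3, duration = 20,
                                   n_events = 2, seed = 1))
  expect_equal(ncol(sub$recording$data), 500 * 20)
  expect_equal(nrow(sub$recording$data), 3)
  expect_true(all(is.finite(sub$recording$data)))
})

test_that("identical spec and seed reproduce the recording exactly", {
  spec <- sim_spec(n_channels = 4, duration = 15, n_events = 2, seed = 42)
  a <- simulate_subject(spec)
  b <- simulate_subject(spec)
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(a$events, b$events)
})

test_that("the oscillation peaks at the requested mu frequency", {
  for (impf in c(5, 8, 10.32)) {
    sub <- simulate_subject(sim_spec(n_channels = 1, duration = 90,
                                     impf = impf, coupling = matrix(0, 1, 1),
                                     suppression = 1, n_events = 0,
                                     seed = 3))
    expect_lt(abs(peak_freq(sub$recording$data[1, ], 500) - impf), 0.5)
  }
})

test_that("event onsets are increasing and epoch-compatible", {
  sub <- simulate_subject(sim_spec(n_channels = 2, duration = 60,
                                   n_events = 5, seed = 9))
  on <- sub$events$onset
  expect_true(all(diff(on) > 0))
  expect_true(all(on >= 1))       # room for the 1 s pre-onset segment
  expect_true(all(on + 3 <= 60))  # room for the 3 s post-onset segment
  expect_error(sim_spec(duration = 10, n_events = 5),
               "exceed the recording duration")
})

test_that("coupling raises the mu-band envelope correlation", {
  n_better <- 0L
  for (s in 1:10) {
    cors <- vapply(c(0, 0.7), function(cc) {
      eps <- coupled_pair_epochs(cc, seed = 1000 + s, n_epochs = 3)
      mean(vapply(eps, function(e) {
        cor(envelope(e[1, ]), envelope(e[2, ]))
      }, numeric(1)))
    }, numeric(1))
    n_better <- n_better + (cors[2] > cors[1])
  }
  expect_equal(n_better, 10L)
})

test_that("prehension windows carry suppressed mu-band variance", {
  for (supp in c(0.3, 0.5)) {
    spec <- sim_spec(n_channels = 2, duration = 120, impf = 10,
                     coupling = 0, suppression = supp, noise_sd = 0.3,
                     n_events = 6, seed = 11)
    sub <- simulate_subject(spec)
    mu <- bandpass(sub$recording, 8, 12)
    fs <- 500
    on <- sub$events$onset
    supp_idx <- unlist(lapply(on, function(t) {
      (floor(t * fs) + 251):(floor((t + 3) * fs) - 250) # avoid edges
    }))
    blocked <- unlist(lapply(on, function(t) {
      max(1, floor((t - 5) * fs)):min(ncol(mu$data), floor((t + 8) * fs))
    }))
    rest_idx <- setdiff(seq_len(ncol(mu$data)), blocked)
    ratio <- var(mu$data[1, supp_idx]) / var(mu$data[1, rest_idx])
    expect_lte(ratio, supp^2 + 0.1)
  }
})

test_that("cohorts carry one subject per spec with faithful metadata", {
  impfs <- c(4.46, 7.41, 8.71, 8.50, 10.32)
  specs <- list()
  k <- 0L
  for (g in seq_along(impfs)) {
    for (j in 1:6) {
      k <- k + 1L
      specs[[k]] <- list(subject_id = sprintf("g%d_s%d", g, j),
                         group = paste0("G", g), age = 10 * g,
                         spec = sim_spec(n_channels = 2, duration = 10,
                                         impf = impfs[g], n_events = 0,
                                         seed = k))
    }
  }
  cohort <- simulate_cohort(specs)
  expect_length(cohort, 30)
  got_impf <- vapply(cohort, function(s) s$meta$impf, numeric(1))
  expect_equal(unique(got_impf), impfs)
  expect_error(simulate_cohort(list()), "empty")
  specs[[2]]$subject_id <- specs[[1]]$subject_id
  expect_error(simulate_cohort(specs), "duplicate")
})
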