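complete_graph <- function(n, w = 1) {
  m <- matrix(w, n, n)
  diag(m) <- 0
  m
}

star_graph <- function(n) {
  m <- matrix(0, n, n)
  m[1, 2:n] <- m[2:n, 1] <- 1
  m
}

test_that("canonical graphs hit their closed-form measures", {
  g <- as_weighted_graph(complete_graph(6))
  d <- shortest_path_matrix(g)
  expect_equal(clustering_coefficient(g), 1)
  expect_equal(local_efficiency(g), 1)
  expect_equal(char_path_length(d)$L, 1)
  expect_equal(global_efficiency(d), 1)

  s <- as_weighted_graph(star_graph(6))
  expect_equal(clustering_coefficient(s), 0)
  expect_equal(local_efficiency(s), 0)

  two <- as_weighted_graph(matrix(c(0, 0.5, 0.5, 0), 2, 2))
  expect_equal(shortest_path_matrix(two)[1, 2], 2)

  chain <- matrix(0, 3, 3)
  chain[1, 2] <- chain[2, 3] <- 1
  chain <- chain + t(chain)
  dc <- shortest_path_matrix(as_weighted_graph(chain))
  expect_equal(dc[1, 3], 2)
  expect_equal(char_path_length(dc)$L, 4 / 3)

  # two disjoint unit-weight edges: 4 finite of 12 ordered pairs
  pairs <- matrix(0, 4, 4)
  pairs[1, 2] <- pairs[3, 4] <- 1
  pairs <- pairs + t(pairs)
  dp <- shortest_path_matrix(as_weighted_graph(pairs))
  pl <- char_path_length(dp)
  expect_equal(pl$L, 1)
  expect_equal(pl$disconnected_pair_fraction, 2 / 3)
  expect_equal(global_efficiency(dp), 4 / 12)
})

test_that("all four measures match brute-force oracles on random graphs", {
  set.seed(10)
  for (rep in 1:50) {
    n <- sample(4:8, 1)
    w <- random_weighted_graph(n, density = runif(1, 0.3, 0.9))
    if (all(w == 0)) next
    g <- as_weighted_graph(w)
    d <- shortest_path_matrix(g)
    expect_equal(clustering_coefficient(g), oracle_clustering(w),
                 tolerance = 1e-9)
    expect_equal(unname(d), oracle_distances(w), tolerance = 1e-9)
    if (any(is.finite(d[row(d) != col(d)]))) {
      expect_equal(char_path_length(d)$L, oracle_char_path(w),
                   tolerance = 1e-9)
    }
    expect_equal(global_efficiency(d), oracle_global_eff(w),
                 tolerance = 1e-9)
    expect_equal(local_efficiency(g), oracle_local_eff(w),
                 tolerance = 1e-9)
  }
})

test_that("weight normalization preserves order and rescales the maximum", {
  set.seed(11)
  w <- random_weighted_graph(8, 0.7)
  g <- normalize_weights(w)
  expect_equal(max(g$W), 1)
  ut <- upper.tri(w)
  expect_equal(order(w[ut]), order(g$W[ut]))
  single <- matrix(c(0, 0.8, 0.8, 0), 2, 2)
  gs <- normalize_weights(single)
  expect_equal(sum(gs$W == 1), 2)
  expect_error(normalize_weights(matrix(0, 3, 3)), "empty network")
})

test_that("C and E_loc are exactly scale-invariant after normalization", {
  set.seed(12)
  w <- random_weighted_graph(10, 0.5)
  for (s in c(0.2, 3)) {
    g1 <- normalize_weights(w)
    g2 <- normalize_weights(w * s)
    expect_equal(clustering_coefficient(g2), clustering_coefficient(g1),
                 tolerance = 1e-12)
    expect_equal(local_efficiency(g2), local_efficiency(g1),
                 tolerance = 1e-12)
    # raw-weight integration measures rescale reciprocally
    d1 <- shortest_path_matrix(as_weighted_graph(w))
    d2 <- shortest_path_matrix(as_weighted_graph(w * s))
    expect_equal(char_path_length(d2)$L, char_path_length(d1)$L / s,
                 tolerance = 1e-12)
    expect_equal(global_efficiency(d2), global_efficiency(d1) * s,
                 tolerance = 1e-12)
  }
})

test_that("planted modules raise clustering over degree-matched rewirings", {
  set.seed(13)
  hits <- 0L
  for (rep in 1:10) {
    w <- matrix(0, 12, 12)
    block <- rep(1:2, each = 6)
    for (i in 1:11) {
      for (j in (i + 1):12) {
        p <- if (block[i] == block[j]) 0.9 else 0.1
        if (runif(1) < p) w[i, j] <- w[j, i] <- runif(1, 0.5, 1)
      }
    }
    rw <- rewire_degree_matched(w)
    c_mod <- clustering_coefficient(as_weighted_graph(w))
    c_rew <- clustering_coefficient(as_weighted_graph(rw))
    hits <- hits + (c_mod > c_rew)
  }
  expect_gte(hits, 9L)
})

test_that("metric assembly is deterministic and complete", {
  set.seed(14)
  w <- random_weighted_graph(10, 0.6)
  t <- structure(list(values = w, threshold = 0, median = NA, mad = NA,
                      N = sum(w != 0),
                      edge_count = sum(w[upper.tri(w)] != 0)),
                 class = "thresholded_sl")
  both <- compute_all(t, t)
  expect_identical(both$rest, both$prehension)
  m <- both$rest
  expect_true(all(c("SL_MEAN", "C", "E_loc", "L", "E_glob",
                    "edge_count", "disconnected_pair_fraction")
                  %in% names(m)))
  expect_true(m$C >= 0 && m$C <= 1)
  expect_true(m$E_glob >= 0 && m$E_glob <= 1)
})

test_that("degenerate graphs are rejected with clear errors", {
  two <- as_weighted_graph(matrix(c(0, 1, 1, 0), 2, 2))
  expect_error(clustering_coefficient(two), "at least 3")
  expect_error(local_efficiency(two), "at least 3")
  d_inf <- matrix(Inf, 3, 3)
  diag(d_inf) <- 0
  expect_error(char_path_length(d_inf), "disconnected")
  expect_equal(global_efficiency(d_inf), 0)
})
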