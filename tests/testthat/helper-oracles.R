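# Independent brute-force oracles for the weighted graph measures and
# the mixed-design ANOVA, used to cross-check the package implementation.

# random symmetric weighted graph with given edge density
random_weighted_graph <- function(n, density = 0.6) {
  w <- matrix(0, n, n)
  ut <- which(upper.tri(w))
  on <- runif(length(ut)) < density
  w[ut[on]] <- runif(sum(on), 0.05, 1)
  w + t(w)
}

# exhaustive triangle enumeration for the mean weighted clustering
# coefficient (geometric-mean triangle intensity)
oracle_clustering <- function(w) {
  n <- nrow(w)
  k <- rowSums(w > 0)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    if (k[i] < 2) next
    t_i <- 0
    for (j in seq_len(n)) {
      for (h in seq_len(n)) {
        if (j != i && h != i && j != h) {
          t_i <- t_i + (w[i, j] * w[i, h] * w[j, h])^(1 / 3)
        }
      }
    }
    ci[i] <- t_i / (k[i] * (k[i] - 1))
  }
  mean(ci)
}

# Floyd-Warshall all-pairs shortest paths on lengths 1/w
oracle_distances <- function(w) {
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  d[w > 0] <- 1 / w[w > 0]
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

oracle_char_path <- function(w) {
  d <- oracle_distances(w)
  off <- d[row(d) != col(d)]
  mean(off[is.finite(off)])
}

oracle_global_eff <- function(w) {
  d <- oracle_distances(w)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (nrow(w) * (nrow(w) - 1))
}

oracle_local_eff <- function(w) {
  n <- nrow(w)
  e <- numeric(n)
  for (i in seq_len(n)) {
    nbrs <- which(w[i, ] > 0)
    k <- length(nbrs)
    if (k < 2) next
    dsub <- oracle_distances(w[nbrs, nbrs, drop = FALSE])
    acc <- 0
    for (a in seq_len(k)) {
      for (b in seq_len(k)) {
        if (a != b && is.finite(dsub[a, b])) {
          acc <- acc + (w[i, nbrs[a]] * w[i, nbrs[b]] / dsub[a, b])^(1 / 3)
        }
      }
    }
    e[i] <- acc / (k * (k - 1))
  }
  mean(e)
}

# degree-preserving random rewiring by repeated edge swaps (binary
# topology; weights reassigned to the rewired edges)
rewire_degree_matched <- function(w, n_swaps = 200) {
  m <- (w > 0) * 1
  vals <- w[upper.tri(w) & w > 0]
  for (s in seq_len(n_swaps)) {
    ed <- which(upper.tri(m) & m > 0, arr.ind = TRUE)
    if (nrow(ed) < 2) break
    pick <- sample(nrow(ed), 2)
    a <- ed[pick[1], ]; b <- ed[pick[2], ]
    i <- a[1]; j <- a[2]; u <- b[1]; v <- b[2]
    if (length(unique(c(i, j, u, v))) < 4) next
    if (m[i, v] == 0 && m[u, j] == 0) {
      m[i, j] <- m[j, i] <- 0; m[u, v] <- m[v, u] <- 0
      m[i, v] <- m[v, i] <- 1; m[u, j] <- m[j, u] <- 1
    }
  }
  out <- matrix(0, nrow(w), ncol(w))
  idx <- which(upper.tri(m) & m > 0)
  out[idx] <- sample(vals, length(idx), replace = length(idx) > length(vals))
  out + t(out)
}

# textbook sums-of-squares decomposition for a balanced
# groups x condition design with subjects nested in groups
oracle_mixed_anova <- function(tbl, measure) {
  y <- tbl[[measure]]
  g <- factor(tbl$group)
  cond <- factor(tbl$condition)
  s <- factor(tbl$subject_id)
  grand <- mean(y)
  n_subj <- nlevels(s)
  n_g <- nlevels(g)
  subj_means <- tapply(y, s, mean)
  subj_group <- tapply(as.character(g), s, function(x) x[1])
  group_means <- tapply(y, g, mean)
  group_of_subj <- group_means[subj_group]
  ss_between_subj <- 2 * sum((subj_means - grand)^2)
  ss_group <- sum(tapply(y, g, function(v) length(v) * (mean(v) - grand)^2))
  ss_subj_wg <- ss_between_subj - ss_group
  cond_means <- tapply(y, cond, mean)
  ss_cond <- sum(tapply(y, cond, function(v) length(v) * (mean(v) - grand)^2))
  cell_means <- tapply(y, list(g, cond), mean)
  n_per_group <- table(g) / 2
  ss_inter <- 0
  for (gi in seq_len(n_g)) {
    for (ci in 1:2) {
      ss_inter <- ss_inter + n_per_group[gi] *
        (cell_means[gi, ci] - group_means[gi] - cond_means[ci] + grand)^2
    }
  }
  ss_total <- sum((y - grand)^2)
  ss_err_w <- ss_total - ss_group - ss_subj_wg - ss_cond - ss_inter
  df_bw <- n_subj - n_g
  list(
    F_group = unname((ss_group / (n_g - 1)) / (ss_subj_wg / df_bw)),
    F_cond = unname(ss_cond / (ss_err_w / df_bw)),
    F_inter = unname((ss_inter / (n_g - 1)) / (ss_err_w / df_bw)),
    ss = c(group = ss_group, subj_wg = ss_subj_wg, cond = ss_cond,
           inter = unname(ss_inter), err_w = unname(ss_err_w),
           total = ss_total))
}
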