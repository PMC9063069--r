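# Brute-force oracles, independent of the package implementation.

# Dixon decision for a triple: recompute Q from its definition and compare to
# the critical value; returns the 1-based index removed, or NA.
oracle_dixon <- function(values, crit = 0.970) {
  rng <- max(values) - min(values)
  if (rng == 0) return(NA_integer_)
  med <- median(values)
  suspect <- if ((max(values) - med) >= (med - min(values))) {
    which.max(values)
  } else {
    which.min(values)
  }
  gap <- min(abs(values[suspect] - values[-suspect]))
  if (gap / rng > crit) suspect else NA_integer_
}

# Exact two-sided signed-rank p by full enumeration of all 2^n sign
# assignments (requires nonzero diffs with distinct absolute values).
oracle_signed_rank_p <- function(diffs) {
  diffs <- diffs[diffs != 0]
  n <- length(diffs)
  r <- rank(abs(diffs))
  v_obs <- sum(r[diffs > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  v_all <- as.matrix(signs) %*% r
  min(1, 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs)))
}

# Exact two-sided rank-sum p by enumeration of all group labelings.
# Statistic: Mann-Whitney W for group x (rank sum of x minus n(n+1)/2).
oracle_rank_sum_p <- function(x, y) {
  nx <- length(x)
  all_v <- c(x, y)
  r <- rank(all_v)
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  labelings <- combn(length(all_v), nx)
  w_all <- apply(labelings, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
}

# Closest pair among three values by explicit pairwise enumeration; ties go
# to the earliest pair in (1,2), (1,3), (2,3) order.
oracle_closest_pair <- function(v) {
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  gaps <- vapply(pairs, function(p) abs(v[p[1]] - v[p[2]]), numeric(1))
  pairs[[which.min(gaps)]]
}

# Edge counts of a correlation matrix at the two absolute-r thresholds,
# counted pair by pair.
oracle_edge_counts <- function(r, thin = 0.3, thick = 0.7) {
  p <- ncol(r)
  n_thin <- 0L
  n_thick <- 0L
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      a <- abs(r[i, j])
      if (a >= thick) n_thick <- n_thick + 1L
      else if (a >= thin) n_thin <- n_thin + 1L
    }
  }
  c(thin = n_thin, thick = n_thick)
}
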