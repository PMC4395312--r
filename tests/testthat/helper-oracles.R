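# Independent oracles and small fixture builders used across tests.

# Exact two-tailed Mann-Whitney p by full enumeration of all rank
# assignments (independent of stats::wilcox.test).
mw_exact_p <- function(a, b) {
  m <- length(a)
  pooled <- c(a, b)
  u_stat <- function(idx) {
    x <- pooled[idx]
    y <- pooled[-idx]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  u_obs <- u_stat(seq_len(m))
  us <- apply(utils::combn(length(pooled), m), 2, u_stat)
  mu <- m * (length(b)) / 2
  # two-tailed: probability of a U at least as extreme (as far from mu)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# clean (distortion-free) series for geometry tests
clean_series <- function(seed = 1, n_sections = 8, neurons_per_pool = 15) {
  sim_series(seed = seed, n_sections = n_sections,
             neurons_per_pool = neurons_per_pool,
             enlargement_amplitude = 0, rigid_jitter_translation = 0,
             rigid_jitter_rotation = 0, landmark_noise = 0)
}

# apply one global rigid motion (theta, shift) to every section of a series
apply_global_rigid <- function(series, theta, shift) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  is_axis <- series$record_type == "axis"
  xy <- cbind(series$x, series$y) %*% t(R)
  xy[!is_axis, 1] <- xy[!is_axis, 1] + shift[1]
  xy[!is_axis, 2] <- xy[!is_axis, 2] + shift[2]
  series$x <- xy[, 1]
  series$y <- xy[, 2]
  series
}

# truth coordinates of one pool from a simulated series, ordered by neuron id
series_truth <- function(series, pool) {
  tr <- series[series$record_type == "neuron" & series$pool_label == pool, ]
  tr <- tr[order(tr$neuron_id), c("neuron_id", "x_true", "y_true")]
  tibble::as_tibble(tr)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / abs(expected)), tol)
}
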