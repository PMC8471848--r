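# Independent oracles used across the suite. These deliberately use the
# slowest, most literal formulation of each quantity so they share no code
# with the package implementation.

# Literal double-loop time-averaged MSD (planar).
naive_msd <- function(x, y) {
  N <- length(x) - 1L
  vapply(seq_len(N), function(n) {
    acc <- 0
    for (i in 0:(N - n)) {
      acc <- acc + (x[i + n + 1] - x[i + 1])^2 + (y[i + n + 1] - y[i + 1])^2
    }
    acc / (N - n + 1)
  }, numeric(1))
}

# Exhaustive all-pairs nearest-tumor scan.
brute_nearest <- function(cells, tumors) {
  out <- data.frame(id = cells$cell_id, nearest = NA, dist = NA_real_)
  for (i in seq_len(nrow(cells))) {
    best <- Inf; best_id <- NA
    for (j in seq_len(nrow(tumors))) {
      d <- sqrt((cells$x[i] - tumors$x[j])^2 +
                  (cells$y[i] - tumors$y[j])^2 +
                  (cells$z[i] - tumors$z[j])^2)
      if (d < best || (d == best && tumors$cell_id[j] < best_id)) {
        best <- d; best_id <- tumors$cell_id[j]
      }
    }
    out$nearest[i] <- best_id; out$dist[i] <- best
  }
  out
}

# Textbook Pearson coefficient.
pearson_textbook <- function(a, b) {
  sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
}

random_track <- function(n, seed) {
  set.seed(seed)
  data.frame(x = cumsum(rnorm(n)), y = cumsum(rnorm(n)), z = 0,
             t = seq_len(n) - 1)
}

# A small strongly-separated two-group plate: a planted-block fixture whose
# within-group spread is small relative to the planted fold change, so the
# block structure is unambiguous by construction.
block_plate_config <- function(seed = 1, log_sd = 0.15) {
  sim_config(seed = seed,
             secretion_params = list(
               n_analytes = 12, log_mean = log(100), log_sd = log_sd,
               group_effect = 2, affected_frac = 0.5, lod = 0,
               n_samples = c(control = 10, treated = 10)))
}
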