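# Independent oracles used to cross-check the package implementations.
# These deliberately avoid the code paths they verify.

# Brute-force Ward clustering: at every step merge the pair of clusters whose
# union minimizes the increase in within-cluster error sum of squares; heights
# on the sqrt(2 * delta ESS) scale (squared-Euclidean Ward).
ward_heights_brute <- function(X) {
  clusters <- lapply(seq_len(nrow(X)), function(i) i)
  heights <- numeric(0)
  ess <- function(idx) {
    if (length(idx) == 1) return(0)
    sum(scale(X[idx, , drop = FALSE], scale = FALSE)^2)
  }
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    bestd <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i < j) {
          d <- ess(c(clusters[[i]], clusters[[j]])) -
            ess(clusters[[i]]) - ess(clusters[[j]])
          if (d < bestd) {
            bestd <- d
            best <- c(i, j)
          }
        }
      }
    }
    heights <- c(heights, sqrt(2 * bestd))
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
  }
  heights
}

# Hand-worked Benjamini-Hochberg step-up: adjusted p for the i-th smallest
# raw p is min over j >= i of p_(j) * m / j, capped at 1.
bh_stepup_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Discrete time-average of the post-step force transient over a hold sampled
# at times k * dt, k = 1..N (closed-form geometric sum).
hold_mean_lengthen <- function(f_ss, overshoot, tau, dt, n) {
  r <- exp(-dt / tau)
  f_ss * (1 + overshoot * r * (1 - r^n) / (n * (1 - r)))
}

# One default noisy three-cycle trace reduced to curves (shared fixture).
default_curves <- function(seed = 1, noise_sd = 0.2) {
  simulate_trace(three_cycle_protocol(), default_tissue_params(),
                 noise_sd = noise_sd, seed = seed) |>
    segment_steps() |>
    build_cycle_curves()
}
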