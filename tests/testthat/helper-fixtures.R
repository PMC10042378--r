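# Shared fixtures: small walkers, hand-built trajectories, forged chains.

# A small, fast walker: 11 grid states, DS0 timing (unit perturbation gain).
tiny_walker <- function(a = 0.5, b = 1, fail_bound = 0.05,
                        grid_half_n = 5L, timing = "DS0", ...) {
  walker_config(a = a, b = b, fail_bound = fail_bound,
                grid_half_n = grid_half_n, timing = timing, ...)
}

# A hand-built constant-channel step trajectory (all 100 samples equal the
# given channel values; unspecified channels are 0, Fn defaults to 100).
make_traj <- function(..., T = 1, L = 1, n_samples = 100L) {
  vals <- list(...)
  samples <- matrix(0, n_samples, length(trajectory_channels()),
                    dimnames = list(NULL, trajectory_channels()))
  samples[, "Fn"] <- 100
  for (ch in names(vals)) samples[, ch] <- vals[[ch]]
  structure(list(samples = samples, T = T, L = L, v = L / T,
                 failed = FALSE),
            class = "step_trajectory")
}

# Forge an absorbing chain directly from Q (R is the row-sum complement).
forge_chain <- function(Q) {
  Q <- as.matrix(Q)
  structure(list(Q = Q, R = 1 - rowSums(Q), cell_masses = NULL,
                 state_labels = seq_len(nrow(Q)), mesh_ref = NULL),
            class = "absorbing_chain")
}

# Forge a weighted_step_stats object.
forge_stats <- function(mu, sigma) {
  structure(list(mu = mu, sigma = sigma,
                 survive_mass = rep(1, length(mu))),
            class = "weighted_step_stats")
}

# Logistic-map series at full chaos (analytic Lyapunov exponent ln 2).
logistic_series <- function(n, x0 = 0.412) {
  x <- numeric(n)
  x[1] <- x0
  for (i in 2:n) x[i] <- 4 * x[i - 1] * (1 - x[i - 1])
  x
}

# Simulate absorption times of a forged/small chain by direct state-level
# walks (independent oracle for the fundamental-matrix MFPT).
simulate_absorption_steps <- function(chain, n_walks, start = 1L,
                                      max_steps = 1e6L) {
  P <- cbind(chain$Q, chain$R)
  absorbing <- ncol(P)
  vapply(seq_len(n_walks), function(w) {
    s <- start
    for (t in seq_len(max_steps)) {
      s <- sample.int(absorbing, 1L, prob = P[s, ])
      if (s == absorbing) return(as.numeric(t))
    }
    stop("walk did not absorb within max_steps")
  }, numeric(1))
}
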