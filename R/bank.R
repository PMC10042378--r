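# The study's walker preset bank: a two-family, graded-fragility set of
# synthetic gaits spanning many orders of magnitude of mean first passage
# time, with three perturbation-timing conditions per gait.

#' Walker preset bank
#'
#' Builds the bank of walker configurations used throughout the package's
#' studies. Each preset is indexed by a fragility coordinate `t` in [0, 1]
#' (0 = most fragile, 1 = most stable), a template family (`"A"` or `"B"`,
#' differing in waveform amplitudes and perturbation gain, playing the role
#' of a second model class) and a perturbation timing (`"DS0"`, `"SS0"`,
#' `"SS0.5"`). Along `t` the bank grades the map contraction, the failure
#' boundary, the nominal spatiotemporal parameters and the waveform
#' sensitivities together, the way speed, step length and stability co-vary
#' across real gaits; the resulting MFPTs span from under a hundred to
#' beyond a hundred million steps.
#'
#' @param use `"train"` (2 families x 6 fragility levels x 3 timings = 36
#'   conditions) or `"validation"` (2 x 2 x 3 = 12 conditions at
#'   intermediate fragility levels).
#' @param timings Timings to include (default all three).
#' @return A data frame with one row per condition: `label`, `family`, `t`,
#'   `timing`, and a list-column `config` of [walker_config()] objects.
#' @export
walker_bank <- function(use = c("train", "validation"),
                        timings = c("DS0", "SS0", "SS0.5")) {
  use <- match.arg(use)
  t_vals <- if (use == "train") seq(0, 1, by = 0.2) else c(0.3, 0.7)
  grid <- expand.grid(t = t_vals, family = c("A", "B"), timing = timings,
                      stringsAsFactors = FALSE)
  grid$label <- sprintf("%s_t%.1f_%s", grid$family, grid$t, grid$timing)
  grid$config <- lapply(seq_len(nrow(grid)), function(r) {
    bank_config(grid$t[r], grid$family[r], grid$timing[r])
  })
  grid[, c("label", "family", "t", "timing", "config")]
}

# One bank configuration from the fragility coordinate, family and timing.
# Each condition carries a deterministic idiosyncratic jitter (derived from
# its own seed) on top of the smooth parameter grading: gait families in
# the wild do not lie exactly on a parametric curve, and without this
# condition-level heterogeneity the chain metrics would determine the MFPT
# exactly and any regression on them would be degenerate.
bank_config <- function(t, family, timing) {
  seed <- 1000L + round(1000 * t) + (family == "B") * 7L +
    match(timing, c("DS0", "SS0", "SS0.5")) * 131L
  jit <- withr::with_seed(seed, stats::rnorm(6L))
  walker_config(
    state_dim = 1L,
    a = 0.35 + 0.30 * t + 0.01 * jit[1],
    b = 1.0,
    fail_bound = (0.030 + 0.042 * t) * exp(0.03 * jit[2]),
    grid_half_n = 20L,
    noise_sd = 0.013,
    timing = timing,
    nominal_step_length = (0.96 + 0.10 * t) * exp(0.01 * jit[3]),
    nominal_step_duration = (1.05 - 0.10 * t) * exp(0.01 * jit[4]),
    sens_state = (1 + 0.5 * t) * exp(0.08 * jit[5]),
    sens_pert = (1 + 0.5 * t) * exp(0.08 * jit[5]),
    spatio_gain = c(T_state = 0.05,
                    T_pert = (0.09 + 0.05 * t) * exp(0.05 * jit[6]),
                    L_state = -0.04,
                    L_pert = -(0.10 + 0.05 * t) * exp(0.05 * jit[6])),
    family = family,
    seed = seed)
}

#' Chain data for a bank of conditions
#'
#' For every condition of a [walker_bank()]: builds the deterministic mesh
#' and the absorbing chain, computes the first-passage statistics and the
#' chain metric vector. This is the training (or validation) table of the
#' fall-risk study.
#'
#' @param bank A [walker_bank()] data frame (or subset of its rows).
#' @param cfg An [embedding_config()].
#' @param lyapunov Compute the chain-sampled Lyapunov metrics (expensive)?
#' @param mfpt_from `"eigen"` (default) or `"exact"`: which MFPT variant is
#'   reported as the true number of steps to fall.
#' @param ... Passed to [chain_metric_vector()].
#' @return A list: `metrics` (conditions x 49 matrix), `mfpt`, `lambda2`,
#'   `mfpt_exact`, and the input `table` (without configs refitted).
#' @export
bank_chain_data <- function(bank, cfg = embedding_config(),
                            lyapunov = FALSE,
                            mfpt_from = c("eigen", "exact"), ...) {
  mfpt_from <- match.arg(mfpt_from)
  n <- nrow(bank)
  metrics <- matrix(NA_real_, n, 49L,
                    dimnames = list(bank$label, metric_names()))
  mfpt_eigen <- mfpt_exact <- lambda2 <- numeric(n)
  for (r in seq_len(n)) {
    mesh <- build_deterministic_mesh(bank$config[[r]])
    chain <- build_chain(mesh)
    st <- chain_statistics(chain)
    mfpt_eigen[r] <- st$mfpt_eigen
    mfpt_exact[r] <- st$mfpt_exact
    lambda2[r] <- st$lambda2
    metrics[r, ] <- as.numeric(
      chain_metric_vector(chain, mesh, cfg, lyapunov = lyapunov, ...))
  }
  list(metrics = metrics,
       mfpt = if (mfpt_from == "eigen") mfpt_eigen else mfpt_exact,
       mfpt_eigen = mfpt_eigen, mfpt_exact = mfpt_exact,
       lambda2 = lambda2,
       table = bank[, c("label", "family", "t", "timing")])
}
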