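# Synthetic metastable walker: a step-to-step return map with an absorbing
# failure region, plus template-based synthesis of within-step trajectories.

#' Channel names of a step trajectory
#'
#' Every step trajectory carries 28 channels sampled at 100 points per step:
#' the eight configuration coordinates `q1..q8` (`q1..q6` joint angles, `q7`
#' and `q8` the horizontal and vertical hip position), their velocities
#' `dq1..dq8`, the stance-contact position (`xst`, `yst`), the normal ground
#' reaction force `Fn`, the stance ankle torque `tau_a`, the gravitational
#' force on the foot (`Fgx`, `Fgy`), the foot-mass centre (`Gx`, `Gy`), the
#' ankle point (`Ax`, `Ay`) and the ankle force (`Fax`, `Fay`).
#'
#' @return Character vector of 28 channel names.
#' @export
trajectory_channels <- function() {
  c(paste0("q", 1:8), paste0("dq", 1:8),
    "xst", "yst", "Fn", "tau_a",
    "Fgx", "Fgy", "Gx", "Gy", "Ax", "Ay", "Fax", "Fay")
}

#' Configuration of the synthetic metastable walker
#'
#' The walker is a discrete step-to-step return map with an absorbing failure
#' region. Its start-of-step state `x` (1- or 2-dimensional) evolves as
#' `x+ = A x + b_eff * s`, where `s` is a horizontal velocity perturbation
#' (m/s) applied once per step and `b_eff` depends on the perturbation
#' timing. A step fails when any component of the post-step state leaves the
#' failure bounds; surviving states are saturated at the failure boundary.
#' Within-step trajectories are synthesised from per-channel 100-sample
#' nominal templates, linearly deformed by the start-state deviation and the
#' perturbation.
#'
#' @param state_dim State dimension, 1 or 2.
#' @param a Contraction of the return map: scalar (`state_dim = 1`) or a
#'   `state_dim x state_dim` matrix with spectral radius below 1.
#' @param b Perturbation gain mapping an impulse (m/s) into state units;
#'   length `state_dim`.
#' @param fixed_point Nominal periodic state (the fixed point of the
#'   unperturbed map); length `state_dim`.
#' @param fail_bound Failure boundary: a step fails when
#'   `|x - fixed_point| > fail_bound` in any component; length `state_dim`
#'   or scalar.
#' @param grid_half_n State grid resolution: each dimension is discretised
#'   into `2 * grid_half_n + 1` equally spaced points spanning
#'   `fixed_point +/- fail_bound`.
#' @param pert_min,pert_max,pert_spacing Perturbation grid (m/s). The
#'   defaults give the 201-point grid from -0.200 to 0.200 at 0.002
#'   spacing; `pert_spacing` must divide `pert_max - pert_min` exactly.
#' @param noise_sd Standard deviation (m/s) of the Gaussian perturbation
#'   distribution N(0, noise_sd^2). Default 0.013.
#' @param timing Perturbation timing condition: `"DS0"` (start of double
#'   support), `"SS0"` (start of single support) or `"SS0.5"` (halfway
#'   through single support). Later timings couple less strongly into the
#'   step-to-step state and deform a later portion of the waveforms.
#' @param g Gravitational acceleration (m/s^2).
#' @param nominal_step_length,nominal_step_duration Nominal step length (m)
#'   and duration (s); nominal speed is their ratio.
#' @param sens_state,sens_pert Global multipliers on the per-channel waveform
#'   deformation gains for start-state deviation and perturbation.
#' @param spatio_gain Named numeric vector with elements `T_state`, `T_pert`,
#'   `L_state`, `L_pert`: relative sensitivities of step duration and step
#'   length to the normalised state deviation and perturbation.
#' @param family Template family, `"A"` or `"B"`; families differ in template
#'   amplitudes and perturbation gain, playing the role of a second
#'   model class (like instantaneous vs. finite-time double support).
#' @param seed Integer seed recorded in the config; all stochastic
#'   operations on this walker derive their streams from it.
#' @return An object of class `walker_config`.
#' @export
walker_config <- function(state_dim = 1L,
                          a = 0.5,
                          b = 1.0,
                          fixed_point = 0,
                          fail_bound = 0.05,
                          grid_half_n = 20L,
                          pert_min = -0.200,
                          pert_max = 0.200,
                          pert_spacing = 0.002,
                          noise_sd = 0.013,
                          timing = c("SS0.5", "DS0", "SS0"),
                          g = 9.81,
                          nominal_step_length = 1.0,
                          nominal_step_duration = 1.0,
                          sens_state = 1.0,
                          sens_pert = 1.0,
                          spatio_gain = c(T_state = 0.05, T_pert = 0.09,
                                          L_state = -0.04, L_pert = -0.10),
                          family = c("A", "B"),
                          seed = 1L) {
  timing <- match.arg(timing)
  family <- match.arg(family)
  state_dim <- as.integer(state_dim)
  if (!state_dim %in% c(1L, 2L))
    stop("state_dim must be 1 or 2")
  a <- as.matrix(a)
  if (!all(dim(a) == state_dim))
    a <- diag(as.numeric(a), state_dim)
  if (max(Mod(eigen(a, only.values = TRUE)$values)) >= 1)
    stop("return map must be contracting: spectral radius of 'a' >= 1")
  b <- rep_len(as.numeric(b), state_dim)
  fixed_point <- rep_len(as.numeric(fixed_point), state_dim)
  fail_bound <- rep_len(as.numeric(fail_bound), state_dim)
  if (any(fail_bound <= 0)) stop("fail_bound must be positive")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (nominal_step_duration <= 0) stop("nominal_step_duration must be positive")
  n_cells <- (pert_max - pert_min) / pert_spacing
  if (abs(n_cells - round(n_cells)) > 1e-9)
    stop("pert_spacing must divide pert_max - pert_min exactly")
  stopifnot(all(c("T_state", "T_pert", "L_state", "L_pert") %in%
                  names(spatio_gain)))
  pg <- seq(pert_min, pert_max, by = pert_spacing)
  if (isTRUE(all.equal(pert_min, -pert_max)))
    pg <- (pg - rev(pg)) / 2  # exact floating-point symmetry
  cfg <- list(
    state_dim = state_dim, a = a, b = b,
    fixed_point = fixed_point, fail_bound = fail_bound,
    grid_half_n = as.integer(grid_half_n),
    pert_grid = pg,
    noise_sd = noise_sd, timing = timing, g = g,
    nominal_step_length = nominal_step_length,
    nominal_step_duration = nominal_step_duration,
    nominal_speed = nominal_step_length / nominal_step_duration,
    sens_state = sens_state, sens_pert = sens_pert,
    spatio_gain = spatio_gain, family = family,
    seed = as.integer(seed))
  cfg$timing_gain <- switch(timing, DS0 = 1.0, SS0 = 0.9, SS0.5 = 0.6)
  cfg$b_eff <- cfg$b * cfg$timing_gain * if (family == "B") 1.15 else 1.0
  cfg$templates <- walker_templates(cfg)
  class(cfg) <- "walker_config"
  cfg
}

#' @export
print.walker_config <- function(x, ...) {
  cat("Synthetic metastable walker configuration\n")
  cat(sprintf("  state dim %d, family %s, timing %s\n",
              x$state_dim, x$family, x$timing))
  cat(sprintf("  contraction %s, perturbation gain %s (effective %s)\n",
              paste(signif(diag(x$a), 3), collapse = "/"),
              paste(signif(x$b, 3), collapse = "/"),
              paste(signif(x$b_eff, 3), collapse = "/")))
  cat(sprintf("  failure bound %s, grid %d states/dim\n",
              paste(signif(x$fail_bound, 3), collapse = "/"),
              2L * x$grid_half_n + 1L))
  cat(sprintf("  perturbations: %d grid points, noise sd %.3f m/s\n",
              length(x$pert_grid), x$noise_sd))
  cat(sprintf("  nominal step: L = %.3f m, T = %.3f s, v = %.3f m/s\n",
              x$nominal_step_length, x$nominal_step_duration,
              x$nominal_speed))
  invisible(x)
}

# Nominal 100-sample waveforms for every channel, plus the per-channel
# deformation gains (alpha: start-state deviation, beta: perturbation) and
# the deformation mode shapes. Kinetic channels are template-based, not
# dynamically consistent; this is a documented fixture property.
walker_templates <- function(cfg) {
  tt <- seq(0, 1, length.out = 100)
  L <- cfg$nominal_step_length
  T0 <- cfg$nominal_step_duration
  v <- cfg$nominal_speed
  amp <- if (cfg$family == "B") 1.2 else 1.0
  w <- 2 * pi
  tmpl <- cbind(
    q1 = 0.05 * amp * sin(w * tt),
    q2 = 0.30 * amp * sin(w * tt + 0.5),
    q3 = 0.40 + 0.20 * amp * cos(w * tt),
    q4 = 0.20 * amp * sin(2 * w * tt),
    q5 = 0.10 * amp * cos(w * tt + 1.0),
    q6 = 0.15 * amp * sin(w * tt + 2.0),
    q7 = L * (tt - 0.5),
    q8 = 0.95 + 0.02 * amp * cos(2 * w * tt),
    dq1 = 0.05 * amp * w * cos(w * tt) / T0,
    dq2 = 0.30 * amp * w * cos(w * tt + 0.5) / T0,
    dq3 = -0.20 * amp * w * sin(w * tt) / T0,
    dq4 = 0.40 * amp * w * cos(2 * w * tt) / T0,
    dq5 = -0.10 * amp * w * sin(w * tt + 1.0) / T0,
    dq6 = 0.15 * amp * w * cos(w * tt + 2.0) / T0,
    dq7 = v * (1 + 0.10 * amp * sin(2 * w * tt)),
    dq8 = -0.04 * amp * w * sin(2 * w * tt) / T0,
    xst = rep(0, 100),
    yst = rep(0, 100),
    Fn = 850 + 80 * amp * sin(w * tt),
    tau_a = 10 * amp * sin(w * tt + 0.3),
    Fgx = rep(0, 100),
    Fgy = rep(-30, 100),
    Gx = 0.05 + 0.01 * amp * sin(w * tt),
    Gy = rep(0.02, 100),
    Ax = rep(0, 100),
    Ay = 0.08 + 0.005 * amp * cos(w * tt),
    Fax = 20 * amp * sin(w * tt),
    Fay = -820 + 50 * amp * cos(w * tt))
  stopifnot(identical(colnames(tmpl), trajectory_channels()))
  # deformation gains per channel, scaled to each template's magnitude so
  # that a unit normalised deviation deforms every coordinate measurably
  alpha <- c(q1 = 0.010, q2 = 0.040, q3 = 0.030, q4 = 0.030, q5 = 0.015,
             q6 = 0.020, q7 = 0.020, q8 = 0.004,
             dq1 = 0.060, dq2 = 0.200, dq3 = 0.150, dq4 = 0.250, dq5 = 0.070,
             dq6 = 0.100, dq7 = 0.050, dq8 = 0.030,
             xst = 0, yst = 0, Fn = 30, tau_a = 2,
             Fgx = 0, Fgy = 0, Gx = 0.002, Gy = 0, Ax = 0, Ay = 0.001,
             Fax = 5, Fay = 15)
  beta <- c(q1 = 0.006, q2 = 0.025, q3 = 0.018, q4 = 0.020, q5 = 0.010,
            q6 = 0.012, q7 = 0.012, q8 = 0.003,
            dq1 = 0.040, dq2 = 0.120, dq3 = 0.090, dq4 = 0.160, dq5 = 0.045,
            dq6 = 0.060, dq7 = 0.040, dq8 = 0.020,
            xst = 0, yst = 0, Fn = 20, tau_a = 1.5,
            Fgx = 0, Fgy = 0, Gx = 0.001, Gy = 0, Ax = 0, Ay = 0.0005,
            Fax = 3, Fay = 10)
  stopifnot(identical(names(alpha), trajectory_channels()),
            identical(names(beta), trajectory_channels()))
  # mode shapes: state deviation deforms the whole step; the perturbation
  # deforms the waveform from its application onset onwards. Both shapes
  # stay non-zero at the end of the step (an impulse shifts the velocities
  # persistently), so end-of-step quantities feel the deformation too.
  onset <- switch(cfg$timing, DS0 = 0.0, SS0 = 0.1, SS0.5 = 0.55)
  shape_state <- 0.5 + 0.5 * sin(pi * tt)
  shape_pert <- ifelse(tt < onset, 0,
                       0.5 + 0.5 * sin(pi * (tt - onset) / (1 - onset)))
  list(tmpl = tmpl, alpha = alpha, beta = beta,
       shape_state = shape_state, shape_pert = shape_pert)
}

# Normalised scalar deviation of a state from the nominal point, used to
# modulate waveforms and spatiotemporal scalars. For 2-D states the first
# component carries the waveform coupling.
state_deviation <- function(cfg, state) {
  (state[1L] - cfg$fixed_point[1L]) / cfg$fail_bound[1L]
}

# Internal: next state of the return map (before snapping), plus failure.
step_map <- function(cfg, state, perturbation) {
  dev <- state - cfg$fixed_point
  nxt <- cfg$fixed_point + as.numeric(cfg$a %*% dev) +
    cfg$b_eff * perturbation
  failed <- any(abs(nxt - cfg$fixed_point) > cfg$fail_bound)
  if (!failed) {
    # saturate survivors at the failure boundary
    nxt <- pmin(pmax(nxt, cfg$fixed_point - cfg$fail_bound),
                cfg$fixed_point + cfg$fail_bound)
  }
  list(state = nxt, failed = failed)
}

# Internal: synthesise the 100-sample trajectory for a step taken from
# `state` under perturbation `s`.
synth_trajectory <- function(cfg, state, s, failed = FALSE) {
  tp <- cfg$templates
  dev <- state_deviation(cfg, state)
  sn <- s / 0.013  # perturbation in units of the reference noise scale
  def <- outer(tp$shape_state, cfg$sens_state * dev * tp$alpha) +
    outer(tp$shape_pert, cfg$sens_pert * sn * tp$beta)
  samples <- tp$tmpl + def
  gains <- cfg$spatio_gain
  T <- cfg$nominal_step_duration *
    (1 + gains[["T_state"]] * dev + gains[["T_pert"]] * sn)
  T <- max(T, 0.05 * cfg$nominal_step_duration)
  L <- cfg$nominal_step_length *
    (1 + gains[["L_state"]] * dev + gains[["L_pert"]] * sn)
  L <- max(L, 0)
  structure(list(samples = samples, T = T, L = L, v = L / T,
                 failed = failed),
            class = "step_trajectory")
}

#' @export
print.step_trajectory <- function(x, ...) {
  cat(sprintf(
    "Step trajectory: 100 samples x %d channels; T = %.3f s, L = %.3f m, v = %.3f m/s%s\n",
    ncol(x$samples), x$T, x$L, x$v, if (x$failed) " [failed step]" else ""))
  invisible(x)
}

#' Simulate one step of the synthetic walker
#'
#' Applies the step-to-step return map to a start-of-step state under a
#' horizontal impulse perturbation and synthesises the within-step
#' trajectory. Deterministic given its inputs.
#'
#' @param config A [walker_config()].
#' @param state Start-of-step state (numeric, length `state_dim`) within the
#'   failure bounds.
#' @param perturbation Horizontal impulse (m/s), `|perturbation|` at most the
#'   perturbation grid maximum.
#' @return A list with elements `state` (the end-of-step state, or `NA` if
#'   the step failed), `failed` (logical) and `trajectory` (a
#'   `step_trajectory`: 100 x 28 sample matrix plus step duration `T`,
#'   length `L` and mean speed `v`).
#' @export
simulate_step <- function(config, state, perturbation) {
  stopifnot(inherits(config, "walker_config"))
  state <- rep_len(as.numeric(state), config$state_dim)
  if (any(abs(state - config$fixed_point) > config$fail_bound + 1e-12))
    stop("state outside the walker's state grid bounds")
  if (abs(perturbation) > max(abs(config$pert_grid)) + 1e-12)
    stop("perturbation outside the perturbation grid")
  mp <- step_map(config, state, perturbation)
  traj <- synth_trajectory(config, state, perturbation, failed = mp$failed)
  list(state = if (mp$failed) rep(NA_real_, config$state_dim) else mp$state,
       failed = mp$failed, trajectory = traj)
}

# Grid of discretised start-of-step states. State 1 is the nominal periodic
# state; the remaining grid points follow in ascending (row-major) order.
state_grid <- function(cfg) {
  axes <- lapply(seq_len(cfg$state_dim), function(d) {
    ax <- seq(-cfg$fail_bound[d], cfg$fail_bound[d],
              length.out = 2L * cfg$grid_half_n + 1L)
    cfg$fixed_point[d] + (ax - rev(ax)) / 2  # exact symmetry
  })
  grid <- as.matrix(expand.grid(axes))
  dimnames(grid) <- NULL
  # put the nominal state first, keep the rest in grid order
  d2 <- rowSums((grid - matrix(cfg$fixed_point, nrow(grid),
                               cfg$state_dim, byrow = TRUE))^2)
  i0 <- which.min(d2)
  grid[c(i0, setdiff(seq_len(nrow(grid)), i0)), , drop = FALSE]
}

# Snap a (non-failed) state to the nearest grid state; ties go to the lower
# index. States are guaranteed in-grid because survivors are saturated.
snap_state <- function(states, x) {
  d2 <- rowSums((states - matrix(x, nrow(states), ncol(states),
                                 byrow = TRUE))^2)
  which.min(d2)
}

#' Build the deterministic state-transition mesh
#'
#' Systematically simulates one step from every discretised start-of-step
#' state under every grid perturbation, snapping end states to the nearest
#' grid state (ties to the lower index). When several perturbations produce
#' the same (start, end) pair, the stored trajectory is the one for the
#' median perturbation.
#'
#' @param config A [walker_config()].
#' @return An object of class `deterministic_mesh` with elements `states`
#'   (matrix of grid states, row 1 = nominal), `transitions` (integer matrix,
#'   states x perturbations, end-state index or 0 for a fall), `rep_pert`
#'   (states x states matrix of the representative median perturbation for
#'   each realised transition, `NA` elsewhere) and `config`. Trajectories
#'   are synthesised on demand with [mesh_trajectory()].
#' @export
build_deterministic_mesh <- function(config) {
  stopifnot(inherits(config, "walker_config"))
  states <- state_grid(config)
  n <- nrow(states)
  perts <- config$pert_grid
  if (length(perts) == 0L) stop("empty perturbation grid")
  trans <- matrix(0L, n, length(perts))
  for (i in seq_len(n)) {
    dev <- states[i, ] - config$fixed_point
    base <- config$fixed_point + as.numeric(config$a %*% dev)
    nxt <- matrix(base, length(perts), config$state_dim, byrow = TRUE) +
      outer(perts, config$b_eff)
    devn <- abs(nxt - matrix(config$fixed_point, length(perts),
                             config$state_dim, byrow = TRUE))
    exceed <- devn > matrix(config$fail_bound, length(perts),
                            config$state_dim, byrow = TRUE)
    ok <- rowSums(exceed) == 0L
    if (any(ok)) {
      sat <- nxt[ok, , drop = FALSE]
      for (d in seq_len(config$state_dim)) {
        sat[, d] <- pmin(pmax(sat[, d],
                              config$fixed_point[d] - config$fail_bound[d]),
                         config$fixed_point[d] + config$fail_bound[d])
      }
      # snap: nearest grid state per dimension-product grid
      idx <- apply(sat, 1L, function(x) snap_state(states, x))
      trans[i, ok] <- as.integer(idx)
    }
  }
  # median representative perturbation for each realised (i, j): when
  # several perturbations give the same transition, its stored trajectory
  # is the one for the median of those perturbations
  rep_pert <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    for (j in unique(trans[i, ])) {
      if (j == 0L) next
      ss <- perts[trans[i, ] == j]
      rep_pert[i, j] <- ss[ceiling(length(ss) / 2)]
    }
  }
  structure(list(states = states, transitions = trans,
                 rep_pert = rep_pert, config = config),
            class = "deterministic_mesh")
}

#' Representative trajectory of a mesh transition
#'
#' The step trajectory stored for transition `i -> j`: the one generated by
#' the median of the perturbations realising that transition.
#'
#' @param mesh A `deterministic_mesh`.
#' @param i,j Start and end state indices.
#' @return A `step_trajectory`.
#' @export
mesh_trajectory <- function(mesh, i, j) {
  s <- mesh$rep_pert[i, j]
  if (is.na(s)) stop(sprintf("no transition %d -> %d in the mesh", i, j))
  synth_trajectory(mesh$config, mesh$states[i, ], s)
}

# All realised transitions of a mesh as a data frame (i, j, s_rep).
mesh_transition_list <- function(mesh) {
  idx <- which(!is.na(mesh$rep_pert), arr.ind = TRUE)
  data.frame(i = idx[, 1], j = idx[, 2],
             s_rep = mesh$rep_pert[idx])
}

#' @export
print.deterministic_mesh <- function(x, ...) {
  n_fail <- sum(x$transitions == 0L)
  cat(sprintf(
    "Deterministic mesh: %d states x %d perturbations (%d transitions, %d to failure)\n",
    nrow(x$states), ncol(x$transitions), length(x$transitions), n_fail))
  cat(sprintf("  %d distinct realised transitions\n",
              sum(!is.na(x$rep_pert))))
  invisible(x)
}

#' Draw per-step perturbation vectors
#'
#' Gaussian perturbation sequences N(0, noise_sd^2), truncated to the
#' perturbation grid range, for use with [simulate_brute()]. The same
#' vectors can be reused across walker configurations.
#'
#' @param n_vectors Number of vectors.
#' @param n_steps Length of each vector.
#' @param noise_sd Perturbation standard deviation (m/s).
#' @param max_abs Truncation bound (m/s); draws beyond it are clipped.
#' @param seed Integer seed.
#' @return A list of numeric vectors.
#' @export
perturbation_vectors <- function(n_vectors, n_steps, noise_sd = 0.013,
                                 max_abs = 0.200, seed = 1L) {
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, {
    lapply(seq_len(n_vectors), function(k) {
      pmin(pmax(stats::rnorm(n_steps, 0, noise_sd), -max_abs), max_abs)
    })
  })
}

#' Brute-force simulation of perturbed walking
#'
#' Simulates the walker from the nominal state with a perturbation applied
#' every step, using the continuous (un-snapped) return map. Each trial ends
#' at `n_steps` completed steps or at the first failure; the failing partial
#' step is not included.
#'
#' @param config A [walker_config()].
#' @param perturbation_vectors List of numeric perturbation sequences (m/s),
#'   each of length at least `n_steps`, e.g. from [perturbation_vectors()].
#' @param n_steps Number of steps per trial.
#' @return A list of trials; each trial is a list of `step_trajectory`
#'   objects with attributes `failed` (logical: did the trial end in a fall)
#'   and `n_completed`.
#' @export
simulate_brute <- function(config, perturbation_vectors, n_steps) {
  stopifnot(inherits(config, "walker_config"))
  lapply(perturbation_vectors, function(pv) {
    if (length(pv) < n_steps)
      stop("perturbation vector shorter than n_steps")
    steps <- vector("list", n_steps)
    x <- config$fixed_point
    failed <- FALSE
    k <- 0L
    for (t in seq_len(n_steps)) {
      mp <- step_map(config, x, pv[t])
      if (mp$failed) { failed <- TRUE; break }
      k <- t
      steps[[t]] <- synth_trajectory(config, x, pv[t])
      x <- mp$state
    }
    steps <- steps[seq_len(k)]
    attr(steps, "failed") <- failed
    attr(steps, "n_completed") <- k
    steps
  })
}

#' Generate surviving fixed-length brute-force segments
#'
#' Keeps simulating fresh trials until `n_segments` disjoint surviving
#' segments of `n_steps` steps are available (e.g. 200 trajectories of 50
#' steps), or an attempt cap is hit.
#'
#' @param config A [walker_config()].
#' @param n_segments Number of segments required.
#' @param n_steps Steps per segment.
#' @param trial_steps Steps per simulated trial (segments are cut from
#'   trials; defaults to `n_steps`).
#' @param seed Integer seed for the perturbation draws.
#' @param max_trials Attempt cap on the number of simulated trials.
#' @return A list of `n_segments` step sequences (or fewer, with a warning,
#'   if the cap is reached).
#' @export
brute_segments <- function(config, n_segments, n_steps,
                           trial_steps = n_steps, seed = 1L,
                           max_trials = 50L * n_segments) {
  segs <- list()
  trial <- 0L
  while (length(segs) < n_segments && trial < max_trials) {
    batch <- min(max(n_segments, 10L), max_trials - trial)
    pv <- perturbation_vectors(batch, trial_steps, config$noise_sd,
                               max(abs(config$pert_grid)),
                               seed = seed + trial)
    trials <- simulate_brute(config, pv, trial_steps)
    trial <- trial + batch
    segs <- c(segs, segment_trials(trials, n_steps))
  }
  if (length(segs) < n_segments)
    warning(sprintf("only %d of %d segments obtained within the trial cap",
                    length(segs), n_segments))
  segs[seq_len(min(n_segments, length(segs)))]
}
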