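# The 49 fall-risk metrics computed directly from the absorbing Markov
# chain: per-state perturbation-probability-weighted step statistics, pooled
# across states with the expected visit counts as frequency weights, plus
# the chain-sampled Lyapunov procedure.

#' Per-state weighted step statistics of a step-level quantity
#'
#' For each transient state i, the mean and standard deviation of a
#' step-level quantity over the surviving transitions out of i, weighted by
#' the perturbation probability mass of each transition:
#' `mu_i = sum_j P_ij rho_ij / sum_j P_ij` and
#' `sigma_i^2 = sum_j P_ij (rho_ij - mu_i)^2 / sum_j P_ij`.
#' Failed transitions are excluded from numerator and denominator (the
#' walker takes no complete step on them).
#'
#' @param mesh A `deterministic_mesh`.
#' @param chain The `absorbing_chain` built from it.
#' @param quantity_extractor Function mapping a `step_trajectory` to a
#'   scalar (e.g. [xcom_step_max()], or `function(tr) tr$T`).
#' @return An object of class `weighted_step_stats`: `mu` and `sigma` per
#'   state (`NA` for states with no surviving mass, which are excluded with
#'   a warning) and `survive_mass`.
#' @export
weighted_step_stats <- function(mesh, chain, quantity_extractor) {
  stopifnot(inherits(mesh, "deterministic_mesh"),
            inherits(chain, "absorbing_chain"))
  tl <- mesh_transition_list(mesh)
  rho <- vapply(seq_len(nrow(tl)), function(r) {
    quantity_extractor(mesh_trajectory(mesh, tl$i[r], tl$j[r]))
  }, numeric(1))
  weighted_stats_from_rho(chain, cbind(tl$i, tl$j), rho)
}

# Per-state weighted mean/SD given precomputed transition values rho
# (one per realised transition, indexed by ij = cbind(i, j)).
weighted_stats_from_rho <- function(chain, ij, rho) {
  Q <- chain$Q
  t_n <- nrow(Q)
  w_tr <- Q[ij]
  sm <- rowSums(Q)
  mu <- sigma <- rep(NA_real_, t_n)
  for (i in seq_len(t_n)) {
    if (sm[i] <= 0) next
    sel <- which(ij[, 1] == i & w_tr > 0)
    w <- w_tr[sel]
    mu[i] <- sum(w * rho[sel]) / sm[i]
    sigma[i] <- sqrt(sum(w * (rho[sel] - mu[i])^2) / sm[i])
  }
  if (any(sm <= 0))
    warning(sprintf("%d state(s) with no surviving transitions excluded",
                    sum(sm <= 0)))
  structure(list(mu = mu, sigma = sigma, survive_mass = sm),
            class = "weighted_step_stats")
}

#' Pool per-state statistics into an overall chain metric
#'
#' Expected visit counts from the nominal state are used as frequency
#' weights: `mu = sum_i n1_i mu_i / sum_i n1_i` and
#' `sigma^2 = sum_i n1_i (sigma_i^2 + (mu_i - mu)^2) / sum_i n1_i`
#' (the weighted law of total variance).
#'
#' @param stats A [weighted_step_stats()] result.
#' @param n1 Expected visit counts (row 1 of the fundamental matrix), same
#'   state set as `stats`.
#' @return Named numeric vector `c(mu =, sigma =)`.
#' @export
chain_metric <- function(stats, n1) {
  stopifnot(inherits(stats, "weighted_step_stats"))
  if (length(n1) != length(stats$mu))
    stop("n1 and stats cover different state sets")
  keep <- !is.na(stats$mu)
  w <- n1[keep]
  if (sum(w) <= 0) stop("total visit weight is zero")
  mu <- sum(w * stats$mu[keep]) / sum(w)
  sig2 <- sum(w * (stats$sigma[keep]^2 + (stats$mu[keep] - mu)^2)) / sum(w)
  c(mu = mu, sigma = sqrt(max(sig2, 0)))
}

# Chain version of the joint variability metrics: the per-state,
# per-time-point weighted mean and SD over surviving transitions, pooled
# across states with the n1 weights, then log (floored) and time-averaged --
# mirroring the brute-force definition with the weighted statistics standing
# in for the plain mean and SD.
chain_joint_variability <- function(mesh, chain, n1, d_floor = 1e-7,
                                    V = NULL, ij = NULL) {
  coords <- variability_coords()
  Q <- chain$Q
  t_n <- nrow(Q)
  if (is.null(V)) {
    tl <- mesh_transition_list(mesh)
    ij <- cbind(tl$i, tl$j)
    V <- t(vapply(seq_len(nrow(tl)), function(r) {
      as.numeric(mesh_trajectory(mesh, tl$i[r], tl$j[r])$samples[, coords])
    }, numeric(100L * length(coords))))
  }
  n_col <- ncol(V)
  mu_i <- matrix(NA_real_, t_n, n_col)
  m2_i <- matrix(NA_real_, t_n, n_col)  # weighted second moment
  w_i <- numeric(t_n)
  for (i in seq_len(t_n)) {
    rows <- which(ij[, 1] == i)
    if (!length(rows)) next
    w <- Q[cbind(i, ij[rows, 2])]
    if (sum(w) <= 0) next
    w_i[i] <- sum(w)
    Vi <- V[rows, , drop = FALSE]
    mu_i[i, ] <- colSums(Vi * w) / sum(w)
    m2_i[i, ] <- colSums(Vi^2 * w) / sum(w)
  }
  keep <- w_i > 0 & !is.na(n1)
  w <- n1[keep]
  mu <- colSums(mu_i[keep, , drop = FALSE] * w) / sum(w)
  # pooled variance = E_w[sigma_i^2 + (mu_i - mu)^2]
  sig2_i <- m2_i[keep, , drop = FALSE] - mu_i[keep, , drop = FALSE]^2
  dev2 <- sweep(mu_i[keep, , drop = FALSE], 2, mu)^2
  sig2 <- colSums((sig2_i + dev2) * w) / sum(w)
  sig <- sqrt(pmax(sig2, 0))
  out <- vapply(seq_along(coords), function(ci) {
    mean(log(pmax(sig[(ci - 1L) * 100L + 1:100], d_floor)))
  }, numeric(1))
  stats::setNames(out, paste0("jvar_", coords))
}

#' Chain-sampled Lyapunov exponents
#'
#' Starting from the states with the largest expected visit counts, samples
#' fixed-length random trajectories through the chain (re-drawing, up to a
#' retry cap, trajectories absorbed early), computes each coordinate's
#' short- and long-term Lyapunov exponents per trajectory with the distance
#' floor, and pools them by a weighted mean with weight
#' `n1_i * (1 / n_vectors)`, normalised to sum to 1.
#'
#' @param chain An `absorbing_chain`.
#' @param mesh The mesh it was built from.
#' @param cfg An [embedding_config()].
#' @param n_states Number of top-visit-count start states (default 20; all
#'   states, with a warning, if the chain has fewer).
#' @param n_vectors Random perturbation vectors (trajectories) per start
#'   state (default 20).
#' @param n_steps Steps per trajectory (default 50).
#' @param seed Integer seed.
#' @param retry_cap Redraws allowed per trajectory before it is dropped
#'   (with weight renormalisation and a warning).
#' @param coords Coordinates to compute (default: all 12 joint angles and
#'   velocities); restricting them cuts the cost proportionally.
#' @return Named numeric vector of the pooled exponents
#'   (`lyap_s_*`, `lyap_l_*` per coordinate), with attribute `detail`
#'   holding the per-trajectory values and weights.
#' @export
chain_lyapunov <- function(chain, mesh, cfg = embedding_config(),
                           n_states = 20L, n_vectors = 20L, n_steps = 50L,
                           seed = 1L, retry_cap = 20L,
                           coords = lyapunov_coords()) {
  st <- chain_statistics(chain)
  t_n <- nrow(chain$Q)
  if (t_n < n_states) {
    warning(sprintf("chain has %d transient states < n_states = %d: using all",
                    t_n, n_states))
    n_states <- t_n
  }
  starts <- order(st$n1, decreasing = TRUE)[seq_len(n_states)]
  lam <- array(NA_real_, c(n_states, n_vectors, 2L * length(coords)))
  wts <- matrix(0, n_states, n_vectors)
  dropped <- 0L
  for (a in seq_len(n_states)) {
    for (v in seq_len(n_vectors)) {
      traj <- NULL
      for (try in 0:retry_cap) {
        sub_seed <- (seed * 1000L + a * 100L + v * 7L + try * 131L) %%
          .Machine$integer.max
        cand <- sample_chain_trajectory(chain, mesh, starts[a], n_steps,
                                        seed = sub_seed)
        if (attr(cand, "n_completed") == n_steps) { traj <- cand; break }
      }
      if (is.null(traj)) { dropped <- dropped + 1L; next }
      wts[a, v] <- st$n1[starts[a]] / n_vectors
      for (ci in seq_along(coords)) {
        series <- unlist(lapply(traj, function(s) s$samples[, coords[ci]]),
                         use.names = FALSE)
        lv <- lyapunov_exponents(
          divergence_curve(series, cfg, indices = fit_indices(cfg)), cfg)
        lam[a, v, ci] <- lv[["lambda_s"]]
        lam[a, v, length(coords) + ci] <- lv[["lambda_l"]]
      }
    }
  }
  if (dropped > 0L)
    warning(sprintf("%d trajectory(ies) absorbed before %d steps dropped after %d retries",
                    dropped, n_steps, retry_cap))
  w <- as.numeric(wts)
  w <- w / sum(w)
  out <- vapply(seq_len(dim(lam)[3]), function(m) {
    v <- as.numeric(lam[, , m])
    sum(w * ifelse(is.na(v), 0, v))
  }, numeric(1))
  names(out) <- c(paste0("lyap_s_", coords), paste0("lyap_l_", coords))
  attr(out, "detail") <- list(values = lam, weights = w, starts = starts)
  out
}

#' Assemble the 49-metric vector directly from the Markov chain
#'
#' Non-Lyapunov metrics via the visit-weighted statistics
#' ([weighted_step_stats()], [chain_metric()]); Lyapunov entries via
#' [chain_lyapunov()] when requested, `NA` otherwise.
#'
#' @param chain An `absorbing_chain`.
#' @param mesh The mesh it was built from.
#' @param cfg An [embedding_config()].
#' @param g Gravitational acceleration (m/s^2).
#' @param lyapunov Compute the 24 chain-sampled Lyapunov entries? These are
#'   by far the most expensive part.
#' @param ... Passed to [chain_lyapunov()] (`n_states`, `n_vectors`,
#'   `n_steps`, `seed`, `retry_cap`).
#' @return A `metric_vector` with `provenance = "chain"`.
#' @export
chain_metric_vector <- function(chain, mesh, cfg = embedding_config(),
                                g = 9.81, lyapunov = FALSE, ...) {
  st <- chain_statistics(chain)
  out <- stats::setNames(rep(NA_real_, 49L), metric_names())
  # one synthesis pass over all realised transitions
  tl <- mesh_transition_list(mesh)
  coords <- variability_coords()
  ij <- cbind(tl$i, tl$j)
  rho <- matrix(NA_real_, nrow(tl), 5L,
                dimnames = list(NULL, c("xcom", "fri", "speed",
                                        "step_length", "step_duration")))
  V <- matrix(NA_real_, nrow(tl), 100L * length(coords))
  for (r in seq_len(nrow(tl))) {
    tr <- mesh_trajectory(mesh, tl$i[r], tl$j[r])
    rho[r, ] <- c(xcom_step_max(tr, g = g), fri_step_max(tr),
                  tr$v, tr$L, tr$T)
    V[r, ] <- as.numeric(tr$samples[, coords])
  }
  for (nm in colnames(rho)) {
    cm <- chain_metric(weighted_stats_from_rho(chain, ij, rho[, nm]),
                       st$n1)
    out[paste0(nm, "_mean")] <- cm[["mu"]]
    out[paste0(nm, "_sd")] <- cm[["sigma"]]
  }
  jv <- chain_joint_variability(mesh, chain, st$n1, d_floor = cfg$d_floor,
                                V = V, ij = ij)
  out[names(jv)] <- jv
  if (lyapunov) {
    ly <- chain_lyapunov(chain, mesh, cfg, ...)
    out[names(ly)] <- as.numeric(ly)
  }
  structure(out, provenance = "chain", n_steps = NA_integer_,
            class = "metric_vector")
}
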