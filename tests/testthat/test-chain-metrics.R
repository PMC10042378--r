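# Chain-side metric statistics: perturbation-weighted per-state moments,
# visit-weighted pooling, and the chain-sampled Lyapunov procedure.

test_that("pooling follows the weighted law of total variance", {
  # n1 = (1, 1), mu_i = (0, 2), sigma_i = (0, 0) -> mu = 1, sigma = 1
  cm <- chain_metric(forge_stats(c(0, 2), c(0, 0)), c(1, 1))
  expect_equal(unname(cm), c(1, 1))
  # pooling identity: equal per-state moments pass through
  cm2 <- chain_metric(forge_stats(rep(2.5, 4), rep(0.3, 4)),
                      c(5, 1, 7, 2))
  expect_equal(unname(cm2), c(2.5, 0.3))
  # mixture-moments oracle on a random 5-state case
  withr::with_seed(13, {
    mu_i <- stats::rnorm(5)
    s_i <- stats::runif(5, 0.1, 2)
    n1 <- stats::runif(5, 0.5, 10)
  })
  w <- n1 / sum(n1)
  mix_mean <- sum(w * mu_i)
  mix_e2 <- sum(w * (s_i^2 + mu_i^2))
  cm3 <- chain_metric(forge_stats(mu_i, s_i), n1)
  expect_equal(unname(cm3["mu"]), mix_mean, tolerance = 1e-12)
  expect_equal(unname(cm3["sigma"]), sqrt(mix_e2 - mix_mean^2),
               tolerance = 1e-12)
  expect_error(chain_metric(forge_stats(1, 0), c(1, 2)), "state set")
})

test_that("per-state weighted stats match brute enumeration over perturbations", {
  cfg <- tiny_walker(grid_half_n = 2L, fail_bound = 0.04)
  mesh <- build_deterministic_mesh(cfg)
  chain <- build_chain(mesh)
  mass <- chain$cell_masses
  ws <- weighted_step_stats(mesh, chain, function(tr) tr$T)
  for (i in seq_len(nrow(chain$Q))) {
    # enumerate every grid perturbation; rho is the stored (i, j) value
    num <- den <- num2 <- 0
    for (s in seq_along(mass)) {
      j <- mesh$transitions[i, s]
      if (j == 0L) next
      rho <- mesh_trajectory(mesh, i, j)$T
      den <- den + mass[s]
      num <- num + mass[s] * rho
      num2 <- num2 + mass[s] * rho^2
    }
    expect_equal(ws$mu[i], num / den, tolerance = 1e-12)
    expect_equal(ws$sigma[i], sqrt(num2 / den - (num / den)^2),
                 tolerance = 1e-8)
  }
  # uniform rho gives mu = c, sigma = 0
  ws2 <- weighted_step_stats(mesh, chain, function(tr) 42)
  expect_equal(ws2$mu, rep(42, 5))
  expect_equal(ws2$sigma, rep(0, 5))
})

test_that("weighted statistics equal full mixture enumeration on small chains", {
  # explicit discrete per-state step distributions (<= 5 states, <= 9
  # perturbation cells), pooled with expected-visit weights: Eqs for the
  # per-state and pooled moments must reproduce the directly enumerated
  # mixture moments to 1e-10
  withr::with_seed(29, {
    for (rep_k in 1:3) {
      t_n <- sample(2:5, 1)
      n_pert <- sample(3:9, 1)
      vals <- matrix(stats::rnorm(t_n * n_pert), t_n)
      pr <- matrix(stats::runif(t_n * n_pert, 0.05, 1), t_n)
      pr <- pr / rowSums(pr)
      n1 <- stats::runif(t_n, 0.1, 5)
      mu_i <- rowSums(pr * vals)
      s_i <- sqrt(rowSums(pr * (vals - mu_i)^2))
      pooled <- chain_metric(forge_stats(mu_i, s_i), n1)
      # direct enumeration over every (state, perturbation) pair
      w_pair <- (n1 / sum(n1)) * pr
      mean_direct <- sum(w_pair * vals)
      var_direct <- sum(w_pair * (vals - mean_direct)^2)
      expect_equal(unname(pooled["mu"]), mean_direct, tolerance = 1e-10)
      expect_equal(unname(pooled["sigma"]), sqrt(var_direct),
                   tolerance = 1e-10)
    }
  })
})

test_that("zero-probability transitions do not affect chain metrics", {
  # two forged meshes differing only in where zero-mass (far-tail)
  # perturbations land must give identical metric vectors
  cfg <- tiny_walker(grid_half_n = 2L, fail_bound = 0.04)
  mesh1 <- build_deterministic_mesh(cfg)
  chain <- build_chain(mesh1)
  zero_cells <- which(chain$cell_masses == 0)
  expect_gt(length(zero_cells), 0)
  mesh2 <- mesh1
  mesh2$transitions[, zero_cells] <- 0L  # reroute zero-mass cells to FAIL
  # rebuild representative perturbations for the altered transition sets
  for (i in seq_len(nrow(mesh2$states))) {
    for (j in seq_len(nrow(mesh2$states))) {
      ss <- cfg$pert_grid[mesh2$transitions[i, ] == j]
      mesh2$rep_pert[i, j] <- if (length(ss)) ss[ceiling(length(ss) / 2)]
      else NA_real_
    }
  }
  chain2 <- build_chain(mesh2)
  expect_equal(chain$Q, chain2$Q)
  v1 <- chain_metric_vector(chain, mesh1)
  v2 <- chain_metric_vector(chain2, mesh2)
  nl <- !grepl("^lyap", metric_names())
  expect_equal(as.numeric(v1)[nl], as.numeric(v2)[nl])
})

test_that("a degenerate single-transition chain reproduces the repeated-step metrics", {
  cfg <- walker_config(a = 0, b = 0.2, fail_bound = 0.03,
                       grid_half_n = 0L, timing = "DS0", noise_sd = 0.05)
  mesh <- build_deterministic_mesh(cfg)
  chain <- build_chain(mesh)
  expect_lt(chain$Q[1, 1], 1)  # far perturbations fail, so it absorbs
  cv <- chain_metric_vector(chain, mesh)
  rep_step <- mesh_trajectory(mesh, 1L, 1L)
  bv <- metric_vector_from_steps(rep(list(rep_step), 10L), lyapunov = FALSE)
  nl <- !grepl("^lyap", metric_names())
  expect_equal(as.numeric(cv)[nl], as.numeric(bv)[nl], tolerance = 1e-10)
  expect_identical(attr(cv, "provenance"), "chain")
  expect_length(cv, 49L)
})

test_that("chain joint variability equals the brute definition under matched weights", {
  cfg <- tiny_walker(grid_half_n = 2L, fail_bound = 0.04)
  mesh <- build_deterministic_mesh(cfg)
  chain <- build_chain(mesh)
  st <- chain_statistics(chain)
  cv <- chain_metric_vector(chain, mesh)
  # oracle for one coordinate: enumerate the mixture of per-transition
  # waveforms with joint weights n1_i * Q_ij, per time point
  co <- "q4"
  tl <- fallrisk:::mesh_transition_list(mesh)
  # joint weight of transition (i, j): visit weight times the conditional
  # surviving-transition probability Q_ij / sum_j Q_ij
  W <- st$n1[tl$i] * chain$Q[cbind(tl$i, tl$j)] /
    rowSums(chain$Q)[tl$i]
  V <- vapply(seq_len(nrow(tl)), function(r) {
    mesh_trajectory(mesh, tl$i[r], tl$j[r])$samples[, co]
  }, numeric(100))
  # mixture SD at each time point, with the population (mass-weighted) form
  m_t <- as.numeric(V %*% W) / sum(W)
  s_t <- sqrt(as.numeric(V^2 %*% W) / sum(W) - m_t^2)
  oracle <- mean(log(pmax(s_t, 1e-7)))
  expect_equal(unname(cv[paste0("jvar_", co)]), oracle, tolerance = 1e-8)
})

test_that("the chain-sampled Lyapunov procedure pools trajectories with normalized weights", {
  cfg <- tiny_walker(grid_half_n = 2L, fail_bound = 0.045)
  mesh <- build_deterministic_mesh(cfg)
  chain <- build_chain(mesh)
  ecfg <- embedding_config(short_range = c(1L, 50L),
                           long_range = c(101L, 300L),
                           min_lyap_steps = 10L)
  expect_warning(
    cl <- chain_lyapunov(chain, mesh, ecfg, n_states = 30L, n_vectors = 2L,
                         n_steps = 10L, seed = 3, coords = c("q2", "dq2")),
    "using all")
  expect_named(cl, c("lyap_s_q2", "lyap_s_dq2", "lyap_l_q2", "lyap_l_dq2"))
  detail <- attr(cl, "detail")
  expect_equal(sum(detail$weights), 1)
  expect_true(all(detail$weights >= 0))
  # reproducible
  cl2 <- suppressWarnings(
    chain_lyapunov(chain, mesh, ecfg, n_states = 30L, n_vectors = 2L,
                   n_steps = 10L, seed = 3, coords = c("q2", "dq2")))
  expect_equal(as.numeric(cl), as.numeric(cl2))
})

test_that("chain and brute long-term Lyapunov exponents agree within one brute SD", {
  # a stable preset: the same estimator applied to chain-sampled and
  # continuous brute data should agree for the long-term exponent (the
  # short-term one is expected to disagree, as in the discretized case)
  cfg <- bank_config(0.8, "A", "SS0.5")
  mesh <- build_deterministic_mesh(cfg)
  chain <- build_chain(mesh)
  ecfg <- embedding_config(short_range = c(1L, 100L),
                           long_range = c(401L, 1000L),
                           min_lyap_steps = 25L)
  cl <- chain_lyapunov(chain, mesh, ecfg, n_states = 4L, n_vectors = 3L,
                       n_steps = 25L, seed = 17, coords = "q2")
  segs <- brute_segments(cfg, 30, 25, seed = 99)
  brute_ll <- vapply(segs, function(sg) {
    series <- unlist(lapply(sg, function(s) s$samples[, "q2"]))
    lyapunov_exponents(
      divergence_curve(series, ecfg,
                       indices = fallrisk:::fit_indices(ecfg)),
      ecfg)[["lambda_l"]]
  }, numeric(1))
  expect_lt(abs(cl[["lyap_l_q2"]] - mean(brute_ll)), stats::sd(brute_ll))
})
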