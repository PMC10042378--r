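# Absorbing Markov chain built from a deterministic transition mesh, and
# its first-passage statistics.

# Probability mass of each perturbation grid cell under N(0, noise_sd^2).
# Cells are the half-open intervals between midpoints of adjacent grid
# perturbations; the two boundary cells absorb the Gaussian tails so the
# masses sum to exactly 1.
pert_cell_masses <- function(pert_grid, noise_sd) {
  edges <- c(-Inf, (pert_grid[-1] + pert_grid[-length(pert_grid)]) / 2, Inf)
  diff(stats::pnorm(edges, mean = 0, sd = noise_sd))
}

#' Build the stochastic absorbing Markov chain from a mesh
#'
#' Assigns each grid perturbation the Gaussian probability mass of its grid
#' cell (cell edges at midpoints between adjacent perturbations, tails folded
#' into the extreme cells) and accumulates these masses into the
#' substochastic transient-transition matrix `Q` and the failure column `R`.
#'
#' @param mesh A [build_deterministic_mesh()] result.
#' @param noise_sd Perturbation standard deviation (m/s); defaults to the
#'   mesh config's `noise_sd`.
#' @return An object of class `absorbing_chain`: `Q` (t x t), `R` (length-t
#'   failure probabilities), `cell_masses`, `state_labels` and `mesh_ref`
#'   (the mesh states).
#' @export
build_chain <- function(mesh, noise_sd = mesh$config$noise_sd) {
  stopifnot(inherits(mesh, "deterministic_mesh"))
  if (noise_sd <= 0) stop("noise_sd must be positive")
  trans <- mesh$transitions
  t_n <- nrow(trans)
  if (t_n == 0L) stop("mesh has no states")
  mass <- pert_cell_masses(mesh$config$pert_grid, noise_sd)
  Q <- matrix(0, t_n, t_n)
  R <- numeric(t_n)
  for (i in seq_len(t_n)) {
    ji <- trans[i, ]
    R[i] <- sum(mass[ji == 0L])
    tab <- rowsum(mass[ji != 0L], ji[ji != 0L])
    Q[i, as.integer(rownames(tab))] <- tab[, 1]
  }
  bad <- abs(rowSums(Q) + R - 1) > 1e-12
  if (any(bad))
    stop("internal error: chain rows do not sum to 1")
  structure(list(Q = Q, R = R, cell_masses = mass,
                 state_labels = seq_len(t_n),
                 mesh_ref = mesh$states),
            class = "absorbing_chain")
}

#' @export
print.absorbing_chain <- function(x, ...) {
  cat(sprintf("Absorbing Markov chain: %d transient states + 1 absorbing\n",
              nrow(x$Q)))
  cat(sprintf("  failure probability from nominal state: %.3g\n", x$R[1]))
  invisible(x)
}

#' First-passage statistics of an absorbing chain
#'
#' Computes the fundamental matrix `N = (I - Q)^-1` (by a dense linear solve,
#' not explicit inversion), the expected visit counts from the nominal state
#' `n1 = N[1, ]`, the largest-magnitude eigenvalue of `Q` (the second-largest
#' eigenvalue of the full stochastic transition matrix), and the mean first
#' passage time to the fall both ways: `mfpt_eigen = -1 / log(lambda2)` and
#' `mfpt_exact = sum(n1)`.
#'
#' @param chain An [build_chain()] result.
#' @return An object of class `chain_statistics` with elements `N`, `n1`,
#'   `lambda2`, `mfpt_eigen` and `mfpt_exact`.
#' @export
chain_statistics <- function(chain) {
  stopifnot(inherits(chain, "absorbing_chain"))
  Q <- chain$Q
  ev <- eigen(Q, only.values = TRUE)$values
  lambda2 <- max(Mod(ev))
  if (lambda2 >= 1)
    stop("spectral radius of Q is >= 1: the chain is not absorbing")
  N <- solve(diag(nrow(Q)) - Q)
  n1 <- N[1, ]
  mfpt_exact <- sum(n1)
  mfpt_eigen <- if (lambda2 <= 0) NA_real_ else -1 / log(lambda2)
  structure(list(N = N, n1 = n1, lambda2 = lambda2,
                 mfpt_eigen = mfpt_eigen, mfpt_exact = mfpt_exact),
            class = "chain_statistics")
}

#' @export
print.chain_statistics <- function(x, ...) {
  cat("Absorbing-chain first-passage statistics\n")
  cat(sprintf("  lambda2     = %.12g\n", x$lambda2))
  cat(sprintf("  MFPT (eigen) = %.6g steps\n", x$mfpt_eigen))
  cat(sprintf("  MFPT (exact) = %.6g steps\n", x$mfpt_exact))
  invisible(x)
}

#' Mean first passage time of a walker configuration
#'
#' Convenience wrapper: mesh, chain and statistics in one call.
#'
#' @param config A [walker_config()].
#' @param which `"eigen"` for the eigenvalue approximation (the default used
#'   as the true MFPT downstream) or `"exact"` for the fundamental-matrix
#'   row sum.
#' @return MFPT in steps.
#' @export
walker_mfpt <- function(config, which = c("eigen", "exact")) {
  which <- match.arg(which)
  st <- chain_statistics(build_chain(build_deterministic_mesh(config)))
  if (which == "eigen") st$mfpt_eigen else st$mfpt_exact
}

#' Sample a random trajectory through the Markov chain
#'
#' Draws a perturbation grid cell per step from the same Gaussian cell
#' masses used by [build_chain()], follows the mesh transition it realises,
#' and appends the mesh's stored (median-perturbation) trajectory for that
#' transition. Terminates early on absorption.
#'
#' @param chain An `absorbing_chain`.
#' @param mesh The mesh the chain was built from.
#' @param start_state Transient start state index (default 1, the nominal
#'   step).
#' @param n_steps Maximum number of steps.
#' @param seed Integer seed.
#' @return A list of `step_trajectory` objects with attributes `failed`,
#'   `n_completed` and `state_path`.
#' @export
sample_chain_trajectory <- function(chain, mesh, start_state = 1L, n_steps,
                                    seed = 1L) {
  stopifnot(inherits(chain, "absorbing_chain"),
            inherits(mesh, "deterministic_mesh"))
  if (start_state < 1L || start_state > nrow(chain$Q))
    stop("start_state is not a transient state of the chain")
  mass <- chain$cell_masses
  trans <- mesh$transitions
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, {
    steps <- vector("list", n_steps)
    path <- integer(n_steps + 1L)
    path[1L] <- i <- as.integer(start_state)
    failed <- FALSE
    k <- 0L
    cells <- sample.int(length(mass), n_steps, replace = TRUE, prob = mass)
    cache <- new.env(parent = emptyenv())
    for (t in seq_len(n_steps)) {
      j <- trans[i, cells[t]]
      if (j == 0L) { failed <- TRUE; break }
      k <- t
      key <- paste0(i, "->", j)
      if (is.null(cache[[key]]))
        cache[[key]] <- mesh_trajectory(mesh, i, j)
      steps[[t]] <- cache[[key]]
      path[t + 1L] <- j
      i <- j
    }
    steps <- steps[seq_len(k)]
    attr(steps, "failed") <- failed
    attr(steps, "n_completed") <- k
    attr(steps, "state_path") <- path[seq_len(k + 1L)]
    steps
  })
}
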