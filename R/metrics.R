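# Per-step and per-sequence fall-risk metrics computed from step
# trajectories (the brute-force route).

#' Names of the 49 fall-risk metrics
#'
#' Mean and standard deviation of the per-step maxima of the extrapolated
#' centre of mass (XCoM) and the foot rotation index (FRI), mean and SD of
#' speed, step length and step duration, short- and long-term Lyapunov
#' exponents of the six joint angles and their velocities (12 + 12), and
#' the mean log variability of the 15 cyclical coordinates (q1..q6, q8 and
#' all eight velocities; the horizontal hip position q7 is excluded because
#' it is not cyclical).
#'
#' @return Character vector of length 49.
#' @export
metric_names <- function() {
  lyco <- c(paste0("q", 1:6), paste0("dq", 1:6))
  jvco <- c(paste0("q", 1:6), "q8", paste0("dq", 1:8))
  c("xcom_mean", "xcom_sd", "fri_mean", "fri_sd",
    "speed_mean", "speed_sd", "step_length_mean", "step_length_sd",
    "step_duration_mean", "step_duration_sd",
    paste0("lyap_s_", lyco), paste0("lyap_l_", lyco),
    paste0("jvar_", jvco))
}

# Coordinates used for the Lyapunov metrics / joint variability.
lyapunov_coords <- function() c(paste0("q", 1:6), paste0("dq", 1:6))
variability_coords <- function() c(paste0("q", 1:6), "q8", paste0("dq", 1:8))

#' Per-step maximum of the extrapolated centre of mass
#'
#' At each of the 100 samples, XCoM = (x7 - xst) + dx7 * sqrt(l / g), where
#' l is the hip-to-stance-contact distance
#' sqrt((x7 - xst)^2 + (x8 - yst)^2). Returns the maximum over the step.
#'
#' @param traj A `step_trajectory`.
#' @param g Gravitational acceleration (m/s^2).
#' @return Maximum XCoM over the step (m).
#' @export
xcom_step_max <- function(traj, g = 9.81) {
  s <- traj$samples
  dx <- s[, "q7"] - s[, "xst"]
  dy <- s[, "q8"] - s[, "yst"]
  l <- sqrt(dx^2 + dy^2)
  if (any(l == 0)) stop("degenerate geometry: hip coincides with stance contact")
  max(dx + s[, "dq7"] * sqrt(l / g))
}

#' Per-step maximum of the foot rotation index
#'
#' At each sample the FRI is the ground point where the net reaction force
#' would have to act to keep the stance foot from rotating:
#' `(cross(OG, Fg) - cross(OA, Fa) - tau_a) / Fn - xst`, with planar cross
#' products taken about the origin (z components) and Fn the normal ground
#' reaction force. Returns the maximum over the step.
#'
#' @param traj A `step_trajectory`.
#' @return Maximum FRI over the step (m).
#' @export
fri_step_max <- function(traj) {
  s <- traj$samples
  if (any(s[, "Fn"] <= 0)) stop("failed step: non-positive normal force")
  cross_g <- s[, "Gx"] * s[, "Fgy"] - s[, "Gy"] * s[, "Fgx"]
  cross_a <- s[, "Ax"] * s[, "Fay"] - s[, "Ay"] * s[, "Fax"]
  max((cross_g - cross_a - s[, "tau_a"]) / s[, "Fn"] - s[, "xst"])
}

#' Spatiotemporal statistics of a step sequence
#'
#' Mean and sample standard deviation of the per-step speed, step length and
#' step duration.
#'
#' @param steps List of `step_trajectory` objects (at least 2).
#' @return Named numeric vector: `speed_mean`, `speed_sd`,
#'   `step_length_mean`, `step_length_sd`, `step_duration_mean`,
#'   `step_duration_sd`.
#' @export
spatiotemporal_stats <- function(steps) {
  if (length(steps) < 2L)
    stop("at least 2 steps are required (SD undefined otherwise)")
  v <- vapply(steps, `[[`, numeric(1), "v")
  L <- vapply(steps, `[[`, numeric(1), "L")
  T <- vapply(steps, `[[`, numeric(1), "T")
  c(speed_mean = mean(v), speed_sd = stats::sd(v),
    step_length_mean = mean(L), step_length_sd = stats::sd(L),
    step_duration_mean = mean(T), step_duration_sd = stats::sd(T))
}

#' Joint variability of a step sequence
#'
#' For each of the 15 cyclical coordinates: the standard deviation across
#' steps at each of the 100 time points, floored at `d_floor`, logged, and
#' averaged over the step. The floor keeps identical (noise-free) steps
#' finite.
#'
#' @param steps List of aligned 100-sample `step_trajectory` objects
#'   (at least 2).
#' @param d_floor Numerical floor applied to each SD before the log.
#' @return Named numeric vector of 15 `jvar_*` values.
#' @export
joint_variability <- function(steps, d_floor = 1e-7) {
  if (length(steps) < 2L) stop("at least 2 steps are required")
  coords <- variability_coords()
  out <- vapply(coords, function(co) {
    M <- vapply(steps, function(st) st$samples[, co], numeric(100))
    sds <- sqrt(pmax(0, rowSums((M - rowMeans(M))^2) / (ncol(M) - 1)))
    mean(log(pmax(sds, d_floor)))
  }, numeric(1))
  names(out) <- paste0("jvar_", coords)
  out
}

#' Assemble the 49-metric vector from a step sequence
#'
#' Composes [xcom_step_max()], [fri_step_max()], [spatiotemporal_stats()],
#' [joint_variability()] and, optionally, the short- and long-term Lyapunov
#' exponents of each joint coordinate (computed on the concatenation of the
#' resampled steps). Lyapunov entries are `NA` when `lyapunov = FALSE` or
#' when fewer than `cfg$min_lyap_steps` steps are available.
#'
#' @param steps List of `step_trajectory` objects.
#' @param cfg An [embedding_config()].
#' @param g Gravitational acceleration (m/s^2).
#' @param lyapunov Compute the 24 Lyapunov entries? They dominate the cost.
#' @return A `metric_vector`: named numeric of length 49 with attributes
#'   `provenance = "brute"` and `n_steps`.
#' @export
metric_vector_from_steps <- function(steps, cfg = embedding_config(),
                                     g = 9.81, lyapunov = TRUE) {
  if (length(steps) < 2L) stop("at least 2 steps are required")
  out <- stats::setNames(rep(NA_real_, 49L), metric_names())
  xc <- vapply(steps, xcom_step_max, numeric(1), g = g)
  fr <- vapply(steps, fri_step_max, numeric(1))
  out["xcom_mean"] <- mean(xc); out["xcom_sd"] <- stats::sd(xc)
  out["fri_mean"] <- mean(fr); out["fri_sd"] <- stats::sd(fr)
  out[names(spatiotemporal_stats(steps))] <- spatiotemporal_stats(steps)
  jv <- joint_variability(steps, d_floor = cfg$d_floor)
  out[names(jv)] <- jv
  if (lyapunov) {
    if (length(steps) < cfg$min_lyap_steps) {
      warning(sprintf(
        "Lyapunov entries need at least %d steps; got %d - left missing",
        cfg$min_lyap_steps, length(steps)))
    } else {
      for (co in lyapunov_coords()) {
        series <- unlist(lapply(steps, function(st) st$samples[, co]),
                         use.names = FALSE)
        lam <- lyapunov_exponents(
          divergence_curve(series, cfg, indices = fit_indices(cfg)), cfg)
        out[paste0("lyap_s_", co)] <- lam[["lambda_s"]]
        out[paste0("lyap_l_", co)] <- lam[["lambda_l"]]
      }
    }
  }
  structure(out, provenance = "brute", n_steps = length(steps),
            class = "metric_vector")
}

#' @export
print.metric_vector <- function(x, ...) {
  cat(sprintf("Fall-risk metric vector (%d metrics; provenance %s, %s steps)\n",
              length(x), attr(x, "provenance"),
              as.character(attr(x, "n_steps"))))
  print(stats::setNames(as.numeric(x), names(x)), ...)
  invisible(x)
}

#' Fit a metric normalization record
#'
#' Per-metric centre (mean) and scale (sample SD) across a set of metric
#' vectors, so that each metric has mean 0 and SD 1 on the fitting set.
#' Zero-variance metrics get scale 1 with a warning. The record is fitted on
#' the Markov-chain metrics and then reused unchanged on brute-force
#' metrics.
#'
#' @param vectors List of `metric_vector`s, or a matrix with metrics in
#'   columns (at least 2 rows).
#' @return An object of class `normalization_record` with fields `center`
#'   and `scale`.
#' @export
fit_normalization <- function(vectors) {
  M <- metric_matrix(vectors)
  if (nrow(M) < 2L) stop("at least 2 vectors are required")
  center <- colMeans(M)
  scale <- apply(M, 2, stats::sd)
  degenerate <- !is.na(scale) & scale == 0
  if (any(degenerate)) {
    warning(sprintf("zero-variance metric(s) %s: scale set to 1",
                    paste(colnames(M)[degenerate], collapse = ", ")))
    scale[degenerate] <- 1
  }
  structure(list(center = center, scale = scale),
            class = "normalization_record")
}

#' Apply a normalization record
#'
#' @param record A [fit_normalization()] result.
#' @param vector A `metric_vector` or a metric matrix.
#' @return The centred and scaled vector/matrix, same shape and attributes.
#' @export
apply_normalization <- function(record, vector) {
  stopifnot(inherits(record, "normalization_record"))
  if (is.matrix(vector)) {
    M <- vector[, names(record$center), drop = FALSE]
    return(sweep(sweep(M, 2, record$center), 2, record$scale, "/"))
  }
  out <- (as.numeric(vector)[match(names(record$center), names(vector))] -
            record$center) / record$scale
  attributes(out) <- attributes(vector)
  names(out) <- names(record$center)
  out
}

# Coerce a list of metric vectors (or a matrix/data.frame) to a plain
# matrix, conditions in rows, metrics in columns.
metric_matrix <- function(vectors) {
  if (is.matrix(vectors)) return(vectors)
  if (is.data.frame(vectors)) return(as.matrix(vectors))
  M <- do.call(rbind, lapply(vectors, as.numeric))
  colnames(M) <- names(vectors[[1]])
  if (!is.null(names(vectors))) rownames(M) <- names(vectors)
  M
}
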