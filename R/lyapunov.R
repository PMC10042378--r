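# Largest-Lyapunov-exponent estimation from a scalar series by the
# nearest-neighbour divergence-curve method (delay embedding, per-pair
# log-distance growth, linear fits over short- and long-term index ranges).

#' Delay-embedding and fit configuration for the Lyapunov estimator
#'
#' @param delay Embedding delay in samples (default 15).
#' @param dim Embedding dimension (default 5).
#' @param exclusion Temporal exclusion half-window for the nearest-neighbour
#'   search: the neighbour of point j must satisfy `|j - k| > exclusion`
#'   (default 50 samples, i.e. half a step, so neighbours come from
#'   different steps).
#' @param short_range Index range of the short-term fit, in divergence-curve
#'   samples. Default 1..200 = 0 to 1 stride at 100 samples/step.
#' @param long_range Index range of the long-term fit. Default 801..2000 =
#'   4 to 10 strides.
#' @param dt Sample interval in normalised time. Steps are resampled to 100
#'   samples, so the default `dt = 1/100` expresses the exponents per step
#'   of normalised time (temporal information about step-duration
#'   variability is removed by the resampling).
#' @param d_floor Distance floor applied before taking logs (default 1e-7,
#'   the numerical tolerance; repeated identical steps otherwise give
#'   log(0)).
#' @param min_lyap_steps Minimum steps for meaningful exponents (default
#'   50).
#' @return An object of class `embedding_config`.
#' @export
embedding_config <- function(delay = 15L, dim = 5L, exclusion = 50L,
                             short_range = c(1L, 200L),
                             long_range = c(801L, 2000L),
                             dt = 1 / 100, d_floor = 1e-7,
                             min_lyap_steps = 50L) {
  if (delay < 1L) stop("delay must be at least 1")
  if (d_floor <= 0) stop("d_floor must be positive")
  if (short_range[1] < 0 || short_range[2] <= short_range[1])
    stop("invalid short_range")
  if (long_range[2] <= long_range[1]) stop("invalid long_range")
  structure(list(delay = as.integer(delay), dim = as.integer(dim),
                 exclusion = as.integer(exclusion),
                 short_range = as.integer(short_range),
                 long_range = as.integer(long_range),
                 dt = dt, d_floor = d_floor,
                 min_lyap_steps = as.integer(min_lyap_steps)),
            class = "embedding_config")
}

# Delay-embed a scalar series into an n_e x dim matrix.
delay_embed <- function(series, delay, dim) {
  n_e <- length(series) - (dim - 1L) * delay
  if (n_e < 2L) stop("series too short for the requested embedding")
  idx <- seq_len(n_e)
  vapply(seq_len(dim) - 1L, function(k) series[idx + k * delay],
         numeric(n_e))
}

# Nearest neighbour of each embedded point outside the temporal exclusion
# window, ties broken by the smaller index. Blocked distance computation to
# bound memory.
nearest_neighbours <- function(X, exclusion, block = 512L) {
  n <- nrow(X)
  sq <- rowSums(X^2)
  nn <- integer(n)
  for (start in seq(1L, n, by = block)) {
    rows <- start:min(start + block - 1L, n)
    D2 <- outer(sq[rows], sq, "+") -
      2 * tcrossprod(X[rows, , drop = FALSE], X)
    # mask the temporal exclusion window |j - k| <= exclusion
    for (r in seq_along(rows)) {
      j <- rows[r]
      lo <- max(1L, j - exclusion)
      hi <- min(n, j + exclusion)
      D2[r, lo:hi] <- Inf
    }
    nn[rows] <- max.col(-D2, ties.method = "first")
  }
  nn
}

#' Mean log-divergence curve of a scalar series
#'
#' Delay-embeds the series, finds each point's nearest neighbour from a
#' different step (outside the temporal exclusion window, ties to the
#' smaller index), tracks the Euclidean distance between each pair `i`
#' samples later (floored at `d_floor`), and averages the log distances over
#' all pairs still inside the series:
#' `y(i) = (1 / dt) * mean(log d_j(i))`.
#'
#' @param series Numeric series (concatenated 100-sample steps).
#' @param cfg An [embedding_config()].
#' @param i_max Largest divergence index computed (default: the end of the
#'   long-term fit range).
#' @param indices Optional subset of divergence indices to evaluate (others
#'   are left `NA`); by default the whole curve 0..`i_max` is computed.
#'   Restricting to the fit ranges saves roughly a third of the cost.
#' @return An object of class `divergence_curve`: data frame columns `i`
#'   (0..i_max) and `y`, with the config as attribute.
#' @export
divergence_curve <- function(series, cfg = embedding_config(),
                             i_max = cfg$long_range[2], indices = NULL) {
  X <- delay_embed(series, cfg$delay, cfg$dim)
  n <- nrow(X)
  if (n <= cfg$exclusion + 1L)
    stop("series too short: no neighbours outside the exclusion window")
  nn <- nearest_neighbours(X, cfg$exclusion)
  j <- seq_len(n)
  k <- nn
  if (is.null(indices)) indices <- 0:i_max
  indices <- indices[indices <= i_max]
  y <- rep(NA_real_, i_max + 1L)
  for (i in indices) {
    ok <- (j + i <= n) & (k + i <= n)
    if (!any(ok)) next
    d2 <- rowSums((X[j[ok] + i, , drop = FALSE] -
                     X[k[ok] + i, , drop = FALSE])^2)
    y[i + 1L] <- mean(log(pmax(sqrt(d2), cfg$d_floor))) / cfg$dt
  }
  structure(data.frame(i = 0:i_max, y = y),
            cfg = cfg, class = c("divergence_curve", "data.frame"))
}

# Divergence indices needed for the two fit ranges of a config.
fit_indices <- function(cfg) {
  unique(c(0:cfg$short_range[2],
           cfg$long_range[1]:cfg$long_range[2]))
}

#' Short- and long-term Lyapunov exponents from a divergence curve
#'
#' Least-squares slopes of the mean divergence curve over the short-term
#' (default 0-1 strides, indices 1-200) and long-term (default 4-10 strides,
#' indices 801-2000) ranges.
#'
#' @param curve A [divergence_curve()] result (or any data frame with
#'   columns `i`, `y`).
#' @param cfg An [embedding_config()] supplying the fit ranges.
#' @return Named numeric vector `c(lambda_s =, lambda_l =)`.
#' @export
lyapunov_exponents <- function(curve, cfg = embedding_config()) {
  fit_slope <- function(range, label) {
    sel <- curve$i >= range[1] & curve$i <= range[2] & !is.na(curve$y)
    if (sum(sel) < 2L)
      stop(sprintf("divergence curve too short for the %s-term range %d..%d",
                   label, range[1], range[2]))
    ii <- curve$i[sel]; yy <- curve$y[sel]
    sum((ii - mean(ii)) * (yy - mean(yy))) / sum((ii - mean(ii))^2)
  }
  c(lambda_s = fit_slope(cfg$short_range, "short"),
    lambda_l = fit_slope(cfg$long_range, "long"))
}
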