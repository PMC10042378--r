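# Validation of the chain metrics against brute-force simulations, and the
# convergence of brute-force metric accuracy with the number of steps.

#' Cut brute-force trials into fixed-length segments
#'
#' Each trial is cut into consecutive disjoint segments of `n` steps; the
#' trailing remainder is discarded. Trials only contain completed steps, so
#' segments never span a fall.
#'
#' @param trials List of trials from [simulate_brute()] (each a list of
#'   `step_trajectory` objects).
#' @param n Steps per segment.
#' @return A list of segments, each a list of `n` `step_trajectory`s with a
#'   `trial` attribute identifying the source trial.
#' @export
segment_trials <- function(trials, n) {
  if (n < 1L) stop("n must be positive")
  out <- list()
  for (ti in seq_along(trials)) {
    len <- length(trials[[ti]])
    k <- floor(len / n)
    if (k < 1L) next
    for (s in seq_len(k)) {
      seg <- trials[[ti]][((s - 1L) * n + 1L):(s * n)]
      attr(seg, "trial") <- ti
      out[[length(out) + 1L]] <- seg
    }
  }
  if (!length(out))
    warning("no trial is long enough for a single segment")
  out
}

# Metric-type groups used when pooling validation statistics: the scalar
# metrics stand alone, the Lyapunov exponents and the joint variability pool
# all their coordinates.
metric_type_of <- function(metric) {
  ifelse(grepl("^lyap_s_", metric), "lyap_s",
  ifelse(grepl("^lyap_l_", metric), "lyap_l",
  ifelse(grepl("^jvar_dq", metric), "jvar_velocity",
  ifelse(grepl("^jvar_q", metric), "jvar_angle", metric))))
}

#' Compare chain metrics with the brute-force metric distribution
#'
#' Normalises the chain metric vector and each brute-force vector with the
#' same record, then flags each metric as matching when the chain value lies
#' within one standard deviation of the brute-force mean, and aggregates by
#' metric type (Lyapunov and variability coordinates pooled): percent match,
#' median absolute difference and median brute-force SD, all in normalised
#' units.
#'
#' @param chain_vec Chain `metric_vector` (raw).
#' @param brute_vecs List of brute-force `metric_vector`s (raw; at least 2).
#' @param record The [fit_normalization()] record shared by both methods.
#' @return An object of class `comparison_result`: `table` (one row per
#'   metric: chain value, brute mean and SD, match flag, absolute
#'   difference) and `aggregates` (one row per metric type).
#' @export
compare_methods <- function(chain_vec, brute_vecs, record) {
  if (length(brute_vecs) < 2L)
    stop("at least 2 brute-force vectors are required")
  if (!identical(names(record$center), metric_names()) &&
      !all(names(chain_vec) %in% names(record$center)))
    stop("normalization record does not cover the metric schema")
  cv <- apply_normalization(record, chain_vec)
  B <- apply_normalization(record, metric_matrix(brute_vecs))
  if (!identical(colnames(B), names(record$center)))
    stop("brute-force vectors do not share the chain metric schema")
  bm <- colMeans(B)
  bs <- apply(B, 2, stats::sd)
  tab <- data.frame(
    metric = names(record$center),
    type = metric_type_of(names(record$center)),
    chain = as.numeric(cv), brute_mean = bm, brute_sd = bs,
    abs_diff = abs(as.numeric(cv) - bm),
    row.names = NULL, stringsAsFactors = FALSE)
  tab$match <- tab$abs_diff <= tab$brute_sd
  ok <- stats::complete.cases(tab[, c("chain", "brute_mean", "brute_sd")])
  agg <- do.call(rbind, lapply(split(tab[ok, ], tab$type[ok]), function(d) {
    data.frame(type = d$type[1], n = nrow(d),
               pct_match = 100 * mean(d$match),
               median_err = stats::median(d$abs_diff),
               median_brute_sd = stats::median(d$brute_sd),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  structure(list(table = tab, aggregates = agg,
                 n_missing = sum(!ok)),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  ok <- stats::complete.cases(x$table[, c("chain", "brute_mean", "brute_sd")])
  cat(sprintf(
    "Chain vs brute-force metric comparison: %d metrics (%d missing), %.1f%% match overall\n",
    nrow(x$table), x$n_missing, 100 * mean(x$table$match[ok])))
  print(x$aggregates, digits = 3)
  invisible(x)
}

#' Fit the accuracy-vs-steps convergence model
#'
#' Least-squares fit of `p = alpha1 * ln(n) + alpha0` to the percentage of
#' brute-force segments within an error threshold, and the extrapolated
#' number of steps at which 90% of segments would be within the threshold:
#' `ceil(exp((90 - alpha0) / alpha1))`, floored at 10 (predictions below 10
#' steps are rounded up to 10). A positive-slope fit predicting more than
#' ten times the largest observed `n` is flagged as extrapolated.
#'
#' @param pcts Percentages (0-100), one per `n`.
#' @param ns Numbers of steps (at least 3 distinct values).
#' @return An object of class `convergence_fit`: `alpha0`, `alpha1`,
#'   `r_squared`, `steps_to_90` (`NA` with `attainable = FALSE` when the
#'   slope is non-positive) and `extrapolated`.
#' @export
convergence_fit <- function(pcts, ns) {
  if (length(pcts) != length(ns)) stop("pcts and ns differ in length")
  if (length(unique(ns)) < 3L)
    stop("at least 3 distinct n values are required")
  fit <- stats::lm(pcts ~ log(ns))
  a0 <- unname(stats::coef(fit)[1])
  a1 <- unname(stats::coef(fit)[2])
  r2 <- summary(fit)$r.squared
  if (a1 > 0) {
    steps <- max(10, ceiling(exp((90 - a0) / a1)))
    attainable <- TRUE
  } else {
    steps <- NA_real_
    attainable <- FALSE
  }
  structure(list(alpha0 = a0, alpha1 = a1, r_squared = r2,
                 steps_to_90 = steps, attainable = attainable,
                 extrapolated = attainable && steps > 10 * max(ns)),
            class = "convergence_fit")
}

#' @export
print.convergence_fit <- function(x, ...) {
  cat(sprintf("Convergence fit p = %.3g ln(n) + %.3g  (R^2 = %.3f)\n",
              x$alpha1, x$alpha0, x$r_squared))
  if (x$attainable)
    cat(sprintf("  steps to 90%% within threshold: %d%s\n", x$steps_to_90,
                if (x$extrapolated) " (extrapolated)" else ""))
  else cat("  90% level unattainable (non-positive slope)\n")
  invisible(x)
}

#' Standard step-count grid for the convergence analysis
#'
#' @return The step counts used when subdividing brute-force simulations.
#' @export
convergence_step_grid <- function() {
  c(10L, 20L, 30L, 40L, 50L, 60L, 70L, 80L, 90L, 100L, 200L, 300L, 500L,
    1000L)
}
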