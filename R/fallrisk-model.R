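# Fall-risk prediction models: individual quadratic fits per metric and the
# combined PCA + consensus-stepwise quadratic model predicting ln(MFPT).

#' Individual quadratic fall-risk model for a single metric
#'
#' Ordinary least squares fit of `y = beta0 + beta1 rho + beta2 rho^2`,
#' where `y` is the natural log of the MFPT and `rho` is one metric's value
#' per condition.
#'
#' @param values Metric values per condition (at least 4).
#' @param y Natural log of the true MFPT per condition.
#' @param metric Optional metric name for printing.
#' @return An object of class `fallrisk_individual` with coefficients
#'   `beta0`, `beta1`, `beta2` and the underlying `lm` fit.
#' @export
fit_individual <- function(values, y, metric = "metric") {
  if (length(values) != length(y)) stop("values and y differ in length")
  if (length(y) < 4L) stop("at least 4 conditions are required")
  if (stats::sd(values) == 0)
    stop("degenerate fit: the metric is constant across conditions")
  fit <- stats::lm(y ~ values + I(values^2))
  beta <- unname(stats::coef(fit))
  if (any(!is.finite(beta))) stop("degenerate fit: rank-deficient design")
  structure(list(metric = metric, beta0 = beta[1], beta1 = beta[2],
                 beta2 = beta[3], fit = fit),
            class = "fallrisk_individual")
}

#' Predict from an individual quadratic model
#'
#' @param object A [fit_individual()] model.
#' @param newdata Metric values.
#' @param type `"log"` for ln(MFPT) (default) or `"response"` for MFPT.
#' @param ... Unused.
#' @return Predicted values.
#' @export
predict.fallrisk_individual <- function(object, newdata,
                                        type = c("log", "response"), ...) {
  type <- match.arg(type)
  yhat <- object$beta0 + object$beta1 * newdata + object$beta2 * newdata^2
  if (type == "response") exp(yhat) else yhat
}

#' @export
coef.fallrisk_individual <- function(object, ...) {
  c(beta0 = object$beta0, beta1 = object$beta1, beta2 = object$beta2)
}

#' @export
print.fallrisk_individual <- function(x, ...) {
  cat(sprintf(
    "Individual quadratic fall-risk model for %s:\n  ln(MFPT) = %.4g + %.4g rho + %.4g rho^2\n",
    x$metric, x$beta0, x$beta1, x$beta2))
  invisible(x)
}

#' Principal components of a normalized metric matrix
#'
#' Singular-value-decomposition PCA of the (already unit-variance) metric
#' matrix, without further scaling. Components are ordered by non-increasing
#' explained variance and signed so the largest-magnitude loading of each is
#' positive. The transformation is frozen after fitting and reapplied
#' verbatim to brute-force metrics.
#'
#' @param M Normalized metric matrix, conditions in rows.
#' @param n_scores Number of leading scores kept (default 15, fewer with a
#'   warning when the matrix supports fewer).
#' @return An object of class `metric_pca`: `rotation`, `center`,
#'   `n_scores`, `sdev` and the training `scores`.
#' @export
fit_pca <- function(M, n_scores = 15L) {
  M <- metric_matrix(M)
  if (!nrow(M) || !ncol(M)) stop("empty metric matrix")
  pr <- stats::prcomp(M, center = TRUE, scale. = FALSE)
  # numerical rank guard: directions with essentially zero variance are
  # artefacts of collinearity, not components
  rank <- sum(pr$sdev > max(pr$sdev) * 1e-7)
  k <- min(n_scores, ncol(pr$rotation), rank)
  if (k < n_scores)
    warning(sprintf("only %d components available (requested %d)", k,
                    n_scores))
  flip <- apply(pr$rotation[, seq_len(k), drop = FALSE], 2,
                function(v) sign(v[which.max(abs(v))]))
  rot <- sweep(pr$rotation[, seq_len(k), drop = FALSE], 2, flip, "*")
  scores <- sweep(pr$x[, seq_len(k), drop = FALSE], 2, flip, "*")
  colnames(rot) <- colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(rotation = rot, center = pr$center, n_scores = k,
                 sdev = pr$sdev[seq_len(k)], scores = scores),
            class = "metric_pca")
}

#' Project metric vectors onto fitted principal components
#'
#' @param pca A [fit_pca()] result.
#' @param x Normalized metric vector or matrix (same columns the PCA was
#'   fitted on).
#' @return Score matrix (rows = inputs, columns `PC1..`).
#' @export
apply_pca <- function(pca, x) {
  stopifnot(inherits(pca, "metric_pca"))
  if (!is.matrix(x)) x <- matrix(x, 1L, dimnames = list(NULL, names(x)))
  x <- x[, names(pca$center), drop = FALSE]
  sweep(x, 2, pca$center) %*% pca$rotation
}

# Bidirectional stepwise selection over a fixed candidate design by partial
# F/t tests: forward-add the most significant candidate, then backward-drop
# the least significant term above p_remove, until stable. The entry
# threshold is Bonferroni-adjusted for the number of candidates screened
# (p_enter / #candidates): the forward step takes the minimum of many
# p-values, and without the adjustment pure-noise responses acquire terms
# in well over half of datasets.
stepwise_select <- function(D, y, candidates = colnames(D),
                            p_enter = 0.05, p_remove = 0.10,
                            max_iter = 100L) {
  # safe internal column names; map back on return
  force(candidates)
  pretty <- colnames(D)
  safe <- paste0("V", seq_along(pretty))
  colnames(D) <- safe
  cand <- safe[match(candidates, pretty)]
  term_p <- function(sel) {
    # marginal t-test p-value of each term in the joint model
    df <- as.data.frame(D[, sel, drop = FALSE])
    fit <- stats::lm(y ~ ., data = df)
    cf <- summary(fit)$coefficients
    pv <- stats::setNames(rep(1, length(sel)), sel)  # collinear -> 1
    has <- intersect(sel, rownames(cf))
    pv[has] <- cf[has, 4]
    pv
  }
  selected <- character(0)
  for (iter in seq_len(max_iter)) {
    changed <- FALSE
    # forward step
    pool <- setdiff(cand, selected)
    if (length(pool)) {
      pvals <- vapply(pool, function(term) {
        term_p(c(selected, term))[[term]]
      }, numeric(1))
      if (min(pvals) < p_enter / length(pool)) {
        selected <- c(selected, pool[which.min(pvals)])
        changed <- TRUE
      }
    }
    # backward step (cannot oscillate: p_enter < p_remove)
    if (length(selected)) {
      pv <- term_p(selected)
      if (max(pv) > p_remove) {
        selected <- selected[-which.max(pv)]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  pretty[match(selected, safe)]
}

# Quadratic candidate design from a score matrix: linear and squared terms
# of each component, no interactions.
quadratic_design <- function(scores) {
  k <- ncol(scores)
  D <- cbind(scores, scores^2)
  colnames(D) <- c(colnames(scores), paste0(colnames(scores), "^2"))
  D
}

#' Fit the combined fall-risk model
#'
#' The package's main fitting function. From raw chain metric vectors and
#' the true MFPT per condition it (1) drops the short-term Lyapunov
#' exponents always and the long-term ones for the `"no_lyap"` variant,
#' (2) fits the metric normalization, (3) fits PCA on the normalized
#' metrics and keeps the first 15 scores, and (4) selects quadratic terms
#' (linear and squared scores, no interactions) by consensus stepwise
#' regression: ten stepwise runs, each with three randomly removed whole
#' conditions, pooling terms selected in at least three runs, and one final
#' stepwise pass over that pool. Stepwise uses bidirectional selection with
#' entry/exit p-thresholds 0.05/0.10.
#'
#' @param metrics Raw chain metric vectors: a list of `metric_vector`s, or
#'   a matrix with one condition per row and the 49 named metric columns.
#' @param mfpt True MFPT per condition (steps), or its natural log if
#'   `log_mfpt = TRUE`.
#' @param conditions Condition labels (one per row); whole conditions are
#'   removed together during the consensus repetitions. Defaults to one
#'   label per row.
#' @param variant `"no_lyap"` (exclude all Lyapunov exponents; the default,
#'   and the more robust choice for brute-force inputs) or `"with_lyap"`
#'   (include the long-term exponents; short-term ones are never used).
#' @param seed Integer seed for the condition-removal draws.
#' @param log_mfpt Is `mfpt` already on the natural-log scale?
#' @param tolerance Prediction tolerance band on ln(MFPT) used by
#'   [summary.fallrisk()] (default 3.3, ten percent of a roughly
#'   33-log-unit MFPT range; see [mfpt_tolerance()] to recompute it from
#'   any dataset's own range).
#' @param p_enter,p_remove Stepwise entry/exit p-value thresholds.
#' @param n_reps,n_remove,min_votes Consensus parameters: repetitions,
#'   conditions removed per repetition, minimum selections for a term to
#'   reach the final pool.
#' @param n_scores Number of leading PCA scores (default 15).
#' @return An object of class `fallrisk` with the normalization record, the
#'   PCA, the selected terms and coefficients, and the training fit.
#' @seealso [predict.fallrisk()], [summary.fallrisk()], [goodness_of_fit()]
#' @export
fallrisk <- function(metrics, mfpt, conditions = NULL,
                     variant = c("no_lyap", "with_lyap"),
                     seed = 1L, log_mfpt = FALSE, tolerance = 3.3,
                     p_enter = 0.05, p_remove = 0.10,
                     n_reps = 10L, n_remove = 3L, min_votes = 3L,
                     n_scores = 15L) {
  variant <- match.arg(variant)
  M <- metric_matrix(metrics)
  y <- if (log_mfpt) as.numeric(mfpt) else log(as.numeric(mfpt))
  if (nrow(M) != length(y)) stop("metrics and mfpt differ in length")
  if (is.null(conditions)) conditions <- seq_len(nrow(M))
  conditions <- as.character(conditions)
  groups <- unique(conditions)
  if (length(groups) < n_reps)
    stop("at least 10 conditions are required for the consensus repetitions")
  M <- M[, variant_metrics(variant), drop = FALSE]
  if (anyNA(M)) stop("missing metric values in the training matrix")
  record <- fit_normalization(M)
  Z <- apply_normalization(record, M)
  pca <- fit_pca(Z, n_scores = n_scores)
  cm <- fit_combined(pca$scores, y, conditions, seed = seed,
                     p_enter = p_enter, p_remove = p_remove,
                     n_reps = n_reps, n_remove = n_remove,
                     min_votes = min_votes)
  structure(list(variant = variant, normalization = record, pca = pca,
                 terms = cm$terms, coefficients = cm$coefficients,
                 fit = cm$fit, votes = cm$votes, seed = as.integer(seed),
                 tolerance = tolerance,
                 training = list(metrics = M, y = y,
                                 conditions = conditions)),
            class = "fallrisk")
}

#' Consensus stepwise selection of quadratic score terms
#'
#' The selection core of [fallrisk()], usable directly on a score matrix:
#' runs `n_reps` bidirectional stepwise regressions of `y` on the linear
#' and squared score terms, each with `n_remove` whole conditions removed
#' at random, pools the terms selected in at least `min_votes` runs, and
#' performs a final stepwise pass restricted to that pool. Deterministic
#' given `seed`.
#'
#' @param scores Score matrix (conditions x components, named columns).
#' @param y Natural log of the true MFPT per row.
#' @param conditions Condition labels (default one per row).
#' @param seed Integer seed for the removal draws.
#' @param p_enter,p_remove Entry/exit p-value thresholds.
#' @param n_reps,n_remove,min_votes Consensus parameters.
#' @return A list: `terms` (selected term names, e.g. `"PC3"`, `"PC3^2"`),
#'   `coefficients` (named, with `"(Intercept)"`), `votes` and the final
#'   `lm` fit.
#' @export
fit_combined <- function(scores, y, conditions = NULL, seed = 1L,
                         p_enter = 0.05, p_remove = 0.10,
                         n_reps = 10L, n_remove = 3L, min_votes = 3L) {
  scores <- as.matrix(scores)
  if (nrow(scores) != length(y)) stop("scores and y differ in length")
  if (is.null(conditions)) conditions <- seq_len(nrow(scores))
  conditions <- as.character(conditions)
  groups <- unique(conditions)
  if (length(groups) < n_reps)
    stop("at least 10 conditions are required for the consensus repetitions")
  D <- quadratic_design(scores)
  votes <- integer(0)
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, {
    for (r in seq_len(n_reps)) {
      drop_g <- sample(groups, n_remove)
      keep <- !(conditions %in% drop_g)
      sel <- stepwise_select(D[keep, , drop = FALSE], y[keep],
                             p_enter = p_enter, p_remove = p_remove)
      for (term in sel) votes[term] <- (if (term %in% names(votes))
        votes[term] else 0L) + 1L
    }
  })
  pool <- names(votes)[votes >= min_votes]
  terms <- if (length(pool))
    stepwise_select(D, y, candidates = pool,
                    p_enter = p_enter, p_remove = p_remove)
  else character(0)
  if (!length(terms)) {
    warning("no term survived the consensus selection: intercept-only model")
    fit <- stats::lm(y ~ 1)
    beta <- stats::setNames(stats::coef(fit), "(Intercept)")
  } else {
    X <- D[, terms, drop = FALSE]
    fit <- stats::lm(y ~ X)
    beta <- stats::setNames(stats::coef(fit),
                            c("(Intercept)", terms))
  }
  list(terms = terms, coefficients = beta, votes = votes, fit = fit)
}

# Metric columns used by each model variant: short-term Lyapunov exponents
# are never used; long-term ones only in the with_lyap variant.
variant_metrics <- function(variant) {
  nm <- metric_names()
  nm <- nm[!grepl("^lyap_s_", nm)]
  if (variant == "no_lyap") nm <- nm[!grepl("^lyap_l_", nm)]
  nm
}

#' Predict ln(MFPT) from a combined fall-risk model
#'
#' Normalizes the incoming metric vector(s) with the model's frozen record,
#' projects onto the fitted principal components, evaluates the selected
#' quadratic terms and returns the predicted log mean first passage time
#' (or `exp` of it).
#'
#' @param object A [fallrisk()] model.
#' @param newdata A `metric_vector`, list of them, or metric matrix. Must
#'   contain the variant's required metrics; missing ones raise an error
#'   naming them.
#' @param type `"log"` (default) or `"response"` for the MFPT in steps.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.fallrisk <- function(object, newdata, type = c("log", "response"),
                             ...) {
  type <- match.arg(type)
  if (is.list(newdata) && !is.data.frame(newdata))
    newdata <- metric_matrix(newdata)
  if (!is.matrix(newdata))
    newdata <- matrix(newdata, 1L, dimnames = list(NULL, names(newdata)))
  need <- variant_metrics(object$variant)
  missing_cols <- setdiff(need, colnames(newdata))
  if (length(missing_cols))
    stop("missing required metric(s): ",
         paste(missing_cols, collapse = ", "))
  M <- newdata[, need, drop = FALSE]
  if (anyNA(M)) {
    bad <- need[colSums(is.na(M)) > 0]
    stop("missing required metric value(s): ", paste(bad, collapse = ", "))
  }
  Z <- apply_normalization(object$normalization, M)
  D <- quadratic_design(apply_pca(object$pca, Z))
  yhat <- rep(object$coefficients[["(Intercept)"]], nrow(D))
  for (term in object$terms)
    yhat <- yhat + object$coefficients[[term]] * D[, term]
  yhat <- unname(yhat)
  if (type == "response") exp(yhat) else yhat
}

#' @export
coef.fallrisk <- function(object, ...) object$coefficients

#' @export
fitted.fallrisk <- function(object, ...) {
  predict(object, object$training$metrics)
}

#' @export
residuals.fallrisk <- function(object, ...) {
  object$training$y - fitted(object)
}

#' @export
print.fallrisk <- function(x, ...) {
  cat(sprintf(
    "Combined quadratic fall-risk model (%s variant)\n",
    if (x$variant == "no_lyap") "excluding Lyapunov exponents"
    else "including long-term Lyapunov exponents"))
  cat(sprintf("  %d conditions, %d PCA scores, %d selected terms\n",
              length(x$training$y), x$pca$n_scores, length(x$terms)))
  if (length(x$terms)) {
    cat("  ln(MFPT) =", sprintf("%.4g", x$coefficients[["(Intercept)"]]))
    for (term in x$terms)
      cat(sprintf(" %+.4g %s", x$coefficients[[term]], term))
    cat("\n")
  } else cat("  intercept-only model\n")
  invisible(x)
}

#' Summary of a combined fall-risk model
#'
#' Training-set goodness of fit: adjusted R-squared of the selected-term
#' regression plus the error measures of [goodness_of_fit()] at the model's
#' tolerance band.
#'
#' @param object A [fallrisk()] model.
#' @param ... Unused.
#' @return An object of class `summary.fallrisk`.
#' @export
summary.fallrisk <- function(object, ...) {
  gof <- goodness_of_fit(fitted(object), object$training$y,
                         groups = object$training$conditions,
                         tolerance = object$tolerance)
  structure(list(model = object,
                 adj_r_squared = summary(object$fit)$adj.r.squared,
                 gof = gof),
            class = "summary.fallrisk")
}

#' @export
print.summary.fallrisk <- function(x, ...) {
  print(x$model)
  cat(sprintf("  adjusted R^2 (model): %.3f\n", x$adj_r_squared))
  print(x$gof)
  invisible(x)
}

#' Predicted-vs-true plot of a fall-risk model
#'
#' Scatter of predicted against true ln(MFPT) on the training data with the
#' identity line and the fitted evaluation line.
#'
#' @param x A [fallrisk()] model.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.fallrisk <- function(x, ...) {
  y <- x$training$y
  yhat <- fitted(x)
  graphics::plot(y, yhat, xlab = "true ln(MFPT)",
                 ylab = "predicted ln(MFPT)", ...)
  graphics::abline(0, 1, lty = 2)
  ev <- stats::lm(yhat ~ y)
  graphics::abline(ev, col = 2)
  invisible(x)
}

#' Goodness-of-fit measures for MFPT predictions
#'
#' Computes, on the natural-log scale: RMSE, MAE, MAPE
#' (`100/n * sum(|(yhat - y)/y|)`, excluding zero-valued `y` with a count),
#' the relative average absolute error RAAE (`sum|yhat - y| / (n * sd(yhat))`,
#' with the SD of the predictions in the denominator), the maximum absolute
#' error, the percentage of predictions within the tolerance band, the
#' least-squares evaluation line `yhat = alpha1 * y + alpha0` with its
#' adjusted R-squared (`Re2`), and (when `groups` is given) the mean over
#' groups of the within-group error SD.
#'
#' @param yhat Predicted ln(MFPT).
#' @param y True ln(MFPT), same length (at least 2).
#' @param groups Optional condition labels for the mean within-group SD.
#' @param tolerance Tolerance band on ln(MFPT) (default 3.3).
#' @return An object of class `goodness_of_fit`.
#' @export
goodness_of_fit <- function(yhat, y, groups = NULL, tolerance = 3.3) {
  if (length(yhat) != length(y)) stop("yhat and y differ in length")
  if (length(y) < 2L) stop("at least 2 pairs are required")
  err <- yhat - y
  nz <- y != 0
  mape <- if (any(nz)) 100 * mean(abs(err[nz] / y[nz])) else NA_real_
  sdy <- stats::sd(yhat)
  raae <- if (sdy > 0) sum(abs(err)) / (length(y) * sdy) else NA_real_
  ident <- isTRUE(all.equal(as.numeric(yhat), as.numeric(y),
                            tolerance = 1e-12))
  if (ident) {
    a0 <- 0; a1 <- 1; re2 <- 1
  } else {
    ev <- stats::lm(yhat ~ y)
    a0 <- unname(stats::coef(ev)[1]); a1 <- unname(stats::coef(ev)[2])
    re2 <- summary(ev)$adj.r.squared
  }
  mean_group_sd <- if (!is.null(groups)) {
    sds <- tapply(err, groups, stats::sd)
    mean(sds[!is.na(sds)])
  } else NA_real_
  structure(list(
    rmse = sqrt(mean(err^2)), mae = mean(abs(err)), mape = mape,
    mape_excluded = sum(!nz), raae = raae, max_abs_err = max(abs(err)),
    pct_in_tolerance = 100 * mean(abs(err) <= tolerance),
    tolerance = tolerance, alpha0 = a0, alpha1 = a1, re2 = re2,
    mean_group_sd = mean_group_sd, n = length(y)),
    class = "goodness_of_fit")
}

#' @export
print.goodness_of_fit <- function(x, ...) {
  cat(sprintf("Goodness of fit over %d cases:\n", x$n))
  cat(sprintf("  RMSE %.4g | MAE %.4g | MAPE %.4g%% | RAAE %.4g | max |err| %.4g\n",
              x$rmse, x$mae, x$mape, x$raae, x$max_abs_err))
  cat(sprintf("  %.1f%% within ln(MFPT) +/- %.2f\n", x$pct_in_tolerance,
              x$tolerance))
  cat(sprintf("  evaluation line yhat = %.3g y + %.3g, Re^2 = %.3f\n",
              x$alpha1, x$alpha0, x$re2))
  if (!is.na(x$mean_group_sd))
    cat(sprintf("  mean within-condition error SD: %.4g\n", x$mean_group_sd))
  invisible(x)
}

#' Tolerance band as ten percent of the observed log-MFPT range
#'
#' @param mfpt MFPT values (steps).
#' @param fraction Fraction of the log range (default 0.1).
#' @return Tolerance on the ln(MFPT) scale.
#' @export
mfpt_tolerance <- function(mfpt, fraction = 0.1) {
  fraction * diff(range(log(mfpt)))
}
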