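# Individual and combined fall-risk models and goodness of fit.

test_that("individual quadratic models recover exact and noisy coefficients", {
  rho <- seq(-2, 2, length.out = 30)
  y <- 1 + 2 * rho + 3 * rho^2
  m <- fit_individual(rho, y, metric = "demo")
  expect_equal(unname(coef(m)), c(1, 2, 3), tolerance = 1e-8)
  expect_equal(predict(m, 0), 1)
  expect_equal(predict(m, 0, type = "response"), exp(1))
  expect_equal(predict(m, c(1, -1)), c(6, 2))
  # noisy planted quadratic: errors within 3x the closed-form OLS SEs
  sigma <- 0.1
  yn <- y + withr::with_seed(42, stats::rnorm(30, 0, sigma))
  mn <- fit_individual(rho, yn)
  X <- cbind(1, rho, rho^2)
  se <- sigma * sqrt(diag(solve(crossprod(X))))
  expect_true(all(abs(unname(coef(mn)) - c(1, 2, 3)) <= 3 * se))
  # constant metric cannot be fitted
  expect_error(fit_individual(rep(1, 10), 1:10), "constant")
  expect_error(fit_individual(1:3, 1:3), "4 conditions")
})

test_that("PCA orders components, fixes signs and reconstructs exactly", {
  # exactly orthogonal centred columns with graded variances: the loadings
  # are a signed permutation of the identity
  Qo <- qr.Q(qr(matrix(withr::with_seed(5, stats::rnorm(64)), 8)))[, 1:3]
  Qo <- scale(Qo, center = TRUE, scale = FALSE)
  M <- Qo %*% diag(c(5, 3, 1))
  colnames(M) <- c("m1", "m2", "m3")
  p <- fit_pca(M, n_scores = 3)
  perm <- abs(p$rotation) > 0.99
  expect_equal(colSums(perm), rep(1, 3), ignore_attr = TRUE)
  # largest-magnitude loading is positive in every component
  expect_true(all(apply(p$rotation, 2, function(v) v[which.max(abs(v))]) > 0))
  # score variances non-increasing
  expect_true(all(diff(apply(p$scores, 2, stats::var)) <= 1e-12))
  # full-rank reconstruction from all components
  M2 <- withr::with_seed(7, matrix(stats::rnorm(60), 10, 6))
  colnames(M2) <- paste0("m", 1:6)
  p2 <- fit_pca(M2, n_scores = 6)
  rec <- p2$scores %*% t(p2$rotation) +
    matrix(p2$center, 10, 6, byrow = TRUE)
  expect_equal(rec, M2, ignore_attr = TRUE, tolerance = 1e-10)
  # projection of the training data reproduces the training scores
  expect_equal(apply_pca(p2, M2), p2$scores, tolerance = 1e-10)
  expect_error(fit_pca(matrix(numeric(0), 0, 0)), "empty")
})

test_that("consensus stepwise recovers a planted quadratic model in the scores", {
  n <- 40L
  k <- 8L
  S <- withr::with_seed(31, matrix(stats::rnorm(n * k), n, k))
  colnames(S) <- paste0("PC", 1:k)
  y <- 4 + 3 * S[, 1] - 2 * S[, 3]^2 +
    withr::with_seed(32, stats::rnorm(n, 0, 0.05))
  cm <- fit_combined(S, y, seed = 50)
  expect_setequal(cm$terms, c("PC1", "PC3^2"))
  expect_equal(cm$coefficients[["PC1"]], 3, tolerance = 0.05)
  expect_equal(cm$coefficients[["PC3^2"]], -2, tolerance = 0.05)
  expect_equal(cm$coefficients[["(Intercept)"]], 4, tolerance = 0.2)
  # deterministic given the seed
  cm2 <- fit_combined(S, y, seed = 50)
  expect_identical(cm$terms, cm2$terms)
  expect_identical(cm$coefficients, cm2$coefficients)
})

test_that("pure-noise responses give an intercept-only model in most seeds", {
  n <- 40L
  S <- withr::with_seed(61, matrix(stats::rnorm(n * 8), n, 8))
  colnames(S) <- paste0("PC", 1:8)
  hits <- 0L
  for (sd_seed in 1:10) {
    y <- withr::with_seed(200 + sd_seed, stats::rnorm(n))
    cm <- suppressWarnings(fit_combined(S, y, seed = sd_seed))
    if (length(cm$terms) == 0L) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("combined model predictions follow the selected quadratic terms", {
  # forged model: identity normalization and identity PCA over the 25
  # metrics of the no-Lyapunov variant, so PC1 equals the first metric
  nm <- fallrisk:::variant_metrics("no_lyap")
  rec <- structure(list(center = stats::setNames(rep(0, 25), nm),
                        scale = stats::setNames(rep(1, 25), nm)),
                   class = "normalization_record")
  pca <- structure(list(rotation = diag(25),
                        center = stats::setNames(rep(0, 25), nm),
                        n_scores = 25L),
                   class = "metric_pca")
  dimnames(pca$rotation) <- list(nm, paste0("PC", 1:25))
  model <- structure(list(variant = "no_lyap", normalization = rec,
                          pca = pca, terms = character(0),
                          coefficients = c("(Intercept)" = 1),
                          tolerance = 3.3),
                     class = "fallrisk")
  x <- stats::setNames(rep(0, 49), metric_names())
  # intercept-only: constant prediction
  expect_equal(predict(model, x), 1)
  # add beta_{1,1} = 2 on PC1 (= the first metric under identity PCA)
  model$terms <- "PC1"
  model$coefficients <- c("(Intercept)" = 1, "PC1" = 2)
  x[1] <- 3
  expect_equal(predict(model, x), 7)
  expect_equal(predict(model, x, type = "response"), exp(7))
  # batch prediction equals per-item prediction
  X <- rbind(x, x * 0.5, x * 2)
  expect_equal(predict(model, X),
               vapply(1:3, function(r) predict(model, X[r, ]), numeric(1)))
  # missing required metrics are named
  expect_error(predict(model, x[-(1:12)]), "xcom_mean")
  # short-term Lyapunov entries are never required
  x_na <- x
  x_na[grepl("^lyap", names(x_na))] <- NA
  expect_equal(predict(model, x_na), 7)
})

test_that("goodness of fit reproduces hand-computed measures", {
  # perfect prediction
  g <- goodness_of_fit(c(1, 5, 9), c(1, 5, 9))
  expect_equal(g$rmse, 0)
  expect_equal(g$mae, 0)
  expect_equal(g$mape, 0)
  expect_equal(g$raae, 0)
  expect_equal(g$pct_in_tolerance, 100)
  expect_equal(c(g$alpha1, g$alpha0, g$re2), c(1, 0, 1))
  # MAPE of yhat = 2 vs y = 4 is 50%
  g2 <- suppressWarnings(goodness_of_fit(c(2, 2), c(4, 4)))
  expect_equal(g2$mape, 50)
  # zero-valued truths are excluded from MAPE with a count
  g3 <- suppressWarnings(goodness_of_fit(c(1, 2, 2), c(1, 0, 4)))
  expect_equal(g3$mape_excluded, 1L)
  expect_equal(g3$mape, 100 * mean(c(0, 0.5)))
  # random vectors: spreadsheet-style recomputation
  withr::with_seed(9, {
    yh <- stats::rnorm(100, 10, 4)
    yt <- stats::rnorm(100, 10, 4)
  })
  grp <- rep(letters[1:10], each = 10)
  g4 <- goodness_of_fit(yh, yt, groups = grp, tolerance = 3.3)
  e <- yh - yt
  expect_equal(g4$rmse, sqrt(sum(e^2) / 100))
  expect_equal(g4$mae, sum(abs(e)) / 100)
  expect_equal(g4$mape, 100 * sum(abs(e / yt)) / 100)
  expect_equal(g4$raae, sum(abs(e)) / (100 * stats::sd(yh)))
  expect_equal(g4$max_abs_err, max(abs(e)))
  expect_equal(g4$pct_in_tolerance, 100 * sum(abs(e) <= 3.3) / 100)
  ev <- stats::lm(yh ~ yt)
  expect_equal(g4$alpha1, unname(coef(ev)[2]))
  expect_equal(g4$alpha0, unname(coef(ev)[1]))
  expect_equal(g4$re2, summary(ev)$adj.r.squared)
  expect_equal(g4$mean_group_sd,
               mean(vapply(split(e, grp), stats::sd, numeric(1))))
  # reordering conditions changes nothing
  perm <- withr::with_seed(2, sample(100))
  g5 <- goodness_of_fit(yh[perm], yt[perm], groups = grp[perm])
  for (f in c("rmse", "mae", "mape", "raae", "max_abs_err",
              "pct_in_tolerance", "alpha1", "alpha0", "re2",
              "mean_group_sd"))
    expect_equal(g4[[f]], g5[[f]])
  # the 3.3 default equals 10% of a 33-log-unit MFPT range
  expect_equal(mfpt_tolerance(c(exp(2), exp(35))), 3.3)
})

test_that("the fitted fallrisk object behaves like a classic model object", {
  bank <- walker_bank("train", timings = "DS0")
  cd <- bank_chain_data(bank)
  fit <- suppressWarnings(fallrisk(cd$metrics, cd$mfpt,
                                   conditions = cd$table$label, seed = 7))
  expect_s3_class(fit, "fallrisk")
  expect_named(coef(fit)[1], "(Intercept)")
  expect_length(fitted(fit), nrow(cd$metrics))
  expect_equal(unname(residuals(fit)), log(cd$mfpt) - fitted(fit))
  s <- summary(fit)
  expect_s3_class(s, "summary.fallrisk")
  expect_true(s$adj_r_squared > 0.5)
  expect_output(print(fit), "fall-risk model")
  # same seed: identical refit
  fit2 <- suppressWarnings(fallrisk(cd$metrics, cd$mfpt,
                                    conditions = cd$table$label, seed = 7))
  expect_identical(fit$terms, fit2$terms)
  expect_equal(coef(fit), coef(fit2))
  # with_lyap variant requires the long-term entries
  expect_error(suppressWarnings(
    fallrisk(cd$metrics, cd$mfpt, conditions = cd$table$label,
             variant = "with_lyap")), "missing")
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
})
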