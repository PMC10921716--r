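test_that("pre-selection applies the Bonferroni rule and matches a permutation oracle", {
  # threshold arithmetic at the headline setting m = 59
  d59 <- gen_lls_like(lls_params(n = 200, m = 59, gompertz_a = 1e-5, seed = 30))
  sel <- preselect_markers(d59, alpha_fw = 0.05)
  expect_equal(attr(sel, "threshold"), 0.05 / 59)

  # a null marker at large n is (almost surely) not selected; an age-coupled
  # marker is
  set.seed(31)
  n <- 1000
  C <- rnorm(n, 50, 5)
  D <- rnorm(n, 0, 2)
  X <- cbind(informative = 0.3 * scale(C)[, 1] + rnorm(n) * sqrt(1 - 0.09),
             null = rnorm(n))
  d <- cohort_data(age = C, markers = X)
  sel2 <- preselect_markers(d)
  expect_true("informative" %in% names(sel2))
  expect_false("null" %in% names(sel2))

  # the t-test p-value agrees with a permutation oracle on a smaller sample
  x <- X[1:300, 1]; y <- C[1:300]
  p_t <- attr(preselect_markers(cohort_data(age = y, markers = cbind(m = x))),
              "p_values")[["m"]]
  p_perm <- perm_cor_oracle(x, y, n_perm = 4000, seed = 2)
  if (p_t > 1e-3) {
    expect_lt(abs(p_t - p_perm), 4 * sqrt(p_perm * (1 - p_perm) / 4000) + 1e-3)
  } else {
    expect_lt(p_perm, 0.01)
  }

  # constant marker skipped with a warning
  dc <- cohort_data(age = C, markers = cbind(flat = rep(1, n), ok = X[, 1]))
  expect_warning(preselect_markers(dc), "constant")
})

test_that("MLR matches the normal-equations oracle and flags rank deficiency", {
  d <- make_fixture(n = 150, seed = 7)
  fit <- fit_mlr(d)
  beta <- ols_oracle(marker_matrix(d), d$age)
  expect_equal(unname(c(fit$intercept, fit$weights)), unname(beta),
               tolerance = 1e-8)

  # a marker equal to age: slope 1, intercept 0, fitted == age
  dd <- cohort_data(age = d$age, markers = cbind(copyC = d$age + 0,
                                                 other = d$m1))
  f1 <- fit_mlr(dd, "copyC")
  expect_equal(unname(f1$weights), 1, tolerance = 1e-10)
  expect_equal(f1$intercept, 0, tolerance = 1e-8)
  expect_equal(predict(f1, dd), dd$age, tolerance = 1e-8)

  # duplicated column -> informative error
  d2 <- cohort_data(age = d$age, markers = cbind(a = d$m1, b = d$m1))
  expect_error(fit_mlr(d2), "collinear")
})

test_that("MLR cannot tell the true from the false marker (sign test over replicates)", {
  diffs <- vapply(1:50, function(r) {
    d <- gen_example1(sim_params1(n = 400, seed = 100 + r))
    fit_mlr(d, "X")$weights[[1]] - fit_mlr(d, "Xprime")$weights[[1]]
  }, numeric(1))
  bt <- binom.test(sum(diffs > 0), length(diffs))
  expect_gt(bt$p.value, 0.01)
})

test_that("cross-validated ridge matches its limits and the brute-force CV oracle", {
  d <- make_fixture(n = 80, seed = 9)
  # lambda = 0 coincides with OLS on the same markers
  r0 <- fit_ridge_cv(d, lambda_grid = 0, folds = 4, seed = 1)
  m0 <- fit_mlr(d)
  expect_equal(r0$weights, m0$weights, tolerance = 1e-6)
  expect_equal(r0$intercept, m0$intercept, tolerance = 1e-6)

  # infinite shrinkage: weights vanish, fitted value -> mean age
  rInf <- fit_ridge_cv(d, lambda_grid = 1e12, folds = 4, seed = 1)
  expect_lt(max(abs(rInf$weights)), 1e-6)
  expect_equal(mean(abs(predict(rInf, d) - mean(d$age))), 0, tolerance = 1e-4)

  # 10-subject fixture: chosen lambda equals the exhaustive oracle's argmin
  ds <- make_fixture(n = 10, seed = 11)
  grid <- 10^seq(-2, 3, length.out = 25)
  fit <- fit_ridge_cv(ds, folds = 5, lambda_grid = grid, seed = 3)
  fold_id <- with_seed_public(3, sample(rep_len(1:5, 10)))
  orc <- ridge_cv_oracle(marker_matrix(ds), ds$age, fold_id, grid)
  expect_equal(fit$ridge_lambda, orc$lambda)
  expect_equal(attr(fit, "cv")$cv_mse, orc$cv_mse, tolerance = 1e-8)

  expect_error(fit_ridge_cv(d, lambda_grid = numeric(0)), "non-empty")
})

test_that("KD reversed regressions match the oracle and the generating model", {
  d <- make_fixture(n = 200, seed = 13)
  fit <- fit_kd(d)
  for (j in 1:2) {
    beta <- ols_oracle(d$age, marker_matrix(d)[, j])
    expect_equal(unname(c(fit$q[j], fit$k[j])), unname(beta), tolerance = 1e-8)
  }
  # plug-in values under the additive generator at large n:
  # k ~ beta = 1, s^2 ~ beta^2*var_delta + var_eps = 5
  big <- gen_example1(sim_params1(n = 1e5, seed = 14))
  kf <- fit_kd(big, "X")
  expect_equal(unname(kf$k), 1, tolerance = 0.02)
  expect_equal(unname(kf$s^2), 5, tolerance = 0.1)

  # deterministic marker: zero residual sd -> dropped with warning
  dd <- cohort_data(age = d$age, markers = cbind(det = 2 + 3 * d$age,
                                                 ok = d$m1))
  expect_warning(kf2 <- fit_kd(dd), "dropping")
  expect_identical(kf2$dropped, "det")
  expect_error(suppressWarnings(fit_kd(dd, "det")), "no usable")
})

test_that("KD point estimate is the precision-weighted minimizer", {
  # single marker reduces to (x - q) / k
  f1 <- structure(list(markers = "m1", q = c(m1 = 2), k = c(m1 = 0.5),
                       s = c(m1 = 1), dropped = character(0)), class = "kd_fit")
  d1 <- cohort_data(age = c(50, 60, 70), markers = cbind(m1 = c(27, 32, 37)))
  expect_equal(predict_kd(f1, d1), (c(27, 32, 37) - 2) / 0.5)

  # equal slopes and sds: the symmetric average
  f2 <- structure(list(markers = c("a", "b"), q = c(a = 1, b = 3),
                       k = c(a = 2, b = 2), s = c(a = 1.5, b = 1.5),
                       dropped = character(0)), class = "kd_fit")
  d2 <- cohort_data(age = c(50, 55), markers = cbind(a = c(101, 111),
                                                     b = c(103, 113)))
  expect_equal(predict_kd(f2, d2),
               ((c(101, 111) - 1) + (c(103, 113) - 3)) / (2 * 2))

  # general case agrees with the grid-search minimizer of the KD objective
  d <- make_fixture(n = 6, seed = 15)
  fit <- fit_kd(d)
  ba <- predict_kd(fit, d)
  for (i in 1:6) {
    ba_oracle <- kd_grid_oracle(fit$q, fit$k, fit$s, marker_matrix(d)[i, ])
    expect_equal(ba[i], ba_oracle, tolerance = 1e-4)
  }
})

test_that("PC1 predictor matches the eigen oracle and its rescaling identity", {
  set.seed(16)
  n <- 300
  C <- rnorm(n, 50, 4)
  X <- cbind(a = C + rnorm(n), b = 0.8 * C + rnorm(n), c = -0.5 * C + rnorm(n),
             d = C + rnorm(n))
  d <- cohort_data(age = C, markers = X)
  fit <- fit_pc1(d)
  # loadings match the SVD oracle up to sign
  ld <- attr(fit, "loadings")
  orc <- pc1_svd_oracle(marker_matrix(d, names(ld)))
  expect_equal(abs(unname(ld)), abs(orc), tolerance = 1e-8)
  # proxy reproduces the training age mean and sd; positively age-oriented
  pr <- predict(fit, d)
  expect_equal(mean(pr), mean(C), tolerance = 1e-8)
  expect_equal(sd(pr), sd(C), tolerance = 1e-8)
  expect_gt(cor(pr, C), 0)

  # two duplicated age-coupled markers: score still positively age-aligned
  d2 <- cohort_data(age = C, markers = cbind(a = X[, "a"], b = X[, "a"] + 1e-8,
                                             e = X[, "b"]))
  expect_gt(cor(predict(fit_pc1(d2), d2), C), 0.5)

  # < 2 surviving markers is an error
  dnull <- cohort_data(age = C, markers = cbind(z1 = rnorm(n), z2 = rnorm(n)))
  expect_error(fit_pc1(dnull), "fewer than 2")
})

test_that("equal-weights rule is the sign-preserving mean of absolute coefficients", {
  base <- new_model_for_test(c(a = 2, b = -4, c = 6), intercept = 5)
  eq <- make_equal_weights(base)
  expect_equal(unname(eq$weights), c(4, -4, 4))
  expect_equal(eq$intercept, 0)

  # all-equal coefficients are a fixed point up to the intercept: same delta
  d <- make_fixture(n = 120, seed = 17)
  m <- new_model_for_test(c(m1 = 3, m2 = 3), intercept = 2)
  expect_equal(predict_delta(make_equal_weights(m), d)$delta_hat,
               predict_delta(m, d)$delta_hat, tolerance = 1e-10)
})

test_that("random-weight draws are reproducible with the stated moments", {
  signs <- c(a = 1, b = -1, c = 1)
  expect_identical(sample_random_weights(signs, 1, seed = 5)[[1]]$weights,
                   sample_random_weights(signs, 1, seed = 5)[[1]]$weights)
  draws <- sample_random_weights(signs, 1000, seed = 6)
  expect_length(draws, 1000)
  expect_identical(draws[[1000]]$draw_index, 1000L)
  W <- t(vapply(draws, function(m) m$weights, numeric(3)))
  expect_true(all(abs(colMeans(W) - c(0.5, -0.5, 0.5)) <
                    4 * sqrt(1 / 12) / sqrt(1000)))
  expect_true(all(sign(W) == rep(c(1, -1, 1), each = 1000)))
  expect_error(sample_random_weights(numeric(0)), "non-empty")
})

test_that("delta extraction is the residual on age, orthogonal by construction", {
  d <- make_fixture(n = 250, seed = 18)
  pd <- predict_delta(fit_mlr(d), d)
  # oracle: residuals of proxy-on-age from explicit normal equations
  beta <- ols_oracle(matrix(d$age), pd$proxy)
  expect_equal(pd$delta_hat, pd$proxy - beta[1] - beta[2] * d$age,
               tolerance = 1e-8)

  # orthogonality invariant across every method on the same data
  preds <- list(predict_delta(fit_mlr(d), d),
                predict_delta(fit_kd(d), d),
                predict_delta(make_equal_weights(fit_mlr(d)), d),
                predict_delta(fit_ridge_cv(d, folds = 5, seed = 1), d),
                predict_delta(sample_random_weights(
                  c(m1 = 1, m2 = -1), 1, seed = 2)[[1]], d))
  for (pd in preds) {
    expect_lt(abs(mean(pd$delta_hat)), 1e-8)
    expect_lt(abs(cor(pd$delta_hat, d$age)), 1e-8)
  }

  # perfect chronological predictor: the biomarker paradox, delta == 0
  pdC <- predict_delta(d$age + 0, d)
  expect_lt(max(abs(pdC$delta_hat)), 1e-10)

  # proxy uncorrelated with age: delta is just the centered proxy
  set.seed(19)
  noise <- rnorm(250)
  pdN <- predict_delta(noise, d)
  b <- cov(noise, d$age) / var(d$age)
  expect_equal(pdN$delta_hat, noise - mean(noise) - b * (d$age - mean(d$age)),
               tolerance = 1e-10)

  # constant proxy: degenerate, all zeros, with a warning
  expect_warning(pd0 <- predict_delta(rep(3, 250), d), "constant")
  expect_true(pd0$degenerate)
  expect_equal(pd0$delta_hat, rep(0, 250))
})

test_that("model JSON serialization round-trips", {
  d <- make_fixture(n = 60, seed = 20)
  for (model in list(fit_mlr(d), fit_ridge_cv(d, folds = 4, seed = 1),
                     fit_kd(d))) {
    back <- model_from_json(model_to_json(model))
    if (inherits(model, "linear_age_model")) {
      expect_equal(back$weights, model$weights)
      expect_equal(back$intercept, model$intercept)
      expect_equal(back$ridge_lambda, model$ridge_lambda)
      expect_equal(predict(back, d), predict(model, d))
    } else {
      expect_equal(back$k, model$k)
      expect_equal(predict_kd(back, d), predict_kd(model, d))
    }
  }
})
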