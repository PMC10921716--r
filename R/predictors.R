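# Cross-sectional age-predictor families and divergence extraction.
#
# All linear families share one container (`linear_age_model`, raw-marker
# scale: proxy = intercept + X %*% weights), so that downstream delta
# extraction and serialization are method-agnostic. The Klemera-Doubal fit
# has its own container because it stores per-marker reversed regressions
# rather than a single linear combination.

new_linear_age_model <- function(method, markers, intercept, weights,
                                 ridge_lambda = NULL, pc_rescale = NULL,
                                 draw_index = NULL) {
  stopifnot(length(weights) == length(markers))
  structure(list(method = method, markers = markers,
                 intercept = unname(intercept),
                 weights = stats::setNames(as.numeric(weights), markers),
                 ridge_lambda = ridge_lambda, pc_rescale = pc_rescale,
                 draw_index = draw_index),
            class = "linear_age_model")
}

#' @export
print.linear_age_model <- function(x, ...) {
  cat(sprintf("<linear_age_model> method = %s, %d markers\n",
              x$method, length(x$weights)))
  if (!is.null(x$ridge_lambda)) cat("  lambda =", format(x$ridge_lambda), "\n")
  invisible(x)
}

#' Predict the raw age proxy of a linear model
#'
#' @param object a `linear_age_model`.
#' @param data a [cohort_data] containing the model's markers.
#' @param ... unused.
#' @return numeric vector: `intercept + X %*% weights`.
#' @export
predict.linear_age_model <- function(object, data, ...) {
  X <- marker_matrix(data, object$markers)
  unname(drop(object$intercept + X %*% object$weights))
}

#' Univariate pre-selection of age-associated markers
#'
#' Selects markers whose Pearson correlation with chronological age is
#' significant at the Bonferroni-corrected level `alpha_fw / m` (two-sided
#' t-test with n - 2 degrees of freedom). With the default family-wise level
#' 0.05 and m = 59 markers this is the per-marker threshold
#' 0.05 / 59 = 8.47e-4.
#'
#' @param data a [cohort_data].
#' @param alpha_fw family-wise significance level.
#' @return integer indices (into the marker set) of selected markers, named
#'   by marker. Attributes: `"threshold"` (the per-marker level),
#'   `"p_values"` (all per-marker p-values).
#' @export
preselect_markers <- function(data, alpha_fw = 0.05) {
  stopifnot(inherits(data, "cohort_data"))
  X <- marker_matrix(data)
  n <- nrow(X)
  if (n < 4L) stop("need at least 4 subjects for pre-selection", call. = FALSE)
  m <- ncol(X)
  thr <- alpha_fw / m
  C <- data$age
  pvals <- vapply(seq_len(m), function(j) {
    x <- X[, j]
    if (stats::sd(x) == 0) {
      warning("marker ", colnames(X)[j], " is constant; skipped", call. = FALSE)
      return(NA_real_)
    }
    r <- stats::cor(x, C)
    tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }, numeric(1))
  names(pvals) <- colnames(X)
  idx <- which(!is.na(pvals) & pvals < thr)
  structure(idx, threshold = thr, p_values = pvals)
}

#' Fit the multiple-linear-regression age predictor
#'
#' Ordinary least squares of chronological age on the selected markers; the
#' fitted value is the age proxy ("predicted biological age").
#'
#' @param data a [cohort_data].
#' @param subset markers to use (names or indices); default all.
#' @return a `linear_age_model` with `method = "mlr"`.
#' @export
fit_mlr <- function(data, subset = NULL) {
  stopifnot(inherits(data, "cohort_data"))
  X <- marker_matrix(data, subset)
  if (nrow(X) <= ncol(X) + 1L) {
    stop("need n > number of markers + 1 for OLS", call. = FALSE)
  }
  A <- cbind(`(Intercept)` = 1, X)
  qrA <- qr(A)
  if (qrA$rank < ncol(A)) {
    bad <- colnames(A)[qrA$pivot[(qrA$rank + 1):ncol(A)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qrA, data$age)
  new_linear_age_model("mlr", colnames(X), beta[1L], beta[-1L])
}

# closed-form ridge with unpenalized intercept on a fixed design
ridge_solve <- function(X, y, lambda) {
  A <- cbind(1, X)
  p <- ncol(A)
  D <- diag(c(0, rep(1, p - 1L)), p)
  solve(crossprod(A) + lambda * D, crossprod(A, y))
}

#' Fit a ridge age predictor with K-fold cross-validated penalty
#'
#' Markers are z-scored internally before penalization (the intercept is
#' unpenalized and chronological age is left on its natural scale); the
#' penalty minimizes `sum((y - b0 - Z w)^2) + lambda * sum(w^2)` on the
#' z-scale. The penalty is chosen from `lambda_grid` by minimizing the mean
#' squared cross-validated prediction error; ties go to the smallest lambda.
#' The returned model is expressed back on the raw marker scale, so
#' `lambda_grid = 0` reproduces [fit_mlr] exactly.
#'
#' @param data a [cohort_data].
#' @param subset markers to use; default all.
#' @param folds number of cross-validation folds (default 10).
#' @param lambda_grid candidate penalties; default logarithmic grid
#'   1e-3..1e4 with 50 points.
#' @param seed seed for the fold assignment.
#' @return a `linear_age_model` with `method = "ridge"`, the chosen penalty
#'   in `$ridge_lambda`, and the per-lambda CV error table in attribute
#'   `"cv"`.
#' @export
fit_ridge_cv <- function(data, subset = NULL, folds = 10,
                         lambda_grid = 10^seq(-3, 4, length.out = 50),
                         seed = 1) {
  stopifnot(inherits(data, "cohort_data"))
  folds <- check_count(folds, "folds", lower = 2L)
  if (!length(lambda_grid)) stop("`lambda_grid` must be non-empty", call. = FALSE)
  lambda_grid <- sort(as.numeric(lambda_grid))
  X <- marker_matrix(data, subset)
  y <- data$age
  n <- nrow(X)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  if (any(scl == 0)) {
    stop("constant marker(s): ", paste(colnames(X)[scl == 0], collapse = ", "),
         call. = FALSE)
  }
  Z <- scale(X, center = ctr, scale = scl)

  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  cv_err <- matrix(NA_real_, length(lambda_grid), folds)
  for (k in seq_len(folds)) {
    tr <- fold_id != k
    for (i in seq_along(lambda_grid)) {
      w <- ridge_solve(Z[tr, , drop = FALSE], y[tr], lambda_grid[i])
      pred <- drop(cbind(1, Z[!tr, , drop = FALSE]) %*% w)
      cv_err[i, k] <- mean((y[!tr] - pred)^2)
    }
  }
  mean_err <- rowMeans(cv_err)
  best <- which.min(mean_err)   # first (= smallest lambda) on ties
  lambda <- lambda_grid[best]

  w <- drop(ridge_solve(Z, y, lambda))
  w_raw <- w[-1L] / scl
  b0 <- w[1L] - sum(w_raw * ctr)
  out <- new_linear_age_model("ridge", colnames(X), b0, w_raw,
                              ridge_lambda = lambda)
  attr(out, "cv") <- data.frame(lambda = lambda_grid, cv_mse = mean_err)
  out
}

#' Fit the Klemera-Doubal reversed regressions
#'
#' Regresses each marker on chronological age (OLS), storing intercept
#' `q_j`, slope `k_j` and residual standard deviation `s_j` (denominator
#' n - 2). Markers whose slope magnitude falls below
#' `1e-8 * sd(marker) / sd(age)`, or whose residual sd is negligible
#' (below `1e-8 * sd(marker)`: a marker that is an exact linear function of
#' age, up to floating point), are dropped with a warning:
#' their precision weights would be unstable or infinite.
#'
#' @param data a [cohort_data].
#' @param subset markers to use; default all.
#' @return an object of class `kd_fit` with fields `markers`, `q`, `k`, `s`
#'   and `dropped`.
#' @export
fit_kd <- function(data, subset = NULL) {
  stopifnot(inherits(data, "cohort_data"))
  X <- marker_matrix(data, subset)
  n <- nrow(X)
  if (n < 4L) stop("need at least 4 subjects", call. = FALSE)
  C <- data$age
  sdC <- stats::sd(C)
  fits <- lapply(seq_len(ncol(X)), function(j) {
    x <- X[, j]
    k <- stats::cov(x, C) / stats::var(C)
    q <- mean(x) - k * mean(C)
    res <- x - q - k * C
    s <- sqrt(sum(res^2) / (n - 2))
    c(q = q, k = k, s = s)
  })
  fits <- do.call(rbind, fits)
  rownames(fits) <- colnames(X)
  sdX <- apply(X, 2, stats::sd)
  tol <- 1e-8 * sdX / sdC
  keep <- abs(fits[, "k"]) >= tol & fits[, "s"] > 1e-8 * sdX
  if (any(!keep)) {
    warning("dropping marker(s) with negligible age slope or zero residual sd: ",
            paste(rownames(fits)[!keep], collapse = ", "), call. = FALSE)
  }
  if (!any(keep)) stop("no usable markers remain for the KD fit", call. = FALSE)
  structure(list(markers = rownames(fits)[keep],
                 q = fits[keep, "q"], k = fits[keep, "k"], s = fits[keep, "s"],
                 dropped = rownames(fits)[!keep]),
            class = "kd_fit")
}

#' @export
print.kd_fit <- function(x, ...) {
  cat(sprintf("<kd_fit> %d markers (%d dropped)\n",
              length(x$markers), length(x$dropped)))
  invisible(x)
}

#' Klemera-Doubal biological-age estimate
#'
#' Precision-weighted least-squares combination of the reversed regressions:
#' the estimate for a subject with marker values x_j is the minimizer over
#' BA of `sum_j ((x_j - q_j - k_j * BA) / s_j)^2`, i.e.
#' `BA = sum_j (x_j - q_j) k_j / s_j^2 / sum_j k_j^2 / s_j^2`.
#'
#' @param fit a [fit_kd] result.
#' @param data a [cohort_data] containing the fit's markers.
#' @return numeric vector of biological-age estimates (the raw age proxy).
#' @export
predict_kd <- function(fit, data) {
  stopifnot(inherits(fit, "kd_fit"))
  if (!length(fit$markers)) stop("empty marker set", call. = FALSE)
  X <- marker_matrix(data, fit$markers)
  wj <- fit$k / fit$s^2
  denom <- sum(fit$k * wj)
  unname(drop(sweep(X, 2, fit$q) %*% wj) / denom)
}

#' Fit the first-principal-component age predictor
#'
#' Pre-selects age-associated markers ([preselect_markers]), z-scores them,
#' and takes the leading eigenvector of their correlation matrix as
#' loadings. The standardized score BS (unit variance, sign-oriented so that
#' cor(BS, age) > 0) is mapped to the age scale as
#' `proxy = BS * sd(age) + mean(age)` using the training sample moments, so
#' the proxy has exactly the age mean and sd on the training data.
#'
#' @param data a [cohort_data].
#' @param alpha_fw family-wise level passed to [preselect_markers].
#' @return a `linear_age_model` with `method = "pc1"` (weights expressed on
#'   the raw marker scale) and `pc_rescale = c(mu_c, sigma_c)`; loadings on
#'   the z-scale are kept in attribute `"loadings"`.
#' @export
fit_pc1 <- function(data, alpha_fw = 0.05) {
  stopifnot(inherits(data, "cohort_data"))
  sel <- preselect_markers(data, alpha_fw)
  if (length(sel) < 2L) {
    stop("fewer than 2 markers survive pre-selection", call. = FALSE)
  }
  X <- marker_matrix(data, names(sel))
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  Z <- scale(X, center = ctr, scale = scl)
  eig <- eigen(stats::cor(X), symmetric = TRUE)
  load <- eig$vectors[, 1L]
  score <- drop(Z %*% load)
  if (stats::cor(score, data$age) < 0) {
    load <- -load
    score <- -score
  }
  mu_c <- mean(data$age)
  sd_c <- stats::sd(data$age)
  sd_s <- stats::sd(score)
  # proxy = mu_c + sd_c * (Z %*% load - mean(score)) / sd(score): affine in X
  w_raw <- sd_c * load / (scl * sd_s)
  b0 <- mu_c - sd_c * mean(score) / sd_s - sum(w_raw * ctr)
  out <- new_linear_age_model("pc1", colnames(X), b0, w_raw,
                              pc_rescale = c(mu_c = mu_c, sigma_c = sd_c))
  attr(out, "loadings") <- stats::setNames(load, colnames(X))
  out
}

#' Naive equal-weights variant of a fitted linear model
#'
#' Replaces every marker weight by `sign(w_j) * mean(|w|)` — the signs are
#' kept, the sizes are flattened to the mean absolute coefficient (intercept
#' excluded from the mean and set to 0; the intercept is irrelevant once the
#' proxy is residualized on age).
#'
#' @param mlr a `linear_age_model` (typically from [fit_mlr]).
#' @return a `linear_age_model` with `method = "equal"`.
#' @export
make_equal_weights <- function(mlr) {
  stopifnot(inherits(mlr, "linear_age_model"))
  if (!length(mlr$weights)) stop("model has no marker weights", call. = FALSE)
  w <- sign(mlr$weights) * mean(abs(mlr$weights))
  new_linear_age_model("equal", mlr$markers, 0, w)
}

#' Sign-preserving random-weight linear combinations
#'
#' Draws `n_draws` weight vectors `sign_j * U_j`, `U_j ~ Uniform(0, 1)`
#' i.i.d., keeping each marker's given sign. Used as the "no skill" reference
#' family: any signal it captures comes from the signs alone.
#'
#' @param signs named numeric vector of per-marker signs (typically
#'   `sign(coef(mlr))`); names are the marker labels.
#' @param n_draws number of draws (default 1000).
#' @param seed integer RNG seed.
#' @return a list of `linear_age_model`s with `method = "random"` and
#'   `draw_index` 1..n_draws.
#' @export
sample_random_weights <- function(signs, n_draws = 1000, seed = 1) {
  if (!length(signs)) stop("`signs` must be non-empty", call. = FALSE)
  n_draws <- check_count(n_draws, "n_draws", lower = 1L)
  markers <- names(signs)
  if (is.null(markers)) stop("`signs` must be named by marker", call. = FALSE)
  with_seed(seed, {
    lapply(seq_len(n_draws), function(i) {
      u <- stats::runif(length(signs))
      new_linear_age_model("random", markers, 0, sign(signs) * u,
                           draw_index = i)
    })
  })
}

#' Extract the predicted divergence from an age proxy
#'
#' The divergence prediction is the residual of the raw age proxy regressed
#' on chronological age (simple OLS), so by construction `mean(delta_hat) =
#' 0` and `cor(delta_hat, age) = 0` to numerical precision. A constant proxy
#' (the biomarker-paradox degeneracy) yields an all-zero delta with a
#' warning.
#'
#' @param model a `linear_age_model`, a `kd_fit`, or a numeric vector
#'   already holding the raw proxy.
#' @param data a [cohort_data].
#' @return an object of class `delta_prediction`: list with `method`,
#'   `proxy`, `delta_hat`, and `degenerate` flag.
#' @export
predict_delta <- function(model, data) {
  stopifnot(inherits(data, "cohort_data"))
  if (inherits(model, "kd_fit")) {
    proxy <- predict_kd(model, data)
    method <- "kd"
    draw <- NULL
  } else if (inherits(model, "linear_age_model")) {
    proxy <- predict(model, data)
    method <- model$method
    draw <- model$draw_index
  } else if (is.numeric(model)) {
    proxy <- as.numeric(model)
    if (length(proxy) != nrow(data)) stop("proxy length mismatch", call. = FALSE)
    method <- "proxy"
    draw <- NULL
  } else {
    stop("unsupported model type", call. = FALSE)
  }
  degenerate <- stats::sd(proxy) < .Machine$double.eps^0.5
  if (degenerate) {
    warning("constant age proxy: delta predictions are identically zero",
            call. = FALSE)
    dh <- rep(0, length(proxy))
  } else {
    C <- data$age
    b <- stats::cov(proxy, C) / stats::var(C)
    a <- mean(proxy) - b * mean(C)
    dh <- proxy - a - b * C
  }
  structure(list(method = method, proxy = proxy, delta_hat = dh,
                 degenerate = degenerate, draw_index = draw),
            class = "delta_prediction")
}

#' @export
print.delta_prediction <- function(x, ...) {
  cat(sprintf("<delta_prediction> method = %s, n = %d, sd = %.3f\n",
              x$method, length(x$delta_hat), stats::sd(x$delta_hat)))
  invisible(x)
}

#' Serialize a fitted model to JSON
#'
#' @param model a `linear_age_model` or `kd_fit`.
#' @param path optional file; if omitted the JSON string is returned.
#' @return JSON string (invisibly, when writing to a file).
#' @export
model_to_json <- function(model, path = NULL) {
  if (inherits(model, "linear_age_model")) {
    obj <- list(class = "linear_age_model", method = model$method,
                markers = model$markers, intercept = model$intercept,
                weights = as.list(model$weights),
                ridge_lambda = model$ridge_lambda,
                pc_rescale = as.list(model$pc_rescale),
                draw_index = model$draw_index)
  } else if (inherits(model, "kd_fit")) {
    obj <- list(class = "kd_fit", markers = model$markers,
                q = as.list(model$q), k = as.list(model$k),
                s = as.list(model$s), dropped = model$dropped)
  } else stop("unsupported model type", call. = FALSE)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' Restore a model from its JSON serialization
#' @param json JSON string or file path.
#' @return the deserialized model object.
#' @export
model_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  if (identical(obj$class, "linear_age_model")) {
    new_linear_age_model(obj$method, obj$markers, obj$intercept,
                         unlist(obj$weights),
                         ridge_lambda = obj$ridge_lambda,
                         pc_rescale = unlist(obj$pc_rescale),
                         draw_index = obj$draw_index)
  } else if (identical(obj$class, "kd_fit")) {
    structure(list(markers = obj$markers, q = unlist(obj$q),
                   k = unlist(obj$k), s = unlist(obj$s),
                   dropped = obj$dropped %||% character(0)),
              class = "kd_fit")
  } else stop("unrecognized model JSON", call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
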