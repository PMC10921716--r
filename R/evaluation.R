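# Evaluation surfaces: divergence recovery against simulated truth,
# age-prediction RMSE, Cox association on the age timescale, and
# observational-equivalence diagnostics.

#' Recovery of the simulated divergence
#'
#' Compares a divergence prediction with the simulated truth: Pearson
#' correlation, root-mean-square error (years), and the slope of truth on
#' prediction (attenuation diagnostic; 1 means calibrated).
#'
#' @param pred a [predict_delta] result or a numeric vector of predicted
#'   divergences.
#' @param truth numeric vector of true divergences.
#' @return object of class `recovery_metrics`: list with `pearson_r`,
#'   `rmse`, `slope`, `degenerate`.
#' @export
eval_delta_recovery <- function(pred, truth) {
  dh <- if (inherits(pred, "delta_prediction")) pred$delta_hat else as.numeric(pred)
  if (length(dh) != length(truth)) stop("length mismatch", call. = FALSE)
  degenerate <- stats::sd(dh) < .Machine$double.eps^0.5
  if (degenerate) {
    r <- 0
    slope <- NA_real_
  } else {
    r <- stats::cor(dh, truth)
    slope <- stats::cov(truth, dh) / stats::var(dh)
  }
  structure(list(pearson_r = r,
                 rmse = sqrt(mean((dh - truth)^2)),
                 slope = slope, degenerate = degenerate),
            class = "recovery_metrics")
}

#' Root-mean-square error of an age proxy
#'
#' @param proxy numeric vector of predicted ages.
#' @param age numeric vector of chronological ages.
#' @return RMSE in years.
#' @export
rmse_age <- function(proxy, age) {
  if (length(proxy) != length(age)) stop("length mismatch", call. = FALSE)
  sqrt(mean((proxy - age)^2))
}

#' Cox association of the scaled divergence with mortality
#'
#' Fits a Cox proportional-hazards model on the chronological-age timescale
#' with delayed entry (`Surv(entry_age, exit_age, event)`), covariates the
#' z-scored divergence prediction and sex, Efron tie handling. Because the
#' divergence is scaled to unit sd before inclusion, the coefficient is a
#' log hazard ratio per sd — comparable across methods.
#'
#' @param pred a [predict_delta] result or numeric vector.
#' @param data a [cohort_data] with survival fields.
#' @return object of class `cox_delta_result`: `loghr_per_sd`, `se`,
#'   `n_subjects`, `n_events`, `method`, `draw_index`, `degenerate`,
#'   `converged`.
#' @export
fit_cox_delta <- function(pred, data) {
  stopifnot(inherits(data, "cohort_data"))
  if (is.null(data$event)) stop("survival fields missing", call. = FALSE)
  if (sum(data$event) < 1) stop("no events in the data", call. = FALSE)
  dh <- if (inherits(pred, "delta_prediction")) pred$delta_hat else as.numeric(pred)
  method <- if (inherits(pred, "delta_prediction")) pred$method else "proxy"
  draw <- if (inherits(pred, "delta_prediction")) pred$draw_index else NULL
  if (length(dh) != nrow(data)) stop("length mismatch", call. = FALSE)

  res <- list(loghr_per_sd = 0, se = NA_real_, n_subjects = nrow(data),
              n_events = sum(data$event), method = method, draw_index = draw,
              degenerate = FALSE, converged = TRUE)
  if (stats::sd(dh) < .Machine$double.eps^0.5) {
    warning("constant divergence prediction; Cox coefficient set to 0",
            call. = FALSE)
    res$degenerate <- TRUE
    return(structure(res, class = "cox_delta_result"))
  }
  z <- as.numeric(scale(dh))
  # drop sex when constant (degenerate toy fixtures)
  use_sex <- !is.null(data$sex) && stats::sd(data$sex) > 0
  df <- data.frame(entry = data$entry_age, exit = data$exit_age,
                   event = data$event, z = z)
  fml <- survival::Surv(entry, exit, event) ~ z
  if (use_sex) {
    df$sex <- data$sex
    fml <- survival::Surv(entry, exit, event) ~ z + sex
  }
  fit <- tryCatch(
    survival::coxph(fml, data = df, ties = "efron"),
    warning = function(w) {
      f <- suppressWarnings(survival::coxph(fml, data = df, ties = "efron"))
      attr(f, "flagged") <- conditionMessage(w)
      f
    })
  res$loghr_per_sd <- unname(stats::coef(fit)["z"])
  res$se <- unname(sqrt(diag(stats::vcov(fit)))["z"])
  res$converged <- is.null(attr(fit, "flagged"))
  structure(res, class = "cox_delta_result")
}

#' @export
print.cox_delta_result <- function(x, ...) {
  cat(sprintf("<cox_delta_result> %s: logHR/sd = %.4f (se %.4f), %d events / %d subjects\n",
              x$method, x$loghr_per_sd, x$se, x$n_events, x$n_subjects))
  invisible(x)
}

#' Observational-equivalence diagnostics for two marker/age pairs
#'
#' Compares the observable joint distribution of two (marker, age) pairs:
#' differences in means, variances and the marker-age covariance, each
#' scaled by its Monte-Carlo standard error, plus two-sample
#' Kolmogorov-Smirnov tests per column. The pair is flagged
#' "indistinguishable" when every moment difference is within `se_mult`
#' standard errors and no KS test rejects at `ks_alpha`.
#'
#' @param pairA,pairB two-column objects (matrix or data.frame) holding the
#'   marker in column 1 and chronological age in column 2, equal row counts.
#' @param se_mult moment tolerance in Monte-Carlo standard errors
#'   (default 4).
#' @param ks_alpha level of the KS check (default 0.01).
#' @return object of class `equiv_report`: data.frame `moments` (statistic,
#'   value in A/B, difference, se, standardized difference), `ks_p`
#'   (p-values for marker and age), and logical `indistinguishable`.
#' @export
observational_equivalence <- function(pairA, pairB, se_mult = 4,
                                      ks_alpha = 0.01) {
  A <- as.matrix(pairA); B <- as.matrix(pairB)
  if (ncol(A) != 2L || ncol(B) != 2L) stop("pairs must have 2 columns", call. = FALSE)
  if (nrow(A) != nrow(B)) stop("equal sample sizes required", call. = FALSE)
  n <- nrow(A)

  stat_row <- function(name, a, b, se) {
    data.frame(statistic = name, A = a, B = b, diff = b - a, se = se,
               z = (b - a) / se)
  }
  # Monte-Carlo SEs of the difference of two independent estimates
  se_mean <- function(x, y) sqrt(stats::var(x) / n + stats::var(y) / n)
  se_var <- function(x, y) {
    # var(s^2) = (mu4 - sigma^4 (n-3)/(n-1)) / n; plug-in moments
    v <- function(u) {
      m <- mean(u); mu4 <- mean((u - m)^4); s2 <- stats::var(u)
      (mu4 - s2^2 * (n - 3) / (n - 1)) / n
    }
    sqrt(v(x) + v(y))
  }
  se_cov <- function(x1, x2, y1, y2) {
    v <- function(u, w) {
      # var of sample covariance: E[(u-mu_u)^2 (w-mu_w)^2] - cov^2, over n
      du <- u - mean(u); dw <- w - mean(w)
      (mean(du^2 * dw^2) - stats::cov(u, w)^2) / n
    }
    sqrt(v(x1, x2) + v(y1, y2))
  }
  moments <- rbind(
    stat_row("mean_marker", mean(A[, 1]), mean(B[, 1]), se_mean(A[, 1], B[, 1])),
    stat_row("mean_age", mean(A[, 2]), mean(B[, 2]), se_mean(A[, 2], B[, 2])),
    stat_row("var_marker", stats::var(A[, 1]), stats::var(B[, 1]), se_var(A[, 1], B[, 1])),
    stat_row("var_age", stats::var(A[, 2]), stats::var(B[, 2]), se_var(A[, 2], B[, 2])),
    stat_row("cov_marker_age", stats::cov(A[, 1], A[, 2]), stats::cov(B[, 1], B[, 2]),
             se_cov(A[, 1], A[, 2], B[, 1], B[, 2]))
  )
  identical_cols <- isTRUE(all.equal(A, B, check.attributes = FALSE))
  ks_p <- c(
    marker = if (identical_cols) 1 else
      suppressWarnings(stats::ks.test(A[, 1], B[, 1])$p.value),
    age = if (identical_cols) 1 else
      suppressWarnings(stats::ks.test(A[, 2], B[, 2])$p.value)
  )
  # exact copies give 0/0 z-scores; treat as 0
  z <- moments$z
  z[moments$diff == 0] <- 0
  indist <- all(abs(z) <= se_mult) && all(ks_p > ks_alpha)
  structure(list(moments = moments, ks_p = ks_p,
                 indistinguishable = indist),
            class = "equiv_report")
}

#' @export
print.equiv_report <- function(x, ...) {
  cat("<equiv_report> indistinguishable:", x$indistinguishable, "\n")
  print(x$moments, row.names = FALSE)
  cat("KS p-values:", paste(names(x$ks_p), format.pval(x$ks_p), collapse = ", "), "\n")
  invisible(x)
}

#' Summarize random-weight Cox coefficients against reference methods
#'
#' @param results list of [fit_cox_delta] results (or a numeric vector of
#'   coefficients) from the random-weights draws.
#' @param references named numeric vector of reference coefficients (e.g.
#'   ridge / MLR / equal-weights).
#' @return object of class `random_weight_summary`: the coefficient vector,
#'   its `median`, and per reference the strict exceedance fraction
#'   (draws > reference) and tie count.
#' @export
summarize_random_coefs <- function(results, references = numeric(0)) {
  coefs <- if (is.numeric(results)) as.numeric(results) else
    vapply(results, function(r) r$loghr_per_sd, numeric(1))
  if (!length(coefs)) stop("no results supplied", call. = FALSE)
  exceed <- vapply(references, function(ref) mean(coefs > ref), numeric(1))
  ties <- vapply(references, function(ref) sum(coefs == ref), numeric(1))
  structure(list(coefs = coefs, median = stats::median(coefs),
                 exceedance = exceed, ties = ties,
                 references = references),
            class = "random_weight_summary")
}

#' @export
print.random_weight_summary <- function(x, ...) {
  cat(sprintf("<random_weight_summary> %d draws, median logHR/sd = %.4f\n",
              length(x$coefs), x$median))
  if (length(x$exceedance)) {
    for (nm in names(x$exceedance)) {
      cat(sprintf("  P(draw > %s = %.4f) = %.3f\n", nm, x$references[[nm]],
                  x$exceedance[[nm]]))
    }
  }
  invisible(x)
}
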