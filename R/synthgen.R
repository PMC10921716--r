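# Synthetic-data generators: the true/false marker pair, the four
# three-marker coefficient scenarios, and the survival cohort emulator.

#' Parameters for the true/false marker-pair generator
#'
#' Describes the additive latent biological-age world with one true and one
#' false marker. Chronological age C ~ N(mu, var_c); divergence
#' D ~ N(0, var_delta); a nuisance component L ~ N(0, var_lambda) with the
#' same variance takes D's place in the false marker. Biological age is
#' B = C + D. The markers are
#' `X  = alpha + beta * (C + D) + eps` and
#' `X' = alpha + beta * (C + L) + eps'`, with eps, eps' ~ N(0, var_eps).
#' By construction (X, C) and (X', C) have identical joint distributions
#' while only X carries information about D.
#'
#' @param n number of subjects.
#' @param mu mean chronological age (years).
#' @param var_c variance of chronological age (years^2).
#' @param var_delta variance of the divergence D (years^2).
#' @param var_lambda variance of the nuisance component (years^2).
#' @param var_eps residual marker variance.
#' @param alpha,beta marker intercept and slope.
#' @param seed integer RNG seed.
#' @param values_are_sd if `TRUE`, interpret `var_*` inputs as standard
#'   deviations and square them (the printed magnitudes in the source model
#'   are ambiguous; the default reads them as variances).
#' @return an object of class `sim_params1`.
#' @export
sim_params1 <- function(n = 1000, mu = 50, var_c = 10, var_delta = 3,
                        var_lambda = 3, var_eps = 2, alpha = 1, beta = 1,
                        seed = 1, values_are_sd = FALSE) {
  n <- check_count(n, "n", lower = 2L)
  for (nm in c("var_c", "var_delta", "var_lambda", "var_eps")) {
    check_number(get(nm), nm, lower = 0)
  }
  check_number(mu, "mu"); check_number(alpha, "alpha"); check_number(beta, "beta")
  if (isTRUE(values_are_sd)) {
    var_c <- var_c^2; var_delta <- var_delta^2
    var_lambda <- var_lambda^2; var_eps <- var_eps^2
  }
  structure(list(n = n, mu = mu, var_c = var_c, var_delta = var_delta,
                 var_lambda = var_lambda, var_eps = var_eps, alpha = alpha,
                 beta = beta, seed = as.integer(seed)),
            class = "sim_params1")
}

#' Generate the true/false marker pair cohort
#'
#' Draws the five independent normal components and constructs `B = C + D`,
#' the true marker `X` (loaded on D) and the false marker `Xprime` (loaded on
#' the nuisance L). Output carries full truth columns.
#'
#' @param params a [sim_params1] object.
#' @return a [cohort_data] with markers `X`, `Xprime` and truth columns
#'   `delta`, `bioage`, `lambda`.
#' @export
gen_example1 <- function(params = sim_params1()) {
  stopifnot(inherits(params, "sim_params1"))
  p <- params
  with_seed(p$seed, {
    C <- stats::rnorm(p$n, p$mu, sqrt(p$var_c))
    D <- stats::rnorm(p$n, 0, sqrt(p$var_delta))
    L <- stats::rnorm(p$n, 0, sqrt(p$var_lambda))
    e <- stats::rnorm(p$n, 0, sqrt(p$var_eps))
    ep <- stats::rnorm(p$n, 0, sqrt(p$var_eps))
    X <- p$alpha + p$beta * (C + D) + e
    Xp <- p$alpha + p$beta * (C + L) + ep
    cohort_data(age = C, markers = cbind(X = X, Xprime = Xp),
                delta = D, bioage = C + D, lambda = L)
  })
}

#' Coefficient grid for the four-scenario generator
#'
#' Three markers, four scenarios. Each marker i is
#' `X_i = beta_c[i] * C + beta_delta[s, i] * D + eps_i`, with the age slopes
#' `beta_c` identical across scenarios. The scenarios encode how a marker's
#' association with chronological age relates to its association with the
#' divergence D: (A) identical, (B) inverted, (C) unrelated, (D) partially
#' informative (sign agrees, size does not).
#'
#' @param beta_c numeric length-3: slopes on chronological age (shared by all
#'   scenarios).
#' @param beta_delta 4 x 3 matrix of slopes on the divergence, rows named
#'   A-D.
#' @param n,mu,var_c,var_delta as in [sim_params1]; defaults are the
#'   scenario-study values (n = 1000, mu = 50, var_c = 10, var_delta = 5).
#' @param base_noise_var floor noise variance added to every marker by the
#'   equalization rule (see [derive_scenario_noise]); must be > 0.
#' @param seed integer RNG seed.
#' @param values_are_sd as in [sim_params1].
#' @return an object of class `scenario_table`.
#' @export
scenario_table <- function(beta_c = c(10, 3, 5),
                           beta_delta = rbind(A = c(10, 3, 5),
                                              B = c(-10, -3, -5),
                                              C = c(0, 10, -1),
                                              D = c(9, 5, 5)),
                           n = 1000, mu = 50, var_c = 10, var_delta = 5,
                           base_noise_var = 25, seed = 1,
                           values_are_sd = FALSE) {
  beta_delta <- as.matrix(beta_delta)
  if (!identical(dim(beta_delta), c(4L, 3L)) && !all(dim(beta_delta) == c(4, 3))) {
    stop("`beta_delta` must be a 4 x 3 matrix (scenarios A-D by markers 1-3)",
         call. = FALSE)
  }
  if (is.null(rownames(beta_delta))) rownames(beta_delta) <- c("A", "B", "C", "D")
  if (length(beta_c) != 3L) stop("`beta_c` must have length 3", call. = FALSE)
  check_number(base_noise_var, "base_noise_var", lower = 0, strict = TRUE)
  n <- check_count(n, "n", lower = 2L)
  check_number(var_c, "var_c", lower = 0)
  check_number(var_delta, "var_delta", lower = 0)
  if (isTRUE(values_are_sd)) {
    var_c <- var_c^2; var_delta <- var_delta^2; base_noise_var <- base_noise_var^2
  }
  structure(list(beta_c = as.numeric(beta_c), beta_delta = beta_delta,
                 n = n, mu = mu, var_c = var_c, var_delta = var_delta,
                 base_noise_var = base_noise_var, seed = as.integer(seed)),
            class = "scenario_table")
}

#' Noise variances that make the four scenarios observationally identical
#'
#' With the age slopes shared across scenarios, the joint distribution of
#' (X_1, X_2, X_3, C) is the same in all four scenarios iff every marker has
#' the same total non-age variance. The rule used here gives marker i a
#' variance budget `T_i = max_s beta_delta[s, i]^2 * var_delta +
#' base_noise_var` and sets `sigma2[s, i] = T_i - beta_delta[s, i]^2 *
#' var_delta`, which is >= base_noise_var by construction. (The divergence
#' and the noise are independent Gaussians, so only the sum of their
#' contributions is observable.)
#'
#' @param table a [scenario_table].
#' @return 4 x 3 matrix of noise variances, rows A-D.
#' @export
derive_scenario_noise <- function(table) {
  stopifnot(inherits(table, "scenario_table"))
  contrib <- table$beta_delta^2 * table$var_delta
  total <- apply(contrib, 2, max) + table$base_noise_var
  sigma2 <- sweep(-contrib, 2, total, `+`)
  if (any(sigma2 < 0)) {
    stop("noise equalization infeasible: negative variance required", call. = FALSE)
  }
  dimnames(sigma2) <- dimnames(table$beta_delta)
  sigma2
}

#' Generate one scenario of the three-marker cohort
#'
#' @param table a [scenario_table].
#' @param scenario one of `"A"`, `"B"`, `"C"`, `"D"`.
#' @return a [cohort_data] with markers `X1..X3` and truth columns. At a
#'   fixed seed the age and divergence draws (and the standard-normal noise
#'   draws, before scaling) are identical across scenarios, so matched-seed
#'   outputs differ only through the coefficient grid.
#' @export
gen_example2 <- function(table = scenario_table(), scenario = c("A", "B", "C", "D")) {
  stopifnot(inherits(table, "scenario_table"))
  scenario <- match.arg(scenario)
  sigma2 <- derive_scenario_noise(table)[scenario, ]
  bd <- table$beta_delta[scenario, ]
  bc <- table$beta_c
  with_seed(table$seed, {
    C <- stats::rnorm(table$n, table$mu, sqrt(table$var_c))
    D <- stats::rnorm(table$n, 0, sqrt(table$var_delta))
    Z <- matrix(stats::rnorm(table$n * 3L), ncol = 3L)
    X <- sapply(1:3, function(i) bc[i] * C + bd[i] * D + sqrt(sigma2[i]) * Z[, i])
    colnames(X) <- paste0("X", 1:3)
    cohort_data(age = C, markers = X, delta = D, bioage = C + D)
  })
}

#' Parameters for the survival-cohort emulator
#'
#' An emulator of a middle-aged metabolomics cohort with registry follow-up:
#' n subjects, age at inclusion ~ N(mean_age, sd_age^2), m continuous
#' markers, a latent divergence D ~ N(0, var_delta), and death ages drawn
#' from a Gompertz hazard on the age timescale,
#' `h(t) = a * exp(b * t) * exp(gamma * D + sex_loghr * sex)`,
#' with delayed entry at the inclusion age and administrative censoring
#' `admin_censor_years` later. Defaults reproduce the descriptives of the
#' motivating cohort: n = 2267, mean age 59.2 (sd 6.7), 59 markers, ~16.3
#' years of follow-up, and a baseline scale calibrated so that the expected
#' number of deaths is about 309.
#'
#' Markers follow a mixture architecture `X_j = beta_c_j * C + beta_delta_j
#' * D + eps_j` (unit noise variance) with four marker classes: age-only
#' (`c_only`), age-and-divergence (`c_delta`), divergence-only
#' (`delta_only`) and pure noise (`none`). Slope magnitudes are drawn
#' uniformly from the stated ranges with random sign; for `c_delta` markers
#' the divergence slope keeps the sign of the age slope with probability
#' `sign_agreement` (1 = the "sign informative, size uninformative" world).
#'
#' @param n subjects; @param mean_age,sd_age inclusion-age distribution
#'   (years); @param m marker count.
#' @param architecture list with `shares` (named numeric summing to 1 over
#'   `c_only`, `c_delta`, `delta_only`, `none`), `beta_c_range`,
#'   `beta_delta_range` (positive magnitude ranges) and `sign_agreement`
#'   (probability in \[0, 1\]).
#' @param var_delta variance of the divergence (years^2).
#' @param gompertz_a baseline hazard scale (1/year); `NULL` means "calibrate
#'   by bisection so the expected event fraction is `target_event_frac`".
#' @param gompertz_b log-hazard slope per year of age.
#' @param gamma log hazard ratio per year of divergence.
#' @param sex_loghr log hazard ratio for males (sex coded 0 = female,
#'   1 = male, drawn Bernoulli(0.5)).
#' @param admin_censor_years administrative censoring horizon (years).
#' @param target_event_frac expected fraction of deaths used when
#'   calibrating `gompertz_a` (default 309/2267).
#' @param seed integer RNG seed.
#' @return an object of class `lls_params`.
#' @export
lls_params <- function(n = 2267, mean_age = 59.2, sd_age = 6.7, m = 59,
                       architecture = list(
                         shares = c(c_only = 0.25, c_delta = 0.20,
                                    delta_only = 0.15, none = 0.40),
                         beta_c_range = c(0.02, 0.08),
                         beta_delta_range = c(0.05, 0.15),
                         sign_agreement = 1),
                       var_delta = 25, gompertz_a = NULL, gompertz_b = 0.095,
                       gamma = 0.1, sex_loghr = log(1.6),
                       admin_censor_years = 16.3,
                       target_event_frac = 309 / 2267, seed = 1) {
  n <- check_count(n, "n", lower = 2L)
  m <- check_count(m, "m", lower = 1L)
  check_number(sd_age, "sd_age", lower = 0)
  check_number(var_delta, "var_delta", lower = 0)
  check_number(gompertz_b, "gompertz_b", lower = 0, strict = TRUE)
  check_number(admin_censor_years, "admin_censor_years", lower = 0, strict = TRUE)
  sh <- architecture$shares
  need <- c("c_only", "c_delta", "delta_only", "none")
  if (is.null(names(sh)) || !setequal(names(sh), need) || any(sh < 0) ||
      abs(sum(sh) - 1) > 1e-8) {
    stop("architecture$shares must be non-negative, named ",
         paste(need, collapse = "/"), " and sum to 1", call. = FALSE)
  }
  if (!is.null(gompertz_a)) check_number(gompertz_a, "gompertz_a", lower = 0, strict = TRUE)
  structure(list(n = n, mean_age = mean_age, sd_age = sd_age, m = m,
                 architecture = architecture, var_delta = var_delta,
                 gompertz_a = gompertz_a, gompertz_b = gompertz_b,
                 gamma = gamma, sex_loghr = sex_loghr,
                 admin_censor_years = admin_censor_years,
                 target_event_frac = target_event_frac,
                 seed = as.integer(seed)),
            class = "lls_params")
}

#' Expected event fraction of the cohort emulator
#'
#' Numerically integrates the Gompertz survival function over the inclusion
#' age, divergence and sex distributions: the probability that a subject
#' entering at age C dies before C + `admin_censor_years` is
#' `1 - exp(-(a/b) * (exp(b*(C+w)) - exp(b*C)) * RR)`. This is the
#' independent check used to calibrate the hazard scale (no simulation
#' involved).
#'
#' @param params an [lls_params] with `gompertz_a` set.
#' @param grid_points quadrature points per Gaussian dimension.
#' @return expected fraction of subjects dying within the follow-up window.
#' @export
expected_event_frac <- function(params, grid_points = 201) {
  stopifnot(inherits(params, "lls_params"))
  a <- params$gompertz_a
  if (is.null(a)) stop("`gompertz_a` must be set", call. = FALSE)
  b <- params$gompertz_b
  w <- params$admin_censor_years
  # weighted grids over C ~ N(mean_age, sd_age^2) and D ~ N(0, var_delta)
  gauss_grid <- function(mu, sd, k) {
    if (sd == 0) return(list(x = mu, w = 1))
    x <- seq(mu - 6 * sd, mu + 6 * sd, length.out = k)
    wt <- stats::dnorm(x, mu, sd)
    list(x = x, w = wt / sum(wt))
  }
  gc <- gauss_grid(params$mean_age, params$sd_age, grid_points)
  gd <- gauss_grid(0, sqrt(params$var_delta), 81)
  p_death_given_rr <- function(rr) {
    # vector over C grid for a scalar relative risk
    H <- (a / b) * (exp(b * (gc$x + w)) - exp(b * gc$x)) * rr
    sum(gc$w * (1 - exp(-H)))
  }
  frac <- 0
  for (sex in c(0, 1)) {
    rrs <- exp(params$gamma * gd$x + params$sex_loghr * sex)
    frac <- frac + 0.5 * sum(gd$w * vapply(rrs, p_death_given_rr, numeric(1)))
  }
  frac
}

#' Calibrate the Gompertz baseline scale to a target event fraction
#'
#' Bisection on log10(a) against [expected_event_frac].
#'
#' @param params an [lls_params]; its `target_event_frac` is the target.
#' @param tol relative tolerance on the event fraction.
#' @return the input params with `gompertz_a` filled in.
#' @export
calibrate_gompertz_a <- function(params, tol = 1e-4) {
  stopifnot(inherits(params, "lls_params"))
  target <- params$target_event_frac
  f <- function(log10a) {
    params$gompertz_a <- 10^log10a
    expected_event_frac(params) - target
  }
  lo <- -10; hi <- -1
  if (f(lo) > 0 || f(hi) < 0) stop("calibration bracket failed", call. = FALSE)
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
    if (abs(f(mid)) < tol * target) break
  }
  params$gompertz_a <- 10^((lo + hi) / 2)
  params
}

#' Generate a survival cohort from the emulator
#'
#' Death ages are drawn by inverse transform of the conditional Gompertz
#' survival function given survival to the inclusion age (left truncation:
#' `entry_age = age`), then administratively censored at `entry_age +
#' admin_censor_years`.
#'
#' @param params an [lls_params]; if `gompertz_a` is `NULL` it is calibrated
#'   first (see [calibrate_gompertz_a]).
#' @return a [cohort_data] with `m` markers `marker_1..m`, truth columns
#'   `delta`/`bioage`, and survival fields. The realized marker architecture
#'   (types and slopes) is attached as attribute `"architecture"`.
#' @export
gen_lls_like <- function(params = lls_params()) {
  stopifnot(inherits(params, "lls_params"))
  if (is.null(params$gompertz_a)) params <- calibrate_gompertz_a(params)
  a <- params$gompertz_a; b <- params$gompertz_b
  arch <- params$architecture
  with_seed(params$seed, {
    n <- params$n; m <- params$m
    C <- stats::rnorm(n, params$mean_age, params$sd_age)
    D <- stats::rnorm(n, 0, sqrt(params$var_delta))
    sex <- stats::rbinom(n, 1, 0.5)

    type <- sample(names(arch$shares), m, replace = TRUE, prob = arch$shares)
    mag <- function(rng, k) stats::runif(k, rng[1], rng[2])
    sgn <- function(k) sample(c(-1, 1), k, replace = TRUE)
    beta_c <- ifelse(type %in% c("c_only", "c_delta"),
                     mag(arch$beta_c_range, m) * sgn(m), 0)
    bd_mag <- mag(arch$beta_delta_range, m)
    agree <- stats::runif(m) < arch$sign_agreement
    bd_sign <- ifelse(beta_c != 0 & agree, sign(beta_c), sgn(m))
    beta_delta <- ifelse(type %in% c("c_delta", "delta_only"),
                         bd_mag * bd_sign, 0)

    X <- outer(C, beta_c) + outer(D, beta_delta) +
      matrix(stats::rnorm(n * m), n, m)
    colnames(X) <- paste0("marker_", seq_len(m))

    rr <- exp(params$gamma * D + params$sex_loghr * sex)
    u <- stats::runif(n)
    # T | T > C from Gompertz: H(T) - H(C) = -log(u) / rr
    death_age <- log(exp(b * C) - b * log(u) / (a * rr)) / b
    censor_age <- C + params$admin_censor_years
    event <- as.numeric(death_age <= censor_age)
    exit_age <- pmin(death_age, censor_age)

    out <- cohort_data(age = C, markers = X, delta = D, bioage = C + D,
                       sex = sex, entry_age = C, exit_age = exit_age,
                       event = event)
    attr(out, "architecture") <- data.frame(
      marker = colnames(X), type = type, beta_c = beta_c,
      beta_delta = beta_delta)
    attr(out, "gompertz_a") <- a
    out
  })
}
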