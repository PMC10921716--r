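# Independent oracles used across the suite. Each takes a deliberately
# different computational route from the implementation it checks.

# OLS by explicit normal equations
ols_oracle <- function(X, y) {
  A <- cbind(1, as.matrix(X))
  drop(solve(t(A) %*% A, t(A) %*% y))
}

# exhaustive K-fold CV for ridge: refits every (fold, lambda) cell from the
# definition of the penalized normal equations and returns the argmin lambda
ridge_cv_oracle <- function(X, y, fold_id, lambda_grid) {
  lambda_grid <- sort(lambda_grid)
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  Z <- scale(X, center = ctr, scale = scl)
  err <- sapply(lambda_grid, function(lam) {
    fold_mse <- sapply(sort(unique(fold_id)), function(k) {
      tr <- fold_id != k
      A <- cbind(1, Z[tr, , drop = FALSE])
      D <- diag(c(0, rep(1, ncol(Z))))
      w <- solve(t(A) %*% A + lam * D, t(A) %*% y[tr])
      mean((y[!tr] - drop(cbind(1, Z[!tr, , drop = FALSE]) %*% w))^2)
    })
    mean(fold_mse)
  })
  list(lambda = lambda_grid[which.min(err)], cv_mse = err)
}

# grid-search minimizer of the KD objective sum_j ((x_j - q_j - k_j*BA)/s_j)^2
# for one subject, refined around the coarse optimum
kd_grid_oracle <- function(q, k, s, x, lo = -200, hi = 400) {
  obj <- function(ba) sum(((x - q - k * ba) / s)^2)
  grid <- seq(lo, hi, length.out = 20001)
  best <- grid[which.min(vapply(grid, obj, numeric(1)))]
  fine <- seq(best - 0.1, best + 0.1, length.out = 20001)
  fine[which.min(vapply(fine, obj, numeric(1)))]
}

# leading eigenvector via SVD of the centered/scaled data matrix (a
# different route from the correlation-matrix eigendecomposition)
pc1_svd_oracle <- function(X) {
  Z <- scale(X)
  v <- svd(Z)$v[, 1]
  v / sqrt(sum(v^2))
}

# log partial likelihood (Breslow) for left-truncated data, hand-coded from
# the definition; maximized with optim as the Cox oracle
coxpl_oracle <- function(entry, exit, event, X) {
  X <- as.matrix(X)
  negll <- function(beta) {
    eta <- drop(X %*% beta)
    ll <- 0
    for (i in which(event == 1)) {
      at_risk <- entry < exit[i] & exit >= exit[i]
      ll <- ll + eta[i] - log(sum(exp(eta[at_risk])))
    }
    -ll
  }
  opt <- optim(rep(0, ncol(X)), negll, method = "BFGS")
  opt$par
}

# permutation-test p-value for a Pearson correlation
perm_cor_oracle <- function(x, y, n_perm = 2000, seed = 1) {
  obs <- abs(cor(x, y))
  set.seed(seed)
  perm <- replicate(n_perm, abs(cor(x, sample(y))))
  (1 + sum(perm >= obs)) / (n_perm + 1)
}

# access to internal constructors/helpers for fixtures
new_model_for_test <- function(weights, intercept = 0) {
  bioagesim:::new_linear_age_model("mlr", names(weights), intercept, weights)
}
with_seed_public <- function(seed, code) bioagesim:::with_seed(seed, code)

# small fixture builder: markers with controllable loadings on age/divergence
make_fixture <- function(n = 200, seed = 42, beta_c = c(1, 0.5), beta_d = c(1, -0.5),
                         var_delta = 4, noise = 1) {
  set.seed(seed)
  C <- rnorm(n, 50, 3)
  D <- rnorm(n, 0, sqrt(var_delta))
  X <- sapply(seq_along(beta_c), function(j) {
    beta_c[j] * C + beta_d[j] * D + rnorm(n, 0, noise)
  })
  colnames(X) <- paste0("m", seq_along(beta_c))
  cohort_data(age = C, markers = X, delta = D, bioage = C + D)
}
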