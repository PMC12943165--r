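# Independent oracles used to cross-check the package's implementations.
# Each deliberately takes the slow/naive route.

# OLS by explicit normal equations (X'X)^-1 X'y, intercept prepended.
ols_normal_equations <- function(X, y) {
  X1 <- cbind(1, as.matrix(X))
  solve(crossprod(X1), crossprod(X1, y))[, 1]
}

# PRESS by n explicit refits, one compound left out at a time.
loo_press_refit <- function(X, y) {
  X1 <- cbind(1, as.matrix(X))
  n <- nrow(X1)
  sum(vapply(seq_len(n), function(i) {
    beta <- solve(crossprod(X1[-i, , drop = FALSE]),
                  crossprod(X1[-i, , drop = FALSE], y[-i]))[, 1]
    (y[i] - sum(X1[i, ] * beta))^2
  }, numeric(1)))
}

# Refit-based Q2(LOO), the fitness a GA subset should earn.
q2_loo_refit_oracle <- function(X, y) {
  1 - loo_press_refit(X, y) / sum((y - mean(y))^2)
}

# QUIK-gated fitness evaluated from first principles (cor + eigen written
# out), for exhaustive-enumeration comparisons.
quik_oracle <- function(M) {
  p <- ncol(M)
  lam <- eigen(stats::cor(M), symmetric = TRUE, only.values = TRUE)$values
  sum(abs(lam / sum(lam) - 1 / p)) / (2 * (p - 1) / p)
}

exhaustive_best_subset <- function(X, y, k, quik_delta) {
  subsets <- utils::combn(ncol(X), k, simplify = FALSE)
  fits <- vapply(subsets, function(idx) {
    Xi <- X[, idx, drop = FALSE]
    pass <- (quik_oracle(cbind(Xi, y)) - quik_oracle(Xi)) >= quik_delta
    if (!pass) return(-Inf)
    q2_loo_refit_oracle(Xi, y)
  }, numeric(1))
  best <- which.max(fits)
  list(subset = sort(subsets[[best]]), fitness = fits[best],
       all_fitness = fits)
}

# Minimum RMSD between paired point sets by direct numeric minimisation
# over Euler angles (multi-start Nelder-Mead), independent of the SVD path.
rmsd_minimize_oracle <- function(mobile, reference, n_starts = 12) {
  P <- sweep(as.matrix(mobile), 2, colMeans(mobile))
  Q <- sweep(as.matrix(reference), 2, colMeans(reference))
  euler <- function(a) {
    cz <- cos(a[1]); sz <- sin(a[1])
    cy <- cos(a[2]); sy <- sin(a[2])
    cx <- cos(a[3]); sx <- sin(a[3])
    rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1)) %*%
      rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy)) %*%
      rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  }
  obj <- function(a) sqrt(mean(rowSums((P %*% t(euler(a)) - Q)^2)))
  starts <- rbind(c(0, 0, 0),
                  as.matrix(expand.grid(a1 = c(0.8, 2.4, 4.2),
                                        a2 = c(0.5, 2.6),
                                        a3 = c(0.9, 3.9)))[seq_len(n_starts - 1), ])
  best <- Inf
  for (i in seq_len(nrow(starts))) {
    r <- stats::optim(starts[i, ], obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
    r <- stats::optim(r$par, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, r$value)
  }
  best
}

# Build two columns with an exact sample Pearson correlation r, via
# Gram-Schmidt on random vectors.
make_correlated_pair <- function(n, r, seed = 1) {
  withr::with_seed(seed, {
    x <- rnorm(n)
    z <- rnorm(n)
  })
  x <- scale(x)[, 1]
  z <- scale(stats::residuals(stats::lm(z ~ x)))[, 1]
  y <- r * x + sqrt(1 - r^2) * z
  cbind(x = x, y = y)
}

# Small random regression problem with well-conditioned design.
random_problem <- function(n, p, seed) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("d", seq_len(p))))
    beta <- rnorm(p)
    y <- 1 + X %*% beta + rnorm(n, sd = 0.7)
  })
  list(X = X, y = as.vector(y),
       data = dplyr::bind_cols(
         tibble::tibble(compound_id = paste0("c", seq_len(n))),
         tibble::as_tibble(X),
         tibble::tibble(pIC50 = as.vector(y))))
}
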