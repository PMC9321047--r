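## Fixtures and independent oracles used across the suite. Oracles are
## deliberately written as explicit closed forms (sums, normal equations,
## numerical residual minimisation), never the model-fitting code paths
## they check.

make_traj <- function(positions, frames = NULL, ...) {
  trajectory("f1", "c1", positions, frames = frames, ...)
}

## constant-step (ballistic) trajectory along x
ballistic_traj <- function(n = 10, step = 1) {
  make_traj(cbind((seq_len(n) - 1) * step, 0, 0))
}

## random gap-free trajectory for oracle-equivalence checks
random_traj <- function(n = 30) {
  make_traj(apply(matrix(rnorm(3 * n, sd = 0.3), n, 3), 2, cumsum))
}

## oracle: conditional-least-squares gamma as the explicit sum formula
## sum(d_t . d_{t-1}) / sum(|d_{t-1}|^2) over consecutive displacement pairs
cls_gamma_oracle <- function(traj) {
  p <- traj$positions
  d <- diff(p)
  num <- sum(d[-1, ] * d[-nrow(d), ])
  den <- sum(d[-nrow(d), ]^2)
  num / den
}

## oracle: simple-regression OLS via the normal equations
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  fitted <- X %*% beta
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(intercept = beta[1], slope = beta[2],
       r_squared = 1 - ss_res / ss_tot)
}

## oracle: sphere fit by direct numerical minimisation of squared radial
## residuals over (center, radius), multi-start Nelder-Mead
sphere_oracle <- function(pts) {
  obj <- function(par) {
    r <- sqrt(rowSums(sweep(pts, 2, par[1:3])^2))
    sum((r - par[4])^2)
  }
  starts <- rbind(c(colMeans(pts), mean(sqrt(rowSums(
    sweep(pts, 2, colMeans(pts))^2)))),
    c(0, 0, 0, 1))
  fits <- apply(starts, 1, function(s)
    optim(s, obj, control = list(maxit = 5000, reltol = 1e-14)))
  best <- fits[[which.min(vapply(fits, `[[`, 0, "value"))]]
  list(center = best$par[1:3], radius = best$par[4])
}

## oracle: two-sided permutation test for a difference in means
permutation_p <- function(a, b, n_perm = 4000) {
  obs <- abs(mean(a) - mean(b))
  pooled <- c(a, b)
  na <- length(a)
  hits <- replicate(n_perm, {
    idx <- sample(length(pooled), na)
    abs(mean(pooled[idx]) - mean(pooled[-idx]))
  })
  mean(hits >= obs - 1e-12)
}

## write a minimal trajectory CSV and return its path
write_traj_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE)
  path
}
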