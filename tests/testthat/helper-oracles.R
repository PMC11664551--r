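# Independent oracles used across the suite. Each is a direct formula or
# brute-force computation, deliberately sharing no code with the package.

# analytic mean/sd of N(mu, sigma) truncated to [a, b]
tnorm_moments <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma
  be <- (b - mu) / sigma
  Z <- pnorm(be) - pnorm(al)
  m <- mu + sigma * (dnorm(al) - dnorm(be)) / Z
  v <- sigma^2 * (1 + (al * dnorm(al) - be * dnorm(be)) / Z -
                    ((dnorm(al) - dnorm(be)) / Z)^2)
  list(mean = m, sd = sqrt(v))
}

# normal-equations least squares with intercept
ols_oracle <- function(X, y) {
  Xd <- cbind(1, as.matrix(X))
  drop(solve(crossprod(Xd), crossprod(Xd, y)))
}

# brute-force LP oracle: enumerate basic solutions of the <=-form system
# (x >= 0 included) and pick the best feasible vertex
vertex_lp_oracle <- function(obj, A, dir, rhs, maximize) {
  n <- ncol(A)
  AA <- rbind(A, -diag(n))
  bb <- c(rhs, rep(0, n))
  dd <- c(dir, rep("<=", n))
  flip <- dd == ">="
  AA[flip, ] <- -AA[flip, , drop = FALSE]
  bb[flip] <- -bb[flip]
  best <- NULL
  bestv <- if (maximize) -Inf else Inf
  for (cmb in utils::combn(nrow(AA), n, simplify = FALSE)) {
    B <- AA[cmb, , drop = FALSE]
    if (abs(det(B)) < 1e-10) next
    x <- solve(B, bb[cmb])
    if (all(AA %*% x <= bb + 1e-8)) {
      v <- sum(obj * x)
      if ((maximize && v > bestv) || (!maximize && v < bestv)) {
        bestv <- v
        best <- x
      }
    }
  }
  list(x = best, value = bestv)
}

# tiny dataset with hand-set values for the registry columns given
toy_dataset <- function(values) {
  orchard_dataset(as.matrix(values))
}
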