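# Independent oracles used to cross-check the package implementations.
# These deliberately use different code paths (brute force, lm(), numeric
# optimizers, Monte-Carlo simulation) from the functions they validate.

# Brute-force spherical erosion: per-voxel min over the spherical
# neighborhood of the thresholded map.
oracle_erode <- function(mask, radius) {
  d <- dim(mask)
  out <- array(FALSE, d)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    keep <- TRUE
    for (dx in -radius:radius) for (dy in -radius:radius) for (dz in -radius:radius) {
      if (dx^2 + dy^2 + dz^2 > radius^2) next
      p <- c(x + dx, y + dy, z + dz)
      inside <- all(p >= 1) && all(p <= d)
      if (!inside || !mask[p[1], p[2], p[3]]) { keep <- FALSE; break }
    }
    out[x, y, z] <- keep
  }
  out
}

# Granger path coefficient via lm() on explicitly standardized series.
oracle_granger <- function(x, y) {
  xs <- (x - mean(x)) / sd(x)
  ys <- (y - mean(y)) / sd(y)
  n <- length(x)
  fit <- lm(ys[-1] ~ ys[-n] + xs[-n])
  unname(coef(fit)[3])
}

# Distance from the nasion to the preauricular line by golden-section
# search over the line parameter.
oracle_origin <- function(N, L, R) {
  f <- function(t) sum((N - (R + t * (L - R)))^2)
  t_star <- optimize(f, c(-10, 10), tol = 1e-12)$minimum
  R + t_star * (L - R)
}

# Independent quaternion -> rotation matrix (outer-product form).
oracle_q2mat <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; v <- q[2:4]
  skew <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0),
                 3, 3, byrow = TRUE)
  (w^2 - sum(v^2)) * diag(3) + 2 * tcrossprod(v) + 2 * w * skew
}

# Uniform-ish random rotation from a normalized Gaussian quaternion.
random_rotation <- function() {
  q <- rnorm(4)
  oracle_q2mat(q / sqrt(sum(q^2)))
}

random_unit_vector <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# Rigid fit by direct numerical minimization over a quaternion + translation
# parameterization (independent of the SVD solution).
oracle_fit_rigid_rmsd <- function(src, dst) {
  obj <- function(p) {
    R <- oracle_q2mat(p[1:4])
    tr <- p[5:7]
    sum((t(R %*% t(src)) + rep(tr, each = nrow(src)) - dst)^2)
  }
  best <- Inf
  for (i in 1:5) {
    p0 <- c(rnorm(4), colMeans(dst) - colMeans(src))
    o <- optim(p0, obj, method = "BFGS", control = list(maxit = 2000,
                                                        reltol = 1e-14))
    best <- min(best, o$value)
  }
  sqrt(best / nrow(src))
}

# Monte-Carlo power for the baseline-adjusted mean-of-follow-ups contrast.
# Simulates per-subject baseline B and follow-up mean M from their implied
# joint normal, analyses each trial by ANCOVA (M ~ group + B) with a
# normal-theory Wald test.
mc_power_mean_followups <- function(n_total, delta = 3, sd = 8, rf = 0.7,
                                    rb = 0.27, k = 3, dropout = 0.2,
                                    alpha = 0.05, nsim = 20000) {
  n_arm <- round(n_total * (1 - dropout) / 2)
  n <- 2 * n_arm
  v_m <- sd^2 * (1 + (k - 1) * rf) / k
  Sigma <- matrix(c(sd^2, rb * sd^2, rb * sd^2, v_m), 2, 2)
  A <- chol(Sigma)
  g <- rep(c(0, 1), each = n_arm)
  zc <- qnorm(1 - alpha / 2)
  rej <- logical(nsim)
  for (s in seq_len(nsim)) {
    BM <- matrix(rnorm(2 * n), n, 2) %*% A
    M <- BM[, 2] + delta * g
    X <- cbind(1, g, BM[, 1])
    fit <- .lm.fit(X, M)
    df <- n - 3
    sigma2 <- sum(fit$residuals^2) / df
    XtXinv <- chol2inv(chol(crossprod(X)))
    se <- sqrt(sigma2 * XtXinv[2, 2])
    rej[s] <- abs(fit$coefficients[2] / se) > zc
  }
  mean(rej)
}

# Monte-Carlo power for the Fisher-z correlation test against rho0.
mc_power_correlation <- function(n, rho0, rho1, alpha = 0.05, tails = 2,
                                 nsim = 40000) {
  zc <- qnorm(1 - alpha / tails)
  rej <- logical(nsim)
  chunk <- 2000
  done <- 0
  while (done < nsim) {
    m <- min(chunk, nsim - done)
    X <- matrix(rnorm(n * m), n, m)
    Y <- rho1 * X + sqrt(1 - rho1^2) * matrix(rnorm(n * m), n, m)
    r <- vapply(seq_len(m), function(j) cor(X[, j], Y[, j]), numeric(1))
    z <- (atanh(r) - atanh(rho0)) * sqrt(n - 3)
    rej[done + seq_len(m)] <- if (tails == 2) abs(z) > zc else z > zc
    done <- done + m
  }
  mean(rej)
}

.crossprod_xy <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Small helper: angle (degrees) between the xy-projection of v and +x.
planar_angle_deg <- function(v) {
  p <- v[1:2]
  acos(sum(p * c(1, 0)) / sqrt(sum(p^2))) * 180 / pi
}
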