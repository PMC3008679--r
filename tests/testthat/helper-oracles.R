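# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: explicit normal equations, Lyapunov solves and
# brute-force definitions.

# Brute-force bivariate Granger fit via explicit normal equations
# (solve(crossprod)) rather than the package's QR path.
oracle_granger <- function(x, y, p = 1) {
  T <- length(y)
  rows <- (p + 1):T
  fit_dir <- function(src, tgt) {
    Y <- tgt[rows]
    own <- vapply(seq_len(p), function(l) tgt[rows - l], numeric(length(rows)))
    oth <- vapply(seq_len(p), function(l) src[rows - l], numeric(length(rows)))
    Xr <- cbind(1, own)
    Xf <- cbind(Xr, oth)
    br <- solve(crossprod(Xr), crossprod(Xr, Y))
    bf <- solve(crossprod(Xf), crossprod(Xf, Y))
    rr <- Y - Xr %*% br
    rf <- Y - Xf %*% bf
    list(s2r = sum(rr^2) / (T - p), s2f = sum(rf^2) / (T - p),
         beta_r = c(br), beta_f = c(bf))
  }
  fy <- fit_dir(x, y)
  fx <- fit_dir(y, x)
  list(fy = fy, fx = fx,
       f = c(f_x_to_y = log(fy$s2r / fy$s2f), f_y_to_x = log(fx$s2r / fx$s2f)))
}

# Population Geweke measures for the 2-node system
#   x_t = a_x x_{t-1} + e1,  y_t = c xy x_{t-1} + a_y y_{t-1} + e2
# via the discrete Lyapunov equation (stationary covariance), independent of
# any sample-based estimation.
oracle_population_f <- function(a_x, a_y, c_xy, sd_x = 1, sd_y = 1) {
  A <- matrix(c(a_x, 0,
                c_xy, a_y), 2, 2, byrow = TRUE)
  Q <- diag(c(sd_x^2, sd_y^2))
  Sigma <- matrix(solve(diag(4) - kronecker(A, A), as.numeric(Q)), 2, 2)
  lag1 <- A %*% Sigma   # Cov(z_t, z_{t-1})
  s2r_y <- Sigma[2, 2] - lag1[2, 2]^2 / Sigma[2, 2]
  s2r_x <- Sigma[1, 1] - lag1[1, 1]^2 / Sigma[1, 1]
  c(f_x_to_y = log(s2r_y / Q[2, 2]), f_y_to_x = log(s2r_x / Q[1, 1]))
}

# Brute-force BH step-up straight from its definition: try every observed
# p-value as cutoff and keep the largest valid one.
oracle_bh <- function(p, q) {
  m <- length(p)
  cutoff <- -Inf
  for (cand in p) {      # try every observed p-value as the cutoff
    rank_at <- sum(p <= cand)
    if (cand <= rank_at * q / m && cand > cutoff) cutoff <- cand
  }
  if (is.finite(cutoff)) {
    list(cutoff = cutoff, reject = p <= cutoff)
  } else {
    list(cutoff = 0, reject = rep(FALSE, m))
  }
}

# Tie-corrected Kruskal-Wallis H computed by explicit midranks.
oracle_kw_binary <- function(a, b) {
  vals <- c(rep(1, a[1]), rep(0, a[2]), rep(1, b[1]), rep(0, b[2]))
  grp <- c(rep(1, sum(a)), rep(2, sum(b)))
  r <- rank(vals)   # midranks
  N <- length(vals)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, grp, function(ri) length(ri) * (mean(ri) - (N + 1) / 2)^2))
  tie <- table(vals)
  H <- H / (1 - sum(tie^3 - tie) / (N^3 - N))
  list(h = H, p = stats::pchisq(H, df = 1, lower.tail = FALSE))
}

# tiny deterministic AR(1) series generator for fixtures
ar1_series <- function(n, a = 0.5, seed = 1, burn = 100) {
  set.seed(seed)
  as.numeric(stats::filter(stats::rnorm(n + burn), a,
                           method = "recursive"))[(burn + 1):(burn + n)]
}
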