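# Minimal Gaussian-process regression surrogate used by the Bayesian
# optimizer: isotropic Matern-5/2 covariance on the unit hypercube, unit
# prior variance on standardized responses, observation-noise variance and
# lengthscale estimated by marginal maximum likelihood.

matern52 <- function(D, ell) {
  r <- sqrt(5) * D / ell
  (1 + r + r^2 / 3) * exp(-r)
}

gp_negloglik <- function(par, D, z) {
  ell <- exp(par[1]); s2n <- exp(par[2])
  n <- length(z)
  K <- matern52(D, ell) + diag(s2n + 1e-10, n)
  R <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(R)) return(1e10)
  a <- backsolve(R, forwardsolve(t(R), z))
  as.numeric(0.5 * sum(z * a) + sum(log(diag(R))) + 0.5 * n * log(2 * pi))
}

# Fit the surrogate to points X (rows in [0,1]^d) with objective values y.
gp_fit <- function(X, y) {
  X <- as.matrix(X)
  mu <- mean(y)
  sdy <- stats::sd(y)
  if (!is.finite(sdy) || sdy < 1e-12) sdy <- 1
  z <- (y - mu) / sdy
  D <- sq_dist(X)
  D <- sqrt(D)
  starts <- list(c(log(0.3), log(0.1)), c(log(1), log(1e-3)))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, gp_negloglik, D = D, z = z, method = "L-BFGS-B",
                   lower = c(log(0.03), log(1e-8)),
                   upper = c(log(3), log(1))),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best)) best <- list(par = c(log(0.3), log(0.1)))
  ell <- exp(best$par[1]); s2n <- exp(best$par[2])
  K <- matern52(D, ell) + diag(s2n + 1e-10, nrow(X))
  R <- chol(K)
  alpha <- backsolve(R, forwardsolve(t(R), z))
  list(X = X, mu = mu, sdy = sdy, ell = ell, s2n = s2n, R = R,
       alpha = alpha)
}

# Posterior mean and sd (of the latent function) at candidate rows Xs,
# back-transformed to the original objective scale.
gp_predict <- function(gp, Xs) {
  Xs <- as.matrix(Xs)
  Ks <- matern52(sqrt(sq_dist(Xs, gp$X)), gp$ell)
  mean_z <- as.numeric(Ks %*% gp$alpha)
  V <- forwardsolve(t(gp$R), t(Ks))
  var_z <- pmax(1 - colSums(V^2), 0)
  list(mean = gp$mu + gp$sdy * mean_z,
       sd = gp$sdy * sqrt(var_z))
}
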