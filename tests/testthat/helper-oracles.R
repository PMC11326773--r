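# Shared test helpers: dense joint-Gaussian oracle for the smoother, random
# small model instances, and brute-force builders used across test files.

# Joint prior over (x_0, ..., x_T) and conditioning on y: the independent
# reference the Kalman smoother must reproduce on small instances.
dense_gaussian_oracle <- function(y, bank, Cm, Rmat) {
  y <- as.matrix(y)
  T_len <- nrow(y); L <- ncol(y)
  A <- transition_matrix(bank)
  Q <- oscomp:::process_covariance(bank)
  P0 <- oscomp:::bank_stationary_covariance(bank)
  d <- nrow(A)
  n <- d * (T_len + 1L)
  Sigma <- matrix(0, n, n)
  Sigma[1:d, 1:d] <- P0
  for (t in seq_len(T_len)) {
    it <- t * d + 1:d; prev <- (t - 1) * d + 1:d
    for (s in 0:(t - 1)) {
      is <- s * d + 1:d
      Sigma[it, is] <- A %*% Sigma[prev, is]
      Sigma[is, it] <- t(Sigma[it, is])
    }
    Sigma[it, it] <- A %*% Sigma[prev, prev] %*% t(A) + Q
  }
  H <- matrix(0, T_len * L, n)
  for (t in seq_len(T_len)) H[(t - 1) * L + 1:L, t * d + 1:d] <- Cm
  Syy <- H %*% Sigma %*% t(H) + kronecker(diag(T_len), Rmat)
  Sxy <- Sigma %*% t(H)
  yv <- as.vector(t(y))
  mu <- drop(Sxy %*% solve(Syy, yv))
  Sig <- Sigma - Sxy %*% solve(Syy, t(Sxy))
  ll <- -0.5 * (length(yv) * log(2 * pi) +
                  as.numeric(determinant(Syy, logarithm = TRUE)$modulus) +
                  sum(yv * solve(Syy, yv)))
  list(mean = mu, cov = Sig, loglik = ll, d = d, T_len = T_len)
}

random_small_instance <- function(seed, T_len = 4, L = 3, M = 2) {
  set.seed(seed)
  bank <- oscillator_bank(f = runif(M, 1, 45), a = runif(M, 0.3, 0.97),
                          sigma2 = runif(M, 0.2, 2), fs = 100)
  Cm <- matrix(rnorm(L * 2 * M), L, 2 * M)
  Rmat <- random_spd_covariance(L, condition_target = 3, seed = seed + 1)
  y <- matrix(rnorm(T_len * L), T_len, L)
  list(bank = bank, Cm = Cm, Rmat = Rmat, y = y, T_len = T_len, L = L, M = M)
}

# Point-mass state posterior built from known states (zero covariance),
# for testing the learning updates against hand-computable statistics.
point_mass_posterior <- function(states, y, x0 = NULL) {
  X <- as.matrix(states); y <- as.matrix(y)
  T_len <- nrow(X); d <- ncol(X)
  if (is.null(x0)) x0 <- numeric(d)
  Xall <- rbind(x0, X)
  S11 <- crossprod(Xall[-1L, , drop = FALSE])
  S00 <- crossprod(Xall[-(T_len + 1L), , drop = FALSE])
  S10 <- t(Xall[-1L, , drop = FALSE]) %*% Xall[-(T_len + 1L), , drop = FALSE]
  Sxy <- t(Xall[-1L, , drop = FALSE]) %*% y
  structure(list(
    suff_stats = list(S11 = S11, S00 = S00, S10 = S10, Sxy = Sxy,
                      Syy = crossprod(y), Sinit = tcrossprod(x0),
                      T_total = T_len, n_epochs = 1L),
    entropy = 0, dims = list(d = d, L = ncol(y))),
    class = "state_posterior")
}

# One full VB inner cycle from a given state; returns posteriors and the
# ELBO evaluated at comparable phases.
vb_cycle <- function(y, bank, mixpost, noisepost, alpha, Psi, nu) {
  sp <- kalman_smooth(y, bank, oscomp:::obs_from_posteriors(mixpost, noisepost))
  F0 <- negative_free_energy(sp, mixpost, noisepost, alpha, Psi, nu, bank)
  mix1 <- update_mixing_posterior(sp, noisepost, alpha)
  F1 <- negative_free_energy(sp, mix1, noisepost, alpha, Psi, nu, bank)
  noise1 <- update_noise_posterior(sp, mix1, Psi, nu)
  F2 <- negative_free_energy(sp, mix1, noise1, alpha, Psi, nu, bank)
  sp2 <- kalman_smooth(y, bank, oscomp:::obs_from_posteriors(mix1, noise1))
  F3 <- negative_free_energy(sp2, mix1, noise1, alpha, Psi, nu, bank)
  list(sp = sp2, mixpost = mix1, noisepost = noise1, F = c(F0, F1, F2, F3))
}
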