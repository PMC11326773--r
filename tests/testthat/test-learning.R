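test_that("mixing posterior: shrinkage limit, OLS limit and conjugate oracle", {
  set.seed(1)
  T_len <- 30; d <- 4; L <- 3
  X <- matrix(rnorm(T_len * d), T_len, d)
  Ctrue <- matrix(rnorm(L * d), L, d)
  y <- X %*% t(Ctrue) + 0.1 * matrix(rnorm(T_len * L), T_len, L)
  sp <- point_mass_posterior(X, y)
  np <- noise_cov_posterior(diag(L), L + 2)  # E[R^-1] = (L+2) I

  # alpha -> infinity shrinks the posterior mean to zero
  mp_inf <- update_mixing_posterior(sp, np, 1e12)
  expect_lt(max(abs(mp_inf$mean)), 1e-6)

  # alpha = 0 with exactly known states and E[R^-1] proportional to I
  # reduces to ordinary least squares
  mp0 <- update_mixing_posterior(sp, np, 0)
  ols <- t(solve(crossprod(X), crossprod(X, y)))
  expect_equal(mp0$mean, ols, tolerance = 1e-8)

  # random instance matches a brute-force Bayesian linear regression built
  # through the stacked long-form design matrix
  T2 <- 4; M <- 1; d2 <- 2; L2 <- 2; alpha <- 0.7
  X2 <- matrix(rnorm(T2 * d2), T2, d2)
  y2 <- matrix(rnorm(T2 * L2), T2, L2)
  Rmat <- random_spd_covariance(L2, 2, seed = 5)
  np2 <- noise_cov_posterior(Rmat * 10, 10)  # some IW posterior
  Rinv <- np2$expected_precision
  sp2 <- point_mass_posterior(X2, y2)
  mp2 <- update_mixing_posterior(sp2, np2, alpha)
  # long form: y_vec = Z w + e, e ~ N(0, I_T (x) R), w = vec(C)
  Z <- matrix(0, T2 * L2, L2 * d2)
  for (t in 1:T2) for (j in 1:d2)
    Z[(t - 1) * L2 + 1:L2, (j - 1) * L2 + 1:L2] <- X2[t, j] * diag(L2)
  Om <- t(Z) %*% kronecker(diag(T2), Rinv) %*% Z + alpha * diag(L2 * d2)
  w <- solve(Om, t(Z) %*% kronecker(diag(T2), Rinv) %*% as.vector(t(y2)))
  expect_equal(as.vector(mp2$mean), as.vector(matrix(w, L2, d2)),
               tolerance = 1e-8)
  expect_equal(mp2$vec_cov, solve(Om), tolerance = 1e-8)
})

test_that("noise posterior: prior at T=0, arithmetic mean, Monte-Carlo scatter", {
  L <- 2; Psi <- random_spd_covariance(L, 2, seed = 3); nu <- L + 3
  empty <- structure(list(
    suff_stats = list(S11 = matrix(0, 2, 2), S00 = matrix(0, 2, 2),
                      S10 = matrix(0, 2, 2), Sxy = matrix(0, 2, L),
                      Syy = matrix(0, L, L), Sinit = matrix(0, 2, 2),
                      T_total = 0, n_epochs = 0),
    dims = list(d = 2, L = L)), class = "state_posterior")
  np <- update_noise_posterior(empty, mixing_posterior(matrix(0, L, 2)),
                               Psi, nu)
  expect_equal(np$scale, Psi)
  expect_equal(np$dof, nu)

  # zero expected residuals: posterior mean is Psi / (nu + T - L - 1)
  T_len <- 10
  X <- matrix(rnorm(T_len * 2), T_len, 2)
  y_exact <- X %*% t(matrix(c(1, 0, 0, 1), 2, 2))
  sp <- point_mass_posterior(X, y_exact)
  np2 <- update_noise_posterior(sp, mixing_posterior(diag(2)), Psi, nu)
  expect_equal(np2$mean, Psi / (nu + T_len - L - 1), tolerance = 1e-10)

  # expected residual scatter matches a Monte-Carlo average over joint
  # draws from q(C) q({x_t})
  set.seed(7)
  T3 <- 3; d3 <- 2; L3 <- 2
  mu_x <- matrix(rnorm(T3 * d3), T3, d3)
  P_x <- 0.3 * crossprod(matrix(rnorm(6), 3, 2)) / 3 + diag(0.2, 2)
  Cbar <- matrix(rnorm(L3 * d3), L3, d3)
  Vc <- 0.2 * crossprod(matrix(rnorm(16), 4, 4)) / 4 + diag(0.05, 4)
  y3 <- matrix(rnorm(T3 * L3), T3, L3)
  suff <- list(S11 = crossprod(mu_x) + T3 * P_x, Sxy = t(mu_x) %*% y3,
               Syy = crossprod(y3), T_total = T3)
  scatter <- oscomp:::expected_residual_scatter(suff, Cbar, Vc)
  nmc <- 2e4
  acc <- matrix(0, L3, L3)
  chP <- chol(P_x); chV <- chol(Vc)
  for (i in seq_len(nmc)) {
    Ci <- Cbar + matrix(drop(rnorm(4) %*% chV), L3, d3)
    Xi <- mu_x + matrix(rnorm(T3 * d3), T3, d3) %*% chP
    Ri <- y3 - Xi %*% t(Ci)
    acc <- acc + crossprod(Ri)
  }
  mc <- acc / nmc
  # 3-sigma band on the Monte-Carlo diagonal entries
  expect_lt(max(abs(mc - scatter)), 3 * max(diag(scatter)) / sqrt(nmc) * 4)
})

test_that("free energy: plug-in limit, evidence bound and per-update ascent", {
  # with a point-mass mixing posterior and the degenerate convention the
  # state contribution reduces to the innovations log-likelihood
  inst <- random_small_instance(41, T_len = 4, L = 2, M = 1)
  obs <- observation_model(inst$Cm, NULL, solve(inst$Rmat))
  sp <- kalman_smooth(inst$y, inst$bank, obs)
  orc <- dense_gaussian_oracle(inst$y, inst$bank, inst$Cm, inst$Rmat)
  expect_equal(sp$loglik_surrogate, orc$loglik, tolerance = 1e-8)

  # ELBO after convergence is below the quadrature log evidence (R prior
  # made tight so the noise covariance is effectively fixed)
  set.seed(2)
  bank <- oscillator_bank(f = 8, a = 0.9, sigma2 = 1, fs = 100)
  T_len <- 3; L <- 1
  R0 <- matrix(0.5)
  y <- matrix(rnorm(T_len) * 0.8, T_len, 1)
  nu <- 200; Psi <- (nu - L - 1) * R0
  alpha <- 1.3
  mix <- mixing_posterior(matrix(0.5, 1, 2), diag(0.5, 2))
  noise <- noise_cov_posterior(Psi, nu)
  for (i in 1:60) {
    cyc <- vb_cycle(y, bank, mix, noise, alpha, Psi, nu)
    mix <- cyc$mixpost; noise <- cyc$noisepost
  }
  F_conv <- cyc$F[4]
  grid <- seq(-6, 6, length.out = 81)
  lse <- -Inf
  for (c1 in grid) for (c2 in grid) {
    ll <- kalman_filter(y, bank,
                        observation_model(matrix(c(c1, c2), 1, 2), NULL,
                                          solve(R0)))$loglik
    lp <- sum(dnorm(c(c1, c2), 0, sqrt(1 / alpha), log = TRUE))
    lse <- max(lse, ll + lp) + log1p(exp(min(lse, ll + lp) -
                                           max(lse, ll + lp)))
  }
  log_ml <- lse + 2 * log(grid[2] - grid[1])
  expect_lt(F_conv, log_ml + 0.05)

  # every inner update individually never decreases the ELBO
  for (seed in 1:12) {
    inst <- random_small_instance(seed + 100, T_len = 8, L = 3, M = 2)
    alpha <- runif(1, 0.2, 3)
    nu <- inst$L + 2; Psi <- (nu - inst$L - 1) * inst$Rmat
    mix <- mixing_posterior(0.2 * inst$Cm, diag(0.3, inst$L * 4))
    noise <- noise_cov_posterior(Psi, nu)
    cyc <- vb_cycle(inst$y, inst$bank, mix, noise, alpha, Psi, nu)
    expect_true(all(diff(cyc$F) >= -1e-8 * abs(cyc$F[1])))
  }
})

test_that("oscillator M-step recovers parameters and matches a numerical maximizer", {
  # statistics from a long noiseless-observation run of a known oscillator
  bank <- oscillator_bank(f = 9.5, a = 0.93, sigma2 = 0.8, fs = 100)
  tr <- simulate_states(bank, 50000, seed = 8)
  sp <- point_mass_posterior(tr$states, matrix(0, 50000, 1), x0 = tr$x0)
  up <- mstep_oscillator_params(sp, fs = 100)
  expect_equal(up$f, 9.5, tolerance = 0.01 * 9.5)
  expect_equal(up$a, 0.93, tolerance = 0.01 * 0.93)
  expect_equal(up$sigma2, 0.8, tolerance = 0.01 * 0.8 * 2)

  # S10 = 0: damping floors, sigma2 = tr(S11) / (2T)
  spz <- structure(list(
    suff_stats = list(S11 = diag(2, 2), S00 = diag(2, 2),
                      S10 = matrix(0, 2, 2), Sxy = matrix(0, 2, 1),
                      Syy = matrix(0, 1, 1), Sinit = diag(2, 2),
                      T_total = 10, n_epochs = 1),
    dims = list(d = 2, L = 1)), class = "state_posterior")
  upz <- mstep_oscillator_params(spz, fs = 100)
  expect_equal(upz$a, 1e-3)
  expect_equal(upz$sigma2, sum(diag(diag(2, 2))) / 20, tolerance = 1e-3)

  # random valid statistics: closed form matches grid + local refinement of
  # the expected complete-data log-likelihood
  ecll <- function(par, suff, T_tot, fs = 100) {
    f <- par[1]; a <- par[2]; s2 <- exp(par[3])
    R <- rotation_matrix(f, fs)
    quad <- sum(diag(suff$S11)) - 2 * a * sum(R * suff$S10) +
      a^2 * sum(diag(suff$S00))
    -T_tot * log(s2) - quad / (2 * s2)
  }
  for (seed in 1:5) {
    bk <- oscillator_bank(f = runif(1, 2, 40), a = runif(1, 0.5, 0.97),
                          sigma2 = runif(1, 0.3, 2), fs = 100)
    trs <- simulate_states(bk, 500, seed = seed)
    spp <- point_mass_posterior(trs$states, matrix(0, 500, 1), x0 = trs$x0)
    up2 <- mstep_oscillator_params(spp, fs = 100)
    # coarse grid then optim refinement
    fgrid <- seq(0.5, 49, by = 0.5)
    best <- NULL; bestv <- -Inf
    for (fg in fgrid) {
      v <- ecll(c(fg, 0.9, 0), spp$suff_stats, 500)
      if (v > bestv) { bestv <- v; best <- fg }
    }
    opt <- optim(c(best, 0.9, 0), function(p) {
      if (p[1] < 0 || p[1] > 50 || p[2] <= 0 || p[2] >= 1) return(1e10)
      -ecll(p, spp$suff_stats, 500)
    }, method = "Nelder-Mead", control = list(maxit = 2000, reltol = 1e-12))
    expect_equal(up2$f, opt$par[1], tolerance = 1e-3)
    expect_equal(up2$a, opt$par[2], tolerance = 1e-3)
    expect_equal(up2$sigma2, exp(opt$par[3]), tolerance = 1e-3)
  }
})

test_that("alpha M-step matches its closed form and a 1-D numerical maximizer", {
  L <- 3; d <- 4
  mp <- mixing_posterior(matrix(0, L, d), diag(1, L * d))
  # E[sum ||c||^2] = tr(V) = 12 = 2ML with M = 2, L = 3 -> alpha = 1
  expect_equal(mstep_alpha(mp), 1)
  mp_half <- mixing_posterior(matrix(0, L, d), diag(0.5, L * d))
  expect_equal(mstep_alpha(mp_half), 2)

  set.seed(9)
  mp_r <- mixing_posterior(matrix(rnorm(L * d), L, d),
                           0.3 * crossprod(matrix(rnorm(144), 12, 12)) / 12)
  a_hat <- mstep_alpha(mp_r)
  e2 <- sum(mp_r$mean^2) + sum(diag(mp_r$vec_cov))
  obj <- function(a) L * d / 2 * log(a) - a / 2 * e2  # E[log p(C|alpha)]
  o <- optimize(obj, c(1e-6, 100), maximum = TRUE)
  expect_equal(a_hat, o$maximum, tolerance = 1e-4)

  expect_equal(mstep_alpha(mixing_posterior(matrix(0, L, d)),
                           alpha_max = 1e8), 1e8)
})

test_that("initialization finds spectral peaks, is seeded, and sets the noise prior mean", {
  set.seed(3)
  s1 <- ar2_source(6, 100, 0.97, 4000, seed = 31)
  s2 <- ar2_source(21, 100, 0.97, 4000, seed = 32)
  y <- cbind(s1 + 0.2 * rnorm(4000), s2 + 0.2 * rnorm(4000),
             s1 - s2 + 0.2 * rnorm(4000))
  init <- initialize_oca(y, 2, 100, seed = 1)
  expect_equal(init$init_freqs[1], 6, tolerance = 0.5)
  expect_equal(init$init_freqs[2], 21, tolerance = 0.5)
  # nu = L + 2 makes the prior mean equal the supplied covariance
  R0 <- random_spd_covariance(3, 2, seed = 4)
  init2 <- initialize_oca(y, 2, 100, seed = 1, R0 = R0)
  expect_equal(init2$noisepost$mean, R0, tolerance = 1e-10)
  init3 <- initialize_oca(y, 2, 100, seed = 1, R0 = R0)
  expect_identical(init2$mixpost$mean, init3$mixpost$mean)
  # more oscillators than peaks: uniform grid fallback with a message
  expect_message(initialize_oca(matrix(rnorm(80), 40, 2), 12, 100, seed = 1),
                 "uniform")
})

test_that("single-model fit recovers generative parameters deterministically", {
  bank <- oscillator_bank(f = c(4, 12), a = c(0.96, 0.94),
                          sigma2 = c(0.5, 0.5), fs = 100)
  set.seed(6)
  Cm <- matrix(rnorm(5 * 4), 5, 4)
  sim <- generative_sim(bank, Cm, diag(0.2, 5), T_len = 2000, seed = 13)
  fit <- fit_single_model(sim$rec$data, M = 2, fs = 100, seed = 2)
  fo <- sort(fit$bank$f)
  expect_lt(abs(fo[1] - 4), 0.5)
  expect_lt(abs(fo[2] - 12), 0.5)
  expect_lt(max(abs(sort(fit$bank$a) - sort(c(0.96, 0.94)))), 0.02)

  tr <- fit$trace$free_energy
  expect_true(all(diff(tr) >= -1e-6 * abs(tr[-1])))

  fit2 <- fit_single_model(sim$rec$data, M = 2, fs = 100, seed = 2)
  expect_identical(fit$bank, fit2$bank)
  expect_identical(fit$free_energy, fit2$free_energy)
})

test_that("free energy is invariant to gauge rotation of one oscillator", {
  inst <- random_small_instance(55, T_len = 10, L = 3, M = 2)
  d <- 4
  alpha <- 1.1; nu <- inst$L + 2; Psi <- (nu - inst$L - 1) * diag(inst$L)
  mix <- mixing_posterior(inst$Cm, diag(0.2, inst$L * d))
  noise <- noise_cov_posterior(Psi, nu)
  sp <- kalman_smooth(inst$y, inst$bank,
                      oscomp:::obs_from_posteriors(mix, noise))
  F0 <- negative_free_energy(sp, mix, noise, alpha, Psi, nu, inst$bank)
  for (phi in c(0.4, -1.2, pi / 3)) {
    G <- diag(d)
    G[1:2, 1:2] <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
    # states x' = G' x, mixing C' = C G: transform posteriors and stats
    K <- kronecker(t(G), diag(inst$L))
    mix_r <- mixing_posterior(mix$mean %*% G, K %*% mix$vec_cov %*% t(K))
    s <- sp$suff_stats
    sp_r <- structure(list(
      suff_stats = list(S11 = t(G) %*% s$S11 %*% G,
                        S00 = t(G) %*% s$S00 %*% G,
                        S10 = t(G) %*% s$S10 %*% G,
                        Sxy = t(G) %*% s$Sxy,
                        Syy = s$Syy,
                        Sinit = t(G) %*% s$Sinit %*% G,
                        T_total = s$T_total, n_epochs = s$n_epochs),
      entropy = sp$entropy, dims = sp$dims), class = "state_posterior")
    F1 <- negative_free_energy(sp_r, mix_r, noise, alpha, Psi, nu, inst$bank)
    expect_equal(F1, F0, tolerance = 1e-8)
  }
})
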