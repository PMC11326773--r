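#' Gaussian posterior over the mixing matrix
#'
#' Container for `q(C)`: the posterior mean of the `L x 2M` mixing matrix and
#' the covariance of its column-major vectorization.
#'
#' @param mean `L x 2M` matrix.
#' @param vec_cov `2ML x 2ML` covariance of `vec(mean)`, or `NULL` for a
#'   point mass.
#' @return An object of class `"mixing_posterior"`.
#' @export
mixing_posterior <- function(mean, vec_cov = NULL) {
  mean <- as.matrix(mean)
  if (!is.null(vec_cov)) {
    vec_cov <- as.matrix(vec_cov)
    stopifnot(nrow(vec_cov) == length(mean), ncol(vec_cov) == length(mean))
  }
  structure(list(mean = mean, vec_cov = vec_cov), class = "mixing_posterior")
}

#' Inverse-Wishart posterior over the sensor-noise covariance
#'
#' @param scale `L x L` symmetric positive definite scale matrix.
#' @param dof Degrees of freedom, `> L - 1`.
#' @return An object of class `"noise_cov_posterior"` with derived moments:
#'   `expected_precision` (`dof * scale^-1`), `logdet_expected_precision_arg`
#'   (`E[log det R^-1]`), and `mean` (`scale / (dof - L - 1)` when defined).
#' @export
noise_cov_posterior <- function(scale, dof) {
  scale <- as.matrix(scale)
  L <- nrow(scale)
  stopifnot(ncol(scale) == L, dof > L - 1)
  ch <- tryCatch(chol(scale), error = function(e)
    stop("noise posterior scale must be positive definite"))
  logdet_scale <- 2 * sum(log(diag(ch)))
  inv_scale <- chol2inv(ch)
  structure(list(
    scale = scale, dof = dof, L = L,
    expected_precision = dof * inv_scale,
    elogdet_precision = sum(digamma((dof + 1 - seq_len(L)) / 2)) +
      L * log(2) - logdet_scale,
    mean = if (dof > L + 1) scale / (dof - L - 1) else NULL),
    class = "noise_cov_posterior")
}

# Observation model induced by the current q(C), q(R).
obs_from_posteriors <- function(mixpost, noisepost) {
  observation_model(mixpost$mean, mixpost$vec_cov,
                    noisepost$expected_precision,
                    noisepost$elogdet_precision)
}

#' Variational update of the mixing-matrix posterior
#'
#' Given the smoothed state statistics and the current noise posterior, the
#' optimal `q(C)` is Gaussian with precision
#' `kron(S11, E[R^-1]) + alpha I` (column-major `vec(C)`) and mean solving
#' the matching normal equations with right-hand side `vec(E[R^-1] Sxy')`.
#'
#' @param sp A `"state_posterior"`.
#' @param noisepost A [noise_cov_posterior()].
#' @param alpha Mixing-prior precision, `> 0`.
#' @return A [mixing_posterior()].
#' @export
update_mixing_posterior <- function(sp, noisepost, alpha) {
  stopifnot(inherits(sp, "state_posterior"), alpha >= 0)
  Rinv <- noisepost$expected_precision
  S11 <- sp$suff_stats$S11
  L <- nrow(Rinv); d <- nrow(S11)
  Om <- kronecker(S11, Rinv) + diag(alpha, L * d)
  rhs <- as.vector(Rinv %*% t(sp$suff_stats$Sxy))
  ch <- tryCatch(chol(0.5 * (Om + t(Om))), error = function(e)
    stop("singular mixing-posterior precision; check the state statistics"))
  vc <- chol2inv(ch)
  m <- vc %*% rhs
  mixing_posterior(matrix(m, L, d), 0.5 * (vc + t(vc)))
}

#' Variational update of the noise-covariance posterior
#'
#' The optimal `q(R)` is inverse-Wishart with degrees of freedom `nu + T`
#' and scale `Psi` plus the expected residual scatter
#' `sum_t E[(y_t - C x_t)(y_t - C x_t)']`, the expectation taken under both
#' the state and mixing posteriors (all second-moment cross terms included).
#'
#' @param sp A `"state_posterior"`.
#' @param mixpost A [mixing_posterior()].
#' @param Psi,nu Inverse-Wishart prior scale and degrees of freedom.
#' @return A [noise_cov_posterior()].
#' @export
update_noise_posterior <- function(sp, mixpost, Psi, nu) {
  stopifnot(inherits(sp, "state_posterior"), inherits(mixpost, "mixing_posterior"))
  scatter <- expected_residual_scatter(sp$suff_stats, mixpost$mean,
                                       mixpost$vec_cov)
  noise_cov_posterior(Psi + scatter, nu + sp$suff_stats$T_total)
}

# log multivariate gamma function.
lmvgamma <- function(a, p) {
  p * (p - 1) / 4 * log(pi) + sum(lgamma(a + (1 - seq_len(p)) / 2))
}

# KL( q(C) = N(m, V) || p(C) = N(0, alpha^-1 I) ).
kl_mixing <- function(mixpost, alpha) {
  n <- length(mixpost$mean)
  # Degenerate (point-mass) posterior: prior and entropy terms are dropped
  # by convention so the bound reduces to the plug-in log-likelihood.
  if (is.null(mixpost$vec_cov)) return(0)
  m2 <- sum(mixpost$mean^2)
  ch <- chol(mixpost$vec_cov + diag(1e-300, n))
  0.5 * (alpha * (sum(diag(mixpost$vec_cov)) + m2) - n -
           n * log(alpha) - 2 * sum(log(diag(ch))))
}

# KL( q(R) = IW(Sq, vq) || p(R) = IW(Sp, vp) ).
kl_noise <- function(noisepost, Psi, nu) {
  L <- noisepost$L
  vq <- noisepost$dof; Sq <- noisepost$scale
  ch_q <- chol(Sq); ch_p <- chol(Psi)
  logdet_Sq <- 2 * sum(log(diag(ch_q)))
  logdet_Sp <- 2 * sum(log(diag(ch_p)))
  elog_detR <- -noisepost$elogdet_precision
  (-vq * L / 2 * log(2) - lmvgamma(vq / 2, L) + vq / 2 * logdet_Sq) -
    (-nu * L / 2 * log(2) - lmvgamma(nu / 2, L) + nu / 2 * logdet_Sp) +
    (nu - vq) / 2 * elog_detR -
    vq * L / 2 + 0.5 * sum(noisepost$expected_precision * Psi)
}

#' Negative variational free energy (evidence lower bound)
#'
#' Evaluates the ELBO
#' \deqn{F = E_q[\log p(y, x, C, R)] - E_q[\log q(x, C, R)]}
#' decomposed as `E[log p(y|x,C,R)] + E[log p(x)] + H[q(x)] - KL(q(C)||p(C))
#' - KL(q(R)||p(R))`. The state-entropy term is the one stored by
#' [kalman_smooth()], so the expression remains a valid bound when `q(C)`,
#' `q(R)` or the oscillator parameters have been updated after the last
#' state pass (only `q(x)` is held fixed).
#'
#' @param sp A `"state_posterior"`.
#' @param mixpost A [mixing_posterior()] (must carry `vec_cov`; a point mass
#'   uses the degenerate zero-entropy convention).
#' @param noisepost A [noise_cov_posterior()].
#' @param alpha Mixing-prior precision.
#' @param Psi,nu Noise-prior scale and degrees of freedom.
#' @param bank The current [oscillator_bank()].
#' @return Scalar ELBO value.
#' @export
negative_free_energy <- function(sp, mixpost, noisepost, alpha, Psi, nu, bank) {
  obs <- obs_from_posteriors(mixpost, noisepost)
  expected_obs_loglik(sp$suff_stats, obs) +
    expected_state_loglik(sp$suff_stats, bank) +
    sp$entropy -
    kl_mixing(mixpost, alpha) -
    kl_noise(noisepost, Psi, nu)
}

#' M-step update of the oscillator parameters
#'
#' Per oscillator, `(f, a, sigma2)` jointly maximize the expected
#' complete-data log-likelihood of the state dynamics given the 2x2 blocks
#' of the smoothed statistics. Writing `B` for the oscillator's block of
#' `S10`, the optimal rotation angle is `atan2(B21 - B12, B11 + B22)`
#' (constrained to `[0, pi]`), the damping is the ratio of the rotated
#' cross-covariance trace to `tr(S00)`, and `sigma2` is the residual
#' variance per coordinate. Constraints `a` in `[a_min, a_max]` and
#' `f` in `[0, fs/2]` are enforced by projection.
#'
#' @param sp A `"state_posterior"`.
#' @param fs Sampling rate in Hz.
#' @param a_min,a_max Projection bounds for the damping factor.
#' @return An [oscillator_bank()] with the updated parameters.
#' @export
mstep_oscillator_params <- function(sp, fs, a_min = 1e-3, a_max = 1 - 1e-6) {
  stopifnot(inherits(sp, "state_posterior"))
  suff <- sp$suff_stats
  d <- nrow(suff$S11); M <- d / 2L
  T_tot <- suff$T_total
  f <- a <- s2 <- numeric(M)
  for (m in seq_len(M)) {
    i <- (2L * m - 1L):(2L * m)
    B <- suff$S10[i, i]
    tr11 <- sum(diag(suff$S11[i, i]))
    tr00 <- sum(diag(suff$S00[i, i]))
    if (tr00 <= 1e-12 * max(1, tr11))
      stop("degenerate state statistics: tr(S00) ~ 0 for oscillator ", m)
    P <- B[1, 1] + B[2, 2]
    Qc <- B[2, 1] - B[1, 2]
    w <- atan2(Qc, P)
    if (w < 0) w <- if (P >= -P) 0 else pi  # boundary of [0, pi]
    rho <- P * cos(w) + Qc * sin(w)
    a_m <- min(max(rho / tr00, a_min), a_max)
    s2_m <- (tr11 - 2 * a_m * rho + a_m^2 * tr00) / (2 * T_tot)
    f[m] <- min(max(w * fs / (2 * pi), 0), fs / 2)
    a[m] <- a_m
    s2[m] <- max(s2_m, 1e-12)
  }
  oscillator_bank(f, a, s2, fs)
}

#' M-step update of the mixing-prior precision
#'
#' `alpha` maximizes the expected log prior of the mixing matrix:
#' `alpha = 2ML / E[sum ||c_{l,m}||^2]`, the expectation including the
#' posterior covariance mass.
#'
#' @param mixpost A [mixing_posterior()].
#' @param alpha_max Cap applied when the expected norm is (near) zero.
#' @return Updated scalar precision.
#' @export
mstep_alpha <- function(mixpost, alpha_max = 1e8) {
  n <- length(mixpost$mean)
  e2 <- sum(mixpost$mean^2) +
    if (is.null(mixpost$vec_cov)) 0 else sum(diag(mixpost$vec_cov))
  if (e2 <= n / alpha_max) return(alpha_max)
  n / e2
}

# Default fitting configuration. Tolerances: inner loop stops when the
# relative ELBO change falls below tol_inner (or max_inner cycles); the
# outer GEM loop stops below tol_outer (or max_outer iterations).
#' Fitting configuration
#'
#' @param tol_inner,max_inner Inner (VB cycle) convergence tolerance and cap.
#' @param tol_outer,max_outer Outer (GEM) convergence tolerance and cap.
#' @param a_min,a_max,a_init Damping projection bounds and initial value.
#' @param alpha_max Cap for the mixing-prior precision update.
#' @param var_frac PCA retained-variance fraction used by [oca_fit()].
#' @return A list of class `"oca_config"`.
#' @export
oca_config <- function(tol_inner = 1e-6, max_inner = 20,
                       tol_outer = 1e-6, max_outer = 100,
                       a_min = 1e-3, a_max = 1 - 1e-6, a_init = 0.98,
                       alpha_max = 1e8, var_frac = 0.999) {
  structure(list(tol_inner = tol_inner, max_inner = max_inner,
                 tol_outer = tol_outer, max_outer = max_outer,
                 a_min = a_min, a_max = a_max, a_init = a_init,
                 alpha_max = alpha_max, var_frac = var_frac),
            class = "oca_config")
}

# Smoothed-periodogram spectral peaks pooled (averaged) over all channels;
# returns up to M peak frequencies selected greedily by power with a
# minimum mutual separation, ties broken toward lower frequency, output
# ascending.
spectral_peak_freqs <- function(y, fs, M, f_min = 0.1, min_sep = 0.75) {
  y <- as_epoch_list(y)
  ycat <- do.call(rbind, y)
  L <- ncol(ycat)
  spans <- max(5, 2 * floor(nrow(ycat) / 250) + 1)
  pool <- NULL
  for (j in seq_len(L)) {
    s <- stats::spec.pgram(stats::ts(ycat[, j], frequency = fs),
                           spans = spans, detrend = TRUE, plot = FALSE,
                           taper = 0.1)
    if (is.null(pool)) { freq <- s$freq; pool <- s$spec }
    else pool <- pool + s$spec
  }
  keep <- freq >= f_min & freq < fs / 2
  freq <- freq[keep]; pool <- pool[keep]
  # extra ~0.5 Hz moving average so residual periodogram jitter on the
  # slopes of strong peaks does not masquerade as separate maxima
  df <- freq[2] - freq[1]
  k <- max(3L, as.integer(2 * floor(0.25 / df) + 1))
  if (k < length(pool)) {
    sm <- stats::filter(pool, rep(1 / k, k), sides = 2)
    pool <- ifelse(is.na(sm), pool, as.numeric(sm))
  }
  n <- length(pool)
  is_peak <- c(FALSE, pool[2:(n - 1)] > pool[1:(n - 2)] &
                 pool[2:(n - 1)] >= pool[3:n], FALSE)
  pk_f <- freq[is_peak]; pk_p <- pool[is_peak]
  ord <- order(-pk_p, pk_f)  # by power, ties toward lower frequency
  pk_f <- pk_f[ord]
  sel <- numeric(0)
  for (f0 in pk_f) {
    if (length(sel) == M) break
    if (all(abs(sel - f0) >= min_sep)) sel <- c(sel, f0)
  }
  sort(sel)
}

# Band power per channel around a center frequency (smoothed periodogram).
band_power_per_channel <- function(ycat, fs, f0, half_bw = 1) {
  L <- ncol(ycat)
  spans <- max(3, 2 * floor(nrow(ycat) / 200) + 1)
  vapply(seq_len(L), function(j) {
    s <- stats::spec.pgram(stats::ts(ycat[, j], frequency = fs),
                           spans = spans, detrend = TRUE, plot = FALSE,
                           taper = 0.1)
    sel <- abs(s$freq - f0) <= half_bw
    if (!any(sel)) sel <- which.min(abs(s$freq - f0))
    mean(s$spec[sel])
  }, numeric(1))
}

#' Initialize parameters and posteriors for one model order
#'
#' Deterministic given `seed`. Center frequencies start at the `M` largest
#' smoothed-periodogram peaks of the leading (whitened, PCA-rotated)
#' channels, falling back to a uniform grid over `(0, fs/2)` when fewer
#' peaks exist; damping starts at `a_init`; process-noise variances are set
#' by stationary-variance matching (unit stationary state variance, the
#' scale being carried by the mixing matrix); the mixing mean is seeded from
#' per-channel band power at each initial frequency with a small jitter;
#' `alpha = 1`. The noise prior is `nu = L + 2`,
#' `Psi = (nu - L - 1) R0` so its mean equals the supplied noise covariance.
#'
#' @param y Whitened, PCA-rotated data (matrix or epoch list).
#' @param M Number of oscillators.
#' @param fs Sampling rate in Hz.
#' @param config An [oca_config()].
#' @param seed Integer seed.
#' @param R0 Initial noise covariance in the whitened space (default
#'   identity).
#' @return List with `bank`, `mixpost`, `noisepost`, `alpha`, `Psi`, `nu`,
#'   and `init_freqs`.
#' @export
initialize_oca <- function(y, M, fs, config = oca_config(), seed = 1,
                           R0 = NULL) {
  epochs <- as_epoch_list(y)
  L <- ncol(epochs[[1L]])
  ycat <- do.call(rbind, epochs)
  if (is.null(R0)) R0 <- diag(L)
  pk <- spectral_peak_freqs(epochs, fs, M)
  if (length(pk) < M) {
    grid <- seq(0, fs / 2, length.out = M + 2L)[2:(M + 1L)]
    pk <- sort(c(pk, setdiff(grid, pk)))[seq_len(M)]
    message("fewer spectral peaks than M; uniform frequency grid used")
  }
  a0 <- rep(config$a_init, M)
  s20 <- (1 - a0^2)  # unit stationary state variance per coordinate
  bank <- oscillator_bank(pk, a0, s20, fs)

  old <- local_seed(seed)
  on.exit(restore_seed(old))
  Cm <- matrix(0, L, 2L * M)
  for (m in seq_len(M)) {
    bp <- sqrt(pmax(band_power_per_channel(ycat, fs, pk[m]), 0))
    scale <- max(mean(bp), 1e-3)
    Cm[, 2L * m - 1L] <- bp + stats::rnorm(L, sd = 0.05 * scale)
    Cm[, 2L * m] <- stats::rnorm(L, sd = 0.05 * scale)
  }
  nu <- L + 2
  Psi <- (nu - L - 1) * R0
  list(bank = bank,
       mixpost = mixing_posterior(Cm, diag(1e-6, length(Cm))),
       noisepost = noise_cov_posterior(Psi, nu),
       alpha = 1, Psi = Psi, nu = nu, init_freqs = pk)
}

#' Fit the oscillation model for a fixed number of oscillators
#'
#' Runs the full variational-Bayes / generalized-EM loop on whitened,
#' PCA-rotated data: inner cycles update the state, mixing and noise
#' posteriors to convergence of the negative variational free energy; outer
#' iterations then re-estimate the oscillator parameters and the
#' mixing-prior precision. The noise-prior hyperparameters `Psi`, `nu` are
#' derived from the supplied initial noise covariance and never updated.
#'
#' @param y Whitened data: `T x L` matrix or list of epoch matrices.
#' @param M Number of oscillators (`>= 1`).
#' @param fs Sampling rate in Hz.
#' @param config An [oca_config()].
#' @param seed Integer seed (controls initialization only).
#' @param R0 Initial noise covariance in this space (default identity).
#' @return An object of class `"oca_single_fit"`: `bank`, `mixpost`,
#'   `noisepost`, `state` (final smoothed posterior), `alpha`, `Psi`, `nu`,
#'   `free_energy` (final ELBO), `trace` (tibble of per-update ELBO values),
#'   `converged`, `M`, `seed`.
#' @export
fit_single_model <- function(y, M, fs, config = oca_config(), seed = 1,
                             R0 = NULL) {
  stopifnot(M >= 1)
  epochs <- as_epoch_list(y)
  init <- initialize_oca(epochs, M, fs, config, seed, R0)
  bank <- init$bank; mixpost <- init$mixpost; noisepost <- init$noisepost
  alpha <- init$alpha; Psi <- init$Psi; nu <- init$nu

  trace_outer <- integer(0); trace_inner <- integer(0)
  trace_phase <- character(0); trace_F <- numeric(0)
  rec <- function(o, i, ph, F) {
    trace_outer <<- c(trace_outer, o); trace_inner <<- c(trace_inner, i)
    trace_phase <<- c(trace_phase, ph); trace_F <<- c(trace_F, F)
  }

  F_outer_prev <- -Inf
  converged <- FALSE
  sp <- NULL
  for (outer in seq_len(config$max_outer)) {
    F_inner_prev <- -Inf
    for (inner in seq_len(config$max_inner)) {
      sp <- kalman_smooth(epochs, bank, obs_from_posteriors(mixpost, noisepost),
                          keep_moments = FALSE)
      mixpost <- update_mixing_posterior(sp, noisepost, alpha)
      noisepost <- update_noise_posterior(sp, mixpost, Psi, nu)
      F <- negative_free_energy(sp, mixpost, noisepost, alpha, Psi, nu, bank)
      rec(outer, inner, "inner", F)
      if (is.finite(F_inner_prev) &&
          abs(F - F_inner_prev) <= config$tol_inner * abs(F)) break
      F_inner_prev <- F
    }
    bank <- mstep_oscillator_params(sp, fs, config$a_min, config$a_max)
    alpha <- mstep_alpha(mixpost, config$alpha_max)
    F_out <- negative_free_energy(sp, mixpost, noisepost, alpha, Psi, nu, bank)
    rec(outer, NA_integer_, "outer", F_out)
    if (is.finite(F_outer_prev) &&
        abs(F_out - F_outer_prev) <= config$tol_outer * abs(F_out)) {
      converged <- TRUE
      break
    }
    F_outer_prev <- F_out
  }
  if (!converged)
    warning("GEM loop reached the outer iteration cap without converging")

  # Final fresh state pass under the final parameters.
  sp <- kalman_smooth(epochs, bank, obs_from_posteriors(mixpost, noisepost))
  mixpost <- update_mixing_posterior(sp, noisepost, alpha)
  noisepost <- update_noise_posterior(sp, mixpost, Psi, nu)
  F_final <- negative_free_energy(sp, mixpost, noisepost, alpha, Psi, nu, bank)
  rec(trace_outer[length(trace_outer)], NA_integer_, "final", F_final)

  structure(list(bank = bank, mixpost = mixpost, noisepost = noisepost,
                 state = sp, alpha = alpha, Psi = Psi, nu = nu,
                 free_energy = F_final,
                 trace = tibble::tibble(outer = trace_outer,
                                        inner = trace_inner,
                                        phase = trace_phase,
                                        free_energy = trace_F),
                 converged = converged, M = M, fs = fs, seed = seed,
                 config = config, init_freqs = init$init_freqs),
            class = "oca_single_fit")
}

#' @export
print.oca_single_fit <- function(x, ...) {
  cat(sprintf("<oca_single_fit> M = %d, ELBO = %.3f, %s\n", x$M,
              x$free_energy,
              if (x$converged) "converged" else "iteration cap reached"))
  print(tidy.oscillator_bank(x$bank))
  invisible(x)
}

# Gauge fix for reporting: rotate each oscillator's state coordinates so
# the mixing pair at its maximum-magnitude channel is purely real-positive.
# Returns the rotated mixing posterior and the per-component angles.
gauge_fix_mixing <- function(mixpost) {
  Cm <- mixpost$mean
  L <- nrow(Cm); d <- ncol(Cm); M <- d / 2L
  V <- mixpost$vec_cov
  G <- diag(d)
  phis <- numeric(M)
  for (m in seq_len(M)) {
    i <- c(2L * m - 1L, 2L * m)
    norms <- sqrt(Cm[, i[1]]^2 + Cm[, i[2]]^2)
    l_star <- which.max(norms)
    phi <- atan2(Cm[l_star, i[2]], Cm[l_star, i[1]])
    phis[m] <- phi
    G[i, i] <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2L, 2L)
  }
  # x' = G' x rotates states; C' = C G keeps C x invariant.
  Cm_new <- Cm %*% G
  V_new <- if (is.null(V)) NULL else {
    K <- kronecker(t(G), diag(L))
    K %*% V %*% t(K)
  }
  list(mixpost = mixing_posterior(Cm_new, V_new), angles = phis)
}
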