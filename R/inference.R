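#' Expected observation model for state inference
#'
#' During variational state inference the mixing matrix `C` and the noise
#' covariance `R` are uncertain; the state update uses their posterior
#' moments. The quadratic term is `E[C' R^-1 C]`, which adds a correction
#' from the mixing posterior covariance on top of `E[C]' E[R^-1] E[C]`.
#'
#' @param mixing_mean `L x 2M` matrix, `E[C]`.
#' @param mixing_vec_cov Covariance of `vec(C)` (column-major, `2ML x 2ML`),
#'   or `NULL` for a point mass at `mixing_mean`.
#' @param noise_precision_mean `L x L` symmetric positive definite matrix,
#'   `E[R^-1]`.
#' @param logdet_noise_precision `E[log det R^-1]`; defaults to
#'   `log det(noise_precision_mean)`, the point-mass convention.
#' @return An object of class `"observation_model"`.
#' @export
observation_model <- function(mixing_mean, mixing_vec_cov = NULL,
                              noise_precision_mean,
                              logdet_noise_precision = NULL) {
  mixing_mean <- as.matrix(mixing_mean)
  L <- nrow(mixing_mean); d <- ncol(mixing_mean)
  noise_precision_mean <- as.matrix(noise_precision_mean)
  stopifnot(nrow(noise_precision_mean) == L, ncol(noise_precision_mean) == L)
  if (max(abs(noise_precision_mean - t(noise_precision_mean))) >
      1e-8 * (1 + max(abs(noise_precision_mean))))
    stop("noise_precision_mean must be symmetric")
  if (!is.null(mixing_vec_cov)) {
    mixing_vec_cov <- as.matrix(mixing_vec_cov)
    stopifnot(nrow(mixing_vec_cov) == L * d, ncol(mixing_vec_cov) == L * d)
  }
  if (is.null(logdet_noise_precision))
    logdet_noise_precision <-
      as.numeric(determinant(noise_precision_mean, logarithm = TRUE)$modulus)
  structure(list(mixing_mean = mixing_mean,
                 mixing_vec_cov = mixing_vec_cov,
                 noise_precision_mean = noise_precision_mean,
                 logdet_noise_precision = logdet_noise_precision),
            class = "observation_model")
}

# E[C' R^-1 C] including the mixing-covariance correction.
expected_CtRinvC <- function(obs) {
  Cm <- obs$mixing_mean
  Rinv <- obs$noise_precision_mean
  G <- t(Cm) %*% Rinv %*% Cm
  if (!is.null(obs$mixing_vec_cov)) {
    L <- nrow(Cm); d <- ncol(Cm)
    # G_{jk} += sum_{l,l'} Rinv[l,l'] Cov(C_{l j}, C_{l' k}), contracted as
    # one matrix product over the (l, l') axes of the 4-way covariance.
    V4 <- array(obs$mixing_vec_cov, c(L, d, L, d))
    Vg <- matrix(aperm(V4, c(2L, 4L, 1L, 3L)), d * d, L * L)
    G <- G + matrix(Vg %*% as.vector(Rinv), d, d)
  }
  0.5 * (G + t(G))
}

# Gamma_{ll'} = sum_{jk} S11[j,k] Cov(C_{l j}, C_{l' k}): the L x L mixing-
# covariance contribution to the expected residual scatter.
mixing_cov_scatter <- function(mixing_vec_cov, S11, L) {
  d <- nrow(S11)
  if (is.null(mixing_vec_cov)) return(matrix(0, L, L))
  V4 <- array(mixing_vec_cov, c(L, d, L, d))
  Vl <- matrix(aperm(V4, c(1L, 3L, 2L, 4L)), L * L, d * d)
  Gam <- matrix(Vl %*% as.vector(S11), L, L)
  0.5 * (Gam + t(Gam))
}

# Expected residual scatter sum_t E[(y_t - C x_t)(y_t - C x_t)'] under
# q(C) q({x_t}), from aggregated sufficient statistics.
expected_residual_scatter <- function(suff, mixing_mean, mixing_vec_cov) {
  Cm <- mixing_mean
  CS <- Cm %*% suff$Sxy                 # L x L
  scatter <- suff$Syy - t(CS) - CS + Cm %*% suff$S11 %*% t(Cm) +
    mixing_cov_scatter(mixing_vec_cov, suff$S11, nrow(Cm))
  0.5 * (scatter + t(scatter))
}

as_epoch_list <- function(y) {
  if (is.list(y)) y <- lapply(y, as.matrix) else y <- list(as.matrix(y))
  if (!all(vapply(y, function(e) all(is.finite(e)), logical(1))))
    stop("observations must be finite (missing samples are not supported)")
  L <- unique(vapply(y, ncol, integer(1)))
  if (length(L) != 1L) stop("all epochs must have the same channel count")
  y
}

run_core <- function(y, bank, obs, smooth, want_moments = TRUE) {
  epochs <- as_epoch_list(y)
  L <- ncol(epochs[[1L]])
  if (nrow(obs$mixing_mean) != L)
    stop("observation model channel count does not match the data")
  if (ncol(obs$mixing_mean) != state_dim(bank))
    stop("observation model state dimension does not match the bank")
  A <- transition_matrix(bank)
  Q <- process_covariance(bank)
  P0 <- bank_stationary_covariance(bank)
  G <- expected_CtRinvC(obs)
  lapply(epochs, function(e)
    .kalman_core(e, A, Q, P0, rep(0, state_dim(bank)),
                 obs$mixing_mean, G, obs$noise_precision_mean,
                 obs$logdet_noise_precision, smooth, want_moments))
}

#' Kalman filter under the expected observation model
#'
#' Forward filtering of the oscillator state sequence. Per-oscillator
#' dynamics come from the bank; the measurement update uses the expected
#' observation operator including the `E[C' R^-1 C]` correction from the
#' mixing posterior covariance. Epoched input (a list of matrices) restarts
#' the recursion per epoch from the stationary prior.
#'
#' @param y `T x L` matrix, or a list of such matrices (epochs).
#' @param bank An [oscillator_bank()].
#' @param obs An [observation_model()].
#' @return List with `filtered_means` (per epoch, `(T+1) x 2M`, first row is
#'   the prior state `x_0`), `filtered_covs`, and `loglik` (the summed
#'   surrogate log-likelihood; exact innovations log-likelihood when the
#'   observation posteriors are point masses).
#' @export
kalman_filter <- function(y, bank, obs) {
  res <- run_core(y, bank, obs, smooth = FALSE, want_moments = TRUE)
  list(filtered_means = lapply(res, `[[`, "filtered_means"),
       filtered_covs = lapply(res, `[[`, "filtered_covs"),
       loglik = sum(vapply(res, `[[`, numeric(1), "logZ")))
}

#' Kalman smoother and sufficient statistics
#'
#' Runs the forward filter and RTS backward smoother, returning the smoothed
#' posterior of the state sequence together with the aggregated sufficient
#' statistics consumed by the learning updates:
#' `S11 = sum_t E[x_t x_t']` (t = 1..T), `S00` (t = 0..T-1),
#' `S10 = sum_t E[x_t x_{t-1}']`, `Sxy = sum_t E[x_t] y_t'`, plus
#' `Syy = sum_t y_t y_t'`, the per-epoch initial-state scatter `Sinit`, the
#' total sample count and epoch count. For epoched input the recursions
#' restart per epoch from the stationary prior and statistics are summed.
#'
#' @inheritParams kalman_filter
#' @param keep_moments Keep the full per-sample smoothed covariances and
#'   lag-one covariances (default). The learning loop only needs the
#'   aggregated statistics and passes `FALSE` to avoid the moment storage.
#' @return An object of class `"state_posterior"`; see Details. `means` /
#'   `covariances` / `lag_one_covariances` are per-epoch lists; means are
#'   `(T+1) x 2M` with the smoothed `x_0` in row 1, and lag-one slices pair
#'   `(x_t, x_{t-1})` for t = 1..T. `loglik_surrogate` is the state-integral
#'   contribution to the negative variational free energy and `entropy` the
#'   entropy of the smoothed state posterior.
#' @export
kalman_smooth <- function(y, bank, obs, keep_moments = TRUE) {
  epochs <- as_epoch_list(y)
  res <- run_core(epochs, bank, obs, smooth = TRUE, want_moments = keep_moments)
  d <- state_dim(bank); L <- ncol(epochs[[1L]])
  add <- function(f) Reduce(`+`, lapply(res, `[[`, f))
  suff <- list(
    S11 = add("S11"), S00 = add("S00"), S10 = add("S10"), Sxy = add("Sxy"),
    Syy = Reduce(`+`, lapply(epochs, crossprod)),
    Sinit = add("Sinit"),
    T_total = sum(vapply(epochs, nrow, integer(1))),
    n_epochs = length(epochs))
  logZ <- sum(vapply(res, `[[`, numeric(1), "logZ"))
  e_logp_y <- expected_obs_loglik(suff, obs)
  e_logp_x <- expected_state_loglik(suff, bank)
  structure(list(
    means = lapply(res, `[[`, "means"),
    covariances = if (keep_moments) lapply(res, `[[`, "covs"),
    lag_one_covariances = if (keep_moments) lapply(res, `[[`, "lag1"),
    loglik_surrogate = logZ,
    entropy = logZ - e_logp_y - e_logp_x,
    suff_stats = suff,
    dims = list(d = d, L = L)),
    class = "state_posterior")
}

# E_q[log p(y | x, C, R)] from sufficient statistics under the expected
# observation model.
expected_obs_loglik <- function(suff, obs) {
  L <- nrow(obs$mixing_mean)
  scatter <- expected_residual_scatter(suff, obs$mixing_mean, obs$mixing_vec_cov)
  suff$T_total * (-L / 2 * log(2 * pi) + 0.5 * obs$logdet_noise_precision) -
    0.5 * sum(obs$noise_precision_mean * scatter)
}

# E_q[log p(x_0..x_T)] under the bank's dynamics, from sufficient statistics.
expected_state_loglik <- function(suff, bank) {
  M <- n_oscillators(bank)
  total <- 0
  for (m in seq_len(M)) {
    i <- (2L * m - 1L):(2L * m)
    s2 <- bank$sigma2[m]; a <- bank$a[m]
    s0 <- s2 / (1 - a^2)
    Rm <- rotation_matrix(bank$f[m], bank$fs)
    quad <- sum(diag(suff$S11[i, i])) - 2 * a * sum(Rm * suff$S10[i, i]) +
      a^2 * sum(diag(suff$S00[i, i]))
    total <- total +
      (-suff$n_epochs * (log(2 * pi) + log(s0)) -
         sum(diag(suff$Sinit[i, i])) / (2 * s0)) +
      (-suff$T_total * (log(2 * pi) + log(s2)) - quad / (2 * s2))
  }
  total
}

#' Recompute sufficient statistics from smoothed moments
#'
#' Rebuilds `S11`, `S00`, `S10`, `Sxy` from the stored smoothed means,
#' covariances and lag-one covariances. Used as a consistency check on the
#' smoother output.
#'
#' @param sp A `"state_posterior"` from [kalman_smooth()].
#' @param y The observations the posterior was computed from (matrix or
#'   epoch list), needed for `Sxy`.
#' @return A list with `S11`, `S00`, `S10`, `Sxy`.
#' @export
recompute_suff_stats <- function(sp, y) {
  stopifnot(inherits(sp, "state_posterior"))
  if (is.null(sp$covariances))
    stop("posterior was computed with keep_moments = FALSE")
  epochs <- as_epoch_list(y)
  if (length(epochs) != length(sp$means)) stop("epoch count mismatch")
  d <- sp$dims$d
  S11 <- S00 <- S10 <- matrix(0, d, d)
  Sxy <- matrix(0, d, sp$dims$L)
  for (e in seq_along(epochs)) {
    ms <- sp$means[[e]]; Ps <- sp$covariances[[e]]
    lag1 <- sp$lag_one_covariances[[e]]
    T_e <- nrow(epochs[[e]])
    if (nrow(ms) != T_e + 1L) stop("posterior/observation length mismatch")
    for (t in seq_len(T_e)) {
      S11 <- S11 + Ps[, , t + 1L] + tcrossprod(ms[t + 1L, ])
      S00 <- S00 + Ps[, , t] + tcrossprod(ms[t, ])
      S10 <- S10 + lag1[, , t] + ms[t + 1L, ] %o% ms[t, ]
      Sxy <- Sxy + ms[t + 1L, ] %o% epochs[[e]][t, ]
    }
  }
  list(S11 = S11, S00 = S00, S10 = S10, Sxy = Sxy)
}
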