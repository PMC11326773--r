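#' Simulate an AR(2) oscillatory source
#'
#' Univariate AR(2) process with a complex pole pair at radius `pole_radius`
#' and angle `2 pi f / fs`, i.e. coefficients
#' `phi1 = 2 * pole_radius * cos(2 pi f / fs)`, `phi2 = -pole_radius^2`,
#' driven by unit-variance Gaussian innovations. This is the standard way to
#' generate a stable stochastic oscillation at a chosen center frequency.
#'
#' @param f Oscillation frequency in Hz, `0 < f < fs/2`.
#' @param fs Sampling rate in Hz.
#' @param pole_radius Pole radius in `[0, 1)`; closer to 1 gives a narrower
#'   spectral peak.
#' @param T_len Number of samples.
#' @param seed Integer seed.
#' @return Numeric vector of length `T_len`.
#' @export
ar2_source <- function(f, fs, pole_radius = 0.98, T_len, seed) {
  stopifnot(f > 0, f < fs / 2, T_len >= 1)
  if (pole_radius < 0 || pole_radius >= 1)
    stop("pole_radius must lie in [0, 1) for a stable oscillation")
  phi1 <- 2 * pole_radius * cos(2 * pi * f / fs)
  phi2 <- -pole_radius^2
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  innov <- stats::rnorm(T_len + 200L)  # burn-in to reach stationarity
  x <- numeric(T_len + 200L)
  for (t in 3:length(x)) x[t] <- phi1 * x[t - 1] + phi2 * x[t - 2] + innov[t]
  x[(length(x) - T_len + 1L):length(x)]
}

#' Random symmetric positive definite covariance
#'
#' Seeded SPD matrix with eigenvalues geometrically spaced so the condition
#' number is close to `condition_target`, conjugated by a random orthogonal
#' basis.
#'
#' @param L Dimension (`>= 2`).
#' @param condition_target Desired condition number (`>= 1`).
#' @param seed Integer seed.
#' @param scale Trace is normalized to `L * scale`.
#' @return `L x L` SPD matrix.
#' @export
random_spd_covariance <- function(L, condition_target = 4, seed = 1,
                                  scale = 1) {
  stopifnot(L >= 2, condition_target >= 1)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  ev <- exp(seq(log(condition_target), 0, length.out = L))
  Qb <- qr.Q(qr(matrix(stats::rnorm(L * L), L, L)))
  S <- Qb %*% diag(ev) %*% t(Qb)
  S <- 0.5 * (S + t(S))
  S * (L * scale / sum(diag(S)))
}

#' Mixing specification for lagged linear source-to-sensor projection
#'
#' @param weights `L x n_sources` matrix of channel weights (each source
#'   must have at least one nonzero weight).
#' @param lags `L x n_sources` matrix of non-negative integer sample lags
#'   applied per channel and source.
#' @return An object of class `"mixing_spec"`.
#' @export
mixing_spec <- function(weights, lags = NULL) {
  weights <- as.matrix(weights)
  if (is.null(lags)) lags <- matrix(0L, nrow(weights), ncol(weights))
  lags <- matrix(as.integer(lags), nrow(weights), ncol(weights))
  if (any(lags < 0)) stop("lags must be non-negative")
  if (any(colSums(abs(weights)) == 0))
    stop("every source needs at least one nonzero channel weight")
  structure(list(weights = weights, lags = lags, L = nrow(weights)),
            class = "mixing_spec")
}

#' Project sources to sensors with per-channel lags and colored noise
#'
#' Channel `l` receives `sum_s weights[l, s] * source_s(t - lags[l, s])`
#' plus one draw of multivariate Gaussian noise with covariance
#' `noise_cov`. Lags are integer sample shifts; the leading `max(lags)`
#' samples are trimmed so all channels align.
#'
#' @param sources `T x n_sources` matrix of source time courses.
#' @param spec A [mixing_spec()].
#' @param noise_cov `L x L` SPD noise covariance.
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed for the noise draw.
#' @return List with `rec` (an [oca_recording()] of `T - max(lags)`
#'   samples) and `truth` (sources, weights, lags, noise covariance, seed).
#' @export
simulate_sensor_data <- function(sources, spec, noise_cov, fs, seed) {
  sources <- as.matrix(sources)
  stopifnot(inherits(spec, "mixing_spec"),
            ncol(sources) == ncol(spec$weights))
  T_len <- nrow(sources)
  max_lag <- max(spec$lags)
  if (max_lag >= T_len) stop("lag exceeds the series length")
  T_out <- T_len - max_lag
  L <- spec$L
  Y <- matrix(0, T_out, L)
  for (l in seq_len(L)) {
    for (s in seq_len(ncol(sources))) {
      w <- spec$weights[l, s]
      if (w == 0) next
      lag <- spec$lags[l, s]
      idx <- (max_lag + 1L - lag):(T_len - lag)
      Y[, l] <- Y[, l] + w * sources[idx, s]
    }
  }
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  ch <- chol(noise_cov)
  noise <- matrix(stats::rnorm(T_out * L), T_out, L) %*% ch
  list(rec = oca_recording(Y + noise, fs),
       truth = list(sources = sources[(max_lag + 1L):T_len, , drop = FALSE],
                    weights = spec$weights, lags = spec$lags,
                    noise_cov = noise_cov, seed = seed))
}

#' Simulate data exactly from the generative oscillation model
#'
#' Draws latent states from the oscillator bank and observes
#' `y_t = C x_t + noise`, the data-generating process the fitting algorithm
#' assumes. Used for parameter-recovery validation.
#'
#' @param bank An [oscillator_bank()].
#' @param mixing `L x 2M` mixing matrix.
#' @param noise_cov `L x L` SPD noise covariance.
#' @param T_len Samples per epoch.
#' @param seed Integer seed.
#' @param n_epochs Number of independent epochs.
#' @return List with `rec` (an [oca_recording()]) and `truth` (list with
#'   `states` per epoch, `bank`, `mixing`, `noise_cov`, `seed`).
#' @export
generative_sim <- function(bank, mixing, noise_cov, T_len, seed,
                           n_epochs = 1L) {
  mixing <- as.matrix(mixing)
  stopifnot(ncol(mixing) == state_dim(bank))
  L <- nrow(mixing)
  ch <- chol(noise_cov)
  epochs <- vector("list", n_epochs)
  states <- vector("list", n_epochs)
  for (e in seq_len(n_epochs)) {
    tr <- simulate_states(bank, T_len, seed = seed + 7919L * (e - 1L))
    old <- local_seed(seed + 7919L * (e - 1L) + 104729L)
    noise <- matrix(stats::rnorm(T_len * L), T_len, L) %*% ch
    restore_seed(old)
    states[[e]] <- tr$states
    epochs[[e]] <- tr$states %*% t(mixing) + noise
  }
  dat <- if (n_epochs == 1L) epochs[[1L]] else epochs
  list(rec = oca_recording(dat, bank$fs),
       truth = list(states = states, bank = bank, mixing = mixing,
                    noise_cov = noise_cov, seed = seed))
}

#' Three-oscillation synthetic EEG study fixture
#'
#' A seeded multichannel fixture with the statistical structure the method
#' targets: three AR(2) sources — one slow/delta oscillation at 1.6 Hz
#' shared by two channel groups with a 10 ms relative lag (one sample at
#' fs = 100 Hz), and two independent alpha oscillations at 10 and 12 Hz
#' carried by two further groups — projected through seeded synthetic
#' channel weights with additive spatially colored Gaussian noise. The
#' mixing is synthetic (no head-model lead field): four channel groups
#' stand in for the four cortical source regions.
#'
#' @param scale `"full"` (2 epochs x 20 s x 16 channels) or `"reduced"`
#'   (2 epochs x 10 s x 8 channels).
#' @param seed Integer seed.
#' @param noise_scale Per-channel noise variance scale relative to the
#'   unit-variance sources (default 0.1).
#' @return List with `rec` (epoched [oca_recording()]) and `truth`
#'   (`sources` with true frequencies, group assignments, weights, lag,
#'   noise covariance).
#' @export
sim_fixture_eeg <- function(scale = c("reduced", "full"), seed = 1,
                            noise_scale = 0.1) {
  scale <- match.arg(scale)
  fs <- 100
  n_epochs <- 2L
  T_ep <- if (scale == "full") 20 * fs else 10 * fs
  L <- if (scale == "full") 16L else 8L
  per_group <- L / 4L
  freqs <- c(1.6, 10, 12)
  lag_samples <- 1L  # 10 ms at 100 Hz

  max_lag <- lag_samples
  old <- local_seed(seed)
  weights <- matrix(0, L, 3L)
  lags <- matrix(0L, L, 3L)
  groups <- rep(1:4, each = per_group)
  # groups 1 and 2 share the slow source (group 2 lagged); groups 3 and 4
  # carry the independent alpha sources.
  src_of_group <- c(1L, 1L, 2L, 3L)
  for (g in 1:4) {
    rows <- which(groups == g)
    s <- src_of_group[g]
    weights[rows, s] <- abs(stats::rnorm(length(rows), mean = 1, sd = 0.25))
    if (g == 2L) lags[rows, s] <- lag_samples
  }
  restore_seed(old)
  noise_cov <- random_spd_covariance(L, condition_target = 4,
                                     seed = seed + 11L, scale = noise_scale)

  epochs <- vector("list", n_epochs)
  src_list <- vector("list", n_epochs)
  spec <- mixing_spec(weights, lags)
  for (e in seq_len(n_epochs)) {
    S <- vapply(seq_along(freqs), function(s)
      ar2_source(freqs[s], fs, 0.98, T_ep + max_lag,
                 seed = seed + 1000L * e + s), numeric(T_ep + max_lag))
    S <- scale(S, center = TRUE, scale = apply(S, 2, stats::sd))
    sim <- simulate_sensor_data(S, spec, noise_cov, fs,
                                seed = seed + 500L + e)
    epochs[[e]] <- sim$rec$data[[1L]]
    src_list[[e]] <- sim$truth$sources
  }
  list(rec = oca_recording(epochs, fs),
       truth = list(freqs = freqs, sources = src_list, weights = weights,
                    lags = lags, groups = groups,
                    src_of_group = src_of_group,
                    lag_ms = 1000 * lag_samples / fs,
                    noise_cov = noise_cov, seed = seed, fs = fs))
}
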