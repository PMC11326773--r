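#' Parameters of a single stochastic oscillator
#'
#' An oscillation is modelled as a damped stochastic rotation in a
#' two-dimensional state space,
#' \deqn{x_t = a R(f) x_{t-1} + v_t, \qquad v_t \sim N_2(0, \sigma^2 I),}
#' where the two state coordinates behave like the real and imaginary parts
#' of an analytic signal. `f` is the center frequency in Hz, `a` the
#' dimensionless damping factor (per-step amplitude retention, `0 < a < 1`
#' for a stationary process) and `sigma2` the process-noise variance.
#'
#' @param f Center frequency in Hz, in `[0, fs/2]`.
#' @param a Damping factor, strictly inside `(0, 1)` (a = 0 is allowed and
#'   means a memoryless process).
#' @param sigma2 Process-noise variance, `> 0`.
#' @return An object of class `"oscillator_params"`.
#' @export
oscillator_params <- function(f, a, sigma2) {
  stopifnot(is.numeric(f), length(f) == 1L, is.finite(f),
            is.numeric(a), length(a) == 1L, is.finite(a),
            is.numeric(sigma2), length(sigma2) == 1L, is.finite(sigma2))
  if (f < 0) stop("center frequency must be non-negative")
  if (a < 0 || a >= 1) stop("damping factor must lie in [0, 1)")
  if (sigma2 <= 0) stop("process-noise variance must be positive")
  structure(list(f = f, a = a, sigma2 = sigma2), class = "oscillator_params")
}

#' A bank of oscillators sharing one sampling rate
#'
#' Bundles `M` oscillators into the block state-space model whose transition
#' matrix is block-diagonal with blocks \eqn{a^{(m)} R(f^{(m)})}. The state
#' dimension is `2 * M`.
#'
#' @param f,a,sigma2 Numeric vectors of equal length `M` with per-oscillator
#'   parameters (see [oscillator_params()]).
#' @param fs Sampling rate in Hz, `> 0`; all `f` must be `<= fs/2`.
#' @return An object of class `"oscillator_bank"` with fields `f`, `a`,
#'   `sigma2` (length-`M` vectors) and `fs`.
#' @export
oscillator_bank <- function(f, a, sigma2, fs) {
  stopifnot(length(f) >= 1L, length(f) == length(a), length(f) == length(sigma2),
            is.numeric(fs), length(fs) == 1L, fs > 0)
  for (m in seq_along(f)) {
    p <- oscillator_params(f[m], a[m], sigma2[m])  # validates each entry
    if (p$f > fs / 2) stop("center frequency exceeds the Nyquist frequency fs/2")
  }
  structure(list(f = as.numeric(f), a = as.numeric(a),
                 sigma2 = as.numeric(sigma2), fs = fs),
            class = "oscillator_bank")
}

#' @export
print.oscillator_bank <- function(x, ...) {
  cat(sprintf("<oscillator_bank> %d oscillator(s), fs = %g Hz\n",
              length(x$f), x$fs))
  print(tidy.oscillator_bank(x))
  invisible(x)
}

n_oscillators <- function(bank) length(bank$f)

state_dim <- function(bank) 2L * length(bank$f)

#' Tidy summary of an oscillator bank
#'
#' @param x An [oscillator_bank()].
#' @param ... Unused.
#' @return A tibble with one row per oscillator: `component`, `f`, `a`,
#'   `sigma2` and the stationary per-coordinate state variance
#'   `sigma2 / (1 - a^2)`.
#' @export
tidy.oscillator_bank <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$f),
    f = x$f, a = x$a, sigma2 = x$sigma2,
    stationary_var = x$sigma2 / (1 - x$a^2)
  )
}

#' Rotation matrix of an oscillator
#'
#' The deterministic part of one oscillator step is the planar rotation by
#' \eqn{\omega = 2\pi f / f_s}:
#' \deqn{R(f) = \begin{pmatrix} \cos\omega & -\sin\omega \\ \sin\omega &
#'   \cos\omega \end{pmatrix}.}
#'
#' @param f Frequency in Hz, in `[0, fs/2]`.
#' @param fs Sampling rate in Hz.
#' @return A 2x2 orthogonal matrix with determinant 1.
#' @export
rotation_matrix <- function(f, fs) {
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be positive")
  if (!is.numeric(f) || length(f) != 1L || !is.finite(f) || f < 0 || f > fs / 2)
    stop("f must lie in [0, fs/2]")
  w <- 2 * pi * f / fs
  matrix(c(cos(w), sin(w), -sin(w), cos(w)), 2L, 2L)
}

#' Block-diagonal transition matrix of an oscillator bank
#'
#' @param bank An [oscillator_bank()].
#' @return The `2M x 2M` transition matrix with m-th diagonal block
#'   `a[m] * rotation_matrix(f[m], fs)`; off-block entries are exactly zero.
#' @export
transition_matrix <- function(bank) {
  stopifnot(inherits(bank, "oscillator_bank"))
  M <- n_oscillators(bank)
  A <- matrix(0, 2L * M, 2L * M)
  for (m in seq_len(M)) {
    i <- (2L * m - 1L):(2L * m)
    A[i, i] <- bank$a[m] * rotation_matrix(bank$f[m], bank$fs)
  }
  A
}

# Block-diagonal process-noise covariance (sigma2[m] * I2 per block).
process_covariance <- function(bank) {
  diag(rep(bank$sigma2, each = 2L), 2L * n_oscillators(bank))
}

#' Stationary state covariance of one oscillator
#'
#' The fixed point of `V = a^2 R V R' + sigma2 I`, which is isotropic:
#' `sigma2 / (1 - a^2) * I`.
#'
#' @param p An [oscillator_params()] object (requires `a < 1`).
#' @return A 2x2 matrix.
#' @export
stationary_covariance <- function(p) {
  stopifnot(inherits(p, "oscillator_params"))
  if (p$a >= 1) stop("nonstationary oscillator: damping factor must be < 1")
  diag(p$sigma2 / (1 - p$a^2), 2L)
}

# Stationary covariance of the whole bank (block diagonal, isotropic blocks).
bank_stationary_covariance <- function(bank) {
  diag(rep(bank$sigma2 / (1 - bank$a^2), each = 2L), 2L * n_oscillators(bank))
}

#' Simulate latent oscillator states
#'
#' Exact forward simulation of the stochastic difference equation
#' `x_t = A x_{t-1} + v_t` with `A = transition_matrix(bank)` and
#' `v_t ~ N(0, diag(sigma2[m] I_2))`. Identical arguments (including `seed`)
#' give bit-identical output.
#'
#' @param bank An [oscillator_bank()].
#' @param T_len Number of samples to simulate (`>= 1`).
#' @param seed Integer seed for the draws.
#' @param init Optional initial state (length `2M`) used as `x_0`; by default
#'   `x_0` is drawn from the stationary distribution so the simulation is
#'   stationary from the first sample.
#' @return An object of class `"state_trajectory"`: list with `states`
#'   (`T_len x 2M` matrix, rows are `x_1 ... x_T`), `x0`, `fs`.
#' @export
simulate_states <- function(bank, T_len, seed, init = NULL) {
  stopifnot(inherits(bank, "oscillator_bank"), T_len >= 1)
  d <- state_dim(bank)
  A <- transition_matrix(bank)
  sd_step <- rep(sqrt(bank$sigma2), each = 2L)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  if (is.null(init)) {
    init <- stats::rnorm(d, sd = sqrt(rep(bank$sigma2 / (1 - bank$a^2), each = 2L)))
  }
  stopifnot(length(init) == d)
  X <- matrix(0, T_len, d)
  x <- as.numeric(init)
  for (t in seq_len(T_len)) {
    x <- drop(A %*% x) + stats::rnorm(d, sd = sd_step)
    X[t, ] <- x
  }
  structure(list(states = X, x0 = as.numeric(init), fs = bank$fs),
            class = "state_trajectory")
}

# Seed handling: set a local RNG seed and restore the caller's RNG state.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
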