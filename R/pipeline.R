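#' Multichannel recording container
#'
#' @param data `T x L` numeric matrix (continuous recording) or a list of
#'   equally sized `T_e x L` matrices (epochs).
#' @param fs Sampling rate in Hz.
#' @param channel_names Optional character vector of length `L`.
#' @return An object of class `"oca_recording"` with fields `data` (always a
#'   list of epoch matrices), `fs`, `channel_names`, `epoched`.
#' @export
oca_recording <- function(data, fs, channel_names = NULL) {
  epoched <- is.list(data)
  data <- as_epoch_list(data)
  T_e <- unique(vapply(data, nrow, integer(1)))
  if (length(T_e) != 1L) stop("all epochs must have equal length")
  L <- ncol(data[[1L]])
  if (L < 2L) stop("a recording needs at least 2 channels")
  stopifnot(is.numeric(fs), fs > 0)
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(L))
  stopifnot(length(channel_names) == L)
  structure(list(data = data, fs = fs, channel_names = channel_names,
                 epoched = epoched),
            class = "oca_recording")
}

#' @export
print.oca_recording <- function(x, ...) {
  cat(sprintf("<oca_recording> %d epoch(s) x %d samples x %d channels, fs = %g Hz\n",
              length(x$data), nrow(x$data[[1L]]), ncol(x$data[[1L]]), x$fs))
  invisible(x)
}

n_channels <- function(rec) ncol(rec$data[[1L]])

#' Pre-whiten a recording against a noise covariance
#'
#' Applies any supplied orthogonal projector (e.g. the average reference),
#' then scales by the inverse matrix square root of the noise covariance
#' restricted to its non-null subspace; zero-variance directions (from
#' rank-deficient covariances, e.g. average-referenced EEG) are dropped, so
#' the output dimension can be lower than the channel count.
#'
#' @param rec An [oca_recording()].
#' @param noise_cov `L x L` symmetric positive semidefinite noise covariance.
#' @param projector Optional `L x L` projection matrix applied to channels
#'   (and, congruently, to `noise_cov`) before whitening.
#' @return List with `rec` (the whitened recording) and `whitener` (class
#'   `"oca_whitener"`: `forward` k x L, `inverse` L x k, `rank` k).
#' @export
prewhiten <- function(rec, noise_cov, projector = NULL) {
  stopifnot(inherits(rec, "oca_recording"))
  L <- n_channels(rec)
  noise_cov <- as.matrix(noise_cov)
  stopifnot(nrow(noise_cov) == L, ncol(noise_cov) == L)
  dat <- rec$data
  if (!is.null(projector)) {
    projector <- as.matrix(projector)
    dat <- lapply(dat, function(e) e %*% t(projector))
    noise_cov <- projector %*% noise_cov %*% t(projector)
  }
  noise_cov <- 0.5 * (noise_cov + t(noise_cov))
  if (max(abs(noise_cov - diag(diag(noise_cov), L))) == 0) {
    # exactly diagonal: scale channels in place (no eigenbasis rotation)
    eg <- list(values = diag(noise_cov), vectors = diag(L))
  } else {
    eg <- eigen(noise_cov, symmetric = TRUE)
  }
  if (min(eg$values) < -1e-8 * sum(abs(diag(noise_cov))))
    stop("noise covariance has substantially negative eigenvalues")
  keep <- eg$values > max(eg$values) * 1e-10
  ev <- eg$values[keep]; U <- eg$vectors[, keep, drop = FALSE]
  W <- diag(1 / sqrt(ev), length(ev)) %*% t(U)       # k x L forward
  W_inv <- U %*% diag(sqrt(ev), length(ev))          # L x k inverse
  wdat <- lapply(dat, function(e) e %*% t(W))
  wh <- structure(list(forward = W, inverse = W_inv, rank = sum(keep),
                       projector = projector,
                       channel_names = rec$channel_names),
                  class = "oca_whitener")
  list(rec = oca_recording(wdat, rec$fs,
                           paste0("wh", seq_len(sum(keep)))),
       whitener = wh)
}

#' PCA rotation of a whitened recording
#'
#' Rotates the (whitened) data onto its principal axes and retains the
#' leading components explaining at least `var_frac` of the total variance.
#' This is a purely spatial rotation: the temporal structure is untouched.
#'
#' @param rec A whitened [oca_recording()].
#' @param var_frac Retained-variance fraction in `(0, 1]` (default 0.999).
#' @return List with `rec` (rotated, reduced recording), `basis`
#'   (`k x r` orthonormal retained basis), `dropped_basis`, `variances`
#'   (all PC variances), `retained` (indices).
#' @export
pca_reduce <- function(rec, var_frac = 0.999) {
  stopifnot(inherits(rec, "oca_recording"), var_frac > 0, var_frac <= 1)
  ycat <- do.call(rbind, rec$data)
  ycat <- sweep(ycat, 2, colMeans(ycat))
  cv <- crossprod(ycat) / nrow(ycat)
  eg <- eigen(0.5 * (cv + t(cv)), symmetric = TRUE)
  vars <- pmax(eg$values, 0)
  cum <- cumsum(vars) / sum(vars)
  r <- which(cum >= var_frac)[1L]
  nz <- vars > max(vars) * 1e-12
  r <- min(r, sum(nz))  # never keep exact zero-variance directions
  B <- eg$vectors[, seq_len(r), drop = FALSE]
  rot <- lapply(rec$data, function(e) e %*% B)
  list(rec = oca_recording(rot, rec$fs, paste0("pc", seq_len(r))),
       basis = B,
       dropped_basis = eg$vectors[, -seq_len(r), drop = FALSE],
       variances = vars, retained = seq_len(r))
}

#' Fit an oscillation component model to a recording
#'
#' The end-to-end pipeline: pre-whiten against the supplied noise
#' covariance, rotate by PCA (retaining `config$var_frac` of the variance),
#' fit the variational state-space model for every candidate number of
#' oscillators, select the number by empirical Bayes over the candidate
#' grid, and assemble the fitted model with sensor-space mixing maps
#' (gauge-fixed so each component's strongest channel has purely real,
#' positive mixing).
#'
#' @param rec An [oca_recording()].
#' @param noise_cov `L x L` initial sensor-noise covariance.
#' @param candidate_Ms Integer vector of candidate oscillator counts.
#' @param config An [oca_config()].
#' @param seed Integer seed; candidate `M` uses seed `seed + M`.
#' @param projector Optional channel-space projector (see [prewhiten()]).
#' @param strategy Model selection strategy, `"argmax"` or `"knee"`.
#' @return An object of class `"oca_model"`.
#' @export
oca_fit <- function(rec, noise_cov, candidate_Ms, config = oca_config(),
                    seed = 1, projector = NULL,
                    strategy = c("argmax", "knee")) {
  strategy <- match.arg(strategy)
  stopifnot(length(candidate_Ms) >= 1L)
  pw <- prewhiten(rec, noise_cov, projector)
  pr <- pca_reduce(pw$rec, config$var_frac)
  fits <- lapply(candidate_Ms, function(M)
    fit_single_model(pr$rec$data, M, rec$fs, config, seed = seed + M))
  Fs <- vapply(fits, `[[`, numeric(1), "free_energy")
  grid <- model_grid(candidate_Ms, Fs, strategy)
  best <- fits[[which(candidate_Ms == grid$selected_M)[1L]]]
  gf <- gauge_fix_mixing(best$mixpost)
  best$mixpost <- gf$mixpost
  # refresh the stored state posterior under the gauge-fixed mixing so all
  # downstream quantities (sources, residual statistics) are consistent
  best$state <- kalman_smooth(pr$rec$data, best$bank,
                              obs_from_posteriors(best$mixpost,
                                                  best$noisepost))
  sensor_mix <- pw$whitener$inverse %*% pr$basis %*% best$mixpost$mean
  structure(list(fit = best, whitener = pw$whitener, pca = pr,
                 grid = grid, bank = best$bank,
                 sensor_mixing = sensor_mix,
                 component_scale = rep(1, best$M),
                 channel_names = rec$channel_names, fs = rec$fs,
                 config = config, seed = seed),
            class = "oca_model")
}

#' @export
print.oca_model <- function(x, ...) {
  cat(sprintf("<oca_model> %d oscillation component(s), %d sensor channel(s), fs = %g Hz\n",
              x$fit$M, length(x$channel_names), x$fs))
  cat(sprintf("  ELBO = %.2f; candidates tried: %s\n", x$fit$free_energy,
              paste(x$grid$candidate_Ms, collapse = ", ")))
  print(tidy.oscillator_bank(x$bank))
  invisible(x)
}

# Whiten + PCA-rotate a new recording with the stored transforms.
project_recording <- function(model, rec) {
  stopifnot(inherits(model, "oca_model"), inherits(rec, "oca_recording"))
  if (n_channels(rec) != length(model$channel_names))
    stop("channel count does not match the fitted model")
  dat <- rec$data
  if (!is.null(model$whitener$projector))
    dat <- lapply(dat, function(e) e %*% t(model$whitener$projector))
  Wt <- t(model$whitener$forward)
  lapply(dat, function(e) (e %*% Wt) %*% model$pca$basis)
}

#' Extract oscillation component time courses
#'
#' Whitens and rotates the recording with the transforms stored in the
#' model, then runs the Kalman smoother under the fitted parameters. Each
#' component yields a pair of time courses (the real/imaginary
#' analytic-signal coordinates), given as the smoothed posterior means.
#'
#' @param model An `oca_model` (from [oca_fit()]) from [oca_fit()].
#' @param rec An [oca_recording()] with the same channel set the model was
#'   fitted on; defaults to re-deriving sources is not supported — pass the
#'   recording explicitly.
#' @return An object of class `"component_timecourses"`: `states` (list per
#'   epoch of `T x 2M` matrices), `fs`, `M`.
#' @export
get_sources <- function(model, rec) {
  proj <- project_recording(model, rec)
  sp <- kalman_smooth(proj, model$bank,
                      obs_from_posteriors(model$fit$mixpost,
                                          model$fit$noisepost))
  sc <- rep(model$component_scale, each = 2L)
  states <- lapply(sp$means, function(m)
    sweep(m[-1L, , drop = FALSE], 2, sc, `*`))
  structure(list(states = states, fs = model$fs, M = model$fit$M,
                 posterior = sp),
            class = "component_timecourses")
}

#' Reconstruct sensor data from a subset of components
#'
#' Sensor-space reconstruction of the chosen components: the inverse
#' whitening and PCA maps applied to the posterior-mean mixing columns
#' times the smoothed component states. Disjoint subsets sum to the
#' full-subset reconstruction.
#'
#' @param model An `oca_model` (from [oca_fit()]).
#' @param rec The recording to decompose.
#' @param subset Integer vector of component indices (default all); an
#'   empty subset yields an all-zero recording.
#' @param sources Optional precomputed [get_sources()] result for `rec`.
#' @return An [oca_recording()] of the reconstruction.
#' @export
oca_apply <- function(model, rec, subset = seq_len(model$fit$M),
                      sources = NULL) {
  M <- model$fit$M
  if (length(subset) > 0 &&
      (any(subset < 1) || any(subset > M) || anyDuplicated(subset)))
    stop("subset must be distinct component indices in 1..M")
  if (is.null(sources)) sources <- get_sources(model, rec)
  L <- length(model$channel_names)
  cols <- as.vector(rbind(2L * subset - 1L, 2L * subset))
  out <- lapply(sources$states, function(X) {
    if (length(subset) == 0L) return(matrix(0, nrow(X), L))
    X[, cols, drop = FALSE] %*% t(model$sensor_mixing[, cols, drop = FALSE])
  })
  oca_recording(out, model$fs, model$channel_names)
}

#' Residual sensor-noise covariance estimate
#'
#' Combines (a) the expected residual covariance in the retained PC space
#' (data minus the full component reconstruction, moment-matched under the
#' state and mixing posteriors) with (b) the empirical variance of the
#' discarded PCs, mapped back to sensor space through the inverse whitener.
#'
#' @param model An `oca_model` (from [oca_fit()]).
#' @param rec Optional recording; defaults to the statistics of the
#'   training data stored in the model.
#' @return `L x L` symmetric positive semidefinite matrix.
#' @export
get_noise_covariance <- function(model, rec = NULL) {
  wh <- model$whitener
  if (is.null(rec)) {
    suff <- model$fit$state$suff_stats
    scatter <- expected_residual_scatter(suff, model$fit$mixpost$mean,
                                         model$fit$mixpost$vec_cov)
    resid_cov <- scatter / suff$T_total
    drop_var <- model$pca$variances[-model$pca$retained]
  } else {
    proj <- project_recording(model, rec)
    sp <- kalman_smooth(proj, model$bank,
                        obs_from_posteriors(model$fit$mixpost,
                                            model$fit$noisepost))
    scatter <- expected_residual_scatter(sp$suff_stats,
                                         model$fit$mixpost$mean,
                                         model$fit$mixpost$vec_cov)
    resid_cov <- scatter / sp$suff_stats$T_total
    dat <- rec$data
    if (!is.null(wh$projector))
      dat <- lapply(dat, function(e) e %*% t(wh$projector))
    wcat <- do.call(rbind, lapply(dat, function(e) e %*% t(wh$forward)))
    wcat <- sweep(wcat, 2, colMeans(wcat))
    Bd <- model$pca$dropped_basis
    drop_var <- if (ncol(Bd) > 0)
      apply(wcat %*% Bd, 2, function(z) mean(z^2)) else numeric(0)
  }
  B <- model$pca$basis
  Sw <- B %*% resid_cov %*% t(B)
  Bd <- model$pca$dropped_basis
  if (length(drop_var) > 0)
    Sw <- Sw + Bd %*% diag(drop_var, length(drop_var)) %*% t(Bd)
  out <- wh$inverse %*% Sw %*% t(wh$inverse)
  0.5 * (out + t(out))
}

#' Normalize component maps for reporting
#'
#' Rescales each component's sensor map so its maximum channel magnitude is
#' 1, and multiplies the component's extracted time courses by the same
#' factor, leaving every reconstruction (map x time course) unchanged. The
#' extracted traces then carry the data's physical units (e.g. microvolts).
#'
#' @param model An `oca_model` (from [oca_fit()]).
#' @return The model with normalized `sensor_mixing` and updated
#'   `component_scale`.
#' @export
normalize_components <- function(model) {
  M <- model$fit$M
  for (m in seq_len(M)) {
    i <- c(2L * m - 1L, 2L * m)
    mag <- sqrt(model$sensor_mixing[, i[1]]^2 + model$sensor_mixing[, i[2]]^2)
    s <- max(mag)
    if (s <= 0) {
      message("component ", m, " has a zero map; left unscaled")
      next
    }
    model$sensor_mixing[, i] <- model$sensor_mixing[, i] / s
    model$component_scale[m] <- model$component_scale[m] * s
  }
  model
}
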