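#' Canonical frequency-band definitions
#'
#' Default bands used for grouping components by center frequency:
#' slow/delta 0.1-4 Hz, theta 4-8 Hz, alpha 8-13 Hz. Fully user-editable;
#' bands must not overlap.
#'
#' @return A tibble with columns `band`, `low`, `high` (Hz).
#' @export
canonical_bands <- function() {
  tibble::tibble(band = c("slow/delta", "theta", "alpha"),
                 low = c(0.1, 4, 8), high = c(4, 8, 13))
}

check_bands <- function(bands) {
  stopifnot(all(c("band", "low", "high") %in% names(bands)))
  if (any(bands$low >= bands$high)) stop("band edges must satisfy low < high")
  b <- bands[order(bands$low), ]
  if (nrow(b) > 1 && any(b$high[-nrow(b)] > b$low[-1] + 1e-12))
    stop("bands must not overlap")
  invisible(bands)
}

#' Instantaneous amplitude and phase of a component
#'
#' From the paired real/imaginary time courses of component `m`:
#' amplitude `A_t = sqrt(x1^2 + x2^2)` and phase
#' `P_t = atan2(x2, x1)` (four-quadrant, in `(-pi, pi]`; zero amplitude
#' gives phase 0 by convention).
#'
#' @param tc A `"component_timecourses"` object from [get_sources()].
#' @param m Component index.
#' @return List with `amplitude` and `phase`, each a vector over the
#'   concatenated epochs.
#' @export
instantaneous_amplitude_phase <- function(tc, m) {
  stopifnot(inherits(tc, "component_timecourses"), m >= 1, m <= tc$M)
  X <- do.call(rbind, tc$states)
  x1 <- X[, 2L * m - 1L]; x2 <- X[, 2L * m]
  amp <- sqrt(x1^2 + x2^2)
  ph <- atan2(x2, x1)
  ph[amp == 0] <- 0
  list(amplitude = amp, phase = ph)
}

#' Assign components to frequency bands
#'
#' Each component is assigned to the band whose interval
#' `[low, high)` contains its fitted center frequency; frequencies outside
#' all bands map to `"unassigned"`.
#'
#' @param model An `oca_model` (from [oca_fit()]) (or an [oscillator_bank()]).
#' @param bands Band table, see [canonical_bands()].
#' @return Character vector of band labels, one per component.
#' @export
band_group <- function(model, bands = canonical_bands()) {
  check_bands(bands)
  bank <- if (inherits(model, "oca_model")) model$bank else model
  vapply(bank$f, function(f) {
    hit <- which(f >= bands$low & f < bands$high)
    if (length(hit) == 0) "unassigned" else bands$band[hit[1L]]
  }, character(1))
}

# Sensor-wide power of each component: variance of its full sensor-space
# reconstruction summed over channels. Invariant to the reporting
# normalization (map scale and source scale cancel).
component_powers <- function(model, rec, sources = NULL) {
  if (is.null(sources)) sources <- get_sources(model, rec)
  M <- model$fit$M
  vapply(seq_len(M), function(m) {
    recon <- oca_apply(model, rec, subset = m, sources = sources)
    sum(vapply(recon$data, function(e)
      sum(apply(e, 2, stats::var)), numeric(1)))
  }, numeric(1))
}

#' Band coherency of the fitted components
#'
#' Within a frequency band, the ratio of the power of the strongest
#' component to the total power of all components in the band, where power
#' is the sensor-wide variance of the component's reconstruction. A value
#' of 1 means a single component dominates the band.
#'
#' @param model An `oca_model` (from [oca_fit()]).
#' @param rec The recording over which power is measured.
#' @param band Band label present in `bands`.
#' @param bands Band table (default [canonical_bands()]).
#' @param powers Optional precomputed [component_powers()].
#' @return Scalar in `(0, 1]`.
#' @export
band_coherency <- function(model, rec, band, bands = canonical_bands(),
                           powers = NULL) {
  groups <- band_group(model, bands)
  idx <- which(groups == band)
  if (length(idx) == 0) stop("no component has its center frequency in band '",
                             band, "'")
  if (is.null(powers)) powers <- component_powers(model, rec)
  max(powers[idx]) / sum(powers[idx])
}

#' Principal angles between two mixing-map subspaces
#'
#' Measures similarity of the column spans of two sensor-space mixing maps
#' via the singular values of the product of their orthonormal bases. An
#' angle of 0 degrees means one subspace is contained in the other; 90
#' degrees means a direction of one is orthogonal to the other. The scalar
#' summary conventionally reported is the largest angle.
#'
#' @param map1,map2 `L x k` matrices of mixing-map columns (full column
#'   rank required).
#' @return Numeric vector of angles in degrees, ascending.
#' @export
principal_angles <- function(map1, map2) {
  map1 <- as.matrix(map1); map2 <- as.matrix(map2)
  stopifnot(nrow(map1) == nrow(map2))
  for (mp in list(map1, map2))
    if (qr(mp)$rank < ncol(mp))
      stop("rank-deficient mixing map; prune linearly dependent columns")
  Q1 <- qr.Q(qr(map1)); Q2 <- qr.Q(qr(map2))
  sv <- svd(crossprod(Q1, Q2))$d
  sort(acos(pmin(pmax(sv, -1), 1))) * 180 / pi
}

#' Phase-amplitude coupling profile
#'
#' Bins the phase series into equal-width bins over `(-pi, pi]` and reports
#' the conditional mean amplitude per bin — the standard nonparametric
#' summary of cross-frequency phase-amplitude coupling (e.g. alpha
#' amplitude conditioned on slow/delta phase). Empty bins are reported as
#' `NA`, not zero.
#'
#' @param phase_series Phases in radians.
#' @param amplitude_series Amplitudes, same length.
#' @param n_bins Number of bins (`>= 1`).
#' @return A tibble of class `"pac_profile"` with `bin_center` (radians),
#'   `mean_amplitude`, `count`.
#' @export
pac_profile <- function(phase_series, amplitude_series, n_bins = 18) {
  if (length(phase_series) != length(amplitude_series))
    stop("phase and amplitude series must have equal length")
  stopifnot(n_bins >= 1)
  edges <- seq(-pi, pi, length.out = n_bins + 1L)
  # map phases into (-pi, pi]; values equal to -pi wrap to pi
  ph <- ((phase_series + pi) %% (2 * pi)) - pi
  ph[ph == -pi] <- pi
  idx <- findInterval(ph, edges, left.open = TRUE, all.inside = TRUE)
  counts <- tabulate(idx, nbins = n_bins)
  sums <- vapply(seq_len(n_bins), function(b)
    sum(amplitude_series[idx == b]), numeric(1))
  out <- tibble::tibble(
    bin_center = (edges[-1L] + edges[-(n_bins + 1L)]) / 2,
    mean_amplitude = ifelse(counts > 0, sums / pmax(counts, 1L), NA_real_),
    count = counts)
  class(out) <- c("pac_profile", class(out))
  out
}

#' Per-component report table and band coherency
#'
#' @param model An `oca_model` (from [oca_fit()]).
#' @param rec The recording over which component power is measured.
#' @param bands Band table (default [canonical_bands()]).
#' @return List with `components` (tibble: component, frequency, damping,
#'   sigma2, band, power, power_share) and `coherency` (tibble: band,
#'   coherency, n_components).
#' @export
oca_report <- function(model, rec, bands = canonical_bands()) {
  groups <- band_group(model, bands)
  powers <- component_powers(model, rec)
  comp <- tibble::tibble(
    component = seq_along(groups),
    frequency = model$bank$f, damping = model$bank$a,
    sigma2 = model$bank$sigma2, band = groups,
    power = powers, power_share = powers / sum(powers))
  present <- intersect(bands$band, unique(groups))
  coh <- tibble::tibble(
    band = present,
    coherency = vapply(present, function(b)
      band_coherency(model, rec, b, bands, powers = powers), numeric(1)),
    n_components = vapply(present, function(b) sum(groups == b), integer(1)))
  list(components = comp, coherency = coh)
}

#' Sensor-space mixing map magnitudes and phases
#'
#' Each component contributes a 2-vector to every channel encoding its
#' amplitude and phase there; this returns the polar form of the fitted
#' sensor-space maps.
#'
#' @param model An `oca_model` (from [oca_fit()]).
#' @return Tibble with `channel`, `component`, `magnitude`, `phase`.
#' @export
mixing_maps <- function(model) {
  M <- model$fit$M
  Cm <- model$sensor_mixing
  L <- nrow(Cm)
  out <- lapply(seq_len(M), function(m) {
    c1 <- Cm[, 2L * m - 1L]; c2 <- Cm[, 2L * m]
    tibble::tibble(channel = model$channel_names, component = m,
                   magnitude = sqrt(c1^2 + c2^2), phase = atan2(c2, c1))
  })
  do.call(rbind, out)
}

#' Time lag between channel groups from mixing-map phase
#'
#' When two channel groups observe the same oscillation with a time delay,
#' the delay appears as a phase difference in the fitted mixing-map pairs.
#' This converts the (magnitude-weighted circular mean) phase difference of
#' component `m` between two channel groups into a time lag via
#' `lag = dphase / (2 pi f)`, with `f` the component's fitted center
#' frequency.
#'
#' @param model An `oca_model` (from [oca_fit()]).
#' @param m Component index.
#' @param channels_ref,channels_lag Channel indices (or names) of the
#'   reference and the delayed group.
#' @return Lag in milliseconds (positive when `channels_lag` lags the
#'   reference).
#' @export
mixing_phase_lag <- function(model, m, channels_ref, channels_lag) {
  stopifnot(m >= 1, m <= model$fit$M)
  if (is.character(channels_ref))
    channels_ref <- match(channels_ref, model$channel_names)
  if (is.character(channels_lag))
    channels_lag <- match(channels_lag, model$channel_names)
  Cm <- model$sensor_mixing
  z <- complex(real = Cm[, 2L * m - 1L], imaginary = Cm[, 2L * m])
  dphi <- Arg(sum(z[channels_lag]) * Conj(sum(z[channels_ref])))
  1000 * dphi / (2 * pi * model$bank$f[m])
}
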