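#' Write a recording to a delimited text file
#'
#' Plain tab-separated format with a small comment header carrying the
#' sampling rate, channel names and epoch lengths, so a read-write-read
#' round trip is lossless for data, `fs` and channel names.
#'
#' @param rec An [oca_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "oca_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# oscomp recording v1",
               paste0("# fs: ", format(rec$fs, digits = 17)),
               paste0("# channels: ",
                      paste(rec$channel_names, collapse = "\t")),
               paste0("# epochs: ",
                      paste(vapply(rec$data, nrow, integer(1)),
                            collapse = "\t"))), con)
  utils::write.table(do.call(rbind, rec$data), con, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' @param path Input file path.
#' @return An [oca_recording()].
#' @export
read_recording <- function(path) {
  hdr <- readLines(path, n = 4L)
  if (!startsWith(hdr[1L], "# oscomp recording"))
    stop("not an oscomp recording file: ", path)
  fs <- as.numeric(sub("^# fs: ", "", hdr[2L]))
  channels <- strsplit(sub("^# channels: ", "", hdr[3L]), "\t")[[1L]]
  ep_len <- as.integer(strsplit(sub("^# epochs: ", "", hdr[4L]), "\t")[[1L]])
  dat <- as.matrix(utils::read.table(path, sep = "\t", skip = 4L))
  dimnames(dat) <- NULL
  stopifnot(nrow(dat) == sum(ep_len), ncol(dat) == length(channels))
  offs <- cumsum(c(0L, ep_len))
  epochs <- lapply(seq_along(ep_len), function(e)
    dat[(offs[e] + 1L):offs[e + 1L], , drop = FALSE])
  oca_recording(if (length(epochs) == 1L) epochs[[1L]] else epochs,
                fs, channels)
}

mat_to_list <- function(m) list(dim = dim(m), values = as.numeric(m))
list_to_mat <- function(l) {
  d <- as.integer(unlist(l$dim))
  v <- as.numeric(unlist(l$values))
  if (length(v) == 0L) return(matrix(numeric(0), d[1L], d[2L]))
  matrix(v, d[1L], d[2L])
}

#' Serialize a fitted model to a JSON file
#'
#' Versioned single-file archive of all arrays, configuration and seed
#' needed to restore the model with [read_oca_model()].
#'
#' @param model An `oca_model` (from [oca_fit()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_oca_model <- function(model, path) {
  stopifnot(inherits(model, "oca_model"))
  f <- model$fit
  obj <- list(
    schema = "oscomp-model", version = 1L,
    fs = model$fs, seed = model$seed,
    channel_names = model$channel_names,
    config = unclass(model$config),
    bank = list(f = f$bank$f, a = f$bank$a, sigma2 = f$bank$sigma2,
                fs = f$bank$fs),
    mixing_mean = mat_to_list(f$mixpost$mean),
    mixing_vec_cov = mat_to_list(f$mixpost$vec_cov),
    noise_scale = mat_to_list(f$noisepost$scale),
    noise_dof = f$noisepost$dof,
    alpha = f$alpha, Psi = mat_to_list(f$Psi), nu = f$nu,
    free_energy = f$free_energy, converged = f$converged, M = f$M,
    trace = as.list(f$trace),
    whitener = list(forward = mat_to_list(model$whitener$forward),
                    inverse = mat_to_list(model$whitener$inverse),
                    rank = model$whitener$rank,
                    projector = if (is.null(model$whitener$projector)) NULL
                                else mat_to_list(model$whitener$projector)),
    pca = list(basis = mat_to_list(model$pca$basis),
               dropped_basis = mat_to_list(model$pca$dropped_basis),
               variances = model$pca$variances,
               retained = model$pca$retained),
    grid = list(candidate_Ms = model$grid$candidate_Ms,
                free_energies = model$grid$free_energies,
                strategy = model$grid$strategy),
    sensor_mixing = mat_to_list(model$sensor_mixing),
    component_scale = model$component_scale)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Restore a fitted model from [write_oca_model()] output
#'
#' The restored model supports [get_sources()], [oca_apply()],
#' [get_noise_covariance()] and the reporting helpers, but does not carry
#' the training-data state posterior; [get_noise_covariance()] therefore
#' requires an explicit recording.
#'
#' @param path Input file path.
#' @return An `oca_model` (from [oca_fit()]).
#' @export
read_oca_model <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(o$schema, "oscomp-model"))
    stop("not an oscomp model file: ", path)
  bank <- oscillator_bank(o$bank$f, o$bank$a, o$bank$sigma2, o$bank$fs)
  mixpost <- mixing_posterior(list_to_mat(o$mixing_mean),
                              list_to_mat(o$mixing_vec_cov))
  noisepost <- noise_cov_posterior(list_to_mat(o$noise_scale), o$noise_dof)
  config <- do.call(oca_config, o$config)
  fit <- structure(list(
    bank = bank, mixpost = mixpost, noisepost = noisepost, state = NULL,
    alpha = o$alpha, Psi = list_to_mat(o$Psi), nu = o$nu,
    free_energy = o$free_energy,
    trace = tibble::as_tibble(o$trace),
    converged = o$converged, M = o$M, fs = o$fs, seed = o$seed,
    config = config), class = "oca_single_fit")
  whitener <- structure(list(
    forward = list_to_mat(o$whitener$forward),
    inverse = list_to_mat(o$whitener$inverse),
    rank = o$whitener$rank,
    projector = if (is.null(o$whitener$projector)) NULL
                else list_to_mat(o$whitener$projector),
    channel_names = o$channel_names), class = "oca_whitener")
  pca <- list(basis = list_to_mat(o$pca$basis),
              dropped_basis = list_to_mat(o$pca$dropped_basis),
              variances = o$pca$variances, retained = o$pca$retained)
  grid <- model_grid(o$grid$candidate_Ms, o$grid$free_energies,
                     o$grid$strategy)
  structure(list(fit = fit, whitener = whitener, pca = pca, grid = grid,
                 bank = bank, sensor_mixing = list_to_mat(o$sensor_mixing),
                 component_scale = o$component_scale,
                 channel_names = o$channel_names, fs = o$fs,
                 config = config, seed = o$seed),
            class = "oca_model")
}
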