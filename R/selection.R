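#' Model-structure posterior over candidate oscillator counts
#'
#' Under a uniform prior on the number of oscillators, the posterior
#' probability of each candidate model is proportional to the exponential of
#' its negative variational free energy. Computed as a max-subtracted
#' softmax for numerical stability; the uniform-prior constant cancels so
#' non-contiguous candidate grids are normalized over the supplied grid
#' only.
#'
#' @param free_energies Numeric vector of per-model ELBO values.
#' @return Probability vector summing to 1.
#' @export
model_posterior <- function(free_energies) {
  if (length(free_energies) == 0L) stop("empty free-energy list")
  stopifnot(all(is.finite(free_energies)))
  z <- free_energies - max(free_energies)
  e <- exp(z)
  e / sum(e)
}

#' Select the number of oscillators from a fitted grid
#'
#' `"argmax"` returns the candidate with maximal free energy (ties broken
#' toward the smaller count, favoring parsimony). `"knee"` returns the
#' candidate with the largest discrete second difference of the free energy
#' over the sorted candidate list; with fewer than 3 candidates it falls
#' back to argmax with a message.
#'
#' @param candidate_Ms Integer vector of candidate oscillator counts.
#' @param free_energies Matching numeric vector of ELBO values.
#' @param strategy `"argmax"` (default) or `"knee"`.
#' @return The selected integer count.
#' @export
select_model <- function(candidate_Ms, free_energies,
                         strategy = c("argmax", "knee")) {
  strategy <- match.arg(strategy)
  stopifnot(length(candidate_Ms) == length(free_energies),
            length(candidate_Ms) >= 1L)
  ord <- order(candidate_Ms)
  Ms <- candidate_Ms[ord]; Fv <- free_energies[ord]
  if (strategy == "knee" && length(Ms) < 3L) {
    message("knee selection needs >= 3 candidates; falling back to argmax")
    strategy <- "argmax"
  }
  if (strategy == "argmax") {
    return(Ms[which(Fv == max(Fv))[1L]])  # ordered ascending: smallest M wins
  }
  d2 <- abs(diff(Fv, differences = 2))
  Ms[which.max(d2) + 1L]
}

#' Bundle a fitted candidate grid
#'
#' @param candidate_Ms,free_energies Matched candidate counts and ELBOs.
#' @param strategy Selection strategy, see [select_model()].
#' @return An object of class `"model_grid"` with fields `candidate_Ms`,
#'   `free_energies`, `q` (posterior probabilities), `selected_M`,
#'   `strategy`.
#' @export
model_grid <- function(candidate_Ms, free_energies,
                       strategy = c("argmax", "knee")) {
  strategy <- match.arg(strategy)
  q <- model_posterior(free_energies)
  structure(list(candidate_Ms = as.integer(candidate_Ms),
                 free_energies = free_energies, q = q,
                 selected_M = select_model(candidate_Ms, free_energies,
                                           strategy),
                 strategy = strategy),
            class = "model_grid")
}

#' @export
print.model_grid <- function(x, ...) {
  cat(sprintf("<model_grid> selected M = %d (%s)\n", x$selected_M, x$strategy))
  print(tibble::tibble(M = x$candidate_Ms, free_energy = x$free_energies,
                       q = x$q))
  invisible(x)
}
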