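#' @describeIn fit_diffusion_hmm Compact display of the selected model.
#' @param x,object a `diffusion_hmm` fit.
#' @param ... unused.
#' @export
print.diffusion_hmm <- function(x, ...) {
  cat(sprintf("Diffusion HMM: K = %d state(s), %d jumps from %d tracks (dt = %g s)\n",
              x$K, x$n_jumps, x$n_tracks, x$dt))
  tab <- data.frame(state = seq_len(x$K),
                    D_um2_s = round(x$D, 4),
                    occupancy = round(x$pi, 3),
                    dwell_s = round(x$dwell, 3))
  print(tab, row.names = FALSE)
  cat(sprintf("logLik %.2f, BIC %.2f%s\n", x$loglik, x$bic,
              if (x$converged) "" else " (EM not converged)"))
  invisible(x)
}

#' @describeIn fit_diffusion_hmm Full summary including the transition
#'   matrix and the state-selection table.
#' @export
summary.diffusion_hmm <- function(object, ...) {
  print(object)
  cat("\nPer-time-step transition matrix:\n")
  print(round(object$A, 4))
  cat("\nState selection (BIC):\n")
  print(object$selection, row.names = FALSE)
  invisible(object)
}

#' @describeIn fit_diffusion_hmm Named parameter vector (per-state `D`,
#'   occupancies, and off-diagonal transition probabilities).
#' @export
coef.diffusion_hmm <- function(object, ...) {
  K <- object$K
  out <- c(setNames(object$D, paste0("D", seq_len(K))),
           setNames(object$pi, paste0("pi", seq_len(K))))
  if (K > 1) {
    for (i in seq_len(K)) for (j in seq_len(K)) if (i != j)
      out[paste0("A", i, j)] <- object$A[i, j]
  }
  out
}

#' @describeIn fit_diffusion_hmm Maximized log-likelihood with degrees of
#'   freedom and number of jumps.
#' @export
logLik.diffusion_hmm <- function(object, ...) {
  K <- object$K
  structure(object$loglik, df = K + K * (K - 1) + (K - 1),
            nobs = object$n_jumps, class = "logLik")
}

#' @describeIn fit_diffusion_hmm Simulate a new track set from the fitted
#'   model (see [simulate_tracks()]).
#' @param nsim number of tracks to simulate.
#' @param seed integer seed (mandatory).
#' @param mean_track_len mean jumps per simulated track.
#' @export
simulate.diffusion_hmm <- function(object, nsim = object$n_tracks, seed,
                                   mean_track_len = 6, ...) {
  if (missing(seed)) stop("seed is mandatory")
  simulate_tracks(D = object$D, A = object$A, dt = object$dt,
                  loc_error = object$loc_error, n_tracks = nsim,
                  mean_track_len = mean_track_len, seed = seed)
}

#' @describeIn fit_diffusion_hmm Posterior state probabilities and the
#'   maximum a posteriori state for each jump of `newdata` (default: the
#'   class of data the model was fitted to must be re-supplied; posteriors
#'   are computed by a forward-backward pass under the fitted parameters).
#' @param newdata a [track_set()] or [compute_jumps()] result.
#' @export
predict.diffusion_hmm <- function(object, newdata, ...) {
  jumps <- if (inherits(newdata, "jump_set")) newdata else compute_jumps(newdata)
  prep <- hmm_prepare(jumps)
  v <- 4 * object$D * object$dt + 4 * object$loc_error^2
  e <- hmm_estep(prep, object$p0, object$A, pmax(v, 1e-12))
  map <- max.col(e$gamma)
  post <- setNames(as.data.frame(e$gamma), paste0("p_state", seq_len(object$K)))
  cbind(data.frame(track_id = jumps$track_id,
                   magnitude_um = jumps$magnitudes,
                   state = map), post)
}

#' @describeIn fit_diffusion_hmm Histogram of jump magnitudes with the
#'   fitted Rayleigh-mixture density overlaid.
#' @param jumps a [compute_jumps()] result to plot against the fit.
#' @export
plot.diffusion_hmm <- function(x, jumps, ...) {
  r <- jumps$magnitudes
  h <- hist(r, breaks = 60, freq = FALSE,
            xlab = "jump magnitude (um)", main = "Jump magnitudes vs fitted mixture", ...)
  v <- 4 * x$D * x$dt + 4 * x$loc_error^2
  rr <- seq(0, max(r), length.out = 400)
  dens <- rowSums(sapply(seq_len(x$K), function(k)
    x$pi[k] * 2 * rr / v[k] * exp(-rr^2 / v[k])))
  lines(rr, dens, lwd = 2)
  invisible(x)
}
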