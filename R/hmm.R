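## Multi-state diffusion hidden Markov model for pooled short trajectories.
##
## Emissions: the magnitude of a single-step 2D displacement in state k is
## Rayleigh with mean square 4*D_k*dt (+ 4*loc_error^2 when the optional
## static-error term is enabled). The chain switches states between steps
## with a per-time-step transition matrix A. Fitting is maximum-likelihood
## EM (Baum-Welch) with per-track forward-backward passes, vectorized
## across tracks by step index so that thousands of short tracks are
## processed as a handful of matrix operations per step.

# group a jump set into per-track sequences; jumps arrive in track order
hmm_prepare <- function(jumps) {
  r2 <- jumps$magnitudes^2
  rl <- rle(as.character(jumps$track_id))
  len <- rl$lengths
  starts <- cumsum(c(1L, len[-length(len)]))
  maxlen <- max(len)
  idx_by_step <- vector("list", maxlen)
  track_by_step <- vector("list", maxlen)
  for (t in seq_len(maxlen)) {
    act <- which(len >= t)
    idx_by_step[[t]] <- starts[act] + t - 1L
    track_by_step[[t]] <- act
  }
  list(r2 = r2, n_jumps = length(r2), n_tracks = length(len), len = len,
       starts = starts, maxlen = maxlen,
       idx_by_step = idx_by_step, track_by_step = track_by_step)
}

# log emission matrix (n_jumps x K): Rayleigh in the magnitude with
# per-state mean square v_k
hmm_log_emission <- function(r2, v) {
  K <- length(v)
  logB <- matrix(NA_real_, length(r2), K)
  for (k in seq_len(K))
    logB[, k] <- log(2) + 0.5 * log(pmax(r2, 1e-300)) - log(v[k]) - r2 / v[k]
  logB
}

# One E-step over all tracks: scaled forward-backward, vectorized by step.
# Returns loglik, per-jump posteriors gamma, transition count matrix
# xi_sum, and the summed first-jump posteriors (for the p0 update).
hmm_estep <- function(prep, p0, A, v) {
  K <- length(v)
  logB <- hmm_log_emission(prep$r2, v)
  m <- logB[, 1L]
  if (K > 1L) for (k in 2:K) m <- pmax(m, logB[, k])
  Bn <- exp(logB - m)                       # relative emissions, max 1 per row
  n <- prep$n_jumps
  alphas <- matrix(0, n, K)
  scales <- numeric(n)
  alpha_prev <- matrix(0, prep$n_tracks, K) # scaled alpha per track, last step seen
  for (t in seq_len(prep$maxlen)) {
    idx <- prep$idx_by_step[[t]]
    trk <- prep$track_by_step[[t]]
    a <- if (t == 1L)
      matrix(p0, length(idx), K, byrow = TRUE) * Bn[idx, , drop = FALSE]
    else
      (alpha_prev[trk, , drop = FALSE] %*% A) * Bn[idx, , drop = FALSE]
    c_t <- rowSums(a)
    a <- a / c_t
    alphas[idx, ] <- a
    scales[idx] <- c_t
    alpha_prev[trk, ] <- a
  }
  loglik <- sum(log(scales)) + sum(m)
  # backward + accumulation
  gamma <- matrix(0, n, K)
  xi_sum <- matrix(0, K, K)
  beta_next <- matrix(1, prep$n_tracks, K)  # scaled beta, step t+1 per track
  for (t in rev(seq_len(prep$maxlen))) {
    idx <- prep$idx_by_step[[t]]
    trk <- prep$track_by_step[[t]]
    nt <- length(idx)
    # tracks whose last jump is at step t start with beta = 1
    is_last <- prep$len[trk] == t
    beta_t <- matrix(1, nt, K)
    if (any(!is_last)) {
      nidx <- idx[!is_last] + 1L            # their step-(t+1) jump rows
      ntrk <- trk[!is_last]
      M <- Bn[nidx, , drop = FALSE] * beta_next[ntrk, , drop = FALSE] /
        scales[nidx]
      beta_t[!is_last, ] <- M %*% t(A)
      # xi: sum over tracks of alpha_t(i) A_ij Bn_{t+1}(j) beta_{t+1}(j) / c_{t+1}
      xi_sum <- xi_sum +
        (t(alphas[idx[!is_last], , drop = FALSE]) %*% M) * A
    }
    g <- alphas[idx, , drop = FALSE] * beta_t
    gamma[idx, ] <- g / rowSums(g)
    beta_next[trk, ] <- beta_t
  }
  first <- prep$starts
  list(loglik = loglik, gamma = gamma, xi_sum = xi_sum,
       first_gamma = colSums(gamma[first, , drop = FALSE]))
}

# Full EM from one start; returns fitted parameters and the loglik trace
hmm_em <- function(prep, p0, A, v, dt, loc_error, tol, max_iter) {
  trace <- numeric(0)
  loglik <- -Inf
  converged <- FALSE
  floor_v <- 4 * loc_error^2 + 4e-9 * dt    # keep D strictly positive
  for (it in seq_len(max_iter)) {
    e <- hmm_estep(prep, p0, A, v)
    trace <- c(trace, e$loglik)
    if (it > 1L && (e$loglik - loglik) <= tol * abs(loglik)) {
      loglik <- e$loglik
      converged <- TRUE
      break
    }
    loglik <- e$loglik
    p0 <- e$first_gamma / sum(e$first_gamma)
    if (length(v) > 1L) {
      rs <- rowSums(e$xi_sum)
      A <- e$xi_sum / ifelse(rs > 0, rs, 1)
      A[rs == 0, ] <- 1 / length(v)         # state never left: uninformative row
    }
    wsum <- colSums(e$gamma)
    v <- pmax(colSums(e$gamma * prep$r2) / wsum, floor_v)
  }
  D <- (v - 4 * loc_error^2) / (4 * dt)
  list(loglik = loglik, p0 = p0, A = A, D = pmax(D, 0), v = v,
       trace = trace, converged = converged, n_iter = length(trace))
}

#' Fit a multi-state diffusion hidden Markov model
#'
#' Fits diffusion HMMs with 1 to `k_max` states to pooled single-molecule
#' trajectories by maximum-likelihood expectation-maximization
#' (Baum-Welch) over per-track forward-backward passes, then selects the
#' number of states by the Bayesian information criterion. Emissions are
#' zero-mean 2D Gaussian displacements with per-coordinate variance
#' `2 * D_k * dt`; the per-time-step transition matrix, its stationary
#' occupancies, and per-state mean dwell times (`dt / (1 - A_kk)`) are
#' returned. States are labeled in ascending order of diffusion
#' coefficient, so state 1 is the bound/immobile state.
#'
#' The state count is capped at 3 by default to avoid over-fitting short,
#' photobleaching-limited trajectories. Each EM run is restarted
#' `n_restarts` times from different diffusion-coefficient initializations
#' (the first log-spaced across the empirical jump scale, the rest random
#' log-uniform) and the best by log-likelihood is kept.
#'
#' @param tracks a [track_set()], a conforming data.frame, or a
#'   [compute_jumps()] result.
#' @param k_max maximum number of states (1-3, default 3).
#' @param n_restarts EM restarts per state count (default 10).
#' @param tol relative log-likelihood convergence tolerance (default 1e-8).
#' @param max_iter maximum EM iterations per run (default 1000).
#' @param seed integer seed for the restart initializations (mandatory).
#' @param loc_error optional per-coordinate static localization error SD
#'   (um), added to the emission variance as `4 * loc_error^2` (default 0,
#'   matching analyses that ignore localization error).
#' @return Object of class `diffusion_hmm`; see [print.diffusion_hmm()].
#'   Key fields: `K`, `D` (um^2/s, ascending), `A`, `pi` (stationary
#'   occupancies), `dwell` (s), `loglik`, `bic`, `selection` (per-K fit
#'   table), `converged`, `loglik_trace`, `n_jumps`, `n_tracks`, `dt`.
#' @examples
#' sim <- simulate_tracks(D = 0.1, n_tracks = 200, seed = 1)
#' fit <- fit_diffusion_hmm(sim$tracks, k_max = 1, n_restarts = 1, seed = 1)
#' coef(fit)
#' @export
fit_diffusion_hmm <- function(tracks, k_max = 3, n_restarts = 10, tol = 1e-8,
                              max_iter = 1000, seed, loc_error = 0) {
  if (missing(seed)) stop("seed is mandatory")
  if (!k_max %in% 1:3) stop("k_max must be 1, 2, or 3")
  jumps <- if (inherits(tracks, "jump_set")) tracks else compute_jumps(tracks)
  if (jumps$n_jumps < 100) stop("insufficient data: need >= 100 pooled jumps")
  dt <- jumps$dt
  prep <- hmm_prepare(jumps)
  set.seed(seed)
  D_emp_lo <- max(quantile(prep$r2, 0.1) / (4 * dt), 1e-6)
  D_emp_hi <- max(quantile(prep$r2, 0.9) / (4 * dt), 2 * D_emp_lo)
  init_range <- c(0.5 * D_emp_lo, 2 * D_emp_hi)

  fits <- vector("list", k_max)
  for (K in seq_len(k_max)) {
    best <- NULL
    for (rs in seq_len(n_restarts)) {
      D0 <- if (rs == 1L)
        exp(seq(log(init_range[1]), log(init_range[2]), length.out = K))
      else
        sort(exp(runif(K, log(init_range[1]), log(init_range[2]))))
      v0 <- 4 * D0 * dt + 4 * loc_error^2
      A0 <- matrix((1 - 0.8) / max(K - 1, 1), K, K)
      diag(A0) <- if (K == 1) 1 else 0.8
      fit <- hmm_em(prep, rep(1 / K, K), A0, v0, dt, loc_error, tol, max_iter)
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
      if (K == 1L) break                    # closed-form: one run suffices
    }
    npar <- K + K * (K - 1) + (K - 1)
    best$bic <- -2 * best$loglik + npar * log(prep$n_jumps)
    best$K <- K
    fits[[K]] <- best
  }
  bics <- vapply(fits, `[[`, numeric(1), "bic")
  K_sel <- which.min(bics)
  best <- fits[[K_sel]]
  # relabel states by ascending D
  ord <- order(best$D)
  D <- best$D[ord]
  A <- best$A[ord, ord, drop = FALSE]
  p0 <- best$p0[ord]
  pi <- tryCatch(stationary_distribution(A), error = function(e) {
    warning("transition matrix has no unique stationary vector; reporting initial-state weights")
    p0
  })
  structure(list(K = K_sel, D = D, A = A, pi = pi, p0 = p0,
                 dwell = as.numeric(dwell_times(A, dt)),
                 loglik = best$loglik, bic = best$bic,
                 selection = data.frame(
                   K = seq_len(k_max),
                   loglik = vapply(fits, `[[`, numeric(1), "loglik"),
                   bic = bics,
                   converged = vapply(fits, `[[`, logical(1), "converged"),
                   n_iter = vapply(fits, `[[`, numeric(1), "n_iter")),
                 converged = best$converged, loglik_trace = best$trace,
                 n_jumps = prep$n_jumps, n_tracks = prep$n_tracks,
                 dt = dt, loc_error = loc_error,
                 n_restarts = n_restarts, seed = seed,
                 call = match.call()),
            class = "diffusion_hmm")
}
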