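#' Construct two-state Gaussian HMM parameters
#'
#' State 1 is "untranscribed", state 2 "transcribed"; states are ordered
#' by emission mean (transcribed mean >= untranscribed mean). Emissions
#' are Gaussian on the transformed bin counts `log(count + 1)`.
#'
#' @param pi Initial state probabilities (length 2, sums to 1).
#' @param A 2x2 transition matrix (rows sum to 1).
#' @param mu Emission means (length 2, non-decreasing).
#' @param sigma2 Emission variances (length 2, positive).
#' @return An `hmm_params` object.
#' @export
hmm_params <- function(pi, A, mu, sigma2) {
  stopifnot(length(pi) == 2L, length(mu) == 2L, length(sigma2) == 2L,
            all(dim(A) == c(2L, 2L)))
  if (abs(sum(pi) - 1) > 1e-8 || any(abs(rowSums(A) - 1) > 1e-8))
    abort("pi and the rows of A must each sum to 1")
  if (any(sigma2 <= 0)) abort("emission variances must be positive")
  if (mu[2] < mu[1])
    abort("states must be ordered by emission mean (transcribed last)")
  structure(list(pi = as.numeric(pi), A = unname(as.matrix(A)),
                 mu = as.numeric(mu), sigma2 = as.numeric(sigma2)),
            class = "hmm_params")
}

#' @export
print.hmm_params <- function(x, ...) {
  cat("two-state Gaussian HMM:\n",
      sprintf("  pi = (%.4f, %.4f)\n", x$pi[1], x$pi[2]),
      sprintf("  A  = [%.4f %.4f; %.4f %.4f]\n",
              x$A[1, 1], x$A[1, 2], x$A[2, 1], x$A[2, 2]),
      sprintf("  emissions: N(%.3f, %.3f^2) / N(%.3f, %.3f^2)\n",
              x$mu[1], sqrt(x$sigma2[1]), x$mu[2], sqrt(x$sigma2[2])),
      sep = "")
  if (!is.null(attr(x, "iterations")))
    cat(sprintf("  fitted: %d EM iterations, loglik %.4f, %s\n",
                attr(x, "iterations"), attr(x, "loglik"),
                if (isTRUE(attr(x, "converged"))) "converged"
                else "NOT converged"))
  invisible(x)
}

# Emission log densities for each state, T x 2.
emission_logdens <- function(x, params) {
  cbind(dnorm(x, params$mu[1], sqrt(params$sigma2[1]), log = TRUE),
        dnorm(x, params$mu[2], sqrt(params$sigma2[2]), log = TRUE))
}

#' Fit a two-state Gaussian HMM by Baum-Welch EM
#'
#' The workhorse behind [fit_hmm()], operating directly on numeric
#' observation sequences (one element of `x_list` per sequence; the
#' sequences share one parameter set). Initialisation is deterministic
#' and scale-free: the untranscribed emission mean starts at the 25th
#' percentile of the pooled observations and the transcribed mean at
#' the 90th (falling back to the maximum when the two quantiles
#' coincide, as happens when most bins are zero), both variances at the
#' pooled variance, and the transition matrix at
#' `[[0.95, 0.05], [0.10, 0.90]]`. Emission variances are floored at
#' `1e-4` to keep a state locked onto constant (e.g. all-zero)
#' background numerically well behaved.
#'
#' @param x_list List of numeric vectors (observation sequences).
#' @param tol Relative log-likelihood change declaring convergence.
#' @param max_iter Maximum EM iterations; non-convergence warns and
#'   returns the current parameters.
#' @return An `hmm_params` object with attributes `loglik` (final),
#'   `loglik_trace` (per iteration, non-decreasing), `iterations` and
#'   `converged`.
#' @export
hmm_fit <- function(x_list, tol = 1e-6, max_iter = 1000L) {
  if (!is.list(x_list)) x_list <- list(x_list)
  x_list <- x_list[vapply(x_list, length, 1L) > 0L]
  all_x <- unlist(x_list, use.names = FALSE)
  if (length(all_x) < 2L || length(unique(all_x)) < 2L)
    abort("observations are constant; a two-state HMM is degenerate ",
          "here - use the presence rule (mode = \"presence\") instead")

  var_floor <- 1e-4
  mu <- unname(quantile(all_x, c(0.25, 0.90)))
  if (mu[2] - mu[1] < 1e-8) mu[2] <- max(all_x)
  s2 <- rep(max(var(all_x), var_floor), 2L)
  A <- matrix(c(0.95, 0.10, 0.05, 0.90), 2L)
  pi <- c(0.5, 0.5)

  ll_trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    params <- list(pi = pi, A = A, mu = mu, sigma2 = s2)
    ll <- 0
    g_sum <- c(0, 0); gx <- c(0, 0); gx2 <- c(0, 0)
    xi <- matrix(0, 2L, 2L); g1 <- c(0, 0)
    g_sum_nolast <- c(0, 0)
    for (x in x_list) {
      fb <- hmm_fb_cpp(log(pi), log(A), emission_logdens(x, params))
      ll <- ll + fb$loglik
      g <- fb$gamma
      g_sum <- g_sum + colSums(g)
      g_sum_nolast <- g_sum_nolast +
        (if (nrow(g) > 1L) colSums(g[-nrow(g), , drop = FALSE]) else c(0, 0))
      gx <- gx + colSums(g * x)
      gx2 <- gx2 + colSums(g * x^2)
      xi <- xi + fb$xi_sum
      g1 <- g1 + g[1L, ]
    }
    ll_trace <- c(ll_trace, ll)

    if (is.finite(ll_prev) &&
        (ll - ll_prev) <= tol * abs(ll_prev)) {
      converged <- TRUE
      break
    }
    ll_prev <- ll

    pi <- g1 / sum(g1)
    if (all(g_sum_nolast > 0)) A <- xi / g_sum_nolast
    A <- pmin(pmax(A, 1e-12), 1)
    A <- A / rowSums(A)
    mu_new <- gx / g_sum
    s2_new <- gx2 / g_sum - mu_new^2
    mu <- mu_new
    s2 <- pmax(s2_new, var_floor)
  }
  if (!converged)
    warning("Baum-Welch did not converge in ", max_iter,
            " iterations; returning current parameters", call. = FALSE)

  # order states by emission mean: untranscribed first
  if (mu[1] > mu[2]) {
    ord <- c(2L, 1L)
    pi <- pi[ord]; mu <- mu[ord]; s2 <- s2[ord]; A <- A[ord, ord]
  }
  out <- hmm_params(pi = pi, A = A, mu = mu, sigma2 = s2)
  attr(out, "loglik") <- ll_trace[length(ll_trace)]
  attr(out, "loglik_trace") <- ll_trace
  attr(out, "iterations") <- length(ll_trace)
  attr(out, "converged") <- converged
  out
}

#' Fit the segmentation HMM to binned coverage
#'
#' Pools the `log(count + 1)`-transformed bins of all supplied tracks
#' (each track one observation sequence; parameters shared across
#' contigs and strands of a sample) and runs Baum-Welch EM via
#' [hmm_fit()].
#'
#' @param tracks A `binned_coverage_set` from [bin_reads()], or a list
#'   of `binned_coverage` tracks.
#' @param tol,max_iter EM convergence controls; see [hmm_fit()].
#' @return An `hmm_params` object (see [hmm_fit()] for attributes).
#' @export
fit_hmm <- function(tracks, tol = 1e-6, max_iter = 1000L) {
  if (inherits(tracks, "binned_coverage")) tracks <- list(tracks)
  x_list <- lapply(tracks, function(t) log1p(t$counts))
  hmm_fit(x_list, tol = tol, max_iter = max_iter)
}

#' Viterbi decoding of a numeric sequence
#'
#' Maximum-probability state path under an [hmm_params()] model; ties
#' are broken toward the untranscribed state (conservative: fewer false
#' transcribed calls).
#'
#' @param x Numeric observation sequence.
#' @param params An `hmm_params` object.
#' @return Integer vector of 0 (untranscribed) / 1 (transcribed).
#' @export
hmm_viterbi <- function(x, params) {
  if (!length(x)) return(integer(0))
  hmm_viterbi_cpp(log(params$pi), log(params$A),
                  emission_logdens(x, params))
}

#' Decode transcriptional states for a coverage track
#'
#' Applies [hmm_viterbi()] to the `log(count + 1)`-transformed bins of
#' one track.
#'
#' @param track A `binned_coverage` track.
#' @param params Fitted `hmm_params`.
#' @return Integer 0/1 vector, one element per bin.
#' @export
decode_states <- function(track, params) {
  hmm_viterbi(log1p(track$counts), params)
}
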