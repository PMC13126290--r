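#' Gaussian mixture fit of log10 marker intensity
#'
#' Expectation-maximization on log10-transformed intensities with k
#' components (2 for pH3 negative/positive, 3 for PCNA
#' negative/diffuse/punctate). Components are reported with strictly
#' increasing means; the mixture weights are the "areas" of the fitted
#' peaks as fractions of the population. Initialization is by quantiles of
#' the data with seeded jitter over restarts; each restart runs a capped
#' number of iterations and the best is polished to convergence (the EM
#' log-likelihood is non-decreasing within every run). Assignment
#' boundaries are the posterior-equality points between adjacent
#' components.
#'
#' @param values Positive intensities (a.u.).
#' @param k Number of components, 2 or 3.
#' @param seed RNG seed for restart jitter.
#' @param restarts Number of EM restarts (default 20).
#' @param tol Convergence tolerance on the log-likelihood (default 1e-8,
#'   relative).
#' @param max_iter Maximum iterations for the polishing run (default 500).
#' @return A `mixture_fit` list: `k`, `means`, `sigmas`, `weights` (log10
#'   scale, ordered by mean), `boundaries` (k-1 log10 cutpoints),
#'   `log_likelihood`, `ll_trace` (per-iteration log-likelihood of the
#'   winning run), `degenerate` flag (a component collapsed below weight
#'   0.02 or two means merged within half a sigma).
#' @export
fit_log_mixture <- function(values, k, seed = 1L, restarts = 20,
                            tol = 1e-8, max_iter = 500) {
  if (!k %in% c(2L, 3L)) stop("k must be 2 or 3", call. = FALSE)
  values <- values[is.finite(values)]
  if (any(values <= 0)) stop("values must be positive", call. = FALSE)
  x <- log10(values)
  n <- length(x)
  if (n < 10 * k) stop("too few values for a ", k, "-component fit", call. = FALSE)
  qs <- stats::quantile(x, probs = seq_len(k) / (k + 1), names = FALSE)
  s0 <- stats::sd(x) / k
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      mu <- qs + if (r == 1) 0 else stats::rnorm(k, sd = stats::sd(x) / 4)
      run <- em_gauss(x, sort(mu), rep(s0, k), rep(1 / k, k),
                      tol = tol, max_iter = 60L)
      if (is.null(best) || run$ll > best$ll) best <- run
    }
  })
  fit <- em_gauss(x, best$mu, best$sigma, best$w, tol = tol,
                  max_iter = max_iter)
  if (!fit$converged)
    stop("EM did not converge after ", max_iter, " iterations; best ",
         "log-likelihood ", format(fit$ll), call. = FALSE)
  ord <- order(fit$mu)
  mu <- fit$mu[ord]; sigma <- fit$sigma[ord]; w <- fit$w[ord]
  # degenerate when a component collapsed (spurious weight) or the fitted
  # density has fewer modes than components (the split is not supported
  # by any separation in the data)
  grid <- seq(min(x), max(x), length.out = 512)
  dens <- rowSums(vapply(seq_len(k), function(j)
    w[j] * stats::dnorm(grid, mu[j], sigma[j]), numeric(512)))
  n_modes <- sum(diff(sign(diff(dens))) == -2)
  degenerate <- any(w < 0.02) || n_modes < k
  bounds <- vapply(seq_len(k - 1), function(i) {
    f <- function(t) w[i] * stats::dnorm(t, mu[i], sigma[i]) -
      w[i + 1] * stats::dnorm(t, mu[i + 1], sigma[i + 1])
    # posterior-equality point between the adjacent means (falls back to
    # the midpoint when a component has collapsed)
    tryCatch(stats::uniroot(f, c(mu[i], mu[i + 1]))$root,
             error = function(e) (mu[i] + mu[i + 1]) / 2)
  }, numeric(1))
  structure(list(k = k, means = mu, sigmas = sigma, weights = w,
                 boundaries = bounds, log_likelihood = fit$ll,
                 ll_trace = fit$trace, degenerate = degenerate,
                 n = n),
            class = "mixture_fit")
}

# Plain univariate EM. Returns final parameters, log-likelihood and the
# per-iteration log-likelihood trace.
em_gauss <- function(x, mu, sigma, w, tol, max_iter) {
  n <- length(x)
  k <- length(mu)
  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(j)
      w[j] * stats::dnorm(x, mu[j], pmax(sigma[j], 1e-6)), numeric(n))
    tot <- rowSums(dens)
    tot[tot < 1e-300] <- 1e-300
    ll <- sum(log(tot))
    trace <- c(trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    resp <- dens / tot
    nk <- colSums(resp)
    nk[nk < 1e-10] <- 1e-10
    w <- nk / n
    mu <- colSums(resp * x) / nk
    sigma <- sqrt(vapply(seq_len(k), function(j)
      sum(resp[, j] * (x - mu[j])^2) / nk[j], numeric(1)))
    sigma <- pmax(sigma, 1e-4)
  }
  list(mu = mu, sigma = sigma, w = w,
       ll = if (length(trace)) trace[length(trace)] else -Inf,
       trace = trace, converged = converged)
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("<mixture_fit> k=%d n=%d logL=%.1f%s\n", x$k, x$n,
              x$log_likelihood, if (x$degenerate) " [degenerate]" else ""))
  print(data.frame(mean_log10 = x$means, sd_log10 = x$sigmas,
                   weight = x$weights))
  invisible(x)
}
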