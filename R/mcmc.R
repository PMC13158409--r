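#' Posterior sampling of a co-refinement problem
#'
#' Affine-invariant ensemble MCMC (stretch moves) with log-likelihood
#' `-chi2/2` and uniform priors given by the parameter bounds. Mirrors the
#' study's sampling protocol: a burn-in phase, a production phase, and
#' thinning that retains every `thin`-th post-burn-in ensemble sweep.
#'
#' @param problem A [fit_problem()].
#' @param start Named or plain numeric start vector within bounds (typically
#'   the [fit_global()] optimum).
#' @param burn_in Burn-in ensemble sweeps (default 200).
#' @param steps Production ensemble sweeps (default 200).
#' @param thin Thinning factor (default 10; every 10th sweep retained).
#' @param seed Integer seed.
#' @param n_walkers Ensemble size; default `max(2 * n_free + 2, 32)`.
#' @param a Stretch-move scale parameter.
#' @return Object of class `posterior_summary`: per-parameter `median`,
#'   `ci68` (16th/84th percentiles), the retained `samples` matrix, chain
#'   metadata, acceptance fraction and the reduced chi-squared at the
#'   posterior median.
#' @export
sample_posterior <- function(problem, start, burn_in = 200, steps = 200,
                             thin = 10, seed = 1, n_walkers = NULL, a = 2) {
  stopifnot(inherits(problem, "fit_problem"))
  d <- length(problem$lower)
  start <- as.numeric(start)
  if (length(start) != d) stop("start has wrong length")
  if (any(start < problem$lower - 1e-12) || any(start > problem$upper + 1e-12))
    stop("start outside bounds")
  if (is.null(n_walkers)) n_walkers <- max(2 * d + 2, 32)
  free <- problem$upper > problem$lower
  log_post <- function(x) {
    if (any(x < problem$lower) || any(x > problem$upper)) return(-Inf)
    -chi_squared_global(problem, x) / 2
  }

  res <- withr::with_seed(seed, {
    scale <- pmax(problem$upper - problem$lower, 0)
    walkers <- matrix(rep(start, each = n_walkers), nrow = n_walkers)
    jit <- matrix(stats::rnorm(n_walkers * d, sd = 1e-3), nrow = n_walkers)
    walkers <- walkers + jit * matrix(rep(scale, each = n_walkers), nrow = n_walkers)
    walkers <- pmin(pmax(walkers,
                         matrix(rep(problem$lower, each = n_walkers), nrow = n_walkers)),
                    matrix(rep(problem$upper, each = n_walkers), nrow = n_walkers))
    lp <- apply(walkers, 1, log_post)
    n_sweeps <- burn_in + steps
    kept <- list()
    accept <- 0
    for (t in seq_len(n_sweeps)) {
      for (k in seq_len(n_walkers)) {
        j <- sample(seq_len(n_walkers)[-k], 1)
        z <- ((a - 1) * stats::runif(1) + 1)^2 / a
        prop <- walkers[j, ] + z * (walkers[k, ] - walkers[j, ])
        lp_prop <- log_post(prop)
        n_eff <- max(sum(free), 1)
        log_ratio <- (n_eff - 1) * log(z) + lp_prop - lp[k]
        if (is.finite(lp_prop) && log(stats::runif(1)) < log_ratio) {
          walkers[k, ] <- prop
          lp[k] <- lp_prop
          accept <- accept + 1
        }
      }
      if (t > burn_in && (t - burn_in) %% thin == 0)
        kept[[length(kept) + 1]] <- walkers
    }
    list(samples = do.call(rbind, kept),
         acceptance = accept / (n_sweeps * n_walkers))
  })

  if (res$acceptance == 0 && any(free))
    stop("all walkers stuck: zero acceptance over the whole run")

  samples <- res$samples
  colnames(samples) <- problem$free_names
  med <- apply(samples, 2, stats::median)
  ci <- apply(samples, 2, stats::quantile, probs = c(0.16, 0.84))
  red <- chi_squared_global(problem, med) /
    max(problem$n_points - sum(free), 1)
  structure(list(
    median = med,
    ci68 = ci,
    samples = samples,
    red_chi2 = red,
    acceptance = res$acceptance,
    settings = list(n_walkers = n_walkers, burn_in = burn_in, steps = steps,
                    thin = thin, seed = seed)
  ), class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat("Posterior summary (", x$settings$n_walkers, " walkers, ",
      x$settings$burn_in, "+", x$settings$steps, " sweeps, thin ",
      x$settings$thin, ")\n", sep = "")
  tab <- rbind(median = x$median, x$ci68)
  print(signif(t(tab), 5))
  cat(sprintf("  reduced chi2 at median: %.4g, acceptance %.2f\n",
              x$red_chi2, x$acceptance))
  invisible(x)
}

#' Export pairwise sample grids for corner plots
#'
#' @param posterior A [sample_posterior()] result.
#' @return data.frame of retained samples (one column per parameter), suitable
#'   for writing to CSV and pair plotting.
#' @export
corner_data <- function(posterior) {
  as.data.frame(posterior$samples)
}
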