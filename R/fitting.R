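# Free parameters are addressed by path strings into the membrane_model list:
#   "t_tail", "head_in.solvent", "adsorbed1.thickness", ...
# A "+"-joined path sets several fields to the same value (e.g. a shared
# head hydration "head_in.solvent+head_out.solvent").

.set_param <- function(model, path, value) {
  for (p in strsplit(path, "+", fixed = TRUE)[[1]]) {
    parts <- strsplit(p, ".", fixed = TRUE)[[1]]
    if (grepl("^adsorbed[0-9]+$", parts[1])) {
      i <- as.integer(sub("adsorbed", "", parts[1]))
      if (i > length(model$adsorbed)) stop("no adsorbed layer ", i)
      model$adsorbed[[i]][[parts[2]]] <- value
    } else if (length(parts) == 1) {
      if (!parts %in% names(model)) stop("unknown parameter: ", p)
      model[[parts]] <- value
    } else {
      if (!parts[1] %in% names(model)) stop("unknown parameter: ", p)
      model[[parts[1]]][[parts[2]]] <- value
    }
  }
  model
}

.apply_params <- function(model, names, values) {
  for (i in seq_along(names)) model <- .set_param(model, names[i], values[i])
  model
}

#' Co-refinement problem: one structure, several contrasts
#'
#' Binds a membrane model with free-parameter declarations (uniform bounds)
#' to one or more reflectivity datasets measured in different solvent
#' contrasts. All structural parameters are shared across contrasts; only
#' the solvent SLD differs.
#'
#' @param model A [membrane_model()] providing the fixed parameter values.
#' @param datasets List of `list(curve = <reflectivity_curve>, contrast =
#'   <solvent_contrast>)`.
#' @param free Named list of length-2 numeric bounds `c(lower, upper)`; names
#'   are model parameter paths (see Details). Equal bounds pin a parameter.
#' @return Object of class `fit_problem`.
#' @details Paths address fields of the model: top-level scalars
#'   (`"t_tail"`), inventory fields (`"tail_in.cpz"`), adsorbed-layer fields
#'   (`"adsorbed1.solvent"`). Joining paths with `+` ties them to a single
#'   free parameter.
#' @export
fit_problem <- function(model, datasets, free) {
  validate_membrane_model(model)
  if (length(datasets) < 1) stop("at least one dataset required")
  if (length(free) < 1) stop("at least one free parameter required")
  bounds <- do.call(rbind, free)
  if (ncol(bounds) != 2 || any(!is.finite(bounds)))
    stop("every free parameter needs finite c(lower, upper) bounds")
  if (any(bounds[, 1] > bounds[, 2])) stop("lower bound exceeds upper bound")
  datasets <- lapply(datasets, function(d) {
    cv <- d$curve
    if (any(cv$dr == 0 & cv$r != 0) && any(cv$dr == 0))
      stop("dataset has dR = 0 points: floor them or exclude them before fitting")
    res <- attr(cv, "resolution")
    if (is.null(res)) res <- 0.07
    d$smear <- .smear_design(cv$q, res)
    d$resolution <- res
    d
  })
  n_points <- sum(vapply(datasets, function(d) nrow(d$curve), numeric(1)))
  structure(list(model = model, datasets = datasets,
                 free_names = names(free),
                 lower = bounds[, 1], upper = bounds[, 2],
                 n_points = n_points),
            class = "fit_problem")
}

#' Global chi-squared of a co-refinement problem
#'
#' Sum over all contrasts and q-points of `((R_model - R_data)/dR)^2`, with
#' the model curve smeared at each dataset's resolution. Uncertainties are
#' floored at `1e-12 * max(R_data)` per dataset.
#'
#' @param problem A [fit_problem()].
#' @param x Numeric vector of free-parameter values (in `free` order).
#' @return Chi-squared value.
#' @export
chi_squared_global <- function(problem, x) {
  if (any(x < problem$lower - 1e-12) || any(x > problem$upper + 1e-12))
    return(Inf)
  m <- .apply_params(problem$model, problem$free_names, x)
  total <- 0
  for (d in problem$datasets) {
    stack <- compile_stack(m, d$contrast, validate = FALSE)
    r_fine <- slab_reflectivity(stack, d$smear$q_fine)
    r_mod <- as.vector(d$smear$W %*% r_fine)
    dr <- pmax(d$curve$dr, 1e-12 * max(d$curve$r))
    total <- total + sum(((r_mod - d$curve$r) / dr)^2)
  }
  total
}

# Differential evolution (rand/1/bin) within box bounds.
.de_optim <- function(fn, lower, upper, np = NULL, maxiter = 150,
                      F = 0.8, CR = 0.9, tol = 1e-10, ptol = 1e-3,
                      seed = NULL) {
  d <- length(lower)
  fixed <- upper - lower <= 0
  if (is.null(np)) np <- max(10 * sum(!fixed), 20)
  run <- function() {
    pop <- matrix(stats::runif(np * d, lower, upper), nrow = np, byrow = TRUE)
    pop[, fixed] <- matrix(rep(lower[fixed], each = np), nrow = np)
    cost <- apply(pop, 1, fn)
    for (it in seq_len(maxiter)) {
      idx <- seq_len(np)
      for (i in idx) {
        r <- sample(idx[-i], 3)
        v <- pop[r[1], ] + F * (pop[r[2], ] - pop[r[3], ])
        jr <- sample.int(d, 1)
        cross <- stats::runif(d) < CR
        cross[jr] <- TRUE
        u <- ifelse(cross, v, pop[i, ])
        # reflect into bounds
        u <- pmin(pmax(u, 2 * lower - u), upper)
        u <- pmin(pmax(u, lower), upper)
        u[fixed] <- lower[fixed]
        cu <- fn(u)
        if (cu <= cost[i]) {
          pop[i, ] <- u
          cost[i] <- cu
        }
      }
      # stop when the population has collapsed in cost or in parameter space
      if (max(cost) - min(cost) < tol * (abs(min(cost)) + tol)) break
      if (!all(fixed)) {
        spread <- apply(pop[, !fixed, drop = FALSE], 2, function(z)
          diff(range(z)))
        if (all(spread < ptol * (upper - lower)[!fixed])) break
      }
    }
    b <- which.min(cost)
    list(par = pop[b, ], value = cost[b], iterations = it)
  }
  if (!is.null(seed)) withr::with_seed(seed, run()) else run()
}

#' Global fit by differential evolution
#'
#' Stochastic global minimization of [chi_squared_global()] within the
#' uniform parameter bounds, following the study's strategy of a
#' differential-evolution least-squares stage before posterior sampling.
#'
#' @param problem A [fit_problem()].
#' @param seed Integer seed; fixed seed gives a reproducible fit.
#' @param maxiter,np DE generations and population size (default population:
#'   10 per free dimension, at least 20).
#' @param tol Relative population-spread stopping tolerance.
#' @return Object of class `slb_fit`: best-fit parameter vector `par` (named),
#'   `chi2`, `red_chi2`, `n_points`, `n_free`, the updated `model`, and the
#'   `problem`.
#' @export
fit_global <- function(problem, seed = 1, maxiter = 150, np = NULL,
                       tol = 1e-10, ptol = 1e-3) {
  stopifnot(inherits(problem, "fit_problem"))
  fn <- function(x) {
    v <- chi_squared_global(problem, x)
    if (!is.finite(v) && !identical(v, Inf))
      stop("non-finite objective at x = ", paste(signif(x, 4), collapse = ", "))
    v
  }
  opt <- .de_optim(fn, problem$lower, problem$upper, np = np,
                   maxiter = maxiter, tol = tol, ptol = ptol, seed = seed)
  n_free <- sum(problem$upper > problem$lower)
  red <- opt$value / max(problem$n_points - n_free, 1)
  par <- stats::setNames(opt$par, problem$free_names)
  structure(list(par = par, chi2 = opt$value, red_chi2 = red,
                 n_points = problem$n_points, n_free = n_free,
                 iterations = opt$iterations, seed = seed,
                 model = .apply_params(problem$model, problem$free_names, opt$par),
                 problem = problem),
            class = "slb_fit")
}

#' @export
print.slb_fit <- function(x, ...) {
  cat("Co-refinement fit (", x$problem$model$variant, ")\n", sep = "")
  cat(sprintf("  chi2 = %.4g, reduced chi2 = %.4g (%d points, %d free)\n",
              x$chi2, x$red_chi2, x$n_points, x$n_free))
  print(signif(x$par, 5))
  invisible(x)
}

#' Rank fitted model variants by reduced chi-squared
#'
#' Ascending reduced chi-squared; candidates within 1% relative of each other
#' are tied and ordered by fewer free parameters (parsimony).
#'
#' @param fits List of [fit_global()] results fitted on the same datasets.
#' @return data.frame with columns `variant`, `red_chi2`, `n_free`, `rank`,
#'   ordered best first.
#' @export
compare_models <- function(fits) {
  sig <- vapply(fits, function(f)
    sum(vapply(f$problem$datasets, function(d) sum(d$curve$r) + nrow(d$curve),
               numeric(1))), numeric(1))
  if (length(unique(signif(sig, 12))) != 1)
    stop("candidates were fitted on differing datasets")
  red <- vapply(fits, `[[`, numeric(1), "red_chi2")
  nf <- vapply(fits, `[[`, numeric(1), "n_free")
  variant <- vapply(fits, function(f) f$problem$model$variant, character(1))
  o <- order(red)
  red <- red[o]; nf <- nf[o]; variant <- variant[o]
  # group chains of ties (within 1% relative of the previous candidate)
  grp <- cumsum(c(1, diff(red) / pmax(red[-length(red)], .Machine$double.xmin) > 0.01))
  o2 <- order(grp, nf, red)
  out <- data.frame(variant = variant[o2], red_chi2 = red[o2],
                    n_free = nf[o2])
  out$rank <- seq_len(nrow(out))
  out
}
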