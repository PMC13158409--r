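# Small co-refinement fixtures: 2 contrasts / 40 q-points keep the global
# optimizations fast while remaining informative.
small_problem <- function(model = blank_model(), free,
                          truth_model = model, noiseless = TRUE,
                          counts_scale = 1e6, seed = 1, n_q = 40,
                          contrasts = standard_contrasts()[c("h2o", "d2o")]) {
  ds <- gen_reflectivity_dataset(truth_model, contrasts,
                                 counts_scale = counts_scale,
                                 q_grid = default_q_grid(n_q), seed = seed,
                                 noiseless = noiseless)
  fit_problem(model, ds$datasets, free = free)
}

test_that("chi-squared vanishes at the generating parameters and is additive", {
  m <- blank_model()
  cts <- standard_contrasts()
  ds <- gen_reflectivity_dataset(m, cts, q_grid = default_q_grid(50),
                                 noiseless = TRUE)
  free <- list(t_head = c(5, 12), t_tail = c(12, 22))
  prob <- fit_problem(m, ds$datasets, free = free)
  expect_lt(chi_squared_global(prob, c(8, 17.5)), 1e-6)
  # additivity over contrasts
  total <- chi_squared_global(prob, c(8.5, 16))
  singles <- vapply(ds$datasets, function(d) {
    chi_squared_global(fit_problem(m, list(d), free = free), c(8.5, 16))
  }, numeric(1))
  expect_equal(total, sum(singles), tolerance = 1e-12)
})

test_that("perturbing any free parameter away from truth increases chi-squared", {
  m <- cpz_1ad_model(cpz = 0.2)
  free <- list(t_tail = c(12, 20), "tail_in.cpz" = c(0, 0.5),
               "tail_out.cpz" = c(0, 0.5), "head_in.solvent" = c(0.2, 0.8))
  prob <- small_problem(m, free, contrasts = standard_contrasts())
  truth <- c(15, 0.2, 0.2, 0.5)
  chi0 <- chi_squared_global(prob, truth)
  for (j in seq_along(truth)) {
    for (dd in c(-0.05, 0.05)) {
      x <- truth
      x[j] <- x[j] * (1 + dd)
      expect_gt(chi_squared_global(prob, x), chi0)
    }
  }
})

test_that("zero-uncertainty points are rejected with advice", {
  m <- blank_model()
  cv <- reflectivity_curve(c(0.01, 0.02), c(1, 0.5), c(0, 0.01))
  expect_error(
    fit_problem(m, list(list(curve = cv, contrast = mix_solvent_contrast(1))),
                free = list(t_head = c(5, 12))),
    "floor")
})

test_that("degenerate bounds return the pinned point", {
  prob <- small_problem(blank_model(),
                        free = list(t_head = c(8, 8), t_tail = c(17.5, 17.5)))
  fit <- fit_global(prob, seed = 3, maxiter = 5)
  expect_equal(unname(fit$par), c(8, 17.5))
  expect_lt(fit$chi2, 1e-6)
})

test_that("global fit recovers a noiseless blank bilayer", {
  prob <- small_problem(
    blank_model(),
    free = list(t_head = c(5, 12), t_tail = c(12, 22),
                "head_in.solvent+head_out.solvent" = c(0.2, 0.8)))
  fit <- fit_global(prob, seed = 7, np = 24, ptol = 5e-4)
  truth <- c(8, 17.5, 0.5)
  expect_true(all(abs(fit$par - truth) / truth < 0.01))
  expect_lt(fit$red_chi2, 1e-4)
})

test_that("reduced chi-squared concentrates near 1 under correct noise", {
  m <- blank_model()
  red <- vapply(1:20, function(s) {
    ds <- gen_reflectivity_dataset(m, standard_contrasts(),
                                   counts_scale = 1e5,
                                   q_grid = default_q_grid(50), seed = s)
    prob <- fit_problem(m, ds$datasets, free = list(t_head = c(5, 12)))
    chi_squared_global(prob, 8) / prob$n_points
  }, numeric(1))
  expect_gt(mean(red), 0.8)
  expect_lt(mean(red), 1.2)
})

test_that("posterior sampling is deterministic, bounded, and honest about width", {
  prob <- small_problem(
    blank_model(),
    free = list(t_head = c(6, 10), t_tail = c(15, 20)),
    noiseless = FALSE, counts_scale = 1e5)
  start <- c(8, 17.5)
  p1 <- sample_posterior(prob, start, burn_in = 30, steps = 30, thin = 5,
                         seed = 5, n_walkers = 12)
  p2 <- sample_posterior(prob, start, burn_in = 30, steps = 30, thin = 5,
                         seed = 5, n_walkers = 12)
  expect_identical(p1$samples, p2$samples)
  expect_true(all(p1$samples[, 1] >= 6 & p1$samples[, 1] <= 10))
  expect_true(all(p1$samples[, 2] >= 15 & p1$samples[, 2] <= 20))
  # medians near the generating values on low-noise data
  expect_equal(unname(p1$median), start, tolerance = 0.02)
  expect_true(all(p1$ci68[1, ] <= p1$median & p1$median <= p1$ci68[2, ]))
  # a pinned prior collapses to zero posterior width
  prob0 <- small_problem(blank_model(),
                         free = list(t_head = c(8, 8), t_tail = c(15, 20)))
  p0 <- sample_posterior(prob0, c(8, 17.5), burn_in = 10, steps = 10,
                         thin = 2, seed = 1, n_walkers = 8)
  expect_equal(diff(range(p0$samples[, 1])), 0)
})

test_that("longer production runs do not shift posterior medians materially", {
  prob <- small_problem(
    blank_model(),
    free = list(t_head = c(6, 10)),
    noiseless = FALSE, counts_scale = 1e5, n_q = 30)
  pA <- sample_posterior(prob, 8, burn_in = 40, steps = 40, thin = 4,
                         seed = 2, n_walkers = 10)
  pB <- sample_posterior(prob, 8, burn_in = 40, steps = 80, thin = 4,
                         seed = 2, n_walkers = 10)
  width <- diff(pA$ci68[, 1])
  expect_lt(abs(pA$median - pB$median), 0.5 * width)
})

test_that("headgroup-drug extension on tails-only truth skews toward zero", {
  truth <- membrane_model("CPZ_TAILS",
                          tail_in = list(cpz = 0.2, solvent = 0.05),
                          tail_out = list(cpz = 0.2, solvent = 0.05))
  fitted <- membrane_model("CPZ_TAILS",
                           tail_in = list(cpz = 0.2, solvent = 0.05),
                           tail_out = list(cpz = 0.2, solvent = 0.05),
                           allow_headgroup_cpz = TRUE)
  prob <- small_problem(fitted,
                        free = list("head_in.cpz+head_out.cpz" = c(0, 0.3)),
                        truth_model = truth, noiseless = FALSE,
                        counts_scale = 1e5,
                        contrasts = standard_contrasts())
  p <- sample_posterior(prob, 0.01, burn_in = 40, steps = 60, thin = 5,
                        seed = 9, n_walkers = 10)
  # posterior mass piles up against the zero bound: median below prior middle
  expect_lt(median(p$samples), 0.15 / 2)
  expect_lt(p$ci68[1, 1], 0.05)
})

test_that("model ranking orders by reduced chi-squared with parsimony ties", {
  blank <- blank_model()
  ds <- gen_reflectivity_dataset(blank, standard_contrasts()[c("h2o", "d2o")],
                                 counts_scale = 1e5,
                                 q_grid = default_q_grid(40), seed = 3)
  prob_b <- fit_problem(blank, ds$datasets,
                        free = list(t_tail = c(15, 20),
                                    "head_in.solvent+head_out.solvent" = c(0.3, 0.7)))
  cpz <- membrane_model("CPZ_TAILS",
                        tail_in = list(cpz = 0, solvent = 0.05),
                        tail_out = list(cpz = 0, solvent = 0.05))
  prob_c <- fit_problem(cpz, ds$datasets,
                        free = list(t_tail = c(15, 20),
                                    "head_in.solvent+head_out.solvent" = c(0.3, 0.7),
                                    "tail_in.cpz+tail_out.cpz" = c(0, 0.1)))
  fit_b <- fit_global(prob_b, seed = 2, np = 20, maxiter = 60, ptol = 2e-3)
  fit_c <- fit_global(prob_c, seed = 2, np = 24, maxiter = 60, ptol = 2e-3)
  rank <- compare_models(list(fit_c, fit_b))
  # blank truth: both fit equally well, the simpler model wins the tie
  expect_equal(rank$variant[1], "BLANK")
  # single candidate is trivially first
  expect_equal(compare_models(list(fit_b))$rank, 1)
  # differing datasets are refused
  ds2 <- gen_reflectivity_dataset(blank, standard_contrasts()[c("h2o", "d2o")],
                                  counts_scale = 1e5,
                                  q_grid = default_q_grid(41), seed = 4)
  prob_other <- fit_problem(blank, ds2$datasets,
                            free = list(t_tail = c(15, 20)))
  fit_other <- fit_global(prob_other, seed = 1, np = 10, maxiter = 10)
  expect_error(compare_models(list(fit_b, fit_other)), "differing datasets")
})
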