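make_spectrum <- function(i440, i490) {
  wl <- seq(370, 600, by = 2)
  y <- i440 * exp(-(wl - 440)^2 / (2 * 18^2)) +
    i490 * exp(-(wl - 490)^2 / (2 * 18^2))
  emission_spectrum(wl, y)
}

test_that("generalized polarization identities hold", {
  wl <- seq(370, 600, by = 2)
  flat <- emission_spectrum(wl, rep(2, length(wl)))
  expect_equal(general_polarization(flat), 0, tolerance = 1e-12)
  # pure ordered band
  y <- numeric(length(wl)); y[wl == 440] <- 1
  expect_equal(general_polarization(emission_spectrum(wl, y)), 1)
  # direct arithmetic: I440 = 0.5, I490 = 1 -> -1/3
  y2 <- numeric(length(wl)); y2[wl == 440] <- 0.5; y2[wl == 490] <- 1
  expect_equal(general_polarization(emission_spectrum(wl, y2)), -1/3,
               tolerance = 1e-12)
  y0 <- numeric(length(wl))
  expect_error(general_polarization(emission_spectrum(wl, y0)), "undefined")
})

test_that("GP is bounded and invariant to uniform intensity rescaling", {
  withr::with_seed(4, {
    for (i in 1:20) {
      sp <- make_spectrum(runif(1, 0.1, 2), runif(1, 0.1, 2))
      gp <- general_polarization(sp)
      expect_true(gp >= -1 && gp <= 1)
      scaled <- emission_spectrum(sp$wavelength, 7.3 * sp$intensity)
      expect_equal(general_polarization(scaled), gp, tolerance = 1e-12)
    }
  })
})

test_that("dose series GP rises as the relaxed band is suppressed", {
  ratios <- c(0, 1/100, 1/50, 1/25, 1/10, 1/5)
  doses <- data.frame(ratio = ratios,
                      a490_over_a440 = seq(1.3, 0.5, length.out = 6))
  spectra <- gen_laurdan_spectra(doses, replicates = 3, noise_sd = 0, seed = 2)
  tab <- gp_dose_series(spectra)
  expect_equal(tab$ratio, ratios)
  expect_true(all(tab$n == 3))
  # noiseless replicates agree exactly, and match the generator closed form
  expect_true(all(tab$gp_sd < 1e-12))
  truth <- attr(spectra, "ground_truth")$doses
  expect_equal(tab$gp_mean, truth$gp[order(truth$ratio)], tolerance = 1e-9)
  expect_true(all(diff(tab$gp_mean) > 0))
  # noise makes replicate scatter
  noisy <- gen_laurdan_spectra(doses, replicates = 3, noise_sd = 0.01, seed = 2)
  expect_true(all(gp_dose_series(noisy)$gp_sd > 0))
  bad <- gen_laurdan_spectra(data.frame(ratio = 0.3, a490_over_a440 = 1),
                             replicates = 1, noise_sd = 0, seed = 1)
  expect_error(gp_dose_series(bad), "unknown ratio")
})

test_that("triplet line ratio reads peak-to-peak amplitudes", {
  sp <- gen_epr_spectrum(centers = c(330.5, 332, 333.5), widths = 0.25,
                         amplitudes = c(1, 1, 1), noise_sd = 0, seed = 1)
  expect_equal(epr_line_ratio(sp), 1.0, tolerance = 1e-3)
  sp2 <- gen_epr_spectrum(centers = c(330.5, 332, 333.5), widths = 0.25,
                          amplitudes = c(1, 1, 0.8), noise_sd = 0, seed = 1)
  expect_equal(epr_line_ratio(sp2), 1.25, tolerance = 1e-3)
  # inverting the spectrum leaves the ratio unchanged
  inv <- epr_spectrum(sp2$field, -sp2$amplitude, sp2$temperature)
  expect_equal(epr_line_ratio(inv), epr_line_ratio(sp2), tolerance = 1e-9)
  # a lone line is refused with the detected extrema listed
  single <- gen_epr_spectrum(centers = 332, widths = 0.25, noise_sd = 0)
  expect_error(epr_line_ratio(single), "fewer than 3")
})

test_that("line-ratio detection survives noise ripples on the line apex", {
  ratios <- vapply(1:10, function(s) {
    sp <- gen_epr_spectrum(centers = c(330.5, 332, 333.5), widths = 0.25,
                           amplitudes = c(1, 1, 0.75), noise_sd = 0.01,
                           seed = s)
    epr_line_ratio(sp)
  }, numeric(1))
  expect_true(all(abs(ratios - 4/3) < 0.08))
})

test_that("hyperfine coupling is half the outer-line center distance", {
  sp <- gen_epr_spectrum(centers = c(330, 333.5, 337), widths = 0.4,
                         amplitudes = c(0.6, 1, 0.6), noise_sd = 0,
                         shape = "cryo")
  res <- epr_hyperfine_2Az(sp)
  expect_equal(res$a_z, 3.5, tolerance = 1e-6)
  expect_equal(attr(sp, "ground_truth")$two_a_z, 7)
  # translation invariance of the field axis
  shifted <- epr_spectrum(sp$field + 12.5, sp$amplitude, "cryo")
  expect_equal(epr_hyperfine_2Az(shifted)$a_z, res$a_z, tolerance = 1e-9)
  # amplitude scaling invariance
  scaled <- epr_spectrum(sp$field, 0.2 * sp$amplitude, "cryo")
  expect_equal(epr_hyperfine_2Az(scaled)$a_z, res$a_z, tolerance = 1e-9)
  # unresolvable outer lines error out
  flat <- epr_spectrum(seq(320, 345, 0.02),
                       rep(c(0, 1e-12), length.out = 1251), "cryo")
  expect_error(epr_hyperfine_2Az(flat), "not resolvable|fewer")
})

test_that("hyperfine recovery at 5% noise stays within its uncertainty", {
  hits <- vapply(1:10, function(s) {
    sp <- gen_epr_spectrum(centers = c(330, 333.5, 337), widths = 0.4,
                           amplitudes = c(0.6, 1, 0.6), noise_sd = 0.03,
                           seed = s, shape = "cryo")
    res <- epr_hyperfine_2Az(sp)
    abs(res$a_z - 3.5) <= 3 * max(res$se, 1e-4)
  }, logical(1))
  expect_gte(sum(hits), 9)
})
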