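# Synthetic data generators. Every generator is seeded through a single
# withr::with_seed() call and serializes its generating ground truth as the
# "ground_truth" attribute (or list element) of the returned object.

#' Default q grid of the measurement
#'
#' Log-spaced grid over the measured momentum-transfer range
#' 0.008-0.3 A^-1.
#'
#' @param n Number of points.
#' @return Ascending q grid (A^-1).
#' @export
default_q_grid <- function(n = 100) {
  exp(seq(log(0.008), log(0.3), length.out = n))
}

#' Simulate a multi-contrast reflectivity dataset
#'
#' For each solvent contrast, computes the resolution-smeared model curve of
#' the membrane structure and adds counting noise: expected incident counts
#' decay as `counts_scale * q^-2`, detected counts are Poisson with mean
#' `incident * R` (drawn Gaussian with matching variance when the mean
#' exceeds 20), and `dR = R / sqrt(detected counts expectation)`.
#'
#' @param model A [membrane_model()].
#' @param contrasts List of [mix_solvent_contrast()] objects.
#' @param counts_scale Incident-count scale (> 0); larger means less noise.
#' @param q_grid Momentum-transfer grid.
#' @param resolution dq/q FWHM resolution.
#' @param seed Integer seed.
#' @param noiseless If TRUE return the smeared model curves without noise.
#' @return Object of class `contrast_set`: `datasets` (list of
#'   `list(curve, contrast)`) and `ground_truth` (model, settings, seed).
#' @export
gen_reflectivity_dataset <- function(model, contrasts = standard_contrasts(),
                                     counts_scale = 1e4,
                                     q_grid = default_q_grid(),
                                     resolution = 0.07, seed = 1,
                                     noiseless = FALSE) {
  if (counts_scale <= 0) stop("counts_scale must be positive")
  validate_membrane_model(model)
  datasets <- withr::with_seed(seed, {
    lapply(contrasts, function(ct) {
      stack <- compile_stack(model, ct)
      r_true <- model_reflectivity(stack, q_grid, resolution)
      incident <- counts_scale * q_grid^-2
      mu <- incident * r_true              # expected detected counts
      dr <- r_true / sqrt(pmax(mu, .Machine$double.eps))
      if (noiseless) {
        r_obs <- r_true
      } else {
        n_obs <- ifelse(mu > 20,
                        stats::rnorm(length(mu), mean = mu, sd = sqrt(mu)),
                        stats::rpois(length(mu), lambda = mu))
        r_obs <- pmax(n_obs, 0) / incident
      }
      list(curve = reflectivity_curve(q_grid, r_obs, dr,
                                      resolution = resolution),
           contrast = ct)
    })
  })
  structure(list(
    datasets = datasets,
    ground_truth = list(model = model, counts_scale = counts_scale,
                        resolution = resolution, seed = seed,
                        noiseless = noiseless)
  ), class = "contrast_set")
}

#' Simulate an intensity titration series
#'
#' Partition-model means plus Gaussian noise; the zero-lipid normalization
#' point is included and kept exactly 1.
#'
#' @param kp,il_over_iw,gamma_l Generating partition parameters.
#' @param lipid_grid Lipid concentrations (M); 0 is prepended if absent.
#' @param noise_sd Gaussian noise sd on I/I_w.
#' @param seed Integer seed.
#' @return A [titration_series()] with a `ground_truth` attribute.
#' @export
gen_titration <- function(kp = 1e4, il_over_iw = 3, gamma_l = 0.763,
                          lipid_grid = seq(0, 1e-3, length.out = 8),
                          noise_sd = 0.01, seed = 1) {
  if (kp <= 0 || il_over_iw <= 0 || gamma_l <= 0)
    stop("generating parameters must be positive")
  if (!any(lipid_grid == 0)) lipid_grid <- c(0, lipid_grid)
  mu <- partition_model_intensity(kp, gamma_l, lipid_grid, il_over_iw)
  y <- withr::with_seed(seed, mu + stats::rnorm(length(mu), sd = noise_sd))
  y[lipid_grid == 0] <- 1
  out <- titration_series(lipid_grid, y)
  attr(out, "ground_truth") <- list(kp = kp, il_over_iw = il_over_iw,
                                    gamma_l = gamma_l, noise_sd = noise_sd,
                                    seed = seed)
  out
}

#' Simulate Laurdan emission spectra over a dose series
#'
#' Two Gaussian emission bands centred at 440 and 490 nm; the 490/440
#' amplitude ratio is configured per drug:lipid dose (decreasing ratio with
#' dose emulates drug-induced ordering). The ground truth includes the
#' closed-form GP of each dose's noiseless spectrum.
#'
#' @param band_ratios Named-by-nothing data.frame or list: for each dose, a
#'   row/entry `list(ratio = <drug:lipid>, a490_over_a440 = <amplitude ratio>)`.
#' @param replicates Replicate spectra per dose.
#' @param noise_sd Gaussian noise sd relative to the 440-band amplitude.
#' @param seed Integer seed.
#' @param wavelength Wavelength grid (nm).
#' @param width440,width490 Band Gaussian sigmas (nm).
#' @return List of [emission_spectrum()] with a `ground_truth` attribute.
#' @export
gen_laurdan_spectra <- function(band_ratios, replicates = 3, noise_sd = 0.005,
                                seed = 1, wavelength = seq(370, 600, by = 2),
                                width440 = 20, width490 = 25) {
  if (is.data.frame(band_ratios))
    band_ratios <- lapply(seq_len(nrow(band_ratios)),
                          function(i) as.list(band_ratios[i, ]))
  band_value <- function(wl, r) {
    exp(-(wl - 440)^2 / (2 * width440^2)) +
      r * exp(-(wl - 490)^2 / (2 * width490^2))
  }
  gp_closed <- function(r)
    (band_value(440, r) - band_value(490, r)) /
    (band_value(440, r) + band_value(490, r))
  spectra <- withr::with_seed(seed, {
    out <- list()
    for (br in band_ratios) {
      mu <- band_value(wavelength, br$a490_over_a440)
      for (k in seq_len(replicates)) {
        y <- mu + stats::rnorm(length(mu), sd = noise_sd)
        out[[length(out) + 1]] <-
          emission_spectrum(wavelength, y, condition = br$ratio)
      }
    }
    out
  })
  attr(spectra, "ground_truth") <- list(
    doses = data.frame(
      ratio = vapply(band_ratios, `[[`, numeric(1), "ratio"),
      a490_over_a440 = vapply(band_ratios, `[[`, numeric(1), "a490_over_a440"),
      gp = vapply(band_ratios, function(b) gp_closed(b$a490_over_a440),
                  numeric(1))
    ),
    replicates = replicates, noise_sd = noise_sd, seed = seed
  )
  spectra
}

#' Simulate a nitroxide EPR spectrum
#'
#' Room-temperature shape (`"derivative"`): a sum of derivative-Gaussian
#' lines at the given centers. Cryo shape (`"cryo"`): the outer lines of the
#' frozen powder pattern are modeled as a positive Gaussian bump (low field)
#' and a negative Gaussian bump (high field) at the first and last centers,
#' with any middle centers contributing derivative-Gaussian lines; the
#' ground-truth 2A_z is the distance between the outer centers.
#'
#' @param centers Line centers (mT), ascending.
#' @param widths Line Gaussian sigmas (mT), recycled.
#' @param amplitudes Line amplitudes, recycled.
#' @param noise_sd Gaussian noise sd (absolute units).
#' @param seed Integer seed.
#' @param shape `"derivative"` or `"cryo"`.
#' @param field Field grid (mT); default covers the centers with margin.
#' @return An [epr_spectrum()] with a `ground_truth` attribute.
#' @export
gen_epr_spectrum <- function(centers, widths = 0.3, amplitudes = 1,
                             noise_sd = 0, seed = 1,
                             shape = c("derivative", "cryo"),
                             field = NULL) {
  shape <- match.arg(shape)
  k <- length(centers)
  widths <- rep_len(widths, k)
  amplitudes <- rep_len(amplitudes, k)
  if (is.null(field)) {
    pad <- 6 * max(widths) + 1
    field <- seq(min(centers) - pad, max(centers) + pad, by = 0.02)
  }
  dgauss <- function(B, c0, w, A)
    -A * (B - c0) / w * exp(-(B - c0)^2 / (2 * w^2))
  gauss <- function(B, c0, w, A) A * exp(-(B - c0)^2 / (2 * w^2))
  y <- numeric(length(field))
  for (j in seq_len(k)) {
    y <- y + if (shape == "derivative") {
      dgauss(field, centers[j], widths[j], amplitudes[j])
    } else if (j == 1) {
      gauss(field, centers[j], widths[j], amplitudes[j])
    } else if (j == k) {
      -gauss(field, centers[j], widths[j], amplitudes[j])
    } else {
      dgauss(field, centers[j], widths[j], amplitudes[j])
    }
  }
  if (noise_sd > 0)
    y <- withr::with_seed(seed, y + stats::rnorm(length(y), sd = noise_sd))
  sp <- epr_spectrum(field, y,
                     temperature = if (shape == "cryo") "cryo" else "room")
  attr(sp, "ground_truth") <- list(
    centers = centers, widths = widths, amplitudes = amplitudes,
    two_a_z = if (shape == "cryo") centers[k] - centers[1] else NA_real_,
    noise_sd = noise_sd, seed = seed, shape = shape
  )
  sp
}

#' Simulate an AFM approach force curve
#'
#' Baseline, film-compliance ramps, 0/1/2 configured breakthrough drops, and
#' a steep hard-contact wall at zero separation, plus Gaussian noise. For the
#' two-step scenario the generator enforces the observed ordering
#' `f_b1 < f_b2` and `e_b1 > e_b2`.
#'
#' @param scenario `"none"`, `"one"` or `"two"`.
#' @param f_b Breakthrough force(s) (nN), length matching the scenario.
#' @param e_b Rupture distance(s) (nm), length matching the scenario.
#' @param noise_sd Gaussian force noise sd (nN).
#' @param seed Integer seed.
#' @param onset Film-contact onset distance above the (first) rupture (nm).
#' @param k_wall Hard-wall stiffness (nN/nm).
#' @param s_max,ds Separation range start and grid step (nm).
#' @return A [force_curve()] with a `ground_truth` attribute.
#' @export
gen_force_curve <- function(scenario = c("none", "one", "two"),
                            f_b = c(1.5, 3), e_b = c(4.5, 2),
                            noise_sd = 0.02, seed = 1, onset = 8,
                            k_wall = 10, s_max = 25, ds = 0.05) {
  scenario <- match.arg(scenario)
  n_steps <- switch(scenario, none = 0, one = 1, two = 2)
  f_b <- f_b[seq_len(n_steps)]
  e_b <- e_b[seq_len(n_steps)]
  if (n_steps == 2) {
    if (!(f_b[1] < f_b[2] && e_b[1] > e_b[2]))
      stop("two-step scenario requires f_b1 < f_b2 and e_b1 > e_b2")
  }
  s <- seq(s_max, -1.5, by = -ds)
  f <- numeric(length(s))
  if (n_steps == 0) {
    # smooth Hertz-like compression of an intact film, no rupture
    s_on <- onset
    comp <- s < s_on & s > 0
    f[comp] <- 0.03 * (s_on - s[comp])^2
    f_at0 <- 0.03 * s_on^2
  } else {
    s_on <- e_b[1] + onset
    ramp1 <- s < s_on & s >= e_b[1]
    f[ramp1] <- f_b[1] * (s_on - s[ramp1]) / (s_on - e_b[1])
    if (n_steps == 1) {
      resid <- 0.2 * f_b[1]
      after <- s < e_b[1] & s > 0
      f[after] <- resid * (e_b[1] - s[after]) / e_b[1]
      f_at0 <- resid
    } else {
      resid1 <- 0.2 * f_b[1]
      ramp2 <- s < e_b[1] & s >= e_b[2]
      f[ramp2] <- resid1 + (f_b[2] - resid1) *
        (e_b[1] - s[ramp2]) / (e_b[1] - e_b[2])
      resid2 <- 0.2 * f_b[2]
      after <- s < e_b[2] & s > 0
      f[after] <- resid2 * (e_b[2] - s[after]) / e_b[2]
      f_at0 <- resid2
    }
  }
  wall <- s <= 0
  f[wall] <- f_at0 + k_wall * (0 - s[wall])
  if (noise_sd > 0)
    f <- withr::with_seed(seed, f + stats::rnorm(length(f), sd = noise_sd))
  fc <- force_curve(s, f, metadata = list(scenario = scenario))
  attr(fc, "ground_truth") <- list(
    scenario = scenario, f_b = f_b, e_b = e_b, noise_sd = noise_sd,
    seed = seed
  )
  fc
}
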