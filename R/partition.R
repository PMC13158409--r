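#' Titration series of normalized drug fluorescence vs lipid concentration
#'
#' @param lipid_conc Total lipid concentrations (M), non-negative; should
#'   include the 0 normalization point.
#' @param i_over_iw Normalized fluorescence intensity I/I_w (1 at zero lipid
#'   by construction).
#' @param cpz_conc Drug concentration (uM), metadata.
#' @return Object of class `titration_series` (data.frame with attributes).
#' @export
titration_series <- function(lipid_conc, i_over_iw, cpz_conc = 40) {
  if (any(lipid_conc < 0)) stop("lipid concentrations must be non-negative")
  stopifnot(length(lipid_conc) == length(i_over_iw))
  structure(data.frame(lipid_conc = lipid_conc, i_over_iw = i_over_iw),
            cpz_conc = cpz_conc,
            class = c("titration_series", "data.frame"))
}

#' Partition-model intensity ratio
#'
#' Predicted normalized fluorescence of a drug partitioning between aqueous
#' and lipid phases:
#' `I/I_w = (1 + K_P * gamma_L * L * I_L/I_W) / (1 + K_P * gamma_L * L)`.
#' At zero lipid this is 1; in the high-lipid limit it saturates at
#' `I_L/I_W`.
#'
#' @param kp Partition coefficient (dimensionless, > 0).
#' @param gamma_l Phospholipid molar volume (M^-1, > 0).
#' @param lipid_conc Total lipid concentration(s) (M, >= 0).
#' @param il_over_iw Limiting intensity ratio I_L/I_W.
#' @return Predicted I/I_w.
#' @export
partition_model_intensity <- function(kp, gamma_l, lipid_conc, il_over_iw) {
  if (kp <= 0 || gamma_l <= 0) stop("kp and gamma_l must be positive")
  if (any(lipid_conc < 0)) stop("lipid_conc must be non-negative")
  x <- kp * gamma_l * lipid_conc
  (1 + x * il_over_iw) / (1 + x)
}

#' Fit the partition coefficient from a titration series
#'
#' Least-squares fit of `K_P` and `I_L/I_W` with the phospholipid molar
#' volume fixed (default 0.763 M^-1, the POPC value). Unweighted by default;
#' optional per-point sigma weights.
#'
#' @param series A [titration_series()].
#' @param gamma_l Fixed phospholipid molar volume (M^-1).
#' @param weights Optional per-point standard deviations (same length as the
#'   series); residuals are then divided by these.
#' @return Object of class `partition_fit`: `kp`, `il_over_iw`, `gamma_l`,
#'   standard errors `kp_se`, `il_over_iw_se`, plus `fitted` and `residuals`.
#'   Warns (and returns NA estimates) if the design cannot identify `kp`.
#' @export
fit_partition <- function(series, gamma_l = 0.763, weights = NULL) {
  stopifnot(inherits(series, "titration_series"))
  L <- series$lipid_conc
  y <- series$i_over_iw
  flat <- diff(range(y)) < 1e-10
  if (length(L) < 4 || length(unique(L)) < 3 || flat) {
    warning("kp not identifiable: need >= 4 points spanning the transition")
    return(structure(list(kp = NA_real_, il_over_iw = NA_real_,
                          gamma_l = gamma_l, kp_se = NA_real_,
                          il_over_iw_se = NA_real_,
                          fitted = rep(NA_real_, length(L)),
                          residuals = rep(NA_real_, length(L))),
                     class = "partition_fit"))
  }
  ratio0 <- max(y)
  mid <- (1 + ratio0) / 2
  above <- which(y >= mid & L > 0)
  L_half <- if (length(above) > 0) min(L[above]) else stats::median(L[L > 0])
  kp0 <- 1 / (gamma_l * L_half)
  w <- if (is.null(weights)) rep(1, length(L)) else 1 / weights^2
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ (1 + kp * gamma_l * L * ratio) / (1 + kp * gamma_l * L),
      start = list(kp = kp0, ratio = ratio0),
      lower = c(kp = 1e-6, ratio = 0),
      weights = w,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) stop("partition fit failed to converge: ",
                             conditionMessage(e),
                             "; residual range ",
                             paste(signif(range(y - 1), 3), collapse = " to "))
  )
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) c(NA_real_, NA_real_))
  est <- structure(list(
    kp = unname(cf["kp"]), il_over_iw = unname(cf["ratio"]),
    gamma_l = gamma_l,
    kp_se = unname(se[1]), il_over_iw_se = unname(se[2]),
    fitted = stats::fitted(fit), residuals = stats::residuals(fit)
  ), class = "partition_fit")
  # warn when the sampled range does not reach half-saturation
  if (est$kp * gamma_l * max(L) < 1)
    warning("lipid range does not span the transition: kp weakly identified")
  est
}

#' @export
print.partition_fit <- function(x, ...) {
  cat(sprintf("Partition fit: K_P = %.3g +/- %.2g, I_L/I_W = %.3g +/- %.2g (gamma_L = %.3g M^-1)\n",
              x$kp, x$kp_se, x$il_over_iw, x$il_over_iw_se, x$gamma_l))
  invisible(x)
}

#' Normalized intensity ratios from raw emission spectra
#'
#' Upstream helper for the titration analysis: background-subtracts each
#' spectrum with a blank, reads the emission maximum at the stated wavelength
#' (default 420 nm), and normalizes by the drug-only (zero-lipid) intensity.
#'
#' @param spectra List of [emission_spectrum()] objects ordered as
#'   `lipid_conc`.
#' @param blank An [emission_spectrum()] measured on buffer alone.
#' @param lipid_conc Lipid concentrations (M) matching `spectra`; must
#'   include 0 (the normalization point).
#' @param peak_nm Wavelength of the emission maximum used for the readout.
#' @return A [titration_series()].
#' @export
titration_from_spectra <- function(spectra, blank, lipid_conc, peak_nm = 420) {
  stopifnot(length(spectra) == length(lipid_conc))
  if (!any(lipid_conc == 0)) stop("a zero-lipid normalization spectrum is required")
  read_peak <- function(sp) {
    y <- sp$intensity - stats::approx(blank$wavelength, blank$intensity,
                                      xout = sp$wavelength, rule = 2)$y
    stats::approx(sp$wavelength, y, xout = peak_nm, rule = 2)$y
  }
  ivals <- vapply(spectra, read_peak, numeric(1))
  iw <- mean(ivals[lipid_conc == 0])
  titration_series(lipid_conc, ivals / iw)
}
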