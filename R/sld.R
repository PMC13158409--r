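#' Scattering length density from composition and molecular volume
#'
#' Computes the coherent neutron scattering length density of a molecular
#' species as the sum of its atomic coherent scattering lengths divided by its
#' molecular volume.
#'
#' @param composition Named numeric vector or list mapping element symbols
#'   (`"H"`, `"D"`, `"C"`, ...) to atom counts (non-negative).
#' @param volume Molecular volume in cubic Angstroms, strictly positive.
#' @return SLD in units of 1e-6 Angstrom^-2.
#' @examples
#' compute_sld(c(Si = 1, O = 2), volume = 45.35)  # amorphous silica
#' @export
compute_sld <- function(composition, volume) {
  composition <- unlist(composition)
  if (length(composition) == 0)
    stop("composition must be non-empty")
  if (!is.numeric(volume) || length(volume) != 1 || !is.finite(volume) || volume <= 0)
    stop("volume must be a single positive number (A^3)")
  if (any(composition < 0))
    stop("atom counts must be non-negative")
  unknown <- setdiff(names(composition), names(neutron_b_c))
  if (length(unknown) > 0)
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  b_sum <- sum(neutron_b_c[names(composition)] * composition)  # fm
  # 1 fm = 1e-5 A; b_sum [fm] / V [A^3] = b*1e-5 A^-2 = (b/V)*10 in 1e-6 A^-2
  10 * b_sum / volume
}

#' Construct a scattering species record
#'
#' Bundles a named composition, summed scattering length and molecular volume
#' with the derived SLD.
#'
#' @inheritParams compute_sld
#' @param name Species label.
#' @return Object of class `scattering_species` with fields `name`,
#'   `composition`, `b_sum` (fm), `volume` (A^3) and `sld` (1e-6 A^-2).
#' @export
scattering_species <- function(name, composition, volume) {
  sld <- compute_sld(composition, volume)
  composition <- unlist(composition)
  structure(
    list(
      name = name,
      composition = composition,
      b_sum = sum(neutron_b_c[names(composition)] * composition),
      volume = volume,
      sld = sld
    ),
    class = "scattering_species"
  )
}

#' Molecular volume implied by a mass density
#'
#' @param molar_mass Molar mass in g/mol.
#' @param density Mass density in g/cm^3.
#' @return Molecular volume in A^3.
#' @export
volume_from_density <- function(molar_mass, density) {
  if (density <= 0) stop("density must be positive")
  molar_mass / (density * .NA_SCALE)
}

#' SLD of pure H2O and D2O
#'
#' Derived from the water densities 0.997 (H2O) and 1.1044 (D2O) g/cm^3 and
#' the tabulated coherent scattering lengths.
#'
#' @return SLD in 1e-6 A^-2.
#' @export
sld_h2o <- function() {
  compute_sld(c(H = 2, O = 1), volume_from_density(.M_H2O, .RHO_H2O))
}

#' @rdname sld_h2o
#' @export
sld_d2o <- function() {
  compute_sld(c(D = 2, O = 1), volume_from_density(.M_D2O, .RHO_D2O))
}

#' Isotopic solvent contrast from a D2O volume fraction
#'
#' Linear volume-fraction mix of the pure H2O and D2O scattering length
#' densities. The four contrasts of the study are H2O (`f_d2o = 0`),
#' silicon-matched water (`0.38`), four-matched water (`0.66`) and D2O (`1`).
#'
#' @param f_d2o D2O volume fraction in `[0, 1]`.
#' @param name Optional label; a default is derived from the fraction.
#' @return Object of class `solvent_contrast` with fields `name`, `f_d2o`,
#'   `sld` (1e-6 A^-2).
#' @examples
#' mix_solvent_contrast(0.38)  # silicon-matched water, ~2.07
#' @export
mix_solvent_contrast <- function(f_d2o, name = NULL) {
  if (!is.numeric(f_d2o) || length(f_d2o) != 1 || !is.finite(f_d2o) ||
      f_d2o < 0 || f_d2o > 1)
    stop("f_d2o must be a single number in [0, 1]")
  sld <- (1 - f_d2o) * sld_h2o() + f_d2o * sld_d2o()
  if (is.null(name)) name <- sprintf("%d%% D2O", round(100 * f_d2o))
  structure(list(name = name, f_d2o = f_d2o, sld = sld),
            class = "solvent_contrast")
}

#' The four solvent contrasts used in the study
#'
#' H2O, silicon-matched water (38% D2O), four-matched water (66% D2O), and
#' D2O.
#'
#' @return List of [mix_solvent_contrast()] objects.
#' @export
standard_contrasts <- function() {
  list(
    h2o  = mix_solvent_contrast(0,    "H2O"),
    smw  = mix_solvent_contrast(0.38, "silicon-matched water"),
    fmw  = mix_solvent_contrast(0.66, "four-matched water"),
    d2o  = mix_solvent_contrast(1,    "D2O")
  )
}

#' Momentum transfer from wavelength and incident angle
#'
#' `q = 4 pi sin(theta) / lambda` for specular reflection.
#'
#' @param wavelength Neutron wavelength in Angstroms, positive.
#' @param theta Incident angle in degrees.
#' @return Momentum transfer q in A^-1.
#' @examples
#' q_from_wavelength(20, 0.7)  # the low-q end of the measured range, ~0.008
#' @export
q_from_wavelength <- function(wavelength, theta) {
  if (any(wavelength <= 0)) stop("wavelength must be positive")
  4 * pi * sin(theta * pi / 180) / wavelength
}

#' Built-in species table
#'
#' Reads the packaged table of molecular species (formula, volume, provenance)
#' and returns it with a computed SLD column.
#'
#' @return data.frame with columns `species`, `formula`, `volume_A3`,
#'   `source`, `sld`.
#' @export
species_table <- function() {
  path <- system.file("extdata", "species_table.csv", package = "slbtools",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$sld <- vapply(seq_len(nrow(tab)), function(i) {
    compute_sld(parse_formula(tab$formula[i]), tab$volume_A3[i])
  }, numeric(1))
  tab
}

#' Parse an element-count formula
#'
#' Minimal parser for formulas like `"C10H18NO8P"` or `"D2O"`; element symbols
#' are one capital optionally followed by a lowercase letter, counts default
#' to 1. Not a general chemistry parser.
#'
#' @param formula Formula string.
#' @return Named numeric vector element -> count.
#' @export
parse_formula <- function(formula) {
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (sum(nchar(parts)) != nchar(formula))
    stop("cannot parse formula: ", formula)
  el <- sub("[0-9]*$", "", parts)
  ct <- as.numeric(ifelse(grepl("[0-9]+$", parts),
                          sub("^[A-Za-z]+", "", parts), "1"))
  out <- tapply(ct, el, sum)
  stats::setNames(as.numeric(out), names(out))
}
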