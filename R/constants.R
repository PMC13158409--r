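#' Coherent neutron scattering lengths (fm)
#'
#' Bound coherent scattering lengths for the elements used throughout the
#' package, from the standard neutron data tabulation (Sears, Neutron News 3,
#' 1992). `D` is listed as its own symbol.
#'
#' @format Named numeric vector, femtometres.
#' @export
neutron_b_c <- c(
  H  = -3.7390,
  D  =  6.6710,
  C  =  6.6460,
  N  =  9.3600,
  O  =  5.8030,
  P  =  5.1300,
  S  =  2.8470,
  Si =  4.1491,
  Na =  3.6300,
  K  =  3.6700,
  Cl =  9.5770
)

#' Fixed component scattering length densities (1e-6 A^-2)
#'
#' The per-component SLDs used by the membrane models: phosphatidylcholine
#' headgroup, chain-deuterated fatty-acid tails, chlorpromazine (CPZ), native
#' silicon oxide, and bulk silicon. Stored once and referenced everywhere;
#' the CPZ value is a fixed constant (its molecular volume is not independently
#' recomputed here).
#'
#' @format Named numeric vector, units of 1e-6 Angstrom^-2.
#' @export
component_slds <- c(
  headgroup = 1.88,
  tails     = 3.17,
  cpz       = 1.30,
  oxide     = 3.47,
  silicon   = 2.07
)

# Molar masses (g/mol) for the built-in water species
.M_H2O <- 18.0153
.M_D2O <- 20.0276

# Avogadro scaling: V [A^3] = M [g/mol] / (rho [g/cm^3] * 0.602214076)
.NA_SCALE <- 0.602214076

# Pure-water densities at 25 C used to derive molecular volumes
.RHO_H2O <- 0.997
.RHO_D2O <- 1.1044
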