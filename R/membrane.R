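#' Parametrized supported-bilayer structural model
#'
#' Represents the slab-model hierarchy used to analyse the reflectivity data:
#' a silicon-supported symmetric bilayer (five layers: oxide, inner headgroup,
#' inner tails, outer tails, outer headgroup), optionally with a thin water
#' layer under the bilayer, drug (CPZ) intercalated in the fatty-acid region
#' (and optionally in the headgroups), and 0-3 adsorbed layers above the
#' membrane, optionally separated by a pure-solvent gap. Head and tail
#' thicknesses are leaflet-symmetric; the per-layer component inventories are
#' independent between leaflets.
#'
#' Variants map to the model hierarchy: `BLANK` (pristine bilayer),
#' `CPZ_TAILS` (tail-intercalated drug), `CPZ_TAILS_1AD`, `CPZ_TAILS_2AD`,
#' `CPZ_TAILS_3AD` (drug plus 1-3 adsorbed layers).
#'
#' @param variant One of `"BLANK"`, `"CPZ_TAILS"`, `"CPZ_TAILS_1AD"`,
#'   `"CPZ_TAILS_2AD"`, `"CPZ_TAILS_3AD"`.
#' @param t_head,t_tail Headgroup and tail-region thickness per leaflet (A).
#' @param t_water_gap Optional thin water layer between oxide and inner
#'   headgroup (A, 0 disables).
#' @param head_in,tail_in,tail_out,head_out Per-layer inventories:
#'   `list(cpz = <dry fraction>, solvent = <volume fraction>)`. `cpz` is the
#'   drug share of the layer's dry volume; the remainder is lipid.
#' @param adsorbed List (length 0-3 matching the variant) of
#'   `list(thickness, sld, solvent)`; the adsorbed material carries a fitted
#'   SLD directly.
#' @param gap_thickness Pure-solvent slab separating bilayer and adsorbed
#'   layers (A, 0 disables).
#' @param rough_substrate Roughness of the substrate interfaces (A).
#' @param rough_membrane Shared roughness of all membrane interfaces (A).
#' @param oxide Substrate oxide: `list(thickness, solvent)` (SLD fixed at
#'   3.47e-6 A^-2).
#' @param allow_headgroup_cpz Permit non-zero `cpz` in the headgroup layers.
#' @return Object of class `membrane_model`.
#' @export
membrane_model <- function(variant = c("BLANK", "CPZ_TAILS", "CPZ_TAILS_1AD",
                                       "CPZ_TAILS_2AD", "CPZ_TAILS_3AD"),
                           t_head = 8, t_tail = 17.5, t_water_gap = 0,
                           head_in = list(cpz = 0, solvent = 0.5),
                           tail_in = list(cpz = 0, solvent = 0.05),
                           tail_out = list(cpz = 0, solvent = 0.05),
                           head_out = list(cpz = 0, solvent = 0.5),
                           adsorbed = list(),
                           gap_thickness = 0,
                           rough_substrate = 3, rough_membrane = 3,
                           oxide = list(thickness = 12, solvent = 0.1),
                           allow_headgroup_cpz = FALSE) {
  variant <- match.arg(variant)
  m <- structure(list(
    variant = variant, t_head = t_head, t_tail = t_tail,
    t_water_gap = t_water_gap,
    head_in = head_in, tail_in = tail_in, tail_out = tail_out,
    head_out = head_out,
    adsorbed = adsorbed, gap_thickness = gap_thickness,
    rough_substrate = rough_substrate, rough_membrane = rough_membrane,
    oxide = oxide, allow_headgroup_cpz = allow_headgroup_cpz
  ), class = "membrane_model")
  validate_membrane_model(m)
  m
}

#' @rdname membrane_model
#' @param m A `membrane_model`.
#' @export
validate_membrane_model <- function(m) {
  n_ad_expected <- c(BLANK = 0, CPZ_TAILS = 0, CPZ_TAILS_1AD = 1,
                     CPZ_TAILS_2AD = 2, CPZ_TAILS_3AD = 3)[[m$variant]]
  if (length(m$adsorbed) != n_ad_expected)
    stop("variant ", m$variant, " requires ", n_ad_expected,
         " adsorbed layer(s), got ", length(m$adsorbed))
  if (m$t_head <= 0 || m$t_tail <= 0)
    stop("t_head and t_tail must be positive")
  if (m$t_water_gap < 0 || m$gap_thickness < 0)
    stop("optional layer thicknesses must be non-negative")
  for (nm in c("head_in", "tail_in", "tail_out", "head_out")) {
    inv <- m[[nm]]
    if (inv$cpz < 0 || inv$cpz > 1 || inv$solvent < 0 || inv$solvent > 1)
      stop(nm, ": fractions must lie in [0, 1]")
  }
  if (!m$allow_headgroup_cpz && (m$head_in$cpz > 0 || m$head_out$cpz > 0))
    stop("headgroup CPZ present but allow_headgroup_cpz is FALSE")
  for (ad in m$adsorbed) {
    if (ad$thickness < 0 || ad$solvent < 0 || ad$solvent > 1)
      stop("invalid adsorbed layer")
  }
  invisible(m)
}

#' Effective SLD of a hydrated composite layer
#'
#' Volume-fraction weighted mean of the dry component SLDs and the solvent
#' contrast: `SLD = sum(phi_c * SLD_c) + phi_solv * SLD_contrast`. Fractions
#' must sum to 1.
#'
#' @param fractions Named numeric vector of dry component volume fractions.
#' @param slds Named numeric vector of component SLDs (1e-6 A^-2) covering
#'   `names(fractions)`; defaults to [component_slds].
#' @param solvent_fraction Solvent volume fraction.
#' @param contrast_sld SLD of the solvent contrast (1e-6 A^-2).
#' @return SLD in 1e-6 A^-2.
#' @examples
#' effective_layer_sld(c(headgroup = 0.5), solvent_fraction = 0.5,
#'                     contrast_sld = 6.35)
#' @export
effective_layer_sld <- function(fractions, slds = component_slds,
                                solvent_fraction, contrast_sld) {
  tot <- sum(fractions) + solvent_fraction
  if (abs(tot - 1) > 1e-9)
    stop("volume fractions must sum to 1 (got ", format(tot), ")")
  if (any(fractions < 0) || solvent_fraction < 0)
    stop("fractions must be non-negative")
  missing <- setdiff(names(fractions), names(slds))
  if (length(missing) > 0)
    stop("no SLD for component(s): ", paste(missing, collapse = ", "))
  sum(fractions * slds[names(fractions)]) + solvent_fraction * contrast_sld
}

# dry fractions of a bilayer layer given its inventory
.layer_fractions <- function(inv, lipid_component) {
  dry <- 1 - inv$solvent
  f <- c(dry * (1 - inv$cpz), dry * inv$cpz)
  names(f) <- c(lipid_component, "cpz")
  f[f > 0 | names(f) == lipid_component]
}

#' Compile a membrane model into a slab stack for one contrast
#'
#' Produces the ordered stack silicon-oxide, optional thin water layer, inner
#' headgroup, inner tails, outer tails, outer headgroup, optional solvent gap,
#' adsorbed layers, backing solvent. Thicknesses and roughness are contrast
#' independent; only layer SLDs change with the solvent.
#'
#' @param model A [membrane_model()].
#' @param contrast A [mix_solvent_contrast()] object (or list with `$sld`).
#' @return A [slab_stack()].
#' @export
compile_stack <- function(model, contrast, validate = TRUE) {
  if (validate) validate_membrane_model(model)
  cs <- contrast$sld
  sld_head <- component_slds[["headgroup"]]
  sld_tail <- component_slds[["tails"]]
  sld_cpz <- component_slds[["cpz"]]

  mix <- function(inv, lipid_sld) {
    dry <- 1 - inv$solvent
    dry * ((1 - inv$cpz) * lipid_sld + inv$cpz * sld_cpz) + inv$solvent * cs
  }
  th <- model$oxide$thickness
  sl <- (1 - model$oxide$solvent) * component_slds[["oxide"]] +
    model$oxide$solvent * cs
  rg <- model$rough_substrate
  if (model$t_water_gap > 0) {
    th <- c(th, model$t_water_gap); sl <- c(sl, cs)
    rg <- c(rg, model$rough_substrate)
  }
  th <- c(th, model$t_head, model$t_tail, model$t_tail, model$t_head)
  sl <- c(sl, mix(model$head_in, sld_head), mix(model$tail_in, sld_tail),
          mix(model$tail_out, sld_tail), mix(model$head_out, sld_head))
  rg <- c(rg, rep(model$rough_membrane, 4))
  if (length(model$adsorbed) > 0) {
    if (model$gap_thickness > 0) {
      th <- c(th, model$gap_thickness); sl <- c(sl, cs)
      rg <- c(rg, model$rough_membrane)
    }
    for (ad in model$adsorbed) {
      th <- c(th, ad$thickness)
      sl <- c(sl, (1 - ad$solvent) * ad$sld + ad$solvent * cs)
      rg <- c(rg, model$rough_membrane)
    }
  }
  structure(list(incident_sld = component_slds[["silicon"]],
                 layers = list(thickness = th, sld = sl, rough = rg),
                 backing_sld = cs, backing_rough = model$rough_membrane),
            class = "slab_stack")
}

#' Component volume-fraction profile along the surface normal
#'
#' Boxcar per-layer fractions smoothed by error functions of the interfacial
#' roughness. z = 0 at the silicon/oxide boundary, increasing toward
#' solution. The solvent fraction is the complement of all material
#' components, so fractions sum to 1 at every z.
#'
#' @param model A [membrane_model()].
#' @param z_step Grid spacing in A (> 0).
#' @param z_pad Padding beyond the outermost interface (A).
#' @return data.frame with columns `z`, `silicon`, `oxide`, `headgroup`,
#'   `tails`, `cpz`, `adsorbed`, `solvent`.
#' @export
volume_fraction_profile <- function(model, z_step = 0.25, z_pad = 25) {
  if (z_step <= 0) stop("z_step must be positive")
  validate_membrane_model(model)

  # per-layer material fractions (solvent implicit)
  seg <- list()  # list of (t, rough_interface_below, fractions named vec)
  push <- function(seg, t, rough, fr) c(seg, list(list(t = t, rough = rough, fr = fr)))
  seg <- push(seg, model$oxide$thickness, model$rough_substrate,
              c(oxide = 1 - model$oxide$solvent))
  if (model$t_water_gap > 0)
    seg <- push(seg, model$t_water_gap, model$rough_substrate, c(oxide = 0))
  for (b in list(list(model$head_in, "headgroup", model$t_head),
                 list(model$tail_in, "tails", model$t_tail),
                 list(model$tail_out, "tails", model$t_tail),
                 list(model$head_out, "headgroup", model$t_head))) {
    inv <- b[[1]]; dry <- 1 - inv$solvent
    fr <- stats::setNames(c(dry * (1 - inv$cpz), dry * inv$cpz),
                          c(b[[2]], "cpz"))
    seg <- push(seg, b[[3]], model$rough_membrane, fr)
  }
  if (length(model$adsorbed) > 0) {
    if (model$gap_thickness > 0)
      seg <- push(seg, model$gap_thickness, model$rough_membrane, c(adsorbed = 0))
    for (ad in model$adsorbed)
      seg <- push(seg, ad$thickness, model$rough_membrane,
                  c(adsorbed = 1 - ad$solvent))
  }

  bounds <- cumsum(c(0, vapply(seg, `[[`, numeric(1), "t")))
  n <- length(seg)
  roughs <- c(vapply(seg, `[[`, numeric(1), "rough"), model$rough_membrane)
  roughs <- pmax(roughs, 1e-6)
  z <- seq(-z_pad, bounds[n + 1] + z_pad, by = z_step)
  comps <- c("silicon", "oxide", "headgroup", "tails", "cpz", "adsorbed")
  prof <- matrix(0, nrow = length(z), ncol = length(comps),
                 dimnames = list(NULL, comps))
  box <- function(lo_i, hi_i) {
    0.5 * (pracma::erf((z - bounds[lo_i]) / (sqrt(2) * roughs[lo_i])) -
             pracma::erf((z - bounds[hi_i]) / (sqrt(2) * roughs[hi_i])))
  }
  prof[, "silicon"] <- 0.5 * (1 - pracma::erf((z - 0) / (sqrt(2) * roughs[1])))
  for (i in seq_len(n)) {
    b_i <- box(i, i + 1)
    for (cn in names(seg[[i]]$fr))
      prof[, cn] <- prof[, cn] + seg[[i]]$fr[[cn]] * b_i
  }
  solvent <- pmax(1 - rowSums(prof), 0)
  out <- data.frame(z = z, prof, solvent = solvent)
  out
}

#' Structural summary of a membrane model
#'
#' Total bilayer thickness (2 x (t_head + t_tail)), per-leaflet drug share of
#' the fatty-acid dry volume, total drug volume per unit area, substrate
#' coverage (1 - mean tail solvent fraction), and adsorbed-layer geometry.
#'
#' @param model A [membrane_model()].
#' @return Object of class `membrane_summary` (a list).
#' @export
summarize_structure <- function(model) {
  validate_membrane_model(model)
  cpz_vol <- function(inv, t) t * (1 - inv$solvent) * inv$cpz
  cpz_total <- cpz_vol(model$tail_in, model$t_tail) +
    cpz_vol(model$tail_out, model$t_tail) +
    cpz_vol(model$head_in, model$t_head) +
    cpz_vol(model$head_out, model$t_head)
  structure(list(
    variant = model$variant,
    total_thickness = 2 * (model$t_head + model$t_tail),
    cpz_tail_fraction = c(inner = model$tail_in$cpz, outer = model$tail_out$cpz),
    cpz_volume = cpz_total,
    coverage = 1 - mean(c(model$tail_in$solvent, model$tail_out$solvent)),
    adsorbed_extent = sum(vapply(model$adsorbed, `[[`, numeric(1), "thickness")),
    adsorbed_separation = if (length(model$adsorbed) > 0) model$gap_thickness else 0
  ), class = "membrane_summary")
}

#' @export
print.membrane_summary <- function(x, ...) {
  cat("Membrane structure (", x$variant, ")\n", sep = "")
  cat(sprintf("  total bilayer thickness: %.1f A\n", x$total_thickness))
  cat(sprintf("  CPZ share of tail dry volume: inner %.1f%%, outer %.1f%%\n",
              100 * x$cpz_tail_fraction[["inner"]],
              100 * x$cpz_tail_fraction[["outer"]]))
  cat(sprintf("  coverage: %.1f%%\n", 100 * x$coverage))
  if (x$adsorbed_extent > 0)
    cat(sprintf("  adsorbed layers: %.0f A extent, %.0f A separation\n",
                x$adsorbed_extent, x$adsorbed_separation))
  invisible(x)
}

#' Drug retention across a rinse
#'
#' Percent of the initial intercalated drug volume retained after rinsing:
#' `100 * after / before`, rounded to the nearest integer percent.
#'
#' @param before,after [summarize_structure()] records for the pre- and
#'   post-rinse fits of the same model family.
#' @return Retention in percent (integer-rounded).
#' @export
cpz_retention <- function(before, after) {
  stopifnot(inherits(before, "membrane_summary"),
            inherits(after, "membrane_summary"))
  if (before$cpz_volume <= 0)
    stop("retention undefined: no drug volume in the pre-rinse structure")
  round(100 * after$cpz_volume / before$cpz_volume)
}
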