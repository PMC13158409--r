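#' Slab stack for the reflectivity forward model
#'
#' An ordered set of homogeneous layers between a semi-infinite incident
#' medium (silicon) and a semi-infinite backing solvent. Layers are ordered
#' substrate to solution. Each layer's `rough` is the Gaussian width of its
#' interface with the preceding (substrate-side) medium; `backing_rough` is
#' the width of the final interface to the solvent.
#'
#' @param incident_sld SLD of the incident medium (1e-6 A^-2).
#' @param layers data.frame with columns `thickness` (A, >= 0), `sld`
#'   (1e-6 A^-2) and `rough` (A, >= 0). May have zero rows (bare interface).
#' @param backing_sld SLD of the backing medium (1e-6 A^-2).
#' @param backing_rough Roughness of the last interface (A, >= 0).
#' @return Object of class `slab_stack`.
#' @export
slab_stack <- function(incident_sld, layers = NULL, backing_sld,
                       backing_rough = 0) {
  if (is.null(layers))
    layers <- data.frame(thickness = numeric(0), sld = numeric(0),
                         rough = numeric(0))
  layers <- as.data.frame(layers)
  stopifnot(all(c("thickness", "sld", "rough") %in% names(layers)))
  if (any(layers$thickness < 0) || any(layers$rough < 0) || backing_rough < 0)
    stop("thickness and roughness must be non-negative")
  structure(list(incident_sld = incident_sld, layers = layers,
                 backing_sld = backing_sld, backing_rough = backing_rough),
            class = "slab_stack")
}

#' Fresnel reflectivity of a single sharp interface
#'
#' Closed-form two-medium reflectivity; the limit the slab recursion must
#' reproduce for an empty stack. Below the critical edge
#' `q_c = sqrt(16 pi (rho_b - rho_i))` the reflectivity is 1.
#'
#' @param incident_sld,backing_sld SLDs in 1e-6 A^-2.
#' @param q Momentum transfer grid (A^-1, positive).
#' @return Reflectivity values in `[0, 1]`.
#' @export
fresnel_reflectivity <- function(incident_sld, backing_sld, q) {
  if (any(q <= 0)) stop("q must be positive")
  k0 <- q / 2
  drho <- (backing_sld - incident_sld) * 1e-6
  k1 <- sqrt(as.complex(k0^2 - 4 * pi * drho))
  r <- (k0 - k1) / (k0 + k1)
  Mod(r)^2
}

#' Critical edge of an interface
#'
#' @inheritParams fresnel_reflectivity
#' @return q_c in A^-1 (0 if the backing SLD does not exceed the incident one).
#' @export
critical_edge <- function(incident_sld, backing_sld) {
  drho <- (backing_sld - incident_sld) * 1e-6
  if (drho <= 0) return(0)
  sqrt(16 * pi * drho)
}

# Parratt recursion with Nevot-Croce roughness, vectorized over q.
# slds in 1e-6 A^-2; thickness/roughness in A.
.parratt <- function(q, incident_sld, layers, backing_sld, backing_rough) {
  n <- length(layers$thickness)
  rho <- c(incident_sld, layers$sld, backing_sld) * 1e-6
  d <- c(0, layers$thickness, 0)
  sig <- c(layers$rough, backing_rough)  # sig[j]: interface between media j-1, j
  k0 <- q / 2
  # wavevector in each medium (complex, principal branch -> decaying waves)
  kz <- lapply(seq_along(rho), function(j)
    sqrt(as.complex(k0^2 - 4 * pi * (rho[j] - rho[1]))))
  # recursion from the backing interface up
  R <- {
    ka <- kz[[n + 1]]; kb <- kz[[n + 2]]
    (ka - kb) / (ka + kb) * exp(-2 * ka * kb * sig[n + 1]^2)
  }
  if (n > 0) {
    for (j in n:1) {
      ka <- kz[[j]]; kb <- kz[[j + 1]]
      rj <- (ka - kb) / (ka + kb) * exp(-2 * ka * kb * sig[j]^2)
      beta <- exp(2i * kb * d[j + 1])
      R <- (rj + R * beta) / (1 + rj * R * beta)
    }
  }
  pmin(Mod(R)^2, 1)
}

#' Specular reflectivity of a slab stack
#'
#' Parratt recursion over the layers with interfacial roughness applied as
#' Nevot-Croce attenuation factors. For roughness comparable to layer
#' thickness, a micro-slicing evaluation through the error-function SLD
#' profile is available (`method = "microslice"`, 1 A slices).
#'
#' @param stack A [slab_stack()].
#' @param q Positive ascending momentum-transfer grid (A^-1).
#' @param method `"nevot_croce"` (default) or `"microslice"`.
#' @return Reflectivity values, in `[0, 1]`.
#' @export
slab_reflectivity <- function(stack, q, method = c("nevot_croce", "microslice")) {
  method <- match.arg(method)
  stopifnot(inherits(stack, "slab_stack"))
  if (any(q <= 0)) stop("q must be positive")
  if (method == "nevot_croce") {
    .parratt(q, stack$incident_sld, stack$layers, stack$backing_sld,
             stack$backing_rough)
  } else {
    sl <- .slice_stack(stack, dz = 1)
    .parratt(q, stack$incident_sld, sl, stack$backing_sld, 0)
  }
}

# Error-function SLD profile of a stack, sliced into thin zero-roughness slabs
.slice_stack <- function(stack, dz = 1) {
  lay <- stack$layers
  n <- length(lay$thickness)
  bounds <- cumsum(c(0, lay$thickness))        # interface positions
  sig <- pmax(c(lay$rough, stack$backing_rough), 1e-6)
  rho <- c(stack$incident_sld, lay$sld, stack$backing_sld)
  pad <- 4 * max(sig) + 5
  z <- seq(-pad, bounds[n + 1] + pad, by = dz)
  prof <- rep(rho[1], length(z))
  for (j in seq_len(n + 1)) {
    step <- 0.5 * (1 + pracma::erf((z - bounds[j]) / (sqrt(2) * sig[j])))
    prof <- prof + (rho[j + 1] - rho[j]) * step
  }
  data.frame(thickness = rep(dz, length(z)), sld = prof,
             rough = rep(0, length(z)))
}

#' Constant-relative resolution smearing of a reflectivity curve
#'
#' Gaussian convolution in q with full width at half maximum equal to
#' `resolution * q` (the instrument's constant dq/q convention). Operates by
#' linear interpolation of the supplied curve; end points are extended
#' flat.
#'
#' @param q Ascending q grid.
#' @param r Reflectivity sampled on `q`.
#' @param resolution dq/q as FWHM; `0` returns `r` unchanged.
#' @param n_kernel Number of kernel evaluation points (odd, >= 21).
#' @param width Kernel truncation in sigma units.
#' @return Smeared reflectivity on the same grid.
#' @export
smear_resolution <- function(q, r, resolution, n_kernel = 21, width = 3.5) {
  if (resolution < 0) stop("resolution must be >= 0")
  if (resolution == 0) return(r)
  s <- seq(-width, width, length.out = max(n_kernel, 21))
  w <- stats::dnorm(s)
  w <- w / sum(w)
  sigma <- resolution * q / (2 * sqrt(2 * log(2)))
  out <- vapply(seq_along(q), function(i) {
    qq <- q[i] + sigma[i] * s
    rr <- stats::approx(q, r, xout = qq, rule = 2)$y
    sum(w * rr)
  }, numeric(1))
  out
}

# Build the oversampled evaluation grid and weight matrix for exact smearing
# of a model curve at fixed resolution. Returns list(q_fine, W) with
# R_smeared = W %*% R(q_fine).
.smear_design <- function(q, resolution, n_kernel = 21, width = 3.5) {
  if (resolution == 0) {
    return(list(q_fine = q, W = diag(length(q))))
  }
  s <- seq(-width, width, length.out = max(n_kernel, 21))
  w <- stats::dnorm(s); w <- w / sum(w)
  sigma <- resolution * q / (2 * sqrt(2 * log(2)))
  q_fine <- as.vector(t(outer(q, rep(1, length(s))) +
                          outer(sigma, s)))
  q_fine <- pmax(q_fine, 1e-6)
  W <- matrix(0, nrow = length(q), ncol = length(q_fine))
  nk <- length(s)
  for (i in seq_along(q)) W[i, ((i - 1) * nk + 1):(i * nk)] <- w
  list(q_fine = q_fine, W = W)
}

#' Smeared model reflectivity of a stack
#'
#' Exact oversampled evaluation: the model is computed on a fine grid under
#' each q-point's Gaussian resolution kernel and weight-averaged, rather than
#' interpolated.
#'
#' @inheritParams slab_reflectivity
#' @param resolution dq/q FWHM; 0 for no smearing.
#' @return Reflectivity on `q`.
#' @export
model_reflectivity <- function(stack, q, resolution = 0.07) {
  if (resolution == 0) return(slab_reflectivity(stack, q))
  des <- .smear_design(q, resolution)
  as.vector(des$W %*% slab_reflectivity(stack, des$q_fine))
}

#' Reflectivity curve container
#'
#' @param q Strictly ascending positive q grid (A^-1).
#' @param r Reflectivity values.
#' @param dr 1-sigma uncertainties (>= 0).
#' @param resolution dq/q (FWHM) of the measurement.
#' @return Object of class `reflectivity_curve` (a data.frame with attributes).
#' @export
reflectivity_curve <- function(q, r, dr = NULL, resolution = 0.07) {
  if (any(q <= 0)) stop("q must be positive")
  if (is.unsorted(q, strictly = TRUE)) stop("q must be strictly ascending")
  if (is.null(dr)) dr <- rep(0, length(q))
  if (any(dr < 0)) stop("dr must be non-negative")
  stopifnot(length(r) == length(q), length(dr) == length(q))
  structure(data.frame(q = q, r = r, dr = dr),
            resolution = resolution, class = c("reflectivity_curve", "data.frame"))
}
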