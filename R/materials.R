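# Constitutive models used by the foot model: linear-elastic bone,
# second-order polynomial hyperelastic bulk soft tissue, and first-order
# Ogden skin. Units are N and mm throughout, so stresses and moduli are in
# N/mm^2 (= MPa) and the strain energies are per unit reference volume.

#' Linear elastic material
#'
#' Default parameters are the merged-bone values used in the foot model:
#' E = 10 GPa (10000 MPa), Poisson's ratio 0.34.
#'
#' @param youngs_modulus Young's modulus in MPa (> 0).
#' @param poissons_ratio Poisson's ratio in (-1, 0.5).
#' @return A `linear_elastic` material object.
#' @export
linear_elastic <- function(youngs_modulus = 10000, poissons_ratio = 0.34) {
  if (!is.finite(youngs_modulus) || youngs_modulus <= 0) {
    abort("Young's modulus must be positive (MPa).")
  }
  if (poissons_ratio <= -1 || poissons_ratio >= 0.5) {
    abort("Poisson's ratio must lie in (-1, 0.5).")
  }
  structure(list(youngs_modulus = youngs_modulus,
                 poissons_ratio = poissons_ratio),
            class = c("linear_elastic", "fm_material"))
}

#' Second-order polynomial hyperelastic material
#'
#' Strain energy per unit reference volume
#' `U = sum_{i+j=1..2} C_ij (I1bar - 3)^i (I2bar - 3)^j
#'      + sum_{i: D_i > 0} (1/D_i) (J_el - 1)^(2i)`.
#' Defaults are the encapsulated bulk soft tissue coefficients
#' (C10 = 0.8556, C01 = -0.0584, C20 = 0.03900, C11 = -0.02319,
#' C02 = 0.00851 N/mm^2; D1 = 3.65273, D2 = 0 mm^2/N). A zero `D_i` means
#' the corresponding volumetric term is absent, not infinitely stiff.
#'
#' @param C10,C01,C20,C11,C02 deviatoric coefficients (N/mm^2).
#' @param D1,D2 volumetric compliances (mm^2/N); 0 drops the term.
#' @return A `polynomial_n2` material object.
#' @export
polynomial_n2 <- function(C10 = 0.8556, C01 = -0.0584, C20 = 0.03900,
                          C11 = -0.02319, C02 = 0.00851,
                          D1 = 3.65273, D2 = 0) {
  if (D1 < 0 || D2 < 0) abort("Volumetric compliances D1, D2 must be >= 0.")
  structure(list(C10 = C10, C01 = C01, C20 = C20, C11 = C11, C02 = C02,
                 D1 = D1, D2 = D2),
            class = c("polynomial_n2", "fm_material"))
}

#' First-order Ogden hyperelastic material (incompressible form)
#'
#' Strain energy `U = (2 mu / alpha^2) (l1^alpha + l2^alpha + l3^alpha - 3)`
#' on the (deviatoric) principal stretches, the printed first-order Ogden
#' normalisation with no volumetric term. Defaults are the 2-mm skin
#' membrane values mu = 0.122 MPa, alpha = 18.
#'
#' @param mu shear-like modulus (MPa).
#' @param alpha dimensionless exponent; `mu * alpha` must be positive.
#' @return An `ogden_n1` material object.
#' @export
ogden_n1 <- function(mu = 0.122, alpha = 18) {
  if (!is.finite(mu) || !is.finite(alpha) || mu * alpha <= 0) {
    abort("Ogden parameters must satisfy mu * alpha > 0.")
  }
  structure(list(mu = mu, alpha = alpha),
            class = c("ogden_n1", "fm_material"))
}

#' @export
print.fm_material <- function(x, ...) {
  cat(sprintf("<%s>\n", class(x)[1]))
  for (nm in names(x)) cat(sprintf("  %s = %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Principal stretches
#'
#' @param l1,l2,l3 strictly positive principal stretches (dimensionless).
#' @return A `principal_stretches` object.
#' @export
principal_stretches <- function(l1, l2, l3) {
  l <- c(l1, l2, l3)
  if (any(!is.finite(l)) || any(l <= 0)) {
    abort("Principal stretches must all be strictly positive.")
  }
  structure(list(l1 = l1, l2 = l2, l3 = l3), class = "principal_stretches")
}

#' Deviatoric strain invariants
#'
#' `J_el = l1 l2 l3`; deviatoric stretches `lbar_i = J_el^(-1/3) l_i`;
#' `I1bar = sum lbar_i^2`, `I2bar = sum lbar_i^-2`. Pure dilation leaves
#' `I1bar = I2bar = 3`.
#'
#' @param s a [principal_stretches()].
#' @return Named list with `I1bar`, `I2bar`, `J_el`.
#' @export
deviatoric_invariants <- function(s) {
  l <- c(s$l1, s$l2, s$l3)
  J <- prod(l)
  lbar <- J^(-1 / 3) * l
  list(I1bar = sum(lbar^2), I2bar = sum(lbar^-2), J_el = J)
}

#' Strain energy density
#'
#' Evaluates the strain energy per unit reference volume (N/mm^2) of a
#' hyperelastic material at the given principal stretches. Dispatches on the
#' material class.
#'
#' @param material a `polynomial_n2` or `ogden_n1` material.
#' @param s a [principal_stretches()].
#' @return Scalar energy density.
#' @export
strain_energy <- function(material, s) UseMethod("strain_energy")

#' @export
strain_energy.polynomial_n2 <- function(material, s) {
  inv <- deviatoric_invariants(s)
  a <- inv$I1bar - 3
  b <- inv$I2bar - 3
  U <- material$C10 * a + material$C01 * b +
    material$C20 * a^2 + material$C11 * a * b + material$C02 * b^2
  if (material$D1 > 0) U <- U + (1 / material$D1) * (inv$J_el - 1)^2
  if (material$D2 > 0) U <- U + (1 / material$D2) * (inv$J_el - 1)^4
  U
}

#' @export
strain_energy.ogden_n1 <- function(material, s) {
  a <- material$alpha
  (2 * material$mu / a^2) * (s$l1^a + s$l2^a + s$l3^a - 3)
}

#' Nominal uniaxial stress under incompressibility
#'
#' Loading along axis 1 with the incompressible substitution
#' l2 = l3 = lambda^(-1/2) (so J_el = 1 and the volumetric terms vanish).
#' Returns the analytic nominal (first Piola-Kirchhoff) stress dU/dlambda
#' in MPa.
#'
#' @param material a `polynomial_n2` or `ogden_n1` material.
#' @param lambda stretch along the loading axis (> 0); vectorised.
#' @return Nominal stress in MPa (negative in compression).
#' @export
uniaxial_nominal_stress <- function(material, lambda) {
  UseMethod("uniaxial_nominal_stress")
}

#' @export
uniaxial_nominal_stress.polynomial_n2 <- function(material, lambda) {
  if (any(lambda <= 0)) abort("Stretch must be positive.")
  # I1bar = l^2 + 2/l, I2bar = 2 l + 1/l^2 at J = 1
  a <- lambda^2 + 2 / lambda - 3
  b <- 2 * lambda + 1 / lambda^2 - 3
  dU_da <- material$C10 + 2 * material$C20 * a + material$C11 * b
  dU_db <- material$C01 + material$C11 * a + 2 * material$C02 * b
  da <- 2 * lambda - 2 / lambda^2
  db <- 2 - 2 / lambda^3
  dU_da * da + dU_db * db
}

#' @export
uniaxial_nominal_stress.ogden_n1 <- function(material, lambda) {
  if (any(lambda <= 0)) abort("Stretch must be positive.")
  a <- material$alpha
  (2 * material$mu / a) * (lambda^(a - 1) - lambda^(-a / 2 - 1))
}

#' Uniaxial strain energy at a stretch (incompressible substitution)
#'
#' Helper used for finite-difference verification of
#' [uniaxial_nominal_stress()]: evaluates [strain_energy()] at
#' `(lambda, lambda^-1/2, lambda^-1/2)`.
#'
#' @inheritParams uniaxial_nominal_stress
#' @return Scalar energy density; vectorised over `lambda`.
#' @export
uniaxial_strain_energy <- function(material, lambda) {
  vapply(lambda, function(l) {
    strain_energy(material, principal_stretches(l, 1 / sqrt(l), 1 / sqrt(l)))
  }, numeric(1))
}

#' @export
tidy.fm_material <- function(x, ...) {
  tibble::tibble(term = names(unclass(x)),
                 value = unlist(unclass(x), use.names = FALSE))
}
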