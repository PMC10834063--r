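#' Magnetostrictive material parameter set
#'
#' Bundles the constitutive parameters of an isotropic, anhysteretic
#' magnetostrictive material: the Langevin magnetization law is
#' parameterized by the saturation magnetization `Ms` and the initial
#' susceptibility `chi0`, and the quadratic magnetostriction law by the
#' saturation magnetostriction `lambda_s`.  Remanent magnetization is fixed
#' at zero (anhysteretic model).
#'
#' @param Ms Saturation magnetization, A/m.
#' @param lambda_s Saturation magnetostriction, dimensionless strain.
#' @param chi0 Initial magnetic susceptibility, dimensionless.
#' @param youngs_modulus Young's modulus, Pa.
#' @param poisson_ratio Poisson's ratio, in (0, 0.5).
#' @param density Mass density, kg/m^3.
#' @param conductivity Electrical conductivity, S/m.
#' @param rel_permittivity Relative permittivity.
#' @param rel_permeability Relative permeability.
#' @param eta_mech Mechanical (structural) loss factor, dimensionless.
#' @return Object of class `magnetostrictive_material`.
#' @seealso [metglas_material()] for the default parameter set.
#' @export
magnetostrictive_material <- function(Ms, lambda_s, chi0,
                                      youngs_modulus, poisson_ratio, density,
                                      conductivity = 0,
                                      rel_permittivity = 1,
                                      rel_permeability = 1,
                                      eta_mech = 0) {
  stopifnot(is.numeric(Ms), length(Ms) == 1L, Ms > 0,
            lambda_s > 0, chi0 > 0,
            youngs_modulus > 0,
            poisson_ratio > 0, poisson_ratio < 0.5,
            density > 0, conductivity >= 0, eta_mech >= 0)
  structure(list(Ms = Ms, lambda_s = lambda_s, chi0 = chi0,
                 youngs_modulus = youngs_modulus,
                 poisson_ratio = poisson_ratio,
                 density = density,
                 conductivity = conductivity,
                 rel_permittivity = rel_permittivity,
                 rel_permeability = rel_permeability,
                 eta_mech = eta_mech,
                 Mr = 0),
            class = "magnetostrictive_material")
}

#' @export
print.magnetostrictive_material <- function(x, ...) {
  cat("<magnetostrictive_material>\n")
  cat(sprintf("  Ms        = %g A/m (mu0*Ms = %.3f T)\n", x$Ms, .mu0 * x$Ms))
  cat(sprintf("  lambda_s  = %g (%.3g ppm)\n", x$lambda_s, x$lambda_s * 1e6))
  cat(sprintf("  chi0      = %g\n", x$chi0))
  cat(sprintf("  E = %.3g Pa, nu = %g, rho = %g kg/m^3\n",
              x$youngs_modulus, x$poisson_ratio, x$density))
  cat(sprintf("  eta_mech  = %g\n", x$eta_mech))
  invisible(x)
}

#' Default MetGlas (2628 MB) core parameter set
#'
#' The amorphous-alloy parameter set used for the magnetostrictive core:
#' Ms = 700282 A/m, lambda_s = 12 ppm, chi0 = 200, E = 152 GPa, nu = 0.22,
#' rho = 7900 kg/m^3, sigma = 7.25e5 S/m, with a structural loss factor of
#' 1e-4.
#'
#' @return A [magnetostrictive_material()].
#' @examples
#' metglas_material()
#' @export
metglas_material <- function() {
  magnetostrictive_material(
    Ms = 700282, lambda_s = 12e-6, chi0 = 200,
    youngs_modulus = 152e9, poisson_ratio = 0.22, density = 7900,
    conductivity = 7.25e5, rel_permittivity = 1, rel_permeability = 1,
    eta_mech = 1e-4)
}

#' Piezoelectric material parameter set (strain-charge form)
#'
#' Stores the 6x6 elastic compliance at constant field `s_E` (1/Pa), the
#' 3x6 piezoelectric coupling matrix `d` (C/N), and the 3x3 relative
#' permittivity at constant stress, together with dielectric and
#' mechanical loss factors.  Losses are kept as real scalars; complex
#' frequency-domain moduli are formed on demand with
#' [complex_permittivity()] and [complex_stiffness()].
#'
#' @param compliance_sE 6x6 symmetric positive-definite compliance matrix, 1/Pa.
#' @param coupling_d 3x6 piezoelectric coupling matrix, C/N.
#' @param permittivity_rel 3x3 symmetric positive-definite relative
#'   permittivity (constant stress).
#' @param tan_delta Dielectric loss tangent.
#' @param eta_s Mechanical (structural) loss factor.
#' @param density Mass density, kg/m^3.
#' @param conductivity Electrical conductivity, S/m.
#' @return Object of class `piezoelectric_material`.
#' @export
piezoelectric_material <- function(compliance_sE, coupling_d, permittivity_rel,
                                   tan_delta = 0, eta_s = 0,
                                   density, conductivity = 0) {
  stopifnot(is.matrix(compliance_sE), all(dim(compliance_sE) == c(6, 6)),
            is.matrix(coupling_d), all(dim(coupling_d) == c(3, 6)),
            is.matrix(permittivity_rel), all(dim(permittivity_rel) == c(3, 3)),
            tan_delta >= 0, eta_s >= 0, density > 0, conductivity >= 0)
  if (max(abs(compliance_sE - t(compliance_sE))) > 1e-12 * max(abs(compliance_sE)))
    stop("compliance_sE must be symmetric")
  if (max(abs(permittivity_rel - t(permittivity_rel))) > 1e-12 * max(abs(permittivity_rel)))
    stop("permittivity_rel must be symmetric")
  if (min(eigen(compliance_sE, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("compliance_sE must be positive definite")
  if (min(eigen(permittivity_rel, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("permittivity_rel must be positive definite")
  structure(list(compliance_sE = compliance_sE,
                 coupling_d = coupling_d,
                 permittivity_rel = permittivity_rel,
                 tan_delta = tan_delta, eta_s = eta_s,
                 density = density, conductivity = conductivity),
            class = "piezoelectric_material")
}

#' @export
print.piezoelectric_material <- function(x, ...) {
  cat("<piezoelectric_material>\n")
  cat(sprintf("  s11 = %.3g 1/Pa, d33 = %.3g C/N, eps_r = %g\n",
              x$compliance_sE[1, 1], x$coupling_d[3, 3],
              x$permittivity_rel[1, 1]))
  cat(sprintf("  tan_delta = %g, eta_s = %g, rho = %g kg/m^3\n",
              x$tan_delta, x$eta_s, x$density))
  invisible(x)
}

#' Default aluminium nitride (AlN) shell parameter set
#'
#' Assembles the wurtzite (6mm symmetry) compliance, coupling and
#' permittivity of the AlN shell: s11 = s22 = s33 = 2.9e-12 1/Pa,
#' s12 = -0.93e-12, s13 = s23 = -0.5e-12, shear entries s44 = s55 and s66,
#' d15 = d24 = -3.8e-12 C/N, d31 = d32 = -1.9e-12 C/N, d33 = 5e-12 C/N,
#' eps_r = 9 I3, dielectric loss 1e-4, mechanical loss 1e-4,
#' rho = 3300 kg/m^3, sigma = 1e-6 S/m.
#'
#' The two printed shear compliances carry no index labels; the standard
#' 6mm assignment s44 = s55 = 8e-12, s66 = 7.7e-12 is used (it is also the
#' assignment consistent with the hexagonal identity s66 = 2 (s11 - s12))
#' and both entries are exposed as arguments.
#'
#' @param s44 Shear compliance s44 = s55, 1/Pa.
#' @param s66 In-plane shear compliance s66, 1/Pa.
#' @return A [piezoelectric_material()].
#' @examples
#' aln_material()$coupling_d[3, 3]
#' @export
aln_material <- function(s44 = 8e-12, s66 = 7.7e-12) {
  s11 <- 2.9e-12; s12 <- -0.93e-12; s13 <- -0.5e-12
  sE <- matrix(0, 6, 6)
  sE[1:3, 1:3] <- matrix(c(s11, s12, s13,
                           s12, s11, s13,
                           s13, s13, s11), 3, 3, byrow = TRUE)
  sE[4, 4] <- s44; sE[5, 5] <- s44; sE[6, 6] <- s66
  d <- matrix(0, 3, 6)
  d[1, 5] <- -3.8e-12
  d[2, 4] <- -3.8e-12
  d[3, 1] <- -1.9e-12; d[3, 2] <- -1.9e-12; d[3, 3] <- 5e-12
  piezoelectric_material(
    compliance_sE = sE, coupling_d = d,
    permittivity_rel = diag(9, 3),
    tan_delta = 1e-4, eta_s = 1e-4,
    density = 3300, conductivity = 1e-6)
}

#' Core-shell and coil geometry
#'
#' @param core_radius Magnetostrictive core radius, m (default 50 um,
#'   i.e. 100 um diameter).
#' @param shell_thickness Piezoelectric shell thickness, m (default 37.5 um).
#' @param coil_separation Distance between the two drive coils, m
#'   (default 800 um; the device sits midway).
#' @param coil_radius Drive coil radius, m (default 400 um).
#' @param coil_current Coil current amplitude, A (default 100 mA).
#' @return Object of class `core_shell_geometry`.
#' @export
core_shell_geometry <- function(core_radius = 50e-6,
                                shell_thickness = 37.5e-6,
                                coil_separation = 800e-6,
                                coil_radius = 400e-6,
                                coil_current = 0.1) {
  stopifnot(core_radius > 0, shell_thickness > 0,
            coil_separation > 0, coil_radius > 0, coil_current > 0)
  if (shell_thickness >= core_radius)
    stop("shell_thickness must be smaller than core_radius (thin shell)")
  structure(list(core_radius = core_radius,
                 shell_thickness = shell_thickness,
                 coil_separation = coil_separation,
                 coil_radius = coil_radius,
                 coil_current = coil_current),
            class = "core_shell_geometry")
}

#' @export
print.core_shell_geometry <- function(x, ...) {
  cat("<core_shell_geometry>\n")
  cat(sprintf("  core radius %.3g um, shell %.3g um\n",
              x$core_radius * 1e6, x$shell_thickness * 1e6))
  cat(sprintf("  coils: r = %.3g um, separation %.3g um, I = %g A\n",
              x$coil_radius * 1e6, x$coil_separation * 1e6, x$coil_current))
  invisible(x)
}

#' Elastic stiffness from compliance
#'
#' Inverts the 6x6 compliance matrix, `c_E = s_E^-1`.
#'
#' @param x A [piezoelectric_material()] or a 6x6 compliance matrix, 1/Pa.
#' @return 6x6 stiffness matrix, Pa.
#' @export
stiffness_from_compliance <- function(x) {
  s <- if (inherits(x, "piezoelectric_material")) x$compliance_sE else x
  stopifnot(is.matrix(s), nrow(s) == ncol(s))
  rc <- rcond(s)
  if (!is.finite(rc) || rc < 1e-14)
    stop("compliance matrix is singular or near-singular")
  solve(s)
}

#' Complex (lossy) permittivity and stiffness
#'
#' Frequency-domain loss representation: the permittivity is multiplied by
#' `(1 - 1i * tan_delta)` and the stiffness by `(1 + 1i * eta_s)`.
#'
#' @param mat A [piezoelectric_material()].
#' @return Complex 3x3 permittivity matrix (relative) or complex 6x6
#'   stiffness matrix (Pa).
#' @export
complex_permittivity <- function(mat) {
  stopifnot(inherits(mat, "piezoelectric_material"))
  (1 - 1i * mat$tan_delta) * mat$permittivity_rel
}

#' @rdname complex_permittivity
#' @export
complex_stiffness <- function(mat) {
  stopifnot(inherits(mat, "piezoelectric_material"))
  (1 + 1i * mat$eta_s) * stiffness_from_compliance(mat)
}

#' Serialize and restore material sets
#'
#' Materials and geometry round-trip through JSON (single objects) or a
#' structured YAML configuration (see [pipeline_config()]).
#'
#' @param x A material or geometry object.
#' @param path File path.
#' @return `write_material_json` invisibly returns `path`;
#'   `read_material_json` returns the restored object.
#' @export
write_material_json <- function(x, path) {
  cls <- class(x)[1]
  payload <- list(class = cls, fields = unclass(x))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_material_json
#' @export
read_material_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  f <- payload$fields
  switch(payload$class,
    magnetostrictive_material = magnetostrictive_material(
      Ms = f$Ms, lambda_s = f$lambda_s, chi0 = f$chi0,
      youngs_modulus = f$youngs_modulus, poisson_ratio = f$poisson_ratio,
      density = f$density, conductivity = f$conductivity,
      rel_permittivity = f$rel_permittivity,
      rel_permeability = f$rel_permeability, eta_mech = f$eta_mech),
    piezoelectric_material = piezoelectric_material(
      compliance_sE = matrix(unlist(f$compliance_sE), 6, 6, byrow = TRUE),
      coupling_d = matrix(unlist(f$coupling_d), 3, 6, byrow = TRUE),
      permittivity_rel = matrix(unlist(f$permittivity_rel), 3, 3, byrow = TRUE),
      tan_delta = f$tan_delta, eta_s = f$eta_s,
      density = f$density, conductivity = f$conductivity),
    core_shell_geometry = core_shell_geometry(
      core_radius = f$core_radius, shell_thickness = f$shell_thickness,
      coil_separation = f$coil_separation, coil_radius = f$coil_radius,
      coil_current = f$coil_current),
    stop("unknown serialized class: ", payload$class))
}
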