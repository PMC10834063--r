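#' Shell stress transferred from core strain
#'
#' Perfect-bonding thin-shell approximation: the interface strain of the
#' shell equals the core surface strain scaled by the geometric transfer
#' factor `R_core / (R_core + t_shell)`, and the shell stress follows
#' from the shell stiffness, `sigma = c_E (R/(R+t)) eps_core`.  Linear in
#' the core strain.
#'
#' @param core_strain Core strain, Voigt 6-vector (dimensionless).
#' @param geom A [core_shell_geometry()].
#' @param shell_mat A [piezoelectric_material()].
#' @return Shell stress, Voigt 6-vector, Pa.
#' @export
shell_stress_from_strain <- function(core_strain, geom = core_shell_geometry(),
                                     shell_mat = aln_material()) {
  stopifnot(length(core_strain) == 6,
            inherits(geom, "core_shell_geometry"),
            inherits(shell_mat, "piezoelectric_material"))
  transfer <- geom$core_radius / (geom$core_radius + geom$shell_thickness)
  cE <- stiffness_from_compliance(shell_mat)
  as.numeric(cE %*% (transfer * core_strain))
}

#' Open-circuit electric field in the piezoelectric shell
#'
#' With zero free charge in the insulating shell and an open-circuit
#' (zero electric displacement) surface, the strain-charge relations give
#' `E = -(eps0 epsT)^-1 d sigma`.
#'
#' @param sigma Shell stress, Voigt 6-vector, Pa.
#' @param shell_mat A [piezoelectric_material()].
#' @return Electric field 3-vector, V/m.
#' @export
open_circuit_field <- function(sigma, shell_mat = aln_material()) {
  stopifnot(length(sigma) == 6,
            inherits(shell_mat, "piezoelectric_material"))
  eps <- .eps0 * shell_mat$permittivity_rel
  as.numeric(-solve(eps, shell_mat$coupling_d %*% sigma))
}

#' Magnetoelectric coupling coefficient from field amplitudes
#'
#' `alpha_ME = dE / dH`, converted from SI field units to the
#' conventional V/(m Oe) with 1 Oe = 1e3 / (4 pi) A/m.
#'
#' @param E_response_amplitude Electric-field response, V/m.
#' @param H_drive_amplitude Magnetic drive amplitude, A/m (> 0).
#' @return Coupling coefficient, V/(m Oe), reported as a magnitude.
#' @examples
#' me_coefficient(1, 1)   # 1 (V/m)/(A/m) = 79.5775 V/(m Oe)
#' @export
me_coefficient <- function(E_response_amplitude, H_drive_amplitude) {
  if (any(H_drive_amplitude <= 0)) stop("H_drive_amplitude must be positive")
  abs(E_response_amplitude) / H_drive_amplitude * .oersted
}

#' Static magnetoelectric chain: applied field to shell electric field
#'
#' Composes the full reduced-order chain at one operating point: applied
#' axial field -> self-consistent magnetization -> magnetostrictive
#' strain -> shell stress -> open-circuit field.  Returns the axial
#' (poling-direction) electric-field component.
#'
#' @param H_applied Applied axial field, A/m.
#' @param core_mat A [magnetostrictive_material()].
#' @param shell_mat A [piezoelectric_material()].
#' @param geom A [core_shell_geometry()].
#' @return Axial electric field `E_z`, V/m.
#' @export
me_chain_field <- function(H_applied, core_mat = metglas_material(),
                           shell_mat = aln_material(),
                           geom = core_shell_geometry()) {
  vapply(H_applied, function(h) {
    st <- self_consistent_state(c(0, 0, h), mat = core_mat)
    sigma <- shell_stress_from_strain(st$strain_me, geom, shell_mat)
    open_circuit_field(sigma, shell_mat)[3]
  }, numeric(1))
}

#' Small-signal coupling coefficient at a bias point
#'
#' Two-point central difference of the static chain around the operating
#' bias, converted with [me_coefficient()].
#'
#' @param bias_B Operating bias, T (applied flux density).
#' @param core_mat,shell_mat,geom Chain components.
#' @param dH Half-step of the central difference, A/m.
#' @return Coupling coefficient, V/(m Oe).
#' @export
me_coefficient_at_bias <- function(bias_B, core_mat = metglas_material(),
                                   shell_mat = aln_material(),
                                   geom = core_shell_geometry(),
                                   dH = 50) {
  h0 <- bias_B / .mu0
  dE <- me_chain_field(h0 + dH, core_mat, shell_mat, geom) -
    me_chain_field(h0 - dH, core_mat, shell_mat, geom)
  me_coefficient(dE / (2 * dH), 1)
}

#' Bias and shell-thickness sweep of the coupling coefficient
#'
#' Evaluates the small-signal `alpha_ME` on a (bias, thickness) grid and
#' reports the argmax cell.  Deterministic.
#'
#' @param bias_range Bias grid, T.
#' @param thickness_range Shell-thickness grid, m.
#' @param core_mat,shell_mat Chain materials.
#' @param geom Template geometry (thickness is overridden per cell).
#' @return Object of class `coupling_sweep`: data frame with columns
#'   `bias_T`, `thickness_m`, `alpha_me_V_per_m_Oe`; attribute `argmax`
#'   holds the maximizing row.
#' @export
coupling_sweep <- function(bias_range = seq(0, 1, by = 0.025),
                           thickness_range = 37.5e-6,
                           core_mat = metglas_material(),
                           shell_mat = aln_material(),
                           geom = core_shell_geometry()) {
  grid <- expand.grid(bias_T = bias_range, thickness_m = thickness_range)
  grid$alpha_me_V_per_m_Oe <- mapply(function(b, th) {
    g <- geom; g$shell_thickness <- th
    me_coefficient_at_bias(b, core_mat, shell_mat, g)
  }, grid$bias_T, grid$thickness_m)
  i <- which.max(grid$alpha_me_V_per_m_Oe)
  structure(grid, argmax = grid[i, ],
            class = c("coupling_sweep", "data.frame"))
}

#' @export
print.coupling_sweep <- function(x, ...) {
  am <- attr(x, "argmax")
  cat(sprintf(
    "<coupling_sweep> %d cells; max alpha_ME = %.4g V/(m Oe) at bias %.3g T, shell %.3g um\n",
    nrow(x), am$alpha_me_V_per_m_Oe, am$bias_T, am$thickness_m * 1e6))
  invisible(x)
}

#' Shell surface potential difference
#'
#' Models the potential difference between two readout points on the
#' shell surface as `V0 = E_z * electrode_separation` (default 3 um).
#'
#' @param E_z Axial electric field, V/m (scalar or vector).
#' @param electrode_separation Arc distance between the readout points, m.
#' @return Potential difference, V.
#' @export
surface_potential <- function(E_z, electrode_separation = 3e-6) {
  stopifnot(electrode_separation > 0)
  E_z * electrode_separation
}
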