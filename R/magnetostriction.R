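#' Langevin function
#'
#' `L(x) = coth(x) - 1/x`, the classical anhysteretic magnetization law.
#' Odd, monotone increasing, bounded by (-1, 1).  A series expansion
#' `x/3 - x^3/45` is used for `|x| < 1e-4` for numerical stability near 0.
#'
#' @param x Numeric vector.
#' @return `L(x)`, same shape as `x`.
#' @examples
#' langevin(c(0, 3, 50))
#' @export
langevin <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  out <- numeric(length(x))
  small <- abs(x) < 1e-4
  out[small] <- x[small] / 3 - x[small]^3 / 45
  xb <- x[!small]
  out[!small] <- 1 / tanh(xb) - 1 / xb
  out
}

#' Anhysteretic magnetization of an effective field
#'
#' `M = Ms L(3 chi0 |H_eff| / Ms) H_eff / |H_eff|`.  The argument scaling
#' `3 chi0 / Ms` makes the small-field slope equal the initial
#' susceptibility `chi0`.
#'
#' @param H_eff Effective magnetic field, 3-vector, A/m.
#' @param mat A [magnetostrictive_material()].
#' @return Magnetization 3-vector, A/m, with `|M| < Ms`.
#' @export
magnetization_of_field <- function(H_eff, mat) {
  stopifnot(length(H_eff) == 3, all(is.finite(H_eff)),
            inherits(mat, "magnetostrictive_material"))
  h <- sqrt(sum(H_eff^2))
  if (h == 0) return(c(0, 0, 0))
  mat$Ms * langevin(3 * mat$chi0 * h / mat$Ms) * H_eff / h
}

#' Magnetostrictive strain of a magnetization state
#'
#' Deviatoric quadratic law
#' `eps_me = (3/2) (lambda_s / Ms^2) dev(M x M)`, returned in Voigt order
#' (11, 22, 33, 23, 13, 12) with engineering shear strains.  Traceless by
#' construction and invariant under `M -> -M` (the quadratic dependence is
#' what mixes two drive tones into their difference frequency).
#'
#' @param M Magnetization 3-vector, A/m.
#' @param mat A [magnetostrictive_material()].
#' @return Voigt 6-vector of strain (dimensionless).
#' @export
me_strain <- function(M, mat) {
  stopifnot(length(M) == 3, all(is.finite(M)),
            inherits(mat, "magnetostrictive_material"))
  outer_mm <- tcrossprod(M)
  dev <- outer_mm - diag(sum(diag(outer_mm)) / 3, 3)
  eps <- 1.5 * mat$lambda_s / mat$Ms^2 * dev
  # engineering shears (2 * tensor shear) in Voigt positions 4:6
  c(eps[1, 1], eps[2, 2], eps[3, 3],
    2 * eps[2, 3], 2 * eps[1, 3], 2 * eps[1, 2])
}

.voigt_to_tensor <- function(v) {
  matrix(c(v[1], v[6], v[5],
           v[6], v[2], v[4],
           v[5], v[4], v[3]), 3, 3)
}

#' Stress-corrected effective field
#'
#' `H_eff = H + 3 lambda_s / (mu0 Ms^2) S M`, where `S` is the Cauchy
#' stress tensor (given as a Voigt 6-vector, Pa).  Reduces to `H` for zero
#' stress or zero magnetization.
#'
#' @param H Magnetic field 3-vector, A/m.
#' @param S_voigt Stress in Voigt order (11, 22, 33, 23, 13, 12), Pa.
#' @param M Magnetization 3-vector, A/m.
#' @param mat A [magnetostrictive_material()].
#' @return Effective field 3-vector, A/m.
#' @export
effective_field <- function(H, S_voigt, M, mat) {
  stopifnot(length(H) == 3, length(S_voigt) == 6, length(M) == 3,
            inherits(mat, "magnetostrictive_material"))
  S <- .voigt_to_tensor(S_voigt)
  as.numeric(H + 3 * mat$lambda_s / (.mu0 * mat$Ms^2) * (S %*% M))
}

# scalar fixed point for a field applied along one axis; used by the
# vectorial solver and (warm-started) by transduce()
.solve_M_axial <- function(H_app, mat, S_par = 0, N_demag = 1 / 3,
                           M0 = 0, gamma = 0.5, tol = 1e-10,
                           max_iter = 10000L) {
  Ms <- mat$Ms
  k_stress <- 3 * mat$lambda_s / (.mu0 * Ms^2) * S_par
  # Picard slope is bounded by chi0 * |N - k_stress|; cap the damping so
  # the damped iteration is a contraction even at the steepest point.
  gamma <- min(gamma, 1.5 / (1 + mat$chi0 * (N_demag + abs(k_stress))))
  M <- M0
  res <- Inf
  for (it in seq_len(max_iter)) {
    H_int <- H_app - N_demag * M
    H_eff <- H_int + k_stress * M
    target <- Ms * langevin(3 * mat$chi0 * abs(H_eff) / Ms) * sign(H_eff)
    M_new <- (1 - gamma) * M + gamma * target
    res <- abs(M_new - M) / Ms
    M <- M_new
    if (res <= tol) return(list(M = M, iter = it, residual = res))
  }
  stop(sprintf(
    "magnetization fixed point did not converge in %d iterations (last residual %.3g)",
    max_iter, res))
}

#' Self-consistent magnetization state of the spherical core
#'
#' Damped fixed-point solution of the coupled magnetization / effective
#' field / strain relations for a uniformly magnetized sphere.  The
#' internal field is `H_applied - N M` with demagnetizing factor
#' `N = 1/3`, and the external stress feeds back on the effective field.
#' This single-macrospin reduction replaces a spatially resolved field
#' solve.
#'
#' @param H_applied Applied field 3-vector, A/m (uniform far field).
#' @param S_ext External stress, Voigt 6-vector, Pa (default zero).
#' @param mat A [magnetostrictive_material()].
#' @param N_demag Demagnetizing factor (1/3 for a sphere).
#' @param gamma Fixed-point damping factor in (0, 1].
#' @param tol Convergence tolerance on `|dM| / Ms`.
#' @param max_iter Maximum iterations before a diagnostic error.
#' @return Object of class `magnetization_state`: list with `H_applied`,
#'   `H_internal`, `H_eff`, `M`, `strain_me` (Voigt), `iterations`,
#'   `residual`.
#' @export
self_consistent_state <- function(H_applied, S_ext = rep(0, 6),
                                  mat = metglas_material(),
                                  N_demag = 1 / 3, gamma = 0.5,
                                  tol = 1e-10, max_iter = 10000L) {
  stopifnot(length(H_applied) == 3, all(is.finite(H_applied)),
            length(S_ext) == 6, inherits(mat, "magnetostrictive_material"))
  Ms <- mat$Ms
  S <- .voigt_to_tensor(S_ext)
  k_stress <- 3 * mat$lambda_s / (.mu0 * Ms^2) * max(abs(S_ext))
  gamma <- min(gamma, 1.5 / (1 + mat$chi0 * (N_demag + k_stress)))
  M <- c(0, 0, 0)
  for (it in seq_len(max_iter)) {
    H_int <- H_applied - N_demag * M
    H_eff <- H_int + 3 * mat$lambda_s / (.mu0 * Ms^2) * as.numeric(S %*% M)
    target <- magnetization_of_field(H_eff, mat)
    M_new <- (1 - gamma) * M + gamma * target
    res <- sqrt(sum((M_new - M)^2)) / Ms
    M <- M_new
    if (res <= tol) {
      H_int <- H_applied - N_demag * M
      H_eff <- H_int + 3 * mat$lambda_s / (.mu0 * Ms^2) * as.numeric(S %*% M)
      return(structure(list(H_applied = H_applied, H_internal = H_int,
                            H_eff = H_eff, M = M,
                            strain_me = me_strain(M, mat),
                            iterations = it, residual = res),
                       class = "magnetization_state"))
    }
  }
  stop(sprintf(
    "self_consistent_state did not converge in %d iterations (last residual %.3g)",
    max_iter, res))
}

#' @export
print.magnetization_state <- function(x, ...) {
  cat("<magnetization_state>\n")
  cat(sprintf("  |M| = %.6g A/m, strain_zz = %.4g, %d iterations\n",
              sqrt(sum(x$M^2)), x$strain_me[3], x$iterations))
  invisible(x)
}

#' DC bias sweep of the parallel magnetostriction
#'
#' Evaluates the self-consistent parallel strain `lambda(B)` on a grid of
#' applied flux density (the reported bias axis is `mu0 * H_applied`),
#' differentiates by central differences, and locates the positive-bias
#' slope maximum (the optimal operating bias for linear magnetoelectric
#' conversion).  Ties in the argmax are broken toward the smallest bias.
#'
#' @param B_range Applied flux-density grid, T.  Should cover saturation
#'   symmetrically; default `seq(-1, 1, by = 0.005)`.
#' @param mat A [magnetostrictive_material()].
#' @param S_par Optional parallel external stress, Pa (stress feedback).
#' @return Object of class `bias_curve`: data frame with columns `B_T`,
#'   `lambda`, `dlambda_dB`, plus attributes `optimum_bias` (T) and
#'   `optimum_window` (T, bias interval where the slope exceeds half its
#'   maximum).
#' @export
bias_sweep <- function(B_range = seq(-1, 1, by = 0.005),
                       mat = metglas_material(), S_par = 0) {
  stopifnot(is.numeric(B_range), length(B_range) >= 5,
            inherits(mat, "magnetostrictive_material"))
  B_range <- sort(B_range)
  lam <- vapply(B_range, function(B) {
    sol <- .solve_M_axial(B / .mu0, mat, S_par = S_par)
    mat$lambda_s * (sol$M / mat$Ms)^2
  }, numeric(1))
  n <- length(B_range)
  dl <- rep(NA_real_, n)
  dl[2:(n - 1)] <- (lam[3:n] - lam[1:(n - 2)]) / (B_range[3:n] - B_range[1:(n - 2)])
  pos <- which(B_range > 0 & !is.na(dl))
  i_opt <- pos[which.max(dl[pos])]   # which.max returns the first maximum:
                                     # smallest bias wins on ties
  half <- dl[i_opt] / 2
  win <- range(B_range[pos][dl[pos] >= half])
  out <- data.frame(B_T = B_range, lambda = lam, dlambda_dB = dl)
  structure(out,
            optimum_bias = B_range[i_opt],
            optimum_window = win,
            class = c("bias_curve", "data.frame"))
}

#' @export
print.bias_curve <- function(x, ...) {
  cat("<bias_curve> ", nrow(x), " bias points\n", sep = "")
  cat(sprintf("  optimum bias %.3f T, half-maximum slope window [%.3f, %.3f] T\n",
              attr(x, "optimum_bias"), attr(x, "optimum_window")[1],
              attr(x, "optimum_window")[2]))
  cat(sprintf("  lambda range [%.3g, %.3g]\n", min(x$lambda), max(x$lambda)))
  invisible(x)
}

#' @rdname bias_sweep
#' @param x A `bias_curve`.
#' @param path CSV output path (columns `B_T`, `lambda`, `dlambda_dB`).
#' @export
write_bias_curve <- function(x, path) {
  stopifnot(inherits(x, "bias_curve"))
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Recover Langevin parameters from a bias curve
#'
#' Least-squares fit of `lambda_s` and `chi0` to a measured or synthetic
#' `lambda(B)` curve using the same self-consistent chain.  Used as a
#' parameter-identifiability check.
#'
#' @param curve A [bias_sweep()] result (or data frame with `B_T`, `lambda`).
#' @param mat Template material supplying the fixed parameters.
#' @param start Named start values, defaults perturb the template.
#' @return Named vector with fitted `lambda_s` and `chi0`.
#' @export
fit_bias_curve <- function(curve, mat = metglas_material(),
                           start = c(lambda_s = mat$lambda_s * 1.3,
                                     chi0 = mat$chi0 * 0.7)) {
  B <- curve$B_T
  y <- curve$lambda
  obj <- function(p) {
    m <- mat
    m$lambda_s <- exp(p[1]); m$chi0 <- exp(p[2])
    pred <- vapply(B, function(b) {
      sol <- .solve_M_axial(b / .mu0, m)
      m$lambda_s * (sol$M / m$Ms)^2
    }, numeric(1))
    sum((pred - y)^2) / sum(y^2)
  }
  fit <- optim(log(start), obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 2000))
  c(lambda_s = exp(fit$par[[1]]), chi0 = exp(fit$par[[2]]))
}
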