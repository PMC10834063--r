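#' Spherical Bessel function of the first kind
#'
#' `j_l(x) = sqrt(pi / (2 x)) J_{l + 1/2}(x)`, evaluated through the
#' half-integer-order Bessel function.
#'
#' @param l Nonnegative integer order.
#' @param x Positive numeric vector.
#' @return `j_l(x)`.
#' @export
spherical_bessel_j <- function(l, x) {
  stopifnot(l >= 0, all(x > 0))
  sqrt(pi / (2 * x)) * besselJ(x, l + 0.5)
}

# Characteristic function of torsional free vibrations of a homogeneous
# elastic sphere: roots in eta = w R / c_s of
#   (l - 1) j_l(eta) - eta j_{l+1}(eta) = 0,  l >= 2
# (l = 1 admits only rigid rotation).
.torsional_char <- function(l, eta) {
  (l - 1) * spherical_bessel_j(l, eta) - eta * spherical_bessel_j(l + 1, eta)
}

# Spheroidal (Lamb) determinant for a free homogeneous sphere.
# alpha = w R / c_p, beta = w R / c_s; root condition det = 0.
.spheroidal_det <- function(l, beta, ratio_sp) {
  alpha <- beta * ratio_sp   # ratio_sp = c_s / c_p < 1
  jl_a <- spherical_bessel_j(l, alpha)
  jl1_a <- spherical_bessel_j(l + 1, alpha)
  jl_b <- spherical_bessel_j(l, beta)
  jl1_b <- spherical_bessel_j(l + 1, beta)
  e11 <- (l^2 - l - beta^2 / 2) * jl_a + 2 * alpha * jl1_a
  e21 <- (l - 1) * jl_a - alpha * jl1_a
  if (l == 0) return(e11)
  e12 <- l * (l + 1) * ((l - 1) * jl_b - beta * jl1_b)
  e22 <- (l^2 - 1 - beta^2 / 2) * jl_b + beta * jl1_b
  e11 * e22 - e12 * e21
}

.wave_speeds <- function(mat) {
  E <- mat$youngs_modulus; nu <- mat$poisson_ratio; rho <- mat$density
  cs <- sqrt(E / (2 * (1 + nu) * rho))
  cp <- sqrt(E * (1 - nu) / ((1 + nu) * (1 - 2 * nu) * rho))
  c(cs = cs, cp = cp)
}

.bracket_roots <- function(fun, grid) {
  vals <- fun(grid)
  sgn <- sign(vals)
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  vapply(idx, function(i) {
    uniroot(fun, lower = grid[i], upper = grid[i + 1],
            tol = 1e-12 * grid[i + 1])$root
  }, numeric(1))
}

#' Free-vibration eigenfrequencies of the elastic core sphere
#'
#' Analytical mode search for a homogeneous isotropic elastic sphere
#' (shell ignored): the torsional branch solves a transcendental equation
#' in `eta = w R / c_s` with spherical Bessel functions, and the
#' spheroidal branch solves the classical 2x2 (Lamb) determinant in
#' `w R / c_p` and `w R / c_s`.  Roots are located by dense bracketing on
#' a uniform grid followed by bisection polish, deduplicated at relative
#' tolerance 1e-8.  Structural damping enters as a uniform loss factor:
#' each real mode `f` becomes `f (1 + i eta_mech / 2)` with damping ratio
#' `zeta = eta_mech / 2`.
#'
#' @param mat A [magnetostrictive_material()] (isotropic elasticity and
#'   loss factor).
#' @param radius Sphere radius, m.
#' @param f_range Search range `(f_lo, f_hi)`, Hz.
#' @param l_max Largest angular order searched (default 6).
#' @param points_per_decade Scan density (default 20000).
#' @return Object of class `mode_list`: data frame with columns
#'   `f_real_Hz`, `f_imag_Hz`, `branch`, `l`, `overtone`, `zeta`, sorted
#'   by `f_real_Hz`.
#' @export
sphere_mode_frequencies <- function(mat = metglas_material(),
                                    radius = 50e-6,
                                    f_range = c(30e6, 240e6),
                                    l_max = 6L,
                                    points_per_decade = 20000L) {
  stopifnot(inherits(mat, "magnetostrictive_material"),
            radius > 0, length(f_range) == 2, all(f_range > 0),
            f_range[2] > f_range[1])
  cs <- .wave_speeds(mat)[["cs"]]
  cp <- .wave_speeds(mat)[["cp"]]
  eta_lo <- 2 * pi * f_range[1] * radius / cs
  eta_hi <- 2 * pi * f_range[2] * radius / cs
  npts <- max(200L,
              ceiling(points_per_decade * log10(eta_hi / eta_lo)))
  grid <- seq(eta_lo, eta_hi, length.out = npts)

  rows <- list()
  for (l in 2:l_max) {
    r <- .bracket_roots(function(x) .torsional_char(l, x), grid)
    if (length(r))
      rows[[length(rows) + 1L]] <- data.frame(
        eta = r, branch = "torsional", l = l)
  }
  for (l in 0:l_max) {
    r <- .bracket_roots(function(x) .spheroidal_det(l, x, cs / cp), grid)
    if (length(r))
      rows[[length(rows) + 1L]] <- data.frame(
        eta = r, branch = "spheroidal", l = l)
  }
  if (!length(rows)) stop("no eigenmodes found in the requested range")
  df <- do.call(rbind, rows)
  # deduplicate within (branch, l) at relative tolerance 1e-8
  df <- df[order(df$branch, df$l, df$eta), ]
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))[-1]) {
    if (df$branch[i] == df$branch[i - 1] && df$l[i] == df$l[i - 1] &&
        abs(df$eta[i] - df$eta[i - 1]) <= 1e-8 * df$eta[i])
      keep[i] <- FALSE
  }
  df <- df[keep, ]
  df$overtone <- stats::ave(df$eta, df$branch, df$l,
                            FUN = seq_along)
  f_real <- df$eta * cs / (2 * pi * radius)
  zeta <- mat$eta_mech / 2
  out <- data.frame(f_real_Hz = f_real,
                    f_imag_Hz = f_real * zeta,
                    branch = df$branch, l = df$l,
                    overtone = as.integer(df$overtone),
                    zeta = zeta)
  out <- out[order(out$f_real_Hz), ]
  rownames(out) <- NULL
  structure(out, radius = radius, c_s = cs, c_p = cp,
            class = c("mode_list", "data.frame"))
}

#' @export
print.mode_list <- function(x, ...) {
  cat(sprintf("<mode_list> %d modes, R = %.3g um, c_s = %.4g m/s\n",
              nrow(x), attr(x, "radius") * 1e6, attr(x, "c_s")))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("  ...\n")
  invisible(x)
}

#' @rdname sphere_mode_frequencies
#' @param x A `mode_list`.
#' @param path CSV output path.
#' @export
write_mode_list <- function(x, path) {
  stopifnot(inherits(x, "mode_list"))
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Modal damping ratio of a complex eigenfrequency
#'
#' `zeta = Im(f) / |f|`.
#'
#' @param f_complex Complex frequency (Hz); vectorized.
#' @return Damping ratio(s).
#' @examples
#' damping_ratio(complex(real = 100e6, imaginary = 1e6))
#' @export
damping_ratio <- function(f_complex) {
  if (any(Mod(f_complex) == 0)) stop("zero frequency has no damping ratio")
  Im(f_complex) / Mod(f_complex)
}

#' Select the two drive frequencies for temporal interference
#'
#' Picks, among modes with damping ratio at most `zeta_max`, the pair
#' with the lowest summed damping whose separation is at least
#' `min_separation`; ties are broken toward the lower first frequency,
#' then the lower second.
#'
#' @param modes A [sphere_mode_frequencies()] result (or data frame with
#'   `f_real_Hz` and `zeta`).
#' @param min_separation Minimum `|f2 - f1|`, Hz.
#' @param zeta_max Damping-ratio ceiling.
#' @return Named numeric vector `c(f1, f2)`, Hz, with `f1 < f2`.
#' @export
select_mti_pair <- function(modes, min_separation, zeta_max = Inf) {
  f <- modes$f_real_Hz
  z <- modes$zeta
  ok <- which(z <= zeta_max)
  if (length(ok) < 2)
    stop("fewer than two modes satisfy zeta <= zeta_max")
  cand <- NULL
  for (i in ok) for (j in ok) {
    if (f[j] - f[i] >= min_separation)
      cand <- rbind(cand, c(z[i] + z[j], f[i], f[j]))
  }
  if (is.null(cand)) {
    stop(sprintf(
      paste0("no mode pair separated by >= %.4g Hz; candidates (Hz): %s"),
      min_separation, paste(signif(f, 6), collapse = ", ")))
  }
  cand <- cand[order(cand[, 1], cand[, 2], cand[, 3]), , drop = FALSE]
  c(f1 = cand[1, 2], f2 = cand[1, 3])
}
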