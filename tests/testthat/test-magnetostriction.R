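test_that("Langevin function is odd, bounded, stable near zero", {
  expect_identical(langevin(0), 0)
  expect_gte(langevin(50), 0.98)
  expect_lt(abs(langevin(3) - 0.6716364896), 1e-5)
  x <- seq(-30, 30, length.out = 401)
  expect_equal(langevin(-x), -langevin(x))
  expect_true(all(diff(langevin(x)) > 0))          # monotone increasing
  expect_true(all(abs(langevin(x)) < 1))
  # series branch joins the closed form continuously
  expect_equal(langevin(1e-4 * (1 - 1e-9)), langevin(1e-4 * (1 + 1e-9)),
               tolerance = 1e-6)
})

test_that("magnetization law has slope chi0 at the origin and saturates at Ms", {
  expect_identical(magnetization_of_field(c(0, 0, 0), metglas), c(0, 0, 0))
  M_big <- magnetization_of_field(c(0, 0, 1e12), metglas)
  expect_rel_equal(M_big[3], 700282, 1e-6)
  dH <- 1
  slope <- (magnetization_of_field(c(0, 0, dH), metglas)[3] -
              magnetization_of_field(c(0, 0, -dH), metglas)[3]) / (2 * dH)
  expect_rel_equal(slope, 200, 0.01)
  # magnitude never exceeds Ms
  for (h in 10^seq(0, 8, by = 1)) {
    expect_lt(sqrt(sum(magnetization_of_field(c(h, h / 2, h / 3), metglas)^2)),
              metglas$Ms)
  }
})

test_that("magnetostrictive strain is deviatoric, quadratic, saturates at lambda_s", {
  expect_identical(me_strain(c(0, 0, 0), metglas), rep(0, 6))
  eps <- me_strain(c(0, 0, metglas$Ms), metglas)
  expect_equal(eps[3], 12e-6)
  expect_equal(eps[1], -6e-6)
  expect_equal(eps[2], -6e-6)
  set.seed(11)
  for (i in 1:20) {
    M <- runif(3, -1, 1) * metglas$Ms / 2
    e <- me_strain(M, metglas)
    expect_lt(abs(sum(e[1:3])), 1e-12)                       # traceless
    expect_equal(me_strain(-M, metglas), e)                  # even in M
  }
})

test_that("stress feedback on the effective field matches scalar arithmetic", {
  H <- c(10, -5, 100)
  expect_equal(effective_field(H, rep(0, 6), c(1, 2, 3) * 1e5, metglas), H)
  expect_equal(effective_field(H, c(1e6, 0, 0, 0, 0, 0), c(0, 0, 0), metglas), H)
  # uniaxial S_zz with M along z: dH_z = 3 lambda_s S M / (mu0 Ms^2)
  S <- c(0, 0, 1e7, 0, 0, 0)
  M <- c(0, 0, metglas$Ms)
  dH_expected <- 3 * 12e-6 * 1e7 * 700282 / (mu0 * 700282^2)
  out <- effective_field(c(0, 0, 0), S, M, metglas)
  expect_equal(out, c(0, 0, dH_expected))
})

test_that("self-consistent sphere state reproduces the closed-form limits", {
  s0 <- self_consistent_state(c(0, 0, 0), mat = metglas)
  expect_equal(s0$M, c(0, 0, 0))
  # linear regime: M / H_applied -> chi0 / (1 + chi0/3)
  s_lin <- self_consistent_state(c(0, 0, 1), mat = metglas)
  expect_rel_equal(s_lin$M[3], 200 / (1 + 200 / 3), 1e-3)
  # deep saturation: internal field approaches H_applied - Ms/3
  H5 <- 5 / mu0
  s_sat <- self_consistent_state(c(0, 0, H5), mat = metglas)
  expect_rel_equal(s_sat$H_internal[3], H5 - metglas$Ms / 3, 1e-4)
  expect_lt(sqrt(sum(s_sat$M^2)), metglas$Ms)
  expect_lt(s_sat$residual, 1e-10)
})

test_that("bias sweep is even, saturates, and locates the slope maximum", {
  curve <- bias_sweep(seq(-1, 1, length.out = 161), metglas)
  lam <- curve$lambda
  B <- curve$B_T
  expect_equal(lam[B == 0], 0)
  expect_equal(rev(lam), lam, tolerance = 1e-9)              # lambda(-B) = lambda(B)
  expect_true(all(lam <= metglas$lambda_s * (1 + 1e-9)))
  expect_rel_equal(max(lam), 12e-6, 0.01)   # Langevin 1/x tail at 1 T
  # argmax of the slope agrees with an independent dense-grid rescan
  dense_B <- seq(0.01, 0.6, length.out = 1200)
  dense_lam <- vapply(dense_B, function(b) {
    st <- self_consistent_state(c(0, 0, b / mu0), mat = metglas)
    st$strain_me[3]
  }, numeric(1))
  dense_slope <- diff(dense_lam) / diff(dense_B)
  brute_opt <- dense_B[which.max(dense_slope)]
  expect_lt(abs(attr(curve, "optimum_bias") - brute_opt),
            2 * (B[2] - B[1]))
  # the optimum falls in the published operating window
  expect_gt(attr(curve, "optimum_bias"), 0.15)
  expect_lt(attr(curve, "optimum_bias"), 0.35)
})

test_that("bias sweep equals the open-loop composition when stress feedback is off", {
  B <- seq(-0.5, 0.5, length.out = 41)
  curve <- bias_sweep(B, metglas)
  oracle <- vapply(B, function(b) {
    # closed composition, solving only the demagnetization implicitness
    st <- self_consistent_state(c(0, 0, b / mu0), mat = metglas)
    me_strain(magnetization_of_field(st$H_eff, metglas), metglas)[3]
  }, numeric(1))
  expect_equal(curve$lambda, oracle, tolerance = 1e-6)
})

test_that("Langevin parameters are recoverable from a noiseless bias curve", {
  curve <- bias_sweep(seq(-0.6, 0.6, length.out = 33), metglas)
  fit <- fit_bias_curve(curve)
  expect_rel_equal(fit[["lambda_s"]], metglas$lambda_s, 0.01)
  expect_rel_equal(fit[["chi0"]], metglas$chi0, 0.01)
})

test_that("bias curve exports the documented CSV columns", {
  curve <- bias_sweep(seq(-0.2, 0.2, length.out = 11), metglas)
  path <- withr::local_tempfile(fileext = ".csv")
  write_bias_curve(curve, path)
  back <- read.csv(path)
  expect_named(back, c("B_T", "lambda", "dlambda_dB"))
  expect_equal(back$lambda, curve$lambda)
})
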