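test_that("torsional dimensionless roots match an independent dense scan", {
  # independent oracle: brute-force sign-change scan of the characteristic
  # function at 10x the solver's resolution, derivative-free
  sj <- function(l, x) sqrt(pi / (2 * x)) * besselJ(x, l + 0.5)
  tors <- function(l, x) (l - 1) * sj(l, x) - x * sj(l + 1, x)
  scan_roots <- function(l, lo, hi, n = 400000) {
    g <- seq(lo, hi, length.out = n)
    v <- tors(l, g)
    i <- which(v[-1] * v[-n] < 0)
    (g[i] + g[i + 1]) / 2
  }
  cs <- sqrt(152e9 / (2 * 1.22 * 7900))
  R <- 50e-6
  modes <- sphere_mode_frequencies(metglas, R, c(20e6, 240e6))
  eta <- modes$f_real_Hz * 2 * pi * R / cs
  for (l in c(2, 3)) {
    got <- sort(eta[modes$branch == "torsional" & modes$l == l])
    want <- scan_roots(l, 0.5, max(eta) + 0.1)
    want <- want[want >= min(got) - 1e-3]
    expect_equal(got, want[seq_along(got)], tolerance = 1e-3)
  }
  # the classical first torsional l = 2 constant
  first_t2 <- min(eta[modes$branch == "torsional" & modes$l == 2])
  expect_lt(abs(first_t2 - 2.501), 1e-3)
})

test_that("every root satisfies its characteristic equation after polish", {
  modes <- sphere_mode_frequencies(metglas, 50e-6, c(30e6, 240e6), l_max = 4)
  cs <- attr(modes, "c_s"); cp <- attr(modes, "c_p"); R <- attr(modes, "radius")
  for (i in seq_len(nrow(modes))) {
    eta <- modes$f_real_Hz[i] * 2 * pi * R / cs
    resid <- if (modes$branch[i] == "torsional") {
      memti:::.torsional_char(modes$l[i], eta)
    } else {
      memti:::.spheroidal_det(modes$l[i], eta, cs / cp)
    }
    expect_lt(abs(resid), 1e-8)
  }
})

test_that("frequencies scale exactly as 1/R and the mode count is grid-stable", {
  m1 <- sphere_mode_frequencies(metglas, 50e-6, c(30e6, 120e6), l_max = 4)
  m2 <- sphere_mode_frequencies(metglas, 25e-6, c(60e6, 240e6), l_max = 4)
  expect_equal(m2$f_real_Hz, 2 * m1$f_real_Hz, tolerance = 1e-9)
  m_dense <- sphere_mode_frequencies(metglas, 50e-6, c(30e6, 120e6),
                                     l_max = 4, points_per_decade = 40000)
  expect_equal(nrow(m_dense), nrow(m1))
  expect_equal(sort(m_dense$f_real_Hz), sort(m1$f_real_Hz), tolerance = 1e-8)
})

test_that("a MetGlas sphere of 50 um radius has resonances in the search band", {
  modes <- sphere_mode_frequencies(metglas, 50e-6, c(30e6, 240e6))
  expect_gte(nrow(modes), 2)
  expect_true(all(modes$f_real_Hz >= 30e6 & modes$f_real_Hz <= 240e6))
  expect_true(all(diff(modes$f_real_Hz) >= 0))
  # shear speed sanity: fundamental torsional mode near 22 MHz lies below
  # the band, overtones inside it
  cs <- attr(modes, "c_s")
  expect_rel_equal(cs, 2.8e3, 0.05)
})

test_that("damping ratios follow imag/abs and the loss-factor mapping", {
  expect_equal(damping_ratio(complex(real = 1e8, imaginary = 0)), 0)
  expect_rel_equal(damping_ratio(complex(real = 100e6, imaginary = 1e6)),
                   0.0099995, 1e-4)
  expect_error(damping_ratio(0 + 0i), "zero frequency")
  modes <- sphere_mode_frequencies(metglas, 50e-6, c(30e6, 120e6), l_max = 3)
  fc <- complex(real = modes$f_real_Hz, imaginary = modes$f_imag_Hz)
  expect_equal(damping_ratio(fc), modes$zeta, tolerance = 1e-7)
  expect_equal(unique(modes$zeta), metglas$eta_mech / 2)
})

test_that("drive-pair selection prefers low damping and honors the separation", {
  mock <- data.frame(f_real_Hz = c(100e6, 150e6, 160e6),
                     zeta = c(1e-6, 1e-6, 1e-2))
  expect_equal(select_mti_pair(mock, 40e6),
               c(f1 = 100e6, f2 = 150e6))
  expect_error(select_mti_pair(mock, 200e6), "no mode pair")
  expect_error(select_mti_pair(mock[1, ], 10e6, zeta_max = 1e-7),
               "fewer than two")
  # equal damping everywhere: deterministic lowest-f1 tie break
  flat <- data.frame(f_real_Hz = c(110e6, 130e6, 170e6), zeta = rep(1e-5, 3))
  expect_equal(select_mti_pair(flat, 30e6), c(f1 = 110e6, f2 = 170e6))
})

test_that("mode list exports the documented CSV columns", {
  modes <- sphere_mode_frequencies(metglas, 50e-6, c(30e6, 80e6), l_max = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_mode_list(modes, path)
  back <- read.csv(path)
  expect_named(back, c("f_real_Hz", "f_imag_Hz", "branch", "l", "overtone",
                       "zeta"))
  expect_equal(back$f_real_Hz, modes$f_real_Hz)
})
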