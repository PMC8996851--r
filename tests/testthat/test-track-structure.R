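# Amorphous-track microdosimetry: effective charge, radial dose, spectra,
# saturation correction.

test_that("effective charge obeys the high-velocity limit and bounds", {
  expect_equal(effective_charge("carbon", 400), 6, tolerance = 0.1 / 6)
  for (E in c(0.1, 1, 10, 400)) {
    zh <- effective_charge("hydrogen", E)
    expect_gt(zh, 0); expect_lte(zh, 1)
  }
  # closed-form Barkas value at 1 MeV/n, frozen from independent arithmetic:
  # beta = 0.046311, Zeff = 6 (1 - exp(-125 beta 6^(-2/3))) = 4.9606
  expect_equal(effective_charge("carbon", 1), 4.9606, tolerance = 1e-4)
  # monotone non-decreasing on a dense grid
  E <- exp(seq(log(0.1), log(400), length.out = 200))
  expect_true(all(diff(effective_charge("oxygen", E)) >= 0))
  expect_error(effective_charge("carbon", -1), "positive")
})

test_that("radial dose is a normalized core/penumbra profile", {
  rp <- penumbra_radius("carbon", 100)
  expect_equal(radial_dose("carbon", 100, rp * 1.01), 0)
  # 1/r^2 in the penumbra
  rc <- core_radius("carbon", 100)
  r1 <- rc * 10; r2 <- rc * 100
  D <- radial_dose("carbon", 100, c(r1, r2))
  expect_equal(D[1] / D[2], (r2 / r1)^2, tolerance = 1e-12)
  expect_error(radial_dose("carbon", 100, -0.1), "non-negative")
})

test_that("radial integral closes on the LET table within 2%", {
  for (nm in supported_ions()) for (E in c(1, 10, 100)) {
    pr <- hadrondose:::.track_profile(nm, E)
    r <- c(seq(0, pr$rc, length.out = 2000),
           exp(seq(log(pr$rc), log(pr$rp), length.out = 20000)))
    f <- r * radial_dose(nm, E, r)
    integral <- 2 * pi * sum((f[-1] + f[-length(f)]) / 2 * diff(r))
    target <- 0.1602176634 * let_water(nm, E)
    expect_equal(integral, target, tolerance = 0.02,
                 label = sprintf("LET closure %s %g MeV/n", nm, E))
  }
})

test_that("single-event spectra are normalized proper densities", {
  for (nm in c("hydrogen", "carbon")) for (E in c(0.3, 5, 80)) {
    sp <- single_event_spectrum(nm, E, n_impact = 512)
    expect_equal(spectrum_norm(sp), 1, tolerance = 1e-6)
    expect_true(all(sp$density >= 0))
    expect_gte(sp$z1d, sp$zbar)      # Cauchy-Schwarz
    expect_gt(z1d_star(sp, hsg_z0()), 0)
  }
  expect_error(single_event_spectrum("carbon", 10, Rd = -1), "positive")
})

test_that("spectrum frequency mean matches the geometric closed form", {
  # Fubini: integrating z(b) over the impact-parameter plane returns the
  # track's full energy, so zbar = LET_integral / (pi b_max^2)
  for (nm in c("helium", "oxygen")) for (E in c(1, 50, 258)) {
    sp <- single_event_spectrum(nm, E, n_impact = 1024)
    closed <- 0.1602176634 * let_water(nm, E) / (pi * max(sp$b)^2)
    expect_equal(sp$zbar, closed, tolerance = 2e-3,
                 label = sprintf("zbar closure %s %g", nm, E))
  }
})

test_that("quadrature moments agree with impact-parameter sampling", {
  set.seed(12345)
  sp <- single_event_spectrum("carbon", 50, n_impact = 1024)
  bmax <- max(sp$b)
  # independent Monte Carlo: uniform-fluence impact parameters mapped
  # through z(b) evaluated on its own fine grid
  bfine <- c(0, exp(seq(log(1e-4 * 0.32), log(bmax), length.out = 8192)))
  zfine <- specific_energy_at_impact("carbon", 50, bfine)
  n <- 2e5
  u <- runif(n, 0, bmax^2)
  zs <- exp(stats::approx(log(pmax(bfine^2, 1e-300)),
                          log(pmax(zfine, 1e-300)), xout = log(u))$y)
  se1 <- stats::sd(zs) / sqrt(n)
  se2 <- stats::sd(zs^2) / sqrt(n)
  expect_lt(abs(sp$zbar - mean(zs)) / se1, 3)
  expect_lt(abs(sp$z1d * sp$zbar - mean(zs^2)) / se2, 3)
})

test_that("saturation parameter follows its closed form", {
  # (Rn/Rd)^2 / sqrt(beta (1 + (Rn/Rd)^2)) at the HSG parameter set
  expect_equal(saturation_parameter(0.32, 3.9, 0.0615), 48.9833,
               tolerance = 1e-4)
  expect_equal(saturation_parameter(1, 1, 1), 1 / sqrt(2))
  # strictly decreasing in beta
  b <- seq(0.01, 0.3, length.out = 50)
  expect_true(all(diff(saturation_parameter(0.32, 3.9, b)) < 0))
  expect_error(saturation_parameter(0, 3.9, 0.06), "positive")
})

test_that("z1D* applies the saturation correction correctly", {
  # two-atom discrete spectrum, hand-evaluated closed form
  atoms <- data.frame(z = c(10, 100), mass = c(0.5, 0.5))
  z0 <- 50
  num <- z0^2 * (0.5 * (1 - exp(-(10 / 50)^2)) + 0.5 * (1 - exp(-(100 / 50)^2)))
  expect_equal(z1d_star(atoms, z0), num / 55, tolerance = 1e-12)
  # small-argument limit: z << z0 reduces to the uncorrected dose mean
  small <- data.frame(z = c(0.001, 0.004), mass = c(0.3, 0.7))
  zd <- sum(small$mass * small$z^2) / sum(small$mass * small$z)
  expect_equal(z1d_star(small, 50), zd, tolerance = 1e-4)
  # saturation never exceeds the uncorrected dose mean
  sp <- single_event_spectrum("carbon", 5, n_impact = 512)
  expect_lte(z1d_star(sp, hsg_z0()), sp$z1d)
  expect_error(z1d_star(sp, -1), "positive")
})

test_that("z1D* rises with LET at low LET and saturates at high LET", {
  E <- exp(seq(log(1.5), log(400), length.out = 16))  # LET-monotone branch
  zs <- vapply(E, function(e)
    z1d_star(single_event_spectrum("carbon", e, n_impact = 512), hsg_z0()),
    numeric(1))
  let <- let_water("carbon", E)
  low <- let < 50
  expect_true(all(diff(zs[low]) / diff(let[low]) >= 0))
  expect_lt(max(zs), hsg_z0())   # capped well below z0 scale
})
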