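# LQ survival, mMKM coefficient chain, NanOx lethal function, table build.

test_that("LQ survival and its inversion are consistent", {
  co <- lq_coefficients(0.172, 0.0615)
  expect_equal(lq_survival(co, 0), 1)
  expect_equal(lq_survival(lq_coefficients(1, 0), 1), exp(-1))
  # closed-form D10 at the HSG photon-limit coefficients, cross-checked
  # against a numeric root of S(D) = 0.1
  d10 <- d10_from_lq(co)
  expect_equal(d10, 4.87824, tolerance = 1e-5)
  root <- uniroot(function(D) lq_survival(co, D) - 0.1, c(0.1, 50),
                  tol = 1e-12)$root
  expect_equal(d10, root, tolerance = 1e-9)
  expect_equal(lq_survival(co, d10), 0.1, tolerance = 1e-9)
  # linear special case
  expect_equal(d10_from_lq(lq_coefficients(log(10), 0)), 1)
  expect_error(d10_from_lq(lq_coefficients(0, 0)), "undefined")
  expect_error(lq_survival(co, -1), "non-negative")
})

test_that("mMKM alpha is affine in z1D* with the constant beta", {
  p <- hsg_mmkm()
  expect_equal(mmkm_alpha(p, 0)$alpha, 0.172)
  co <- mmkm_alpha(p, 10)
  expect_equal(co$alpha, 0.172 + 0.0615 * 10)  # 0.787
  expect_equal(co$beta, 0.0615)
  z <- seq(0, 60, length.out = 100)
  a <- mmkm_alpha(p, z)$alpha
  expect_true(all(diff(a) > 0))
  expect_true(all(a >= p$alpha0))
  expect_error(mmkm_alpha(p, -1), "non-negative")
})

test_that("D10 decreases in alpha at fixed beta", {
  a <- seq(0.1, 2, length.out = 40)
  d <- d10_from_lq(lq_coefficients(a, 0.0615))
  expect_true(all(diff(d) < 0))
})

test_that("NanOx lethal function is an erf-shaped saturating response", {
  p <- nanox_params()   # HSG set, thousands-separator reading
  expect_equal(nanox_lethal_function(p, p$z0_nx), p$h / 2)
  expect_equal(nanox_lethal_function(p, p$z0_nx + 10 * p$sigma), p$h,
               tolerance = 1e-12)
  # z0 + sigma lands at (h/2)(1 + erf(1)); erf(1) = 0.8427008
  expect_equal(nanox_lethal_function(p, p$z0_nx + p$sigma),
               p$h / 2 * (1 + 0.84270079), tolerance = 1e-7)
  z <- seq(0, 3 * p$z0_nx, length.out = 200)
  Fz <- nanox_lethal_function(p, z)
  expect_true(all(diff(Fz) >= 0))
  expect_true(all(Fz <= p$h))
  # alternative decimal-comma reading stays configurable
  p2 <- nanox_params(z0_nx = 15.654, h = 179.439)
  expect_equal(nanox_lethal_function(p2, 15.654), 179.439 / 2)
  expect_error(nanox_lethal_function(p, -1), "non-negative")
})

test_that("mMKM table build is deterministic and hits the low-LET limit", {
  E <- c(5, 50, 400)
  t1 <- build_mmkm_table("hydrogen", E, n_impact = 512)
  t2 <- build_mmkm_table("hydrogen", E, n_impact = 512)
  expect_identical(t1, t2)
  f1 <- tempfile(); f2 <- tempfile()
  write_survival_table(t1, f1); write_survival_table(t2, f2)
  expect_identical(readLines(file.path(f1, "hydrogen.txt")),
                   readLines(file.path(f2, "hydrogen.txt")))
  # hydrogen at 400 MeV/n is in the low-LET regime: alpha near alpha0
  a_top <- t1$ions$hydrogen$alpha[3]
  expect_equal(a_top, 0.172, tolerance = 0.1)
  expect_true(all(t1$ions$hydrogen$beta == 0.0615))
  expect_error(build_mmkm_table("hydrogen", c(0.01, 1)), "0.1")
  expect_error(build_mmkm_table("hydrogen", c(10, 5)), "increasing")
})

test_that("synthetic NanOx stand-in table preserves structure", {
  base <- build_mmkm_table("carbon", c(5, 50, 400), n_impact = 512)
  nx <- build_synthetic_nanox_table(base)
  expect_identical(names(nx$ions), names(base$ions))
  expect_true(all(nx$ions$carbon$alpha >= base$ions$carbon$alpha))
  expect_true(all(nx$ions$carbon$beta == 0.096))
  expect_match(nx$model, "synthetic")
})
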