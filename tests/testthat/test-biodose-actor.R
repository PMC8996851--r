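# Voxelized mixed-field accumulation and derived biological quantities.

test_that("single- and two-component mixing follow the dose-fraction rule", {
  tab <- toy_table()
  st <- voxel_store()
  accumulate(st, list(voxel = 3L, ion = "carbon", E = 100, edep = 1), tab)
  co <- voxel_coefficients(st, 3L)
  expect_equal(co$alpha, 0.2); expect_equal(co$beta, 0.05)
  # equal-weight mean of alpha 0.1 and 0.3 (helium table endpoints)
  st2 <- voxel_store()
  accumulate(st2, list(voxel = 0L, ion = "helium", E = 0.1, edep = 2), tab)
  accumulate(st2, list(voxel = 0L, ion = "helium", E = 400, edep = 2), tab)
  expect_equal(voxel_coefficients(st2, 0L)$alpha, 0.2)
  expect_error(accumulate(st2, list(voxel = 0L, ion = "oxygen", E = 1,
                                    edep = 1), tab), "absent")
  expect_warning(accumulate(st2, list(voxel = 0L, ion = "oxygen", E = 1,
                                      edep = 1), tab,
                            on_missing_ion = "skip"), "skipped")
})

test_that("streaming accumulation equals the two-pass batch oracle", {
  set.seed(99)
  tab <- toy_table()
  for (rep in 1:5) {
    n <- 200
    records <- data.frame(
      voxel = sample(0:9, n, replace = TRUE),
      ion = sample(c("carbon", "helium"), n, replace = TRUE),
      E = runif(n, 0.1, 400),
      edep = runif(n, 1e-3, 5))
    st <- voxel_store()
    for (i in seq_len(n)) accumulate(st, records[i, ], tab)
    stv <- voxel_store()
    accumulate_records(stv, records, tab)
    oracle <- batch_mix(records, tab)
    for (k in seq_along(oracle)) {
      v <- as.integer(names(oracle)[k])
      co_s <- voxel_coefficients(st, v)
      co_v <- voxel_coefficients(stv, v)
      expect_equal(co_s$alpha, oracle[[k]][["alpha"]], tolerance = 1e-12)
      expect_equal(co_v$alpha, oracle[[k]][["alpha"]], tolerance = 1e-12)
      expect_equal(co_s$beta, oracle[[k]][["beta"]], tolerance = 1e-12)
      # dose fractions sum to one by construction of the ratio
      idx <- records$voxel == v
      expect_equal(sum(records$edep[idx] / sum(records$edep[idx])), 1,
                   tolerance = 1e-12)
    }
  }
})

test_that("mixed coefficients stay within the contributing range", {
  set.seed(3)
  tab <- toy_table()
  records <- data.frame(voxel = 0L, ion = "helium",
                        E = runif(50, 0.1, 400), edep = runif(50, 0.1, 2))
  st <- voxel_store()
  accumulate_records(st, records, tab)
  co <- voxel_coefficients(st, 0L)
  a_each <- interpolate_coefficients(tab, "helium", records$E)$alpha
  expect_gte(co$alpha, min(a_each)); expect_lte(co$alpha, max(a_each))
})

test_that("physical dose conversion follows MeV -> Gy unit arithmetic", {
  # 1 MeV in 1 mm^3 of water: 1.602e-13 J over 1e-6 kg
  expect_equal(edep_to_dose(1, 1), 1.602176634e-7, tolerance = 1e-9)
  expect_equal(edep_to_dose(0, 1), 0)
  expect_equal(edep_to_dose(2, 1), 2 * edep_to_dose(1, 1))
  expect_error(edep_to_dose(1, -1), "positive")
})

test_that("biological dose inverts the reference LQ effect", {
  ref <- reference_radiation(0.2, 0.05)
  mix <- lq_coefficients(0.4, 0.05)
  # closed form: effect = 1.0, (-0.2 + sqrt(0.04 + 0.2)) / 0.1
  expect_equal(biological_dose(mix, 2, ref),
               (-0.2 + sqrt(0.24)) / 0.1, tolerance = 1e-12)
  expect_equal(biological_dose(mix, 2, ref), 2.898979, tolerance = 1e-6)
  # identity when mixed equals reference
  same <- lq_coefficients(0.2, 0.05)
  D <- seq(0, 10, length.out = 50)
  expect_equal(biological_dose(same, D, ref), D, tolerance = 1e-12)
  # monotone in D
  expect_true(all(diff(biological_dose(mix, D, ref)) > 0))
  # linear-reference limit
  ref0 <- reference_radiation(0.2, 0)
  expect_equal(biological_dose(mix, 2, ref0), 1.0 / 0.2)
})

test_that("RBE is the biological-to-physical dose ratio", {
  ref <- reference_radiation(0.2, 0.05)
  mix <- lq_coefficients(0.4, 0.05)
  expect_equal(rbe(mix, 2, ref), 2.898979 / 2, tolerance = 1e-6)
  expect_equal(rbe(lq_coefficients(0.2, 0.05), 2, ref), 1)
  expect_true(is.na(rbe(mix, 0, ref)))
  expect_gt(rbe(lq_coefficients(0.3, 0.05), 2, ref), 1)
})

test_that("RBE at fixed survival uses the generalized LQ inversion", {
  ref <- reference_radiation(0.172, 0.0615)
  expect_equal(rbe_at_survival(lq_coefficients(0.172, 0.0615), ref, 0.1), 1)
  mix <- lq_coefficients(0.4, 0.0615)
  got <- rbe_at_survival(mix, ref, 0.1)
  # oracle: numeric roots of both survival curves at 10%
  d_ref <- uniroot(function(D) lq_survival(ref_lq(ref), D) - 0.1,
                   c(0.01, 60), tol = 1e-12)$root
  d_mix <- uniroot(function(D) lq_survival(mix, D) - 0.1,
                   c(0.01, 60), tol = 1e-12)$root
  expect_equal(got, d_ref / d_mix, tolerance = 1e-9)
  expect_gte(rbe_at_survival(mix, ref, 0.5), 1)
  expect_error(rbe_at_survival(mix, ref, 1.2), "0, 1")
})

test_that("relative difference reproduces reference-denominator arithmetic", {
  expect_equal(relative_difference(0.92, 0.77), 16.30435, tolerance = 1e-5)
  expect_equal(relative_difference(5, 5), 0)
  expect_equal(relative_difference(1.23, 1.22), 0.8130081, tolerance = 1e-6)
  expect_error(relative_difference(0, 1), "non-zero")
})

test_that("survival consistency: reference survival at Dbio equals mixed", {
  set.seed(21)
  for (i in 1:50) {
    mix <- lq_coefficients(runif(1, 0.05, 2), runif(1, 0.01, 0.3))
    ref <- reference_radiation(runif(1, 0.05, 1), runif(1, 0.01, 0.3))
    D <- runif(1, 0, 8)
    db <- biological_dose(mix, D, ref)
    expect_equal(lq_survival(list(alpha = ref$alpha_ref,
                                  beta = ref$beta_ref), db),
                 mixed_survival(mix, D), tolerance = 1e-9)
  }
})

test_that("report files are deterministic with the documented layout", {
  tab <- toy_table()
  ref <- test_ref()
  geom <- phantom_geometry(n_slices = 10)
  records <- data.frame(voxel = c(7L, 2L, 2L), ion = "carbon",
                        E = c(100, 50, 20), edep = c(1, 2, 3))
  rpt <- run_biodose_actor(records, tab, ref, geom)
  expect_identical(rpt$voxel, c(2L, 7L))   # ordered by index
  expect_equal(rpt$z, c(2.5, 7.5))
  expect_equal(rpt$rbe, rpt$dose_bio / rpt$dose)
  f1 <- tempfile(); f2 <- tempfile()
  write_biodose_report(rpt, f1)
  write_biodose_report(run_biodose_actor(records, tab, ref, geom), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(length(readLines(f1)), 3L)  # header + 2 voxels
  # empty store -> header-only file
  empty <- biodose_report(voxel_store(), geom, ref)
  f3 <- tempfile()
  write_biodose_report(empty, f3)
  expect_equal(length(readLines(f3)), 1L)
  expect_match(readLines(f3)[1], "^# voxel")
})
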