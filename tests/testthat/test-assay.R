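test_that("percent displacement spans the assay window linearly", {
  expect_equal(as.numeric(percent_displacement(1000, 100, 1000)), 0)
  expect_equal(as.numeric(percent_displacement(1000, 100, 100)), 100)
  expect_equal(as.numeric(percent_displacement(1000, 100, 550)), 50)
  expect_error(percent_displacement(100, 100, 50), "degenerate")
})

test_that("percent inhibition mirrors the 50% hit cut-off", {
  expect_equal(as.numeric(percent_inhibition(200, 50, 200)), 0)
  expect_equal(as.numeric(percent_inhibition(200, 50, 50)), 100)
  expect_equal(as.numeric(percent_inhibition(200, 50, 125)), 50)
  expect_error(percent_inhibition(50, 200, 100), "degenerate")
})

test_that("percent metrics are affine-invariant in the counts", {
  base <- percent_displacement(1000, 100, 400)
  shifted <- percent_displacement(1250, 350, 650)
  expect_equal(as.numeric(base), as.numeric(shifted))
})

test_that("a noiseless synthetic curve is recovered to machine accuracy", {
  d <- gen_curves(pic50 = 6, hill = 1, top = 100, bottom = 0,
                  noise_sd = 0, n_points = 10)
  fit <- fit_4pl(d$concentration_molar, d$response)
  expect_equal(fit$pic50, 6, tolerance = 1e-6)
  expect_equal(fit$hill, 1, tolerance = 1e-6)
  expect_equal(fit$bottom, 0, tolerance = 1e-6)
  expect_equal(fit$top, 100, tolerance = 1e-6)
  # decreasing curves fit equally well, with bottom <= top after
  # orientation
  dd <- gen_curves(pic50 = 7, hill = -1.2, top = 100, bottom = 5,
                   noise_sd = 0, n_points = 10)
  fd <- fit_4pl(dd$concentration_molar, dd$response)
  expect_equal(fd$pic50, 7, tolerance = 1e-6)
  expect_lte(fd$bottom, fd$top)
})

test_that("fitting contracts reject unusable input", {
  expect_error(fit_4pl(c(1e-6, 1e-5, 1e-4), c(1, 2, 3)), "4 distinct")
  expect_error(fit_4pl(c(-1, 1e-6, 1e-5, 1e-4), c(1, 2, 3, 4)),
               "positive")
})

test_that("median pIC50 recovery error stays below 0.2 at 5% noise", {
  errs <- vapply(1:100, function(i) {
    d <- gen_curves(pic50 = 6, hill = 1, noise_sd = 0.05, n_points = 8,
                    seed = 7000 + i)
    fit <- fit_4pl(d$concentration_molar, d$response)
    abs(fit$pic50 - 6)
  }, 0)
  expect_lt(stats::median(errs), 0.2)
})

test_that("Cheng-Prusoff matches the closed form exactly", {
  # independent arithmetic oracle
  oracle <- function(ic50, L, kd) ic50 * kd / (kd + L)
  cases <- expand.grid(ic50 = c(1e-9, 1e-7, 1e-5),
                       L = c(0, 3e-9, 6e-9), kd = c(1e-9, 6.3e-9))
  for (r in seq_len(nrow(cases))) {
    k <- cheng_prusoff_ki(cases$ic50[r], cases$L[r], cases$kd[r])
    expect_equal(k$ki, oracle(cases$ic50[r], cases$L[r], cases$kd[r]),
                 tolerance = 1e-12)
    expect_lte(k$ki, cases$ic50[r])
  }
  # study constants: IC50 1000 nM, [L] 6 nM, KD 6.3 nM -> ~512.2 nM
  k <- cheng_prusoff_ki(1000e-9, 6e-9, 6.3e-9)
  expect_equal(k$ki * 1e9, 1000 / (1 + 6 / 6.3), tolerance = 1e-12)
  expect_equal(k$ki * 1e9, 512.2, tolerance = 1e-3)
  # no radioligand: Ki equals IC50; Ki decreases as [L] grows
  expect_equal(cheng_prusoff_ki(1e-6, 0, 6.3e-9)$ki, 1e-6)
  kis <- vapply(c(0, 2e-9, 4e-9, 8e-9), function(L) {
    cheng_prusoff_ki(1e-6, L, 6.3e-9)$ki
  }, 0)
  expect_true(all(diff(kis) < 0))
  expect_error(cheng_prusoff_ki(1e-6, 6e-9, 0), "positive")
})

test_that("EC-fraction identities hold exactly", {
  expect_equal(ec_fraction(2e-9, 1, 0.5), 2e-9)
  expect_equal(ec_fraction(2e-9, 1, 0.8), 8e-9)
  expect_equal(ec_fraction(2e-9, 2, 0.8), 4e-9)
  expect_error(ec_fraction(2e-9, 0, 0.8), "non-zero")
})

test_that("pIC50 conversion reproduces the reported potency scale", {
  # a 10.79 uM IC50 corresponds to pIC50 4.97
  expect_equal(ic50_to_pic50(10.79e-6), 4.967, tolerance = 1e-3)
  expect_equal(ic50_to_pic50(1e-6), 6)
})

test_that("curve generation is seed-deterministic with embedded truth", {
  d1 <- gen_curves(seed = 42)
  d2 <- gen_curves(seed = 42)
  expect_identical(d1, d2)
  expect_equal(attr(d1, "truth")$pic50, 6)
  d3 <- gen_curves(seed = 43)
  expect_false(identical(d1$response, d3$response))
})
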