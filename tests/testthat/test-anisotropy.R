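# Exact anisotropy binding models, equilibrium oracles, fitting, simulation.

test_that("direct model: boundary behavior and equilibrium oracle", {
  expect_equal(direct_anisotropy(0, 1e-8, 5e-8), 0.05)
  # saturation: kd -> 0 with excess protein drives r to rb
  expect_equal(direct_anisotropy(1e-6, 1e-13, 5e-8), 0.25, tolerance = 1e-4)
  expect_error(direct_anisotropy(1e-7, 1e-8, 0), "lt")

  set.seed(21)
  for (i in 1:200) {
    kd <- 10^runif(1, -9, -6); lt <- 10^runif(1, -9, -6)
    pt <- 10^runif(1, -9, -5)
    expect_equal(direct_anisotropy(pt, kd, lt),
                 oracle_direct_r(pt, kd, lt), tolerance = 1e-9)
  }
})

test_that("competitive model agrees with the brute-force equilibrium solver", {
  set.seed(33)
  n <- 10000
  kd1 <- 10^runif(n, -9, -6); kd2 <- 10^runif(n, -9, -5)
  pt <- 10^runif(n, -8, -5); lst <- pt * runif(n, 0.05, 0.8)
  lt <- 10^runif(n, -9, -4)
  p_free <- oracle_competitive(lt, kd1, kd2, pt, lst)
  r_oracle <- 0.05 + 0.2 * p_free / (kd1 + p_free)
  r_closed <- competitive_anisotropy(lt, kd1, kd2, pt, lst, warn = FALSE)
  expect_lt(max(abs(r_closed - r_oracle)), 1e-9)
  expect_true(all(r_closed >= 0.05 - 1e-12 & r_closed <= 0.25 + 1e-12))

  # mass balances and both Kd definitions hold for the implied species
  i <- which.max(lt)
  P <- p_free[i]
  Ls <- lst[i] / (1 + P / kd1[i]); Lc <- lt[i] / (1 + P / kd2[i])
  expect_equal(P + P * Ls / kd1[i] + P * Lc / kd2[i], pt[i],
               tolerance = 1e-9 * pt[i])
  expect_equal(Ls + P * Ls / kd1[i], lst[i], tolerance = 1e-9 * lst[i])
})

test_that("competitive model reduces to the direct model in its limits", {
  # no competitor: cubic and quadratic closed forms coincide
  for (pt in c(5e-8, 2.5e-7, 1e-6)) {
    expect_equal(competitive_anisotropy(0, 13e-9, 1e-7, pt, 5e-8,
                                        warn = FALSE),
                 direct_anisotropy(pt, 13e-9, 5e-8), tolerance = 1e-9)
  }
  # non-binding competitor never displaces
  expect_equal(competitive_anisotropy(1e-5, 13e-9, 1e3, 2.5e-7, 5e-8,
                                      warn = FALSE),
               direct_anisotropy(2.5e-7, 13e-9, 5e-8), tolerance = 1e-6)
  expect_warning(competitive_anisotropy(0, 1e-8, 1e-8, 1e-8, 5e-8),
                 "assumption")
})

test_that("titration simulator: exactness at zero noise, determinism, monotonicity", {
  conc <- 10^seq(-9, -6, length.out = 10)
  cur0 <- simulate_titration("direct", conc,
                             list(kd = 2e-8, lt = 5e-8, r0 = 0.05,
                                  rb = 0.25), sigma = 0, replicates = 2,
                             seed = 1)
  expect_equal(cur0$anisotropy[1:10],
               direct_anisotropy(conc, 2e-8, 5e-8), tolerance = 1e-12)
  expect_true(all(diff(cur0$anisotropy[1:10]) >= 0))
  c1 <- simulate_titration("direct", conc, list(kd = 2e-8, lt = 5e-8),
                           sigma = 0.01, seed = 9)
  c2 <- simulate_titration("direct", conc, list(kd = 2e-8, lt = 5e-8),
                           sigma = 0.01, seed = 9)
  expect_identical(c1$anisotropy, c2$anisotropy)
})

test_that("noiseless fits recover parameters to 1e-6 relative", {
  conc <- 10^seq(-9.5, -5.5, length.out = 12)
  cur <- simulate_titration("direct", conc,
                            list(kd = 2e-8, lt = 5e-8, r0 = 0.05,
                                 rb = 0.25), sigma = 0, replicates = 1,
                            seed = 1)
  f <- fit_direct(cur, lt = 5e-8)
  expect_lt(abs(coef(f)[["kd"]] / 2e-8 - 1), 1e-6)
  expect_lt(abs(coef(f)[["r0"]] - 0.05), 1e-6)
  expect_lt(abs(coef(f)[["rb"]] - 0.25), 1e-6)
  expect_true(f$converged)

  comp <- simulate_titration("competitive", 10^seq(-8, -4, length.out = 12),
                             list(kd1 = 13e-9, kd2 = 1e-7, pt = 250e-9,
                                  lst = 50e-9, r0 = 0.05, rb = 0.25),
                             sigma = 0, replicates = 1, seed = 1)
  f2 <- fit_competitive(comp, kd1 = 13e-9)
  expect_lt(abs(coef(f2)[["kd2"]] / 1e-7 - 1), 1e-6)

  # degenerate designs are rejected
  flat <- data.frame(conc_M = rep(1e-7, 8), anisotropy = rnorm(8, 0.1, 0.01))
  expect_error(fit_direct(flat, lt = 5e-8), "degenerate design")
  expect_error(fit_competitive(flat[1:5, ], kd1 = 13e-9),
               "degenerate design")
})

test_that("assay-control diagnostics raise the right flags", {
  conc <- 10^seq(-8, -4, length.out = 12)
  # baseline dropping below the free-peptide anisotropy is flagged
  low <- simulate_titration("competitive", conc,
                            list(kd1 = 13e-9, kd2 = 3e-8, pt = 250e-9,
                                 lst = 50e-9, r0 = 0.05, rb = 0.25),
                            sigma = 0, replicates = 1, seed = 2)
  low$anisotropy[conc > 1e-5] <- 0.02 # artefactual quench below r0
  f <- fit_competitive(low, kd1 = 13e-9, start = list(kd2 = 3e-8),
                       r0_free = 0.05)
  expect_true(any(grepl("baseline", f$flags)))

  # a competitor too weak to displace is reported unidentifiable/flat
  weak <- simulate_titration("competitive", conc,
                             list(kd1 = 13e-9, kd2 = 1e-2, pt = 250e-9,
                                  lst = 50e-9, r0 = 0.05, rb = 0.25),
                             sigma = 1e-4, replicates = 3, seed = 3)
  fw <- fit_competitive(weak, kd1 = 13e-9)
  expect_true(length(fw$flags) > 0)
  expect_lt(diff(range(predict(fw))), 0.02) # fitted curve essentially flat
})

test_that("fit objects expose the standard modelling interface", {
  conc <- 10^seq(-9.5, -5.5, length.out = 12)
  cur <- simulate_titration("direct", conc, list(kd = 2e-8, lt = 5e-8),
                            sigma = 0.003, replicates = 3, seed = 5)
  f <- fit_direct(cur, lt = 5e-8)
  expect_s3_class(f, "anisofit")
  expect_named(coef(f), c("kd", "r0", "rb"))
  expect_equal(nrow(summary(f)), 3)
  expect_equal(length(predict(f)), nrow(cur))
  expect_equal(length(residuals(f)), nrow(cur))
  expect_output(print(f), "Anisotropy fit")
})
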