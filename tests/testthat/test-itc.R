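vols25 <- c(3e-6, rep(1e-5, 25))

test_that("forward model limits: no ligand, tight binding, heat conservation", {
  q0 <- forward_one_site(1, 1e-6, -1e4, volumes = vols25, V0 = 1.4e-3,
                         M0 = 2e-5, X0 = 0)
  expect_true(all(q0 == 0))
  # stoichiometric limit: pre-saturation injections deliver dH per mole
  qt <- forward_one_site(1, 1e-15, -1e4, volumes = vols25, V0 = 1.4e-3,
                         M0 = 2e-5, X0 = 3e-4)
  moles <- 3e-4 * vols25[2]
  expect_equal(qt[2], -1e4 * moles, tolerance = 0.02)
  # heat conservation: without the displacement terms the injection heats
  # telescope exactly to dH * V0 * [MX]_final (bisection oracle)
  orc <- oracle_itc_heats(1, 2e-6, -1e4, vols25, 1.4e-3, 2e-5, 3e-4,
                          displacement = FALSE)
  expect_equal(sum(orc$q), -1e4 * 1.4e-3 * orc$MX_final, tolerance = 1e-12)
  # the displacement-corrected total stays within a quarter of that limit
  q <- forward_one_site(1, 2e-6, -1e4, volumes = vols25, V0 = 1.4e-3,
                        M0 = 2e-5, X0 = 3e-4)
  expect_lt(abs(sum(q) - orc$Q_final), 0.25 * abs(orc$Q_final))
})

test_that("forward heats match an independent bisection equilibrium solver", {
  for (pars in list(c(1, 2.1e-6, -1e4, 2e-5, 3e-4),
                    c(0.8, 5.64e-5, -8e3, 2.8e-3, 3e-2),
                    c(1.2, 1.5e-7, 5e3, 1.5e-5, 1.8e-4))) {
    q <- forward_one_site(pars[1], pars[2], pars[3], volumes = vols25,
                          V0 = 1.4e-3, M0 = pars[4], X0 = pars[5])
    qo <- oracle_itc_heats(pars[1], pars[2], pars[3], vols25, 1.4e-3,
                           pars[4], pars[5])$q
    expect_equal(q, qo, tolerance = 1e-10)
  }
})

test_that("ITC CSV values round-trip to full double precision", {
  s <- simulate_itc(Kd = 2.1e-6, M0 = 2e-5, X0 = 3e-4, noise_sd = 1e-7,
                    seed = 3)
  f <- tempfile(fileext = ".csv")
  write_itc_csv(s, f)
  back <- read_itc_csv(f)
  # the file stores instrument units (uL/uM/ucal); the decimal unit
  # conversion is exact to the last ulp of the double representation
  expect_equal(back$heats, s$heats, tolerance = 1e-14)
  expect_equal(back$volumes, s$volumes, tolerance = 1e-14)
  expect_equal(back$M0, s$M0, tolerance = 1e-14)
  expect_equal(back$X0, s$X0, tolerance = 1e-14)
  expect_identical(back$V0, s$V0)
})

test_that("noise-free fits recover all parameters from perturbed starts", {
  s <- simulate_itc(n = 1, Kd = 2.1e-6, dH = -1e4, M0 = 2e-5, X0 = 3e-4,
                    noise_sd = 0)
  for (fac in c(0.5, 1.5)) {
    fit <- fit_one_site(s, initial = list(n = fac, Kd = 2.1e-6 * fac,
                                          dH = -1e4 * fac))
    cf <- coef(fit)
    expect_equal(cf[["n"]], 1, tolerance = 1e-3)
    expect_equal(cf[["Kd"]], 2.1e-6, tolerance = 1e-3)
    expect_equal(cf[["dH"]], -1e4, tolerance = 1e-3)
  }
})

test_that("median Kd over 50 noisy replicates lands within 10% of truth", {
  kds <- vapply(1:50, function(i) {
    q0 <- forward_one_site(1, 2.1e-6, -1e4, volumes = vols25, V0 = 1.4e-3,
                           M0 = 2e-5, X0 = 3e-4)
    s <- simulate_itc(Kd = 2.1e-6, M0 = 2e-5, X0 = 3e-4,
                      noise_sd = 0.01 * max(abs(q0)), seed = 7000 + i)
    coef(fit_one_site(s))[["Kd"]]
  }, 0)
  expect_lt(abs(median(kds) / 2.1e-6 - 1), 0.10)
})

test_that("fit errors and diagnostics behave", {
  z <- titration_series(vols25, rep(0, 26), V0 = 1.4e-3, M0 = 2e-5,
                        X0 = 3e-4)
  expect_error(fit_one_site(z), "no binding detected")
  # a biphasic (two-site) process trips the lack-of-fit flag
  q2 <- forward_one_site(0.6, 1e-7, -8e3, volumes = vols25, V0 = 1.4e-3,
                         M0 = 2e-5, X0 = 3e-4) +
        forward_one_site(0.6, 1e-5, 6e3, volumes = vols25, V0 = 1.4e-3,
                         M0 = 2e-5, X0 = 3e-4)
  s2 <- titration_series(vols25, q2, V0 = 1.4e-3, M0 = 2e-5, X0 = 3e-4)
  expect_warning(fit2 <- fit_one_site(s2), "lack of fit")
  expect_true(fit2$lack_of_fit)
  expect_error(titration_series(rep(1e-5, 3), rep(1, 3), 1.4e-3, 2e-5, 3e-4),
               "at least 5")
})

test_that("itc_fit methods are coherent", {
  s <- simulate_itc(Kd = 2.1e-6, M0 = 2e-5, X0 = 3e-4, noise_sd = 0)
  fit <- fit_one_site(s)
  expect_equal(predict(fit), fit$fitted)
  expect_equal(s$heats[-1] - predict(fit), residuals(fit),
               tolerance = 1e-12)
  expect_named(coef(fit), c("n", "Kd", "dH"))
  expect_true(all(fit$se >= 0 | is.na(fit$se)))
  sm <- summary(fit)
  expect_s3_class(sm, "summary.itc_fit")
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(dim(sims), c(length(fit$fitted), 2L))
  # predictions for a fresh series cover all of its injections
  expect_length(predict(fit, newdata = s), length(s$heats))
})

test_that("Kd recovery degrades outside the Wiseman window", {
  rel_err <- function(cc) {
    vapply(1:10, function(i) {
      Kd <- 1e-5
      M0 <- cc * Kd
      q0 <- forward_one_site(1, Kd, -1e4, volumes = vols25, V0 = 1.4e-3,
                             M0 = M0, X0 = 12 * M0)
      s <- simulate_itc(Kd = Kd, M0 = M0, X0 = 12 * M0,
                        noise_sd = 0.01 * max(abs(q0)), seed = 900 + i)
      abs(coef(fit_one_site(s))[["Kd"]] / Kd - 1)
    }, 0)
  }
  inside <- rel_err(50)
  outside <- rel_err(0.05)
  expect_gt(median(outside), median(inside))
})

test_that("fractional occupancy follows L/(Kd + L)", {
  expect_equal(fraction_bound(0, 655e-6), 0)
  expect_equal(fraction_bound(655e-6, 655e-6), 0.5)
  expect_equal(fraction_bound(500e-6, 655e-6), 0.4329, tolerance = 1e-4)
  expect_error(fraction_bound(-1, 1), ">= 0")
})
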