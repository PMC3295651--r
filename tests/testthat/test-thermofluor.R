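test_that("simulated melt curves hit the sigmoid midpoint and baseline limits", {
  cv <- simulate_melt_curve(Tm = 60, w = 1, a_f = 10, b_f = 0.1,
                            a_u = 90, b_u = -0.05, noise_sd = 0)
  i <- which(cv$temperature == 60)
  fold <- 10 + 0.1 * 60; unf <- 90 - 0.05 * 60
  expect_equal(cv$fluorescence[i], (fold + unf) / 2)
  # far below Tm the signal sits on the folded baseline
  expect_equal(cv$fluorescence[1], 10 + 0.1 * 30, tolerance = 1e-8)
  expect_error(simulate_melt_curve(Tm = 20), "out of range")
  expect_error(simulate_melt_curve(w = 0), "out of range")
})

test_that("the derivative extremum of a clean transition sits at Tm", {
  cv <- simulate_melt_curve(Tm = 60, w = 1, a_f = 0, a_u = 100, noise_sd = 0)
  # independent finite-difference oracle on the raw curve
  d <- diff(cv$fluorescence) / diff(cv$temperature)
  mid <- (cv$temperature[-1] + cv$temperature[-length(cv$temperature)]) / 2
  expect_lt(abs(mid[which.max(d)] - 60), 0.5)
  fit <- extract_tm(cv)
  expect_lt(abs(fit$Tm - 60), 0.05)
  expect_gt(fit$derivative_extremum, 0)
})

test_that("Tm extraction survives 2% noise and flags flat curves", {
  cv <- simulate_melt_curve(Tm = 72.3, noise_sd = 2, seed = 4)
  expect_lt(abs(extract_tm(cv)$Tm - 72.3), 0.3)
  flat <- melt_curve(seq(30, 90, 0.5), rep(50, 121))
  expect_error(extract_tm(flat), "no transition")
  drift <- melt_curve(seq(30, 90, 0.5), seq(0, 100, length.out = 121))
  expect_error(extract_tm(drift), "no transition")
})

test_that("Tm is invariant to fluorescence gain/offset and common baseline slope", {
  cv <- simulate_melt_curve(Tm = 55.7, noise_sd = 2, seed = 9)
  tm0 <- extract_tm(cv)$Tm
  scaled <- melt_curve(cv$temperature, 3.7 * cv$fluorescence + 250)
  expect_equal(extract_tm(scaled)$Tm, tm0, tolerance = 1e-9)
  sloped <- melt_curve(cv$temperature,
                       cv$fluorescence + 0.8 * cv$temperature)
  expect_equal(extract_tm(sloped)$Tm, tm0, tolerance = 1e-6)
})

test_that("the inverted-derivative convention recovers the same Tm", {
  cv <- simulate_melt_curve(Tm = 64, a_f = 100, a_u = 0, noise_sd = 0)
  # fluorescence falls on unfolding: dF/dT has a minimum at Tm
  fit <- extract_tm(cv, derivative_sign = -1)
  expect_lt(abs(fit$Tm - 64), 0.05)
  # with the wrong sign convention a noisy falling curve has no transition
  noisy <- simulate_melt_curve(Tm = 64, a_f = 100, a_u = 0, noise_sd = 2,
                               seed = 11)
  expect_error(extract_tm(noisy, derivative_sign = 1), "no transition")
})

test_that("parameter recovery: bias under 0.1 and RMSE under 0.3 degC at 2% noise", {
  set.seed(321)
  true_tm <- runif(200, 40, 85)
  err <- vapply(seq_along(true_tm), function(i) {
    cv <- simulate_melt_curve(Tm = true_tm[i], noise_sd = 2,
                              seed = 50000 + i)
    extract_tm(cv)$Tm - true_tm[i]
  }, 0)
  expect_lt(abs(mean(err)), 0.1)
  expect_lt(sqrt(mean(err^2)), 0.3)
})

test_that("delta-Tm keeps its sign and magnitude", {
  apo <- extract_tm(simulate_melt_curve(Tm = 60, noise_sd = 0))
  holo <- extract_tm(simulate_melt_curve(Tm = 77.5, noise_sd = 0))
  expect_equal(delta_tm(apo, holo), 17.5, tolerance = 0.01)
  expect_equal(delta_tm(apo, apo), 0)
  below <- extract_tm(simulate_melt_curve(Tm = 58, noise_sd = 0))
  expect_equal(delta_tm(apo, below), -2, tolerance = 0.01)
})

test_that("the shift table masks sub-threshold shifts and keeps the boundary inclusive", {
  apo <- simulate_melt_curve(Tm = 60, noise_sd = 0, protein = "P1")
  mk <- function(tm, lig) simulate_melt_curve(Tm = tm, noise_sd = 0,
                                              protein = "P1", ligand = lig)
  tab <- build_shift_table(list(apo),
                           list(mk(61.4, "weak"), mk(61.5, "edge"),
                                mk(77.5, "strong")),
                           threshold = 1.5)
  fm <- format(tab)
  expect_identical(fm["weak", "P1"], "-")
  expect_identical(fm["edge", "P1"], "1.5")
  expect_identical(fm["strong", "P1"], "17.5")
  # rows are ranked by descending shift
  expect_identical(rownames(fm)[1], "strong")
  # all-apo input gives an empty, all-dash table
  empty <- build_shift_table(list(apo), list(), threshold = 1.5)
  expect_equal(nrow(empty$delta), 0L)
  expect_error(build_shift_table(list(apo),
                                 list(mk(70, "x"),
                                      simulate_melt_curve(Tm = 70,
                                                          protein = "P2",
                                                          ligand = "x"))),
               "missing apo.*P2")
})

test_that("replicate curves are averaged at the Tm level", {
  apo <- lapply(1:2, function(i) simulate_melt_curve(Tm = 60, noise_sd = 2,
                                                     seed = i, protein = "P"))
  holo <- lapply(3:4, function(i) simulate_melt_curve(Tm = 70, noise_sd = 2,
                                                      seed = i, protein = "P",
                                                      ligand = "L"))
  tab <- build_shift_table(apo, holo)
  expect_equal(tab$delta["L", "P"], 10, tolerance = 0.5)
})
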