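# Enzyme-kinetics analytics: residual activity, Michaelis-Menten, fold
# changes, inhibition calls, Dixon geometry, IC50 and selectivity ratios.

test_that("residual activity is the area ratio in percent, scale-invariant", {
  expect_equal(residual_activity(100, 100), 100)
  expect_equal(residual_activity(25, 100), 25)
  expect_equal(residual_activity(0, 100), 0)
  expect_equal(residual_activity(25, 100), residual_activity(25e3, 100e3))
  expect_error(residual_activity(10, 0), "positive")
  expect_error(residual_activity(-1, 10), "non-negative")
})

test_that("Michaelis-Menten fits recover exact and apparent parameters", {
  S <- c(0.5, 1, 2, 5, 10, 20, 50)
  d <- data.frame(substrate_conc_uM = S,
                  rate_uM_min = 2 * S / (5 + S))
  f <- fit_michaelis_menten(d)
  expect_equal(f$km, 5, tolerance = 1e-6)
  expect_equal(f$vmax, 2, tolerance = 1e-6)
  expect_lt(f$rss, 1e-12)
  # apparent-parameter identities at fixed inhibitor concentration
  apparent <- list(
    competitive = c(km = 5 * (1 + 10 / 10), vmax = 2),
    noncompetitive = c(km = 5, vmax = 2 / (1 + 10 / 10)),
    uncompetitive = c(km = 5 / (1 + 10 / 10), vmax = 2 / (1 + 10 / 10)))
  for (mech in names(apparent)) {
    dd <- gen_kinetics_data(kinetics_sim_spec(km = 5, vmax = 2,
                                              mechanism = mech, ki = 10))
    ff <- fit_michaelis_menten(dd[dd$inhibitor_conc_uM == 10, ])
    expect_equal(ff$km, unname(apparent[[mech]]["km"]), tolerance = 1e-6)
    expect_equal(ff$vmax, unname(apparent[[mech]]["vmax"]),
                 tolerance = 1e-6)
  }
  expect_error(fit_michaelis_menten(d[1:3, ]), "at least 4")
})

test_that("noisy Michaelis-Menten fits stay near truth in the median", {
  set.seed(55)
  S <- c(0.5, 1, 2, 5, 10, 20, 50)
  err <- replicate(60, {
    v <- pmax(0, 2 * S / (5 + S) * (1 + rnorm(length(S), 0, 0.05)))
    f <- fit_michaelis_menten(substrate_conc = S, rate = v)
    abs(f$km - 5) / 5
  })
  expect_lt(median(err), 0.10)
})

test_that("fold changes reproduce the published control ratios", {
  expect_equal(format_fold_change(fold_change(1.617, 0.936)), 1.73)
  expect_equal(format_fold_change(fold_change(1168, 690)), 1.69)
  expect_equal(format_fold_change(fold_change(12.46, 19.08)), 0.65)
  expect_equal(format_fold_change(fold_change(0.0631, 0.1078)), 0.59)
  expect_equal(format_fold_change(fold_change(9.191, 19.08)), 0.48)
  expect_equal(fold_change(3.3, 3.3), 1)
  expect_error(fold_change(1, 0), "positive")
})

test_that("inhibition calls follow the fold-change decision table", {
  expect_equal(classify_inhibition(1.73, 1.04)$type, "competitive")
  expect_equal(classify_inhibition(1.04, 0.65)$type, "noncompetitive")
  expect_equal(classify_inhibition(0.5, 0.5)$type, "uncompetitive")
  expect_equal(classify_inhibition(1.73, 0.59)$type, "mixed")
  expect_equal(classify_inhibition(1.0, 1.0)$type, "none")
  expect_equal(classify_inhibition(1.0, 1.4)$type, "none")  # outside table
  # tolerance boundary: 1.15 is "unchanged" at default tol
  expect_equal(classify_inhibition(1.15, 1.0)$type, "none")
  expect_equal(classify_inhibition(1.16, 1.0)$type, "competitive")
  # closed-form apparent folds recover every generating mechanism
  for (mech in c("competitive", "noncompetitive", "uncompetitive")) {
    for (ratio in c(0.5, 1, 2)) {     # I / Ki well above tolerance
      a <- 1 + ratio * 2
      folds <- switch(mech,
                      competitive = c(a, 1),
                      noncompetitive = c(1, 1 / a),
                      uncompetitive = c(1 / a, 1 / a))
      expect_equal(classify_inhibition(folds[1], folds[2])$type, mech)
    }
  }
})

test_that("Dixon geometry identifies each mechanism from noise-free lines", {
  base <- kinetics_sim_spec(km = 5, vmax = 2, ki = 10,
                            substrate_grid = c(1, 2),
                            inhibitor_grid = c(0, 5, 10, 20))
  # competitive: intersection at I = -Ki above the axis (1/v = 1/Vmax)
  base$mechanism <- "competitive"
  dx <- dixon_regression(gen_kinetics_data(base))
  expect_equal(dx$type, "competitive")
  expect_equal(dx$intersection$i, -10, tolerance = 1e-8)
  expect_equal(dx$intersection$inv_v, 1 / 2, tolerance = 1e-8)
  # noncompetitive: intersection at I = -Ki on the axis
  base$mechanism <- "noncompetitive"
  dn <- dixon_regression(gen_kinetics_data(base))
  expect_equal(dn$type, "noncompetitive")
  expect_equal(dn$intersection$i, -10, tolerance = 1e-8)
  expect_lt(abs(dn$intersection$inv_v), 1e-8)
  # uncompetitive: parallel lines
  base$mechanism <- "uncompetitive"
  du <- dixon_regression(gen_kinetics_data(base))
  expect_equal(du$type, "uncompetitive")
  # no inhibition: flat lines, no finite intersection
  base$mechanism <- "none"
  d0 <- dixon_regression(gen_kinetics_data(base))
  expect_equal(d0$type, "none")
  expect_true(is.na(d0$intersection$i))
  # zero rates excluded with a message; too few substrate levels error
  dd <- gen_kinetics_data(base)
  dd$rate_uM_min[1] <- 0
  expect_message(dixon_regression(dd), "zero-rate")
  expect_error(dixon_regression(dd[dd$substrate_conc_uM == 1, ]),
               "at least 2 substrate")
})

test_that("IC50 logistic fits recover the generating midpoint", {
  x <- c(1, 3, 10, 32.14, 100, 300, 1000)
  y <- 100 / (1 + (x / 32.14)^1)
  f <- fit_ic50(x, y)
  expect_equal(f$ic50, 32.14, tolerance = 1e-4)
  expect_equal(f$hill, 1, tolerance = 1e-4)
  # exact 50% activity at a tested concentration with 0/100 asymptotes
  x2 <- c(1, 5, 20, 80, 320)
  y2 <- 100 / (1 + x2 / 20)
  f2 <- fit_ic50(x2, y2)
  expect_equal(f2$ic50, 20, tolerance = 1e-6)
  expect_equal(y2[x2 == 20], 50)
  # steeper hill slopes round-trip too
  y3 <- 5 + (98 - 5) / (1 + (x / 50)^1.7)
  f3 <- fit_ic50(x, y3)
  expect_equal(f3$ic50, 50, tolerance = 1e-4)
  expect_equal(f3$hill, 1.7, tolerance = 1e-3)
  # monotone-increasing activities are rejected
  expect_error(fit_ic50(x, rev(y)), "not determinable")
  expect_error(fit_ic50(x[1:4], y[1:4]), "at least 5")
})

test_that("selectivity ratios reproduce the published table arithmetic", {
  expect_equal(selectivity_ratio(718.4, 1.617), 444.28)
  expect_equal(round(98 / 0.6), 163)
  expect_equal(selectivity_ratio(7.7, 7.7), 1)
  expect_error(selectivity_ratio(1, 0), "positive")
})

test_that("fold-change and Dixon routes agree on synthetic mechanisms", {
  for (mech in c("competitive", "noncompetitive", "uncompetitive")) {
    spec <- kinetics_sim_spec(km = 5, vmax = 2, mechanism = mech, ki = 10,
                              substrate_grid = c(0.5, 1, 2, 5, 10, 20, 50),
                              inhibitor_grid = c(0, 5, 10, 20))
    dat <- gen_kinetics_data(spec)
    ctrl <- fit_michaelis_menten(dat[dat$inhibitor_conc_uM == 0, ])
    inh <- fit_michaelis_menten(dat[dat$inhibitor_conc_uM == 10, ])
    call <- classify_inhibition(fold_change(inh$km, ctrl$km),
                                fold_change(inh$vmax, ctrl$vmax))
    expect_equal(call$type, mech)
    dx <- dixon_regression(
      gen_kinetics_data(kinetics_sim_spec(km = 5, vmax = 2,
                                          mechanism = mech, ki = 10,
                                          substrate_grid = c(1, 2),
                                          inhibitor_grid = c(0, 5, 10,
                                                             20))))
    expect_equal(dx$type, mech)
  }
})

test_that("the kinetics report lays out parameters, folds and ratios", {
  mk <- function(mech, sub, km, vmax) {
    spec <- kinetics_sim_spec(km = km, vmax = vmax, mechanism = mech,
                              ki = 10, inhibitor_grid = c(0, 10))
    d <- gen_kinetics_data(spec)
    d$substrate <- sub
    d$inhibitor[d$inhibitor_conc_uM > 0] <- "cmpdX"
    d
  }
  dat <- rbind(mk("competitive", "SubA", 1, 0.1),
               mk("noncompetitive", "SubB", 600, 20))
  rep <- kinetics_report(dat)
  expect_equal(nrow(rep$parameters), 4)
  fc <- rep$fold_changes
  expect_equal(fc$type[fc$substrate == "SubA"], "competitive")
  expect_equal(fc$type[fc$substrate == "SubB"], "noncompetitive")
  expect_equal(fc$km_fold[fc$substrate == "SubA"], 2, tolerance = 1e-6)
  sel <- rep$selectivity
  expect_equal(sel$km_ratio[sel$inhibitor == "control"],
               round(1 / 600, 2))
})
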