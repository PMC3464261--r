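# Lipari-Szabo machinery: spectral density, forward model, tumbling time,
# per-residue fitting and model selection.

test_that("spectral density matches closed forms and the oracle", {
  tm <- 7.9e-9
  expect_equal(spectral_density(0, 1, tm), 0.4 * tm)
  expect_equal(spectral_density(0, 0.6, tm, 50e-12),
               0.4 * (0.6 * tm + 0.4 / (1 / tm + 1 / 50e-12)),
               tolerance = 1e-12)
  # s2 = 0, tau_e -> 0 kills the function at every frequency
  expect_lt(spectral_density(2 * pi * 60.8e6, 0, tm, 1e-18),
            1e-6 * spectral_density(2 * pi * 60.8e6, 1, tm))
  # value vs an independent literal transcription
  w <- 2 * pi * 60.8e6
  jt <- 0.4 * (0.8 * tm / (1 + (w * tm)^2) +
                 0.2 * (1 / (1 / tm + 1 / 50e-12)) /
                   (1 + (w / (1 / tm + 1 / 50e-12))^2))
  expect_equal(spectral_density(w, 0.8, tm, 50e-12), jt, tolerance = 1e-12)
  expect_error(spectral_density(0, 1, -1), "tau_m")
})

test_that("forward rates agree with the dual-implementation oracle", {
  cases <- list(c(0.8, 50, 0, 7.9), c(1, 0, 0, 7.9), c(0.6, 300, 0, 7.9),
                c(0.8, 0, 3, 7.9), c(0.2, 500, 0, 7.9), c(1, 0, 0, 6.9))
  for (p in cases) {
    got <- forward_rates(p[1], p[2], p[3], p[4])
    want <- oracle_rates(p[1], p[2], p[3], p[4])
    expect_equal(got$r1, unname(want["r1"]), tolerance = 1e-10)
    expect_equal(got$r2, unname(want["r2"]), tolerance = 1e-10)
    expect_equal(got$noe, unname(want["noe"]), tolerance = 1e-10)
  }
})

test_that("exchange is purely additive in R2 and tumbling is monotone", {
  a <- forward_rates(0.8, 20, 0, 7.9)
  b <- forward_rates(0.8, 20, 3, 7.9)
  expect_equal(b$r2 - a$r2, 3, tolerance = 1e-12)
  expect_equal(b$r1, a$r1)
  expect_equal(b$noe, a$noe)
  # R2/R1 grows with tau_m; R2 >= R1 in the slow-tumbling regime
  slow <- forward_rates(1, 0, 0, 7.9)
  fast <- forward_rates(1, 0, 0, 4)
  expect_gt(slow$r2 / slow$r1, fast$r2 / fast$r1)
  expect_gt(slow$r2, slow$r1)
})

test_that("tau_m estimation inverts the rigid-rotor ratio", {
  for (tm in c(1, 4, 6.9, 7.9, 12, 20)) {
    fr <- forward_rates(1, 0, 0, tm)
    expect_equal(estimate_tau_m(fr$r1, fr$r2), tm, tolerance = 1e-4 * tm)
  }
  # +5% on R2 raises the estimate; magnitude matches a brute-force scan
  fr <- forward_rates(1, 0, 0, 7.9)
  bumped <- estimate_tau_m(fr$r1, fr$r2 * 1.05)
  expect_gt(bumped, 7.9)
  expect_equal(bumped, oracle_tau_m(fr$r1, fr$r2 * 1.05), tolerance = 0.01)
  # a ratio outside the bracket range flags as NA
  expect_true(is.na(estimate_tau_m(10, 10.0001)))
})

test_that("tumbling subset selection excludes mobile and exchange residues", {
  fr <- forward_rates(1, 0, 0, 7.9)
  n <- 12
  rates <- data.frame(residue_index = 1:n,
                      r1 = rep(fr$r1, n), r1_err = 0.01,
                      r2 = rep(fr$r2, n), r2_err = 0.1,
                      noe = rep(fr$noe, n), noe_err = 0.01)
  ts <- select_tumbling_subset(rates)
  expect_equal(length(ts$included), n)
  expect_equal(ts$average_tau_m, 7.9, tolerance = 1e-4)
  # a low-NOE residue is excluded by the threshold rule
  rates$noe[4] <- 0.3
  ts2 <- select_tumbling_subset(rates)
  expect_false(4 %in% ts2$included)
  expect_equal(ts2$excluded$reason[ts2$excluded$residue_index == 4],
               "NOE below threshold")
  # an exchange-shifted R2 is trimmed as a T1/T2 outlier
  rates$r2[7] <- rates$r2[7] + 4
  ts3 <- select_tumbling_subset(rates)
  expect_false(7 %in% ts3$included)
  expect_equal(ts3$average_tau_m, 7.9, tolerance = 1e-4)
  expect_error(select_tumbling_subset(rates[1:4, ]), "fewer than 5")
})

test_that("model-free fitting recovers noiseless parameters exactly", {
  mk_obs <- function(s2, te, rex) {
    fr <- forward_rates(s2, te, rex, 7.9)
    data.frame(r1 = fr$r1, r1_err = 0.02 * fr$r1,
               r2 = fr$r2, r2_err = 0.02 * fr$r2,
               noe = fr$noe, noe_err = 0.02)
  }
  f1 <- fit_modelfree(mk_obs(0.8, 0, 0), 7.9)
  expect_equal(f1$model, "M1")
  expect_equal(f1$s2, 0.8, tolerance = 1e-6)
  expect_lt(f1$chi2, 1e-8)
  f3 <- fit_modelfree(mk_obs(0.8, 0, 3), 7.9)
  expect_equal(f3$model, "M3")
  expect_equal(f3$rex, 3, tolerance = 1e-4)
  expect_equal(f3$s2, 0.8, tolerance = 1e-6)
  expect_lt(f3$chi2, 1e-8)
  f2 <- fit_modelfree(mk_obs(0.7, 500, 0), 7.9)
  expect_equal(f2$model, "M2")
  expect_equal(f2$tau_e, 500, tolerance = 0.05)
  expect_lt(f2$chi2, 1e-8)
  # selected-model chi2 never exceeds a rejected simpler model's chi2
  expect_lte(f3$chi2, f3$candidates$chi2[f3$candidates$model == "M1"])
  expect_error(fit_modelfree(within(mk_obs(0.8, 0, 0), r1_err <- 0), 7.9),
               "> 0")
})

test_that("noisy S2+Rex triples agree with a brute-force grid oracle", {
  fr <- forward_rates(0.82, 0, 2.5, 7.9)
  set.seed(31)
  obs <- data.frame(r1 = fr$r1 * 1.01, r1_err = 0.02 * fr$r1,
                    r2 = fr$r2 * 0.99, r2_err = 0.02 * fr$r2,
                    noe = fr$noe + 0.01, noe_err = 0.02)
  fit <- relaxkit:::mf_fit_model("M3", obs, 7.9, spin_constants())
  oracle <- oracle_fit_s2rex(obs, 7.9)
  expect_equal(fit$s2, oracle$s2, tolerance = 0.01)
  expect_equal(fit$rex, oracle$rex, tolerance = 0.1)
  expect_lte(fit$chi2, oracle$chi2 + 1e-8)
})

test_that("tau_e model is selected reliably under realistic noise", {
  fr <- forward_rates(0.8, 500, 0, 7.9)
  set.seed(77)
  n_rep <- 60
  picked <- vapply(seq_len(n_rep), function(k) {
    obs <- data.frame(r1 = rnorm(1, fr$r1, 0.01 * fr$r1),
                      r1_err = 0.01 * fr$r1,
                      r2 = rnorm(1, fr$r2, 0.01 * fr$r2),
                      r2_err = 0.01 * fr$r2,
                      noe = rnorm(1, fr$noe, 0.012),
                      noe_err = 0.012)
    fit_modelfree(obs, 7.9)$model
  }, character(1))
  expect_gte(mean(picked == "M2"), 0.8)
})

test_that("model_free object supports the standard S3 verbs", {
  prof <- generate_profile(16, seed = 3)
  ds <- generate_dataset(prof, tau_m = 7.9, seed = 4)
  rt <- extract_rates(ds, n_mc = 60, seed = 5)
  fit <- model_free(rt)
  expect_s3_class(fit, "model_free")
  cf <- coef(fit)
  expect_equal(dim(cf), c(16, 3))
  expect_true(all(cf[, "s2"] >= 0 & cf[, "s2"] <= 1))
  pr <- predict(fit)
  expect_equal(nrow(pr), 16)
  res <- residuals(fit)
  # standardized residuals of a healthy fit are O(1)
  expect_lt(stats::median(abs(res$r1)), 3)
  sims <- simulate(fit, nsim = 2, seed = 9)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "rates_table")
  expect_identical(simulate(fit, nsim = 2, seed = 9), sims)
  s <- summary(fit)
  expect_s3_class(s, "summary.model_free")
  expect_output(print(fit), "model-free")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
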