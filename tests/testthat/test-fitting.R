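# fitting layer: goodness-of-fit arithmetic, recovery, failure taxonomy,
# bookkeeping, residual diagnostics

test_that("goodness_of_fit matches its closed forms", {
  obs <- c(0, 5, 12, 20)
  g0 <- goodness_of_fit(obs, obs, k = 2)
  expect_equal(g0$r2, 1)
  expect_equal(g0$rss, 0)

  # n = 9, rss = 9 => sigma2 = 1 => loglik = -(9/2)(log(2 pi) + 1)
  obs9 <- c(0, 2, 5, 9, 14, 20, 27, 35, 44)
  pred9 <- obs9 + 1
  g1 <- goodness_of_fit(obs9, pred9, k = 3)
  expect_equal(g1$rss, 9)
  expect_equal(g1$loglik, -(9 / 2) * (log(2 * pi) + 1))
  expect_equal(g1$loglik, -12.7704, tolerance = 1e-4)

  # published-cell arithmetic: k = 4, n = 9, loglik = -7 -> BIC 22.79
  bic <- 4 * log(9) - 2 * (-7)
  expect_equal(bic, 22.789, tolerance = 1e-3)
  expect_equal(g1$bic, 3 * log(9) - 2 * g1$loglik)

  expect_error(goodness_of_fit(rep(3, 5), rep(3, 5), 2), "zero variance")
  expect_error(goodness_of_fit(1:3, 1:4, 2), "lengths differ")
})

test_that("BIC identity holds on fitted records", {
  prof <- simulate_profile("Log-logistic",
                           table2_presets("Log-logistic", "Corn"),
                           noise_sd = 2, seed = 9)
  fits <- fit_all(list(prof), models = c("Log-logistic", "Weibull",
                                         "Cauchy", "Rayleigh 2p"),
                  options = fast_opts())
  ok <- fits$converged
  expect_true(all(ok))
  expect_equal(fits$bic[ok],
               fits$k[ok] * log(fits$n[ok]) - 2 * fits$loglik[ok])
})

test_that("noise-free profiles are recovered exactly", {
  p <- table2_presets("Exponential 2p", "Compound")
  prof <- simulate_profile("Exponential 2p", p, noise_sd = 0,
                           zero_origin = FALSE)
  f <- fit_model(prof, "Exponential 2p")
  expect_true(f$converged)
  expect_equal(f$m, p[["m"]], tolerance = 1e-4)
  expect_equal(f$r, p[["r"]], tolerance = 1e-4)
  expect_lt(f$rss, 1e-10)
  expect_equal(f$r2, 1, tolerance = 1e-10)
})

test_that("the generating model beats a wrong model on BIC", {
  p <- table2_presets("Burr XII", "Compound")
  prof <- simulate_profile("Burr XII", p, noise_sd = 0, zero_origin = FALSE)
  fb <- fit_model(prof, "Burr XII")
  fc <- fit_model(prof, "Cauchy")
  expect_true(fb$converged && fc$converged)
  expect_lt(fb$bic, fc$bic)
})

test_that("degenerate profiles fail with a taxonomy reason, not an error", {
  prof <- gp_profile("flat", gp_times(), rep(0, 9))
  f <- fit_model(prof, "Exponential 2p")
  expect_false(f$converged)
  expect_identical(f$failure_reason, "no-convergence")
  expect_true(is.na(f$bic))
  expect_true(is.na(f$t_half))
})

test_that("fit_all bookkeeping: one record per profile-model pair", {
  prof <- simulate_profile("Weibull", table2_presets("Weibull", "Legumes"),
                           noise_sd = 1, seed = 3)
  one <- fit_all(list(prof), models = "Weibull", options = fast_opts())
  expect_identical(nrow(one), 1L)

  cfg <- gp_default_config("small")  # 6 categories x 2 feeds x 3 reps
  prof_df <- simulate_dataset(cfg, seed = 21)
  profs <- as_gp_profiles(prof_df)
  sub <- profs[1:12]
  fits <- fit_all(sub, options = fast_opts())
  expect_identical(nrow(fits), 12L * 21L)
  # every profile converges under its generating model
  gen <- fits[fits$model == "Burr XII", ]
  expect_true(all(gen$converged))
  expect_error(fit_all(list(), models = "Weibull"), "no profiles")
  expect_error(fit_all(list(prof), models = "Nope"), "unknown model")
})

test_that("fits are deterministic given options and seed", {
  prof <- simulate_profile("Dagum", table2_presets("Dagum", "Corn"),
                           noise_sd = 1.5, seed = 8)
  f1 <- fit_model(prof, "Gompertz", gp_fit_options(seed = 5))
  f2 <- fit_model(prof, "Gompertz", gp_fit_options(seed = 5))
  expect_identical(f1, f2)
})

test_that("extra parameters never increase rss for nested pairs", {
  prof <- simulate_profile("Exponential 2p",
                           table2_presets("Exponential 2p", "Corn"),
                           noise_sd = 2, seed = 17)
  f2 <- fit_model(prof, "Exponential 2p")
  f3 <- fit_model(prof, "Exponential 3p")
  fw <- fit_model(prof, "Weibull")
  expect_lte(f3$rss, f2$rss + 1e-6)
  # Weibull contains Exponential 2p at the a = 1 boundary
  expect_lte(fw$rss, f2$rss + 1e-6)
})

test_that("profiles need more points than parameters", {
  short <- gp_profile("s", c(0, 4, 12), c(0, 10, 30))
  expect_error(fit_model(short, "Burr XII"), "at least")
})

test_that("residual diagnostics report residuals and sign runs", {
  p <- table2_presets("Log-logistic", "Compound")
  prof <- simulate_profile("Log-logistic", p, noise_sd = 0)
  f <- fit_model(prof, "Log-logistic")
  d <- residual_diagnostics(f, prof)
  expect_true(all(abs(d$residuals$residual) < 1e-6))

  # a rigid model fit to a sigmoid leaves patterned (few-runs) residuals
  sig <- simulate_profile("Logistic", c(m = 60, r = 0.6, mu = 10),
                          noise_sd = 0)
  fr <- fit_model(sig, "Exponential 2p")
  dr <- residual_diagnostics(fr, sig)
  expect_lt(dr$runs, dr$expected_runs)

  # noise-only residuals: grand mean within 3 SE of zero, SE from the known
  # noise sd over all pooled readings (Monte Carlo)
  set.seed(99)
  n_rep <- 30
  means <- replicate(n_rep, {
    pr <- simulate_profile("Weibull", table2_presets("Weibull", "Corn"),
                           noise_sd = 1, seed = sample.int(1e6, 1))
    ff <- fit_model(pr, "Weibull", fast_opts())
    residual_diagnostics(ff, pr)$mean_residual
  })
  expect_lt(abs(mean(means)), 3 * 1 / sqrt(9 * n_rep))

  bad <- fit_model(gp_profile("flat", gp_times(), rep(0, 9)), "Weibull")
  expect_error(residual_diagnostics(bad, prof), "converged")
})
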