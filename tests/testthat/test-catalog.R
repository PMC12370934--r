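# model catalogue: structure, pointwise evaluation, analytic kinetics,
# parameter validation

test_that("catalogue has the fixed 21 entries with the right arities", {
  models <- gp_models()
  expect_length(models, 21)
  ks <- vapply(models, `[[`, 0L, "k")
  two_par <- c("Exponential 2p", "Generalized logistic", "Half logistic",
               "Inverse exponential", "Rayleigh 2p")
  four_par <- c("Burr XII", "Dagum")
  expect_setequal(names(ks)[ks == 2L], two_par)
  expect_setequal(names(ks)[ks == 4L], four_par)
  expect_true(all(ks[setdiff(names(ks), c(two_par, four_par))] == 3L))
  expect_identical(gp_model("Burr XII")$params, c("m", "r", "a", "p"))
  expect_identical(gp_model("Generalized logistic")$params, c("m", "a"))
  for (spec in models)
    expect_identical(spec$k, length(spec$params))
  expect_error(gp_model("Richards"), "unknown model")
})

test_that("cdf/pdf match closed-form spot values", {
  expect_identical(gp_cdf("Exponential 2p", c(m = 10, r = 0.1), 0), 0)
  # t = 1/r is the analytic log-logistic median
  expect_equal(gp_cdf("Log-logistic", c(m = 10, r = 0.125, a = 1.7), 8), 5)
  expect_equal(gp_pdf("Exponential 2p", c(m = 10, r = 0.1), 0), 1.0)
  # logistic rate at its centre: m r / 4
  expect_equal(gp_pdf("Logistic", c(m = 10, r = 0.5, mu = 5), 5), 1.25)
})

test_that("Burr XII cdf equals the quadrature of its pdf", {
  p <- table2_presets("Burr XII", "Compound")
  num <- integrate(function(t) gp_pdf("Burr XII", p, t), 0, 6,
                   rel.tol = 1e-10)$value
  expect_equal(gp_cdf("Burr XII", p, 6), num, tolerance = 1e-6)
})

test_that("kinetic summaries match the analytic formulas and oracles", {
  k1 <- kinetic_summary("Exponential 2p", c(m = 68.2, r = 0.085))
  expect_identical(k1$t_star, 0)
  expect_false(k1$t_star_defined)
  expect_equal(k1$t_half, log(2) / 0.085)
  expect_equal(k1$gp_half, 34.1)

  k2 <- kinetic_summary("Cauchy", c(m = 60, r = 0.3, mu = 7.9))
  expect_equal(k2$t_star, 7.9)
  expect_equal(k2$t_half, 7.9)

  p3 <- c(m = 1, r = 0.1, a = 2, p = 1)
  k3 <- kinetic_summary("Burr XII", p3)
  expect_equal(k3$t_half, 10.0)
  expect_equal(k3$t_star, sqrt(1 / 3) / 0.1)
  spec <- gp_model("Burr XII")
  expect_equal(k3$t_half, oracle_t_half(spec, p3),
               tolerance = 1e-6)
  expect_equal(k3$t_star, oracle_t_star(spec, p3),
               tolerance = 1e-6)
})

test_that("t* precondition failures are flagged and reported as 0", {
  # published-style case: fitted Gompertz shape below 1
  k <- kinetic_summary("Gompertz", c(m = 54.3, r = 0.081, a = 0.989))
  expect_false(k$t_star_defined)
  expect_identical(k$t_star, 0)
  expect_identical(k$gp_star, 0)
  # gp_half stays m/2 regardless
  expect_equal(k$gp_half, 54.3 / 2)
})

test_that("validate_params enforces the declared assumptions", {
  v <- validate_params("Burr XII", c(m = 70, r = 0.1, a = 0.9, p = 1.5))
  expect_false(v$valid)
  expect_true("a>1" %in% v$violations)
  v2 <- validate_params("Weibull", c(m = 77.9, r = 0.132, a = 1.414))
  expect_true(v2$valid)
  expect_length(v2$violations, 0)
  v3 <- validate_params("Exponential 2p", c(m = 10, r = -0.1))
  expect_false(v3$valid)
  expect_true("r>0" %in% v3$violations)
  # evaluability errors name the violated positivity assumption
  expect_error(gp_cdf("Exponential 2p", c(m = 10, r = -0.1), 4), "r>0")
  expect_error(gp_cdf("Burr XII", c(m = -1, r = 0.1, a = 2, p = 1), 4),
               "m>0")
})

test_that("cdf is a monotone [0, m] curve and pdf is non-negative", {
  set.seed(41)
  grid <- c(seq(0, 72, by = 1.5), seq(80, 500, by = 20))
  for (spec in gp_models()) {
    for (i in 1:10) {
      p <- draw_valid_params(spec)
      v <- gp_cdf(spec, p, grid)
      expect_true(all(diff(v) >= -1e-9), label = spec$name)
      expect_true(all(v >= 0 & v <= p[["m"]] + 1e-9), label = spec$name)
      expect_gte(v[length(v)] / p[["m"]],
                 gp_cdf(spec, p, 72) / p[["m"]] - 1e-12)
      expect_true(all(gp_pdf(spec, p, grid) >= 0), label = spec$name)
    }
  }
})

test_that("analytic kinetics agree with numeric oracles on random draws", {
  set.seed(42)
  for (spec in gp_models()) {
    for (i in 1:10) {
      p <- draw_valid_params(spec)
      kin <- kinetic_summary(spec, p)
      expect_equal(kin$gp_half, p[["m"]] / 2, label = spec$name)
      th <- oracle_t_half(spec, p)
      expect_lt(abs(th - kin$t_half), 1e-6 * (1 + abs(kin$t_half)),
                label = spec$name)
      if (kin$t_star_defined) {
        ts <- oracle_t_star(spec, p)
        expect_lt(abs(ts - kin$t_star), 1e-6 * (1 + abs(kin$t_star)),
                  label = spec$name)
        expect_equal(kin$gp_star, gp_cdf(spec, p, kin$t_star))
      }
    }
  }
})

test_that("pdf matches the central finite difference of cdf", {
  set.seed(43)
  for (spec in gp_models()) {
    p <- draw_valid_params(spec)
    kin <- kinetic_summary(spec, p)
    tt <- kin$t_half * c(0.3, 0.7, 1.3, 2) + 0.3
    h <- 1e-5 * (1 + tt)
    fd <- (gp_cdf(spec, p, tt + h) - gp_cdf(spec, p, tt - h)) / (2 * h)
    an <- gp_pdf(spec, p, tt)
    expect_lt(max(abs(fd - an) / (1e-12 + abs(an))), 1e-6,
              label = spec$name)
  }
})
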