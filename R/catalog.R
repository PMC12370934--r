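# Model catalogue: 21 phenomenological GP models, each a scaled CDF
# F(t) = m * F_u(t) with unit CDF F_u, rate f(t) = m * f_u(t), analytic
# inflection time t* (mode of f) and half-life t0.5 (median of f).

#' Canonical parameter order used throughout the package
#' @keywords internal
.gp_par_names <- c("m", "r", "mu", "a", "p")

#' Hohenheim Gas Test reading times
#'
#' The standard nine recording times (h) of the Hohenheim Gas Test design.
#'
#' @return Numeric vector `c(0, 2, 4, 6, 8, 12, 24, 48, 72)`.
#' @export
gp_times <- function() c(0, 2, 4, 6, 8, 12, 24, 48, 72)

#' The six feed categories
#'
#' @return Character vector of the six feed-category labels.
#' @export
gp_feed_categories <- function() {
  c("Compound", "Corn", "Processed protein", "Legumes", "Soft cereal", "Others")
}

# expm1(x)/x with a stable limit at 0; used by the Gompertz curve so that the
# a -> 1 boundary degenerates smoothly to the exponential model.
.phi1 <- function(x) {
  out <- ifelse(abs(x) < 1e-8, 1 + x / 2, expm1(x) / x)
  out
}

# Each catalogue entry:
#   name         model name (Table-style label used in the field)
#   params       ordered subset of (m, r, mu, a, p)
#   cdf_unit     function(t, par) -> F_u(t) in [0, 1], vectorised in t,
#                already 0 below the domain and at singular t = 0 limits
#   pdf_unit     function(t, par) -> f_u(t) >= 0
#   t_star      function(par) -> list(value, defined); value is the analytic
#                mode when defined, otherwise the domain edge (reported as-is
#                for mu-edge models, 0 when the precondition fails)
#   t_half      function(par) -> analytic median
#   domain_lower function(par) -> 0, mu, or -Inf
#   assumptions  list(name = function(par) TRUE/FALSE) of the declared
#                shape assumptions (beyond m, r > 0), with display strings
#   fit_domain   function(par) -> TRUE if the curve is evaluable (positivity)
.gp_entry <- function(name, params, cdf_unit, pdf_unit, t_star, t_half,
                      domain_lower = function(par) 0,
                      assumptions = list(),
                      t_star_text = "", t_half_text = "") {
  list(name = name, params = params, k = length(params),
       cdf_unit = cdf_unit, pdf_unit = pdf_unit,
       t_star = t_star, t_half = t_half, domain_lower = domain_lower,
       assumptions = assumptions,
       t_star_text = t_star_text, t_half_text = t_half_text)
}

# helper for interior-mode t*: undefined (-> 0) when the formula value is not
# finite or lies below the domain lower bound
.mode_or_zero <- function(value, lower = 0) {
  if (is.finite(value) && value >= lower) list(value = value, defined = TRUE)
  else list(value = 0, defined = FALSE)
}

.gp_catalog_build <- function() {
  A <- list(
    a_gt0 = list(label = "a>0", test = function(par) par[["a"]] > 0),
    a_gt1 = list(label = "a>1", test = function(par) par[["a"]] > 1),
    p_gt0 = list(label = "p>0", test = function(par) par[["p"]] > 0),
    p_gt1 = list(label = "p>1", test = function(par) par[["p"]] > 1)
  )
  cat <- list()

  cat[["Burr III"]] <- .gp_entry(
    "Burr III", c("m", "a", "p"),
    cdf_unit = function(t, par) {
      a <- par[["a"]]; p <- par[["p"]]
      out <- numeric(length(t))
      pos <- t > 0
      out[pos] <- (1 + t[pos]^(-a))^(-p)
      out
    },
    pdf_unit = function(t, par) {
      a <- par[["a"]]; p <- par[["p"]]
      out <- numeric(length(t))
      pos <- t > 0
      tp <- t[pos]
      out[pos] <- a * p * (1 + tp^(-a))^(-p) / ((1 + tp^a) * tp)
      out
    },
    t_star = function(par) {
      a <- par[["a"]]; p <- par[["p"]]
      if (a * p > 1) .mode_or_zero(((a * p - 1) / (1 + a))^(1 / a))
      else list(value = 0, defined = FALSE)
    },
    t_half = function(par) (2^(1 / par[["p"]]) - 1)^(-1 / par[["a"]]),
    assumptions = A[c("a_gt1", "p_gt1")],
    t_star_text = "((a p - 1)/(1 + a))^(1/a)",
    t_half_text = "(2^(1/p) - 1)^(-1/a)"
  )

  cat[["Burr XII"]] <- .gp_entry(
    "Burr XII", c("m", "r", "a", "p"),
    cdf_unit = function(t, par) {
      r <- par[["r"]]; a <- par[["a"]]; p <- par[["p"]]
      out <- numeric(length(t))
      pos <- t > 0
      out[pos] <- 1 - (1 + (r * t[pos])^a)^(-p)
      out
    },
    pdf_unit = function(t, par) {
      r <- par[["r"]]; a <- par[["a"]]; p <- par[["p"]]
      out <- numeric(length(t))
      pos <- t > 0
      tp <- t[pos]
      out[pos] <- a * p * (r * tp)^a / ((1 + (r * tp)^a)^(p + 1) * tp)
      out
    },
    t_star = function(par) {
      a <- par[["a"]]; p <- par[["p"]]; r <- par[["r"]]
      if (a > 1) .mode_or_zero(((a - 1) / (1 + a * p))^(1 / a) / r)
      else list(value = 0, defined = FALSE)
    },
    t_half = function(par)
      (2^(1 / par[["p"]]) - 1)^(1 / par[["a"]]) / par[["r"]],
    assumptions = A[c("p_gt0", "a_gt1")],
    t_star_text = "((a - 1)/(1 + a p))^(1/a) / r",
    t_half_text = "(2^(1/p) - 1)^(1/a) / r"
  )

  cat[["Cauchy"]] <- .gp_entry(
    "Cauchy", c("m", "r", "mu"),
    cdf_unit = function(t, par)
      0.5 + atan(par[["r"]] * (t - par[["mu"]])) / pi,
    pdf_unit = function(t, par) {
      r <- par[["r"]]
      r / (pi * (1 + r^2 * (t - par[["mu"]])^2))
    },
    t_star = function(par) list(value = par[["mu"]], defined = TRUE),
    t_half = function(par) par[["mu"]],
    domain_lower = function(par) -Inf,
    t_star_text = "mu", t_half_text = "mu"
  )

  cat[["Dagum"]] <- .gp_entry(
    "Dagum", c("m", "r", "a", "p"),
    cdf_unit = function(t, par) {
      r <- par[["r"]]; a <- par[["a"]]; p <- par[["p"]]
      out <- numeric(length(t))
      pos <- t > 0
      out[pos] <- (1 + (r * t[pos])^(-a))^(-p)
      out
    },
    pdf_unit = function(t, par) {
      r <- par[["r"]]; a <- par[["a"]]; p <- par[["p"]]
      out <- numeric(length(t))
      pos <- t > 0
      tp <- t[pos]
      out[pos] <- a * p * (r * tp)^(a * p) /
        ((1 + (r * tp)^a)^(p + 1) * tp)
      out
    },
    t_star = function(par) {
      a <- par[["a"]]; p <- par[["p"]]; r <- par[["r"]]
      if (a * p > 1) .mode_or_zero(((a * p - 1) / (a + 1))^(1 / a) / r)
      else list(value = 0, defined = FALSE)
    },
    t_half = function(par)
      (2^(1 / par[["p"]]) - 1)^(-1 / par[["a"]]) / par[["r"]],
    assumptions = A[c("a_gt1", "p_gt1")],
    t_star_text = "((a p - 1)/(a + 1))^(1/a) / r",
    t_half_text = "(2^(1/p) - 1)^(-1/a) / r"
  )

  cat[["Exponential 2p"]] <- .gp_entry(
    "Exponential 2p", c("m", "r"),
    cdf_unit = function(t, par) ifelse(t > 0, -expm1(-par[["r"]] * t), 0),
    pdf_unit = function(t, par)
      ifelse(t >= 0, par[["r"]] * exp(-par[["r"]] * t), 0),
    # density is monotone decreasing: mode sits on the t = 0 boundary
    t_star = function(par) list(value = 0, defined = FALSE),
    t_half = function(par) log(2) / par[["r"]],
    t_star_text = "0", t_half_text = "log(2)/r"
  )

  cat[["Exponential 3p"]] <- .gp_entry(
    "Exponential 3p", c("m", "r", "mu"),
    cdf_unit = function(t, par) {
      d <- t - par[["mu"]]
      ifelse(d > 0, -expm1(-par[["r"]] * d), 0)
    },
    pdf_unit = function(t, par) {
      d <- t - par[["mu"]]
      ifelse(d >= 0, par[["r"]] * exp(-par[["r"]] * d), 0)
    },
    t_star = function(par) list(value = par[["mu"]], defined = FALSE),
    t_half = function(par) par[["mu"]] + log(2) / par[["r"]],
    domain_lower = function(par) par[["mu"]],
    t_star_text = "mu", t_half_text = "mu + log(2)/r"
  )

  cat[["Exponentiated exponential"]] <- .gp_entry(
    "Exponentiated exponential", c("m", "r", "a"),
    cdf_unit = function(t, par)
      ifelse(t > 0, (-expm1(-par[["r"]] * t))^par[["a"]], 0),
    pdf_unit = function(t, par) {
      r <- par[["r"]]; a <- par[["a"]]
      out <- numeric(length(t))
      pos <- t > 0
      tp <- t[pos]
      u <- -expm1(-r * tp)                       # 1 - e^{-rt}
      out[pos] <- a * r * u^(a - 1) * exp(-r * tp)
      # at t = 0 the density is a*r for a = 1, 0 for a > 1, +Inf for a < 1
      at0 <- t == 0
      if (any(at0)) out[at0] <- if (a > 1) 0 else if (a == 1) a * r else Inf
      out
    },
    t_star = function(par) {
      a <- par[["a"]]
      if (a > 1) .mode_or_zero(log(a) / par[["r"]])
      else list(value = 0, defined = FALSE)
    },
    t_half = function(par) -log(1 - 2^(-1 / par[["a"]])) / par[["r"]],
    assumptions = A["a_gt0"],
    t_star_text = "log(a)/r", t_half_text = "-log(1 - 2^(-1/a))/r"
  )

  cat[["Frechet"]] <- .gp_entry(
    "Frechet", c("m", "r", "a"),
    cdf_unit = function(t, par) {
      r <- par[["r"]]; a <- par[["a"]]
      out <- numeric(length(t))
      pos <- t > 0
      out[pos] <- exp(-(r * t[pos])^(-a))
      out
    },
    pdf_unit = function(t, par) {
      r <- par[["r"]]; a <- par[["a"]]
      out <- numeric(length(t))
      pos <- t > 0
      tp <- t[pos]
      out[pos] <- a * exp(-(r * tp)^(-a)) / (r^a * tp^(1 + a))
      out
    },
    t_star = function(par)
      .mode_or_zero((par[["a"]] / (1 + par[["a"]]))^(1 / par[["a"]]) /
                      par[["r"]]),
    t_half = function(par) log(2)^(-1 / par[["a"]]) / par[["r"]],
    assumptions = A["a_gt0"],
    t_star_text = "(a/(1 + a))^(1/a) / r", t_half_text = "log(2)^(-1/a) / r"
  )

  cat[["Generalized logistic"]] <- .gp_entry(
    "Generalized logistic", c("m", "a"),
    cdf_unit = function(t, par) 1 - (1 + exp(t))^(-par[["a"]]),
    pdf_unit = function(t, par) {
      a <- par[["a"]]
      a * exp(t) / (1 + exp(t))^(a + 1)
    },
    t_star = function(par) list(value = -log(par[["a"]]), defined = TRUE),
    t_half = function(par) log(2^(1 / par[["a"]]) - 1),
    domain_lower = function(par) -Inf,
    assumptions = A["a_gt0"],
    t_star_text = "-log(a)", t_half_text = "log(2^(1/a) - 1)"
  )

  cat[["Gompertz"]] <- .gp_entry(
    "Gompertz", c("m", "r", "a"),
    cdf_unit = function(t, par) {
      r <- par[["r"]]; la <- log(par[["a"]])
      out <- -expm1(-r * t * .phi1(t * la))
      ifelse(t > 0, out, 0)
    },
    pdf_unit = function(t, par) {
      r <- par[["r"]]; la <- log(par[["a"]])
      out <- r * exp(t * la) * exp(-r * t * .phi1(t * la))
      ifelse(t >= 0, out, 0)
    },
    t_star = function(par) {
      a <- par[["a"]]; r <- par[["r"]]
      if (a > 1) .mode_or_zero(log(log(a) / r) / log(a))
      else list(value = 0, defined = FALSE)
    },
    t_half = function(par) {
      la <- log(par[["a"]])
      if (abs(la) < 1e-12) return(log(2) / par[["r"]])  # a -> 1 limit
      arg <- 1 + log(2) * la / par[["r"]]
      # a < 1 curves saturate below m; m/2 may never be reached
      if (arg <= 0) return(NA_real_)
      log(arg) / la
    },
    assumptions = A["a_gt1"],
    t_star_text = "log(log(a)/r)/log(a)",
    t_half_text = "log(1 + log(2) log(a)/r)/log(a)"
  )

  cat[["Gumbel"]] <- .gp_entry(
    "Gumbel", c("m", "r", "mu"),
    cdf_unit = function(t, par)
      -expm1(-exp(par[["r"]] * (t - par[["mu"]]))),
    pdf_unit = function(t, par) {
      z <- par[["r"]] * (t - par[["mu"]])
      par[["r"]] * exp(z - exp(z))
    },
    t_star = function(par) list(value = par[["mu"]], defined = TRUE),
    t_half = function(par) par[["mu"]] + log(log(2)) / par[["r"]],
    domain_lower = function(par) -Inf,
    t_star_text = "mu", t_half_text = "mu + log(log(2))/r"
  )

  cat[["Half Cauchy"]] <- .gp_entry(
    "Half Cauchy", c("m", "r", "mu"),
    cdf_unit = function(t, par) {
      d <- t - par[["mu"]]
      ifelse(d > 0, 2 * atan(par[["r"]] * d) / pi, 0)
    },
    pdf_unit = function(t, par) {
      r <- par[["r"]]; d <- t - par[["mu"]]
      ifelse(d >= 0, 2 * r / (pi * (1 + r^2 * d^2)), 0)
    },
    t_star = function(par) list(value = par[["mu"]], defined = FALSE),
    t_half = function(par) par[["mu"]] + 1 / par[["r"]],
    domain_lower = function(par) par[["mu"]],
    t_star_text = "mu", t_half_text = "mu + 1/r"
  )

  cat[["Half logistic"]] <- .gp_entry(
    "Half logistic", c("m", "r"),
    cdf_unit = function(t, par) ifelse(t > 0, tanh(par[["r"]] * t / 2), 0),
    pdf_unit = function(t, par)
      ifelse(t >= 0, par[["r"]] / (1 + cosh(par[["r"]] * t)), 0),
    t_star = function(par) list(value = 0, defined = FALSE),
    t_half = function(par) log(3) / par[["r"]],
    t_star_text = "0", t_half_text = "log(3)/r"
  )

  cat[["Inverse exponential"]] <- .gp_entry(
    "Inverse exponential", c("m", "r"),
    cdf_unit = function(t, par) {
      out <- numeric(length(t))
      pos <- t > 0
      out[pos] <- exp(-1 / (par[["r"]] * t[pos]))
      out
    },
    pdf_unit = function(t, par) {
      r <- par[["r"]]
      out <- numeric(length(t))
      pos <- t > 0
      tp <- t[pos]
      out[pos] <- exp(-1 / (r * tp)) / (r * tp^2)
      out
    },
    t_star = function(par) .mode_or_zero(1 / (2 * par[["r"]])),
    t_half = function(par) 1 / (par[["r"]] * log(2)),
    t_star_text = "1/(2r)", t_half_text = "1/(r log(2))"
  )

  cat[["Inverse paralogistic"]] <- .gp_entry(
    "Inverse paralogistic", c("m", "r", "a"),
    cdf_unit = function(t, par) {
      r <- par[["r"]]; a <- par[["a"]]
      out <- numeric(length(t))
      pos <- t > 0
      u <- (r * t[pos])^a
      out[pos] <- (u / (1 + u))^a
      out
    },
    pdf_unit = function(t, par) {
      r <- par[["r"]]; a <- par[["a"]]
      out <- numeric(length(t))
      pos <- t > 0
      tp <- t[pos]
      u <- (r * tp)^a
      out[pos] <- a^2 * (u / (1 + u))^a / ((1 + u) * tp)
      out
    },
    t_star = function(par) {
      a <- par[["a"]]
      if (a > 1) .mode_or_zero((a - 1)^(1 / a) / par[["r"]])
      else list(value = 0, defined = FALSE)
    },
    t_half = function(par)
      (2^(1 / par[["a"]]) - 1)^(-1 / par[["a"]]) / par[["r"]],
    assumptions = A["a_gt1"],
    t_star_text = "(a - 1)^(1/a) / r",
    t_half_text = "(2^(1/a) - 1)^(-1/a) / r"
  )

  cat[["Logistic"]] <- .gp_entry(
    "Logistic", c("m", "r", "mu"),
    cdf_unit = function(t, par)
      plogis(par[["r"]] * (t - par[["mu"]])),
    pdf_unit = function(t, par) {
      r <- par[["r"]]
      r / (2 + 2 * cosh(r * (t - par[["mu"]])))
    },
    t_star = function(par) list(value = par[["mu"]], defined = TRUE),
    t_half = function(par) par[["mu"]],
    domain_lower = function(par) -Inf,
    t_star_text = "mu", t_half_text = "mu"
  )

  cat[["Log-logistic"]] <- .gp_entry(
    "Log-logistic", c("m", "r", "a"),
    cdf_unit = function(t, par) {
      r <- par[["r"]]; a <- par[["a"]]
      out <- numeric(length(t))
      pos <- t > 0
      u <- (r * t[pos])^a
      out[pos] <- u / (1 + u)
      out
    },
    pdf_unit = function(t, par) {
      r <- par[["r"]]; a <- par[["a"]]
      out <- numeric(length(t))
      pos <- t > 0
      tp <- t[pos]
      out[pos] <- a * r^a * tp^(a - 1) / (1 + (r * tp)^a)^2
      if (any(t == 0)) out[t == 0] <- if (a > 1) 0 else if (a == 1) r else Inf
      out
    },
    t_star = function(par) {
      a <- par[["a"]]
      if (a > 1) .mode_or_zero(((a - 1) / (a + 1))^(1 / a) / par[["r"]])
      else list(value = 0, defined = FALSE)
    },
    t_half = function(par) 1 / par[["r"]],
    assumptions = A["a_gt0"],
    t_star_text = "((a - 1)/(a + 1))^(1/a) / r", t_half_text = "1/r"
  )

  cat[["Paralogistic"]] <- .gp_entry(
    "Paralogistic", c("m", "r", "a"),
    cdf_unit = function(t, par) {
      r <- par[["r"]]; a <- par[["a"]]
      out <- numeric(length(t))
      pos <- t > 0
      out[pos] <- 1 - (1 + (r * t[pos])^a)^(-a)
      out
    },
    pdf_unit = function(t, par) {
      r <- par[["r"]]; a <- par[["a"]]
      out <- numeric(length(t))
      pos <- t > 0
      tp <- t[pos]
      u <- (r * tp)^a
      out[pos] <- a^2 * u / ((1 + u)^(a + 1) * tp)
      out
    },
    t_star = function(par) {
      a <- par[["a"]]
      if (a > 1)
        .mode_or_zero(((a - 1) / (a^2 + 1))^(1 / a) / par[["r"]])
      else list(value = 0, defined = FALSE)
    },
    t_half = function(par)
      (2^(1 / par[["a"]]) - 1)^(1 / par[["a"]]) / par[["r"]],
    assumptions = A["a_gt1"],
    t_star_text = "((a - 1)/(a^2 + 1))^(1/a) / r",
    t_half_text = "(2^(1/a) - 1)^(1/a) / r"
  )

  cat[["Rayleigh 2p"]] <- .gp_entry(
    "Rayleigh 2p", c("m", "r"),
    cdf_unit = function(t, par)
      ifelse(t > 0, -expm1(-(par[["r"]] * t)^2 / 2), 0),
    pdf_unit = function(t, par) {
      r <- par[["r"]]
      ifelse(t >= 0, r^2 * t * exp(-(r * t)^2 / 2), 0)
    },
    t_star = function(par) .mode_or_zero(1 / par[["r"]]),
    t_half = function(par) sqrt(log(4)) / par[["r"]],
    t_star_text = "1/r", t_half_text = "sqrt(log(4))/r"
  )

  cat[["Rayleigh 3p"]] <- .gp_entry(
    "Rayleigh 3p", c("m", "r", "mu"),
    cdf_unit = function(t, par) {
      d <- t - par[["mu"]]
      ifelse(d > 0, -expm1(-(par[["r"]] * d)^2 / 2), 0)
    },
    pdf_unit = function(t, par) {
      r <- par[["r"]]; d <- t - par[["mu"]]
      ifelse(d >= 0, r^2 * d * exp(-(r * d)^2 / 2), 0)
    },
    t_star = function(par)
      list(value = par[["mu"]] + 1 / par[["r"]], defined = TRUE),
    t_half = function(par) par[["mu"]] + sqrt(log(4)) / par[["r"]],
    domain_lower = function(par) par[["mu"]],
    t_star_text = "mu + 1/r", t_half_text = "mu + sqrt(log(4))/r"
  )

  cat[["Weibull"]] <- .gp_entry(
    "Weibull", c("m", "r", "a"),
    cdf_unit = function(t, par)
      ifelse(t > 0, -expm1(-(par[["r"]] * t)^par[["a"]]), 0),
    pdf_unit = function(t, par) {
      r <- par[["r"]]; a <- par[["a"]]
      out <- numeric(length(t))
      pos <- t > 0
      tp <- t[pos]
      out[pos] <- a * r^a * tp^(a - 1) * exp(-(r * tp)^a)
      if (any(t == 0)) out[t == 0] <- if (a > 1) 0 else if (a == 1) r else Inf
      out
    },
    t_star = function(par) {
      a <- par[["a"]]
      if (a > 1)
        .mode_or_zero(((a - 1) / a)^(1 / a) / par[["r"]])
      else list(value = 0, defined = FALSE)
    },
    t_half = function(par) log(2)^(1 / par[["a"]]) / par[["r"]],
    assumptions = A["a_gt1"],
    t_star_text = "((a - 1)/a)^(1/a) / r", t_half_text = "log(2)^(1/a) / r"
  )

  # catalogue order is fixed (alphabetical, matching the published listing)
  cat
}

.gp_catalog <- .gp_catalog_build()

#' List the model catalogue
#'
#' Returns the fixed catalogue of 21 phenomenological gas-production models.
#' Each model is a scaled cumulative distribution function
#' \eqn{F(t) = m F_u(t)} with asymptote \eqn{m} and, depending on the family,
#' a rate constant \eqn{r} (1/h), a location/lag parameter \eqn{\mu} (h), and
#' dimensionless shape parameters \eqn{a} and \eqn{p}.
#'
#' @param names_only logical; if `TRUE` return just the model names.
#' @return A list of model specifications (or a character vector). Each
#'   specification carries `name`, `params`, `k`, the unit cdf/pdf evaluators,
#'   analytic `t_star` / `t_half` formulas and the declared parameter
#'   assumptions.
#' @examples
#' length(gp_models())        # 21
#' gp_models(names_only = TRUE)
#' @export
gp_models <- function(names_only = FALSE) {
  if (names_only) names(.gp_catalog) else .gp_catalog
}

#' Look up one catalogue model
#'
#' @param model a model name (see [gp_models()]) or a model specification.
#' @return The model specification list.
#' @export
gp_model <- function(model) {
  if (is.list(model) && !is.null(model$cdf_unit)) return(model)
  if (!is.character(model) || length(model) != 1L)
    stop("`model` must be a single model name or a model specification")
  spec <- .gp_catalog[[model]]
  if (is.null(spec))
    stop(sprintf("unknown model '%s'; see gp_models(names_only = TRUE)",
                 model))
  spec
}

# normalize user params (named vector or list) to a full named vector in
# canonical order with NA for absent parameters
.gp_full_params <- function(spec, params) {
  par <- unlist(params)
  missing <- setdiff(spec$params, names(par))
  if (length(missing))
    stop(sprintf("model '%s' requires parameter(s): %s", spec$name,
                 paste(missing, collapse = ", ")))
  out <- stats::setNames(rep(NA_real_, length(.gp_par_names)), .gp_par_names)
  out[spec$params] <- as.numeric(par[spec$params])
  out
}

# evaluability (fitting) domain: strictly positive m, r, a, p where present.
.gp_fit_domain_ok <- function(spec, par) {
  for (nm in intersect(spec$params, c("m", "r", "a", "p")))
    if (!is.finite(par[[nm]]) || par[[nm]] <= 0) return(FALSE)
  if ("mu" %in% spec$params && !is.finite(par[["mu"]])) return(FALSE)
  TRUE
}

.gp_check_evaluable <- function(spec, par) {
  for (nm in intersect(spec$params, c("m", "r", "a", "p")))
    if (!is.finite(par[[nm]]) || par[[nm]] <= 0)
      stop(sprintf("invalid parameter for model '%s': violated assumption %s>0",
                   spec$name, nm))
  if ("mu" %in% spec$params && !is.finite(par[["mu"]]))
    stop(sprintf("invalid parameter for model '%s': mu must be finite",
                 spec$name))
  invisible(TRUE)
}

#' Validate parameters against the declared model assumptions
#'
#' Checks the full set of declared parameter assumptions for a model:
#' positivity of \eqn{m} and \eqn{r}, and the shape conditions of the family
#' (for instance `a>1` for Burr XII, Weibull or Gompertz; `a>1` and `p>1` for
#' Burr III and Dagum; `p>0` for Burr XII). The shape conditions guarantee a
#' meaningful interior inflection point; curves remain evaluable under the
#' weaker positivity domain, which is what the fitting layer enforces.
#'
#' @param model model name or specification.
#' @param params named vector/list of parameter values.
#' @return A list with `valid` (logical) and `violations` (character vector of
#'   violated assumption strings, empty when valid).
#' @examples
#' validate_params("Burr XII", c(m = 70, r = 0.1, a = 0.9, p = 1.2))
#' @export
validate_params <- function(model, params) {
  spec <- gp_model(model)
  par <- .gp_full_params(spec, params)
  viol <- character()
  if (!is.finite(par[["m"]]) || par[["m"]] <= 0) viol <- c(viol, "m>0")
  if ("r" %in% spec$params && (!is.finite(par[["r"]]) || par[["r"]] <= 0))
    viol <- c(viol, "r>0")
  if ("mu" %in% spec$params && !is.finite(par[["mu"]]))
    viol <- c(viol, "mu finite")
  for (asm in spec$assumptions) {
    ok <- tryCatch(isTRUE(asm$test(par)), error = function(e) FALSE)
    if (!ok) viol <- c(viol, asm$label)
  }
  list(valid = length(viol) == 0L, violations = viol)
}

#' Evaluate the cumulative gas-production curve
#'
#' \eqn{F(t) = m F_u(t)}, in mL/200 mg DM. Times below the model's domain
#' (e.g. `t < mu` for lag-time models) return 0; singular algebra at `t = 0`
#' (Burr III, Dagum, Frechet, Inverse exponential, Inverse paralogistic) is
#' evaluated as the right-limit 0.
#'
#' @param model model name or specification.
#' @param params named parameter vector/list (see [gp_models()]).
#' @param t time(s), h.
#' @return Numeric vector of cumulative GP values in `[0, m]`.
#' @examples
#' gp_cdf("Exponential 2p", c(m = 10, r = 0.1), t = c(0, 8, 72))
#' @export
gp_cdf <- function(model, params, t) {
  spec <- gp_model(model)
  par <- .gp_full_params(spec, params)
  .gp_check_evaluable(spec, par)
  par[["m"]] * spec$cdf_unit(t, par)
}

#' Evaluate the gas-production rate curve
#'
#' \eqn{f(t) = F'(t)}, in mL/h. Zero below the model's domain.
#'
#' @inheritParams gp_cdf
#' @return Numeric vector of GP rates (mL/h), non-negative.
#' @examples
#' gp_pdf("Logistic", c(m = 10, r = 0.5, mu = 5), t = 5)  # m r / 4
#' @export
gp_pdf <- function(model, params, t) {
  spec <- gp_model(model)
  par <- .gp_full_params(spec, params)
  .gp_check_evaluable(spec, par)
  par[["m"]] * spec$pdf_unit(t, par)
}

#' Analytic kinetic summary of a fitted curve
#'
#' Computes the half-life \eqn{t_{0.5}} (median of the associated density, the
#' time at which GP reaches \eqn{m/2}), the inflection time \eqn{t^*} (mode of
#' the density, time of maximum GP rate) where its analytic precondition
#' holds, and the corresponding gas volumes. When the inflection precondition
#' fails (e.g. a fitted shape \eqn{a \le 1}), or when the density mode sits on
#' the domain boundary (Exponential 2p/3p, Half Cauchy, Half logistic),
#' `t_star_defined` is `FALSE` and the reported `t_star` is the boundary value
#' (0 for models starting at the origin).
#'
#' @inheritParams gp_cdf
#' @return List with `t_half`, `gp_half` (= m/2), `t_star`, `t_star_defined`,
#'   `gp_star` (= F(t_star)), and `gp0` (= F(0), the model-implied initial GP).
#' @examples
#' kinetic_summary("Exponential 2p", c(m = 10, r = 0.1))
#' @export
kinetic_summary <- function(model, params) {
  spec <- gp_model(model)
  par <- .gp_full_params(spec, params)
  .gp_check_evaluable(spec, par)
  ts <- spec$t_star(par)
  gp_star <- par[["m"]] * spec$cdf_unit(ts$value, par)
  list(
    t_half = spec$t_half(par),
    gp_half = par[["m"]] / 2,
    t_star = ts$value,
    t_star_defined = ts$defined,
    gp_star = gp_star,
    gp0 = par[["m"]] * spec$cdf_unit(0, par)
  )
}

#' Catalogue overview table
#'
#' One row per model: name, number of parameters, parameter names, declared
#' assumptions and the analytic formulas for the inflection time and
#' half-life. This backs the `models` CLI subcommand.
#'
#' @return A data.frame with 21 rows.
#' @export
gp_catalog_table <- function() {
  rows <- lapply(.gp_catalog, function(spec) {
    asm <- c("m>0", if ("r" %in% spec$params) "r>0",
             vapply(spec$assumptions, `[[`, "", "label"))
    data.frame(
      model = spec$name,
      k = spec$k,
      params = paste(spec$params, collapse = ","),
      assumptions = paste(asm, collapse = ";"),
      t_star = spec$t_star_text,
      t_half = spec$t_half_text,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
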