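# Nonlinear least-squares fitting of catalogue models to GP profiles.
#
# The asymptote m enters linearly (F = m * F_u), so it is profiled out
# analytically at every objective evaluation (variable projection); the
# remaining 1-3 nonlinear parameters are optimised by nlminb over a
# log-transformed (positivity-respecting) scale with a seeded multistart.

# evaluate expr with a temporary RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# deterministic fan-out of one user seed into per-stage / per-task streams;
# kept below 2^31 - 1
.gp_subseed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 9973) %% 2147483629) + 1L
}

#' A single gas-production profile
#'
#' @param sample_id character id of the curve.
#' @param times ordered times (h); must start at 0.
#' @param volumes cumulative GP (mL/200 mg DM); `volumes[1]` must be 0.
#' @param feed_category feed-category label.
#' @return An object of class `gp_profile`.
#' @export
gp_profile <- function(sample_id, times, volumes, feed_category = "Others") {
  times <- as.numeric(times); volumes <- as.numeric(volumes)
  if (length(times) != length(volumes))
    stop("times and volumes must have equal length")
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing")
  if (times[1] != 0)
    stop("profiles must start at t = 0 (GP0 = 0 by definition)")
  if (any(volumes < 0)) stop("volumes must be non-negative")
  structure(list(sample_id = as.character(sample_id),
                 feed_category = as.character(feed_category),
                 times = times, volumes = volumes),
            class = "gp_profile")
}

#' @export
print.gp_profile <- function(x, ...) {
  cat(sprintf("<gp_profile> %s [%s]: %d points, 0-%g h, max %.1f mL\n",
              x$sample_id, x$feed_category, length(x$times),
              max(x$times), max(x$volumes)))
  invisible(x)
}

#' Split a long profile table into gp_profile objects
#'
#' @param profiles either a list of [gp_profile()] objects or a long
#'   data.frame with columns `sample_id`, `feed_category`, `time_h`, `gp_ml`.
#' @return A list of `gp_profile` objects.
#' @export
as_gp_profiles <- function(profiles) {
  if (inherits(profiles, "gp_profile")) return(list(profiles))
  if (is.list(profiles) && !is.data.frame(profiles) &&
      all(vapply(profiles, inherits, TRUE, "gp_profile")))
    return(profiles)
  if (!is.data.frame(profiles))
    stop("`profiles` must be a data.frame or a list of gp_profile objects")
  need <- c("sample_id", "feed_category", "time_h", "gp_ml")
  miss <- setdiff(need, names(profiles))
  if (length(miss))
    stop("missing profile column(s): ", paste(miss, collapse = ", "))
  ids <- unique(profiles$sample_id)
  lapply(ids, function(id) {
    sub <- profiles[profiles$sample_id == id, , drop = FALSE]
    sub <- sub[order(sub$time_h), , drop = FALSE]
    gp_profile(id, sub$time_h, sub$gp_ml, sub$feed_category[1])
  })
}

#' Fitting options
#'
#' @param max_iter maximum optimiser iterations per start.
#' @param tol relative convergence tolerance on the cost.
#' @param n_starts number of multistart launches (first is the heuristic
#'   start, the rest are seeded jitters of it).
#' @param seed integer seed making the multistart deterministic.
#' @param jitter_sd standard deviation of the start jitter on the transformed
#'   scale.
#' @param dense_check check predictions for negativity on a dense 0-72 h grid
#'   in addition to the observation grid.
#' @return A list of options for [fit_model()].
#' @export
gp_fit_options <- function(max_iter = 500, tol = 1e-10, n_starts = 5,
                           seed = 1L, jitter_sd = 0.3, dense_check = TRUE) {
  list(max_iter = max_iter, tol = tol, n_starts = n_starts,
       seed = as.integer(seed), jitter_sd = jitter_sd,
       dense_check = dense_check)
}

# observed time at half of maximum volume, linearly interpolated
.obs_half_time <- function(times, volumes) {
  vmax <- max(volumes)
  half <- vmax / 2
  i <- which(volumes >= half)[1]
  if (is.na(i) || i == 1L) return(max(times[2] / 2, 0.5))
  t1 <- times[i - 1]; t2 <- times[i]
  v1 <- volumes[i - 1]; v2 <- volumes[i]
  if (v2 <= v1) return(t2)
  t1 + (half - v1) / (v2 - v1) * (t2 - t1)
}

# heuristic start on the transformed scale for the nonlinear parameters
.gp_start <- function(spec, times, volumes) {
  t50 <- .obs_half_time(times, volumes)
  nl <- setdiff(spec$params, "m")
  th <- numeric(length(nl)); names(th) <- nl
  if ("r" %in% nl) th[["r"]] <- log(log(2) / t50)
  if ("a" %in% nl) {
    if (spec$name == "Generalized logistic")
      th[["a"]] <- log(log(2) / log1p(exp(t50)))
    else th[["a"]] <- log(1.5)
  }
  if ("p" %in% nl) th[["p"]] <- log(1.5)
  if ("mu" %in% nl) {
    loc <- spec$name %in% c("Cauchy", "Gumbel", "Logistic")
    th[["mu"]] <- if (loc) t50 else 0
  }
  th
}

.gp_backtransform <- function(spec, theta) {
  nl <- names(theta)
  par <- stats::setNames(rep(NA_real_, length(.gp_par_names)), .gp_par_names)
  for (nm in nl)
    par[[nm]] <- if (nm == "mu") theta[[nm]] else exp(theta[[nm]])
  par
}

# profiled-m residual sum of squares for transformed nonlinear parameters
.gp_objective <- function(theta, spec, times, volumes) {
  par <- .gp_backtransform(spec, theta)
  # extreme transient parameter values can overflow; the guard below turns
  # any non-finite evaluation into a rejected point, so warnings are noise
  fu <- tryCatch(suppressWarnings(spec$cdf_unit(times, par)),
                 error = function(e) NULL)
  if (is.null(fu) || any(!is.finite(fu))) return(1e30)
  den <- sum(fu * fu)
  if (den < 1e-280) return(sum(volumes^2))
  m <- sum(volumes * fu) / den
  if (!is.finite(m) || m <= 0) m <- 1e-8
  sum((volumes - m * fu)^2)
}

.gp_profiled_m <- function(spec, theta, times, volumes) {
  par <- .gp_backtransform(spec, theta)
  fu <- suppressWarnings(spec$cdf_unit(times, par))
  den <- sum(fu * fu)
  if (den < 1e-280) return(1e-8)
  max(sum(volumes * fu) / den, 1e-8)
}

# numerical Jacobian of F(t; par) wrt the model's own parameters
.gp_jacobian <- function(spec, par, times) {
  k <- length(spec$params)
  J <- matrix(NA_real_, nrow = length(times), ncol = k)
  for (j in seq_len(k)) {
    nm <- spec$params[j]
    h <- 1e-6 * max(abs(par[[nm]]), 1e-3)
    up <- par; up[[nm]] <- par[[nm]] + h
    dn <- par; dn[[nm]] <- par[[nm]] - h
    fu_up <- up[["m"]] * spec$cdf_unit(times, up)
    fu_dn <- dn[["m"]] * spec$cdf_unit(times, dn)
    J[, j] <- (fu_up - fu_dn) / (2 * h)
  }
  J
}

#' Goodness-of-fit metrics
#'
#' Computes the residual sum of squares, coefficient of determination, root
#' mean square error on the maximum-likelihood scale
#' (\eqn{RMSE = \sqrt{RSS/n}}), the Gaussian maximum log-likelihood with
#' \eqn{\hat\sigma^2 = RSS/n}, and \eqn{BIC = k \ln n - 2 \ln \hat L}. The
#' error model is additive, homoscedastic, Gaussian.
#'
#' @param observed,predicted equal-length numeric vectors (n >= 2).
#' @param k number of model parameters.
#' @return List with `rss`, `r2`, `rmse`, `loglik`, `bic`, `n`, `k`.
#' @examples
#' goodness_of_fit(c(0, 1, 3), c(0, 1.1, 2.9), k = 2)
#' @export
goodness_of_fit <- function(observed, predicted, k) {
  n <- length(observed)
  if (length(predicted) != n) stop("observed and predicted lengths differ")
  if (n < 2) stop("need at least 2 points")
  tss <- sum((observed - mean(observed))^2)
  if (tss == 0) stop("zero variance in observed values: r2 undefined")
  rss <- sum((observed - predicted)^2)
  sigma2 <- rss / n
  loglik <- if (rss == 0) Inf else -(n / 2) * (log(2 * pi) + log(sigma2) + 1)
  list(rss = rss, r2 = 1 - rss / tss, rmse = sqrt(sigma2),
       loglik = loglik, bic = k * log(n) - 2 * loglik, n = n, k = k)
}

.gp_failure_row <- function(profile, spec, reason, n) {
  out <- list(sample_id = profile$sample_id,
              feed_category = profile$feed_category,
              model = spec$name, converged = FALSE, failure_reason = reason)
  for (nm in .gp_par_names) out[[nm]] <- NA_real_
  for (nm in .gp_par_names) out[[paste0("se_", nm)]] <- NA_real_
  out <- c(out, list(n = n, k = spec$k, rss = NA_real_, r2 = NA_real_,
                     rmse = NA_real_, loglik = NA_real_, bic = NA_real_,
                     t_half = NA_real_, gp_half = NA_real_, t_star = NA_real_,
                     t_star_defined = NA, gp_star = NA_real_, gp0 = NA_real_))
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Fit one catalogue model to one profile
#'
#' Constrained nonlinear least squares: minimises
#' \eqn{\sum_i (y_i - m F_u(t_i))^2} over the model's parameters, with the
#' evaluability constraints \eqn{m, r, a, p > 0} enforced through log
#' transforms and the linear asymptote `m` profiled out analytically.
#' Failures are captured, never raised: the returned record carries
#' `converged = FALSE` and a `failure_reason` of `"no-convergence"`,
#' `"nan-estimates"`, `"negative-predictions"` or `"constraint-violation"`.
#'
#' @param profile a [gp_profile()] (or a one-profile long data.frame).
#' @param model model name or specification.
#' @param options see [gp_fit_options()].
#' @return A one-row data.frame with estimates, standard errors, fit metrics
#'   (`rss`, `r2`, `rmse`, `loglik`, `bic`), convergence status and the
#'   derived kinetic summary.
#' @export
fit_model <- function(profile, model, options = gp_fit_options()) {
  if (is.data.frame(profile)) profile <- as_gp_profiles(profile)[[1]]
  spec <- gp_model(model)
  times <- profile$times; volumes <- profile$volumes
  n <- length(times)
  if (n < spec$k + 1)
    stop(sprintf("profile '%s' has %d points; model '%s' needs at least %d",
                 profile$sample_id, n, spec$name, spec$k + 1))

  if (max(volumes) <= 0 || stats::sd(volumes) == 0)
    return(.gp_failure_row(profile, spec,
                           "no-convergence", n))  # degenerate asymptote

  th0 <- .gp_start(spec, times, volumes)
  d <- length(th0)
  starts <- .with_seed(options$seed, {
    s <- list(th0)
    if (options$n_starts > 1)
      for (i in seq_len(options$n_starts - 1)) {
        jit <- stats::rnorm(d, 0, options$jitter_sd)
        if ("mu" %in% names(th0))
          jit[names(th0) == "mu"] <- stats::rnorm(1, 0, 1.5)
        s[[i + 1]] <- th0 + jit
      }
    s
  })

  best <- NULL
  for (st in starts) {
    res <- tryCatch(
      stats::nlminb(st, .gp_objective, spec = spec, times = times,
                    volumes = volumes,
                    control = list(iter.max = options$max_iter,
                                   eval.max = 4L * options$max_iter,
                                   rel.tol = options$tol)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$objective < best$objective) best <- res
  }

  if (is.null(best))
    return(.gp_failure_row(profile, spec, "no-convergence", n))
  ok_codes <- best$convergence == 0 ||
    grepl("false convergence|singular convergence", best$message %||% "")
  theta <- best$par; names(theta) <- names(th0)
  par <- .gp_backtransform(spec, theta)
  par[["m"]] <- .gp_profiled_m(spec, theta, times, volumes)

  if (any(!is.finite(par[spec$params])))
    return(.gp_failure_row(profile, spec, "nan-estimates", n))
  if (!ok_codes)
    return(.gp_failure_row(profile, spec, "no-convergence", n))
  if (!.gp_fit_domain_ok(spec, par))
    return(.gp_failure_row(profile, spec, "constraint-violation", n))

  pred <- par[["m"]] * spec$cdf_unit(times, par)
  check_grid <- if (isTRUE(options$dense_check))
    c(times, seq(0, max(times), length.out = 145)) else times
  pred_check <- par[["m"]] * spec$cdf_unit(check_grid, par)
  if (any(!is.finite(pred_check)) || any(pred_check < -1e-8))
    return(.gp_failure_row(profile, spec, "negative-predictions", n))

  gof <- goodness_of_fit(volumes, pred, spec$k)
  kin <- kinetic_summary(spec, par[spec$params])

  se <- stats::setNames(rep(NA_real_, length(.gp_par_names)), .gp_par_names)
  if (n > spec$k && gof$rss > 0) {
    se_try <- tryCatch({
      J <- .gp_jacobian(spec, par, times)
      covm <- gof$rss / (n - spec$k) * solve(crossprod(J))
      sqrt(pmax(diag(covm), 0))
    }, error = function(e) NULL)
    if (!is.null(se_try)) se[spec$params] <- se_try
  }

  out <- list(sample_id = profile$sample_id,
              feed_category = profile$feed_category,
              model = spec$name, converged = TRUE, failure_reason = "none")
  for (nm in .gp_par_names) out[[nm]] <- unname(par[[nm]])
  for (nm in .gp_par_names) out[[paste0("se_", nm)]] <- unname(se[[nm]])
  out <- c(out, list(n = n, k = spec$k, rss = gof$rss, r2 = gof$r2,
                     rmse = gof$rmse, loglik = gof$loglik, bic = gof$bic,
                     t_half = kin$t_half, gp_half = kin$gp_half,
                     t_star = kin$t_star, t_star_defined = kin$t_star_defined,
                     gp_star = kin$gp_star, gp0 = kin$gp0))
  as.data.frame(out, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit many models to many profiles
#'
#' One record per profile-model pair; per-pair failures are captured in the
#' record, never raised, so the output always has
#' `length(profiles) * length(models)` rows.
#'
#' @param profiles list of [gp_profile()] objects or a long data.frame.
#' @param models `"all"` (default) or a character vector of catalogue names.
#' @param options see [gp_fit_options()].
#' @param verbose print a progress line per profile batch.
#' @return A data.frame of fit records (see [fit_model()]).
#' @export
fit_all <- function(profiles, models = "all", options = gp_fit_options(),
                    verbose = FALSE) {
  profiles <- as_gp_profiles(profiles)
  if (length(profiles) == 0) stop("no profiles supplied")
  if (identical(models, "all")) models <- gp_models(names_only = TRUE)
  if (length(models) == 0) stop("no models supplied")
  bad <- setdiff(models, gp_models(names_only = TRUE))
  if (length(bad)) stop("unknown model(s): ", paste(bad, collapse = ", "))

  rows <- vector("list", length(profiles) * length(models))
  idx <- 1L
  for (i in seq_along(profiles)) {
    prof <- profiles[[i]]
    for (mod in models) {
      opts <- options
      # per-pair deterministic multistart stream
      opts$seed <- .gp_subseed(options$seed, idx)
      rows[[idx]] <- fit_model(prof, mod, opts)
      idx <- idx + 1L
    }
    if (verbose && (i %% 50L == 0L || i == length(profiles)))
      message(sprintf("[fit] %d/%d profiles", i, length(profiles)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Residual diagnostics for a converged fit
#'
#' Per-time residuals, their mean, and a sign-runs summary: the number of
#' runs in the residual sign sequence together with its expectation under
#' randomness, usable to flag systematic lack of fit.
#'
#' @param fit a one-row fit record from [fit_model()].
#' @param profile the profile that was fitted.
#' @return List with `residuals` (data.frame time_h/observed/predicted/
#'   residual), `mean_residual`, `runs`, `expected_runs`.
#' @export
residual_diagnostics <- function(fit, profile) {
  if (is.data.frame(profile)) profile <- as_gp_profiles(profile)[[1]]
  if (!isTRUE(fit$converged[1]))
    stop("residual diagnostics require a converged fit")
  spec <- gp_model(fit$model[1])
  par <- stats::setNames(as.numeric(fit[1, .gp_par_names]), .gp_par_names)
  pred <- par[["m"]] * spec$cdf_unit(profile$times, par)
  resid <- profile$volumes - pred
  s <- sign(resid)
  s <- s[s != 0]
  runs <- if (length(s)) 1L + sum(s[-1] != s[-length(s)]) else 0L
  n_pos <- sum(s > 0); n_neg <- sum(s < 0)
  exp_runs <- if (n_pos + n_neg > 0)
    1 + 2 * n_pos * n_neg / (n_pos + n_neg) else 0
  list(residuals = data.frame(time_h = profile$times,
                              observed = profile$volumes,
                              predicted = pred, residual = resid),
       mean_residual = mean(resid), runs = runs, expected_runs = exp_runs)
}
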