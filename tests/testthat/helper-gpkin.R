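# shared test helpers: random valid parameter draws and numeric oracles

# full canonical parameter vector (NA for absent parameters)
full_par <- function(spec, p) {
  v <- stats::setNames(rep(NA_real_, 5), c("m", "r", "mu", "a", "p"))
  v[names(p)] <- p
  v
}

# one random parameter draw satisfying the declared (strict) assumptions,
# over ranges realistic for 0-72 h fermentation curves
draw_valid_params <- function(spec) {
  p <- c(m = runif(1, 40, 100))
  if ("r" %in% spec$params) p["r"] <- runif(1, 0.06, 0.4)
  if ("a" %in% spec$params) {
    a_gt1 <- any(vapply(spec$assumptions,
                        function(x) x$label == "a>1", TRUE))
    p["a"] <- if (a_gt1) 1 + runif(1, 0.1, 2) else runif(1, 0.4, 2.5)
  }
  if ("p" %in% spec$params)
    p["p"] <- if (spec$name == "Burr XII") runif(1, 0.4, 2.5)
              else 1 + runif(1, 0.1, 2)
  if ("mu" %in% spec$params)
    p["mu"] <- if (spec$name %in% c("Cauchy", "Gumbel", "Logistic"))
      runif(1, 2, 10) else runif(1, -2, 2)
  p
}

# numeric half-life: root of F(t) = m/2 (bisection via uniroot)
oracle_t_half <- function(spec, p) {
  kin <- kinetic_summary(spec, p)
  dl <- spec$domain_lower(full_par(spec, p))
  r_scale <- if (is.na(p["r"])) 0.2 else p[["r"]]
  lo <- if (is.finite(dl)) dl else kin$t_half - 80 / r_scale
  uniroot(function(t) gp_cdf(spec, p, t) - p[["m"]] / 2,
          c(lo + 1e-12, kin$t_half + 1), extendInt = "upX",
          tol = 1e-12)$root
}

# numeric inflection: golden-section argmax of f
oracle_t_star <- function(spec, p) {
  kin <- kinetic_summary(spec, p)
  dl <- spec$domain_lower(full_par(spec, p))
  r_scale <- if (is.na(p["r"])) 0.2 else p[["r"]]
  lo <- if (is.finite(dl)) dl else kin$t_half - 80 / r_scale
  lo <- max(lo, kin$t_star - max(5, abs(kin$t_star)))
  up <- max(kin$t_half, kin$t_star) * 2 + 2
  optimize(function(t) gp_pdf(spec, p, t), c(lo, up), maximum = TRUE,
           tol = 1e-10)$maximum
}

# quick-fit options for tests that do many fits
fast_opts <- function(seed = 1L) gp_fit_options(n_starts = 2, seed = seed)

# small per-category Burr XII config used by selection tests
burrxii_config <- function(n_feeds, replicates, noise_sd = 1.5) {
  cats <- lapply(gp_feed_categories(), function(fc)
    list(model = "Burr XII", truth = table2_presets("Burr XII", fc),
         n_feeds = n_feeds, replicates = replicates))
  names(cats) <- gp_feed_categories()
  gp_sim_config(cats, noise_sd = noise_sd)
}
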