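# Seeded synthetic GP data with the statistical structure the analysis
# assumes: curves from catalogue models on the nine-point Hohenheim grid,
# additive homoscedastic Gaussian noise truncated at zero, 3-7 replicates
# per feed, six feed categories, optional between-feed parameter jitter.

.gp_reference_path <- function(file)
  system.file("extdata", file, package = "gpkin", mustWork = TRUE)

#' Published reference summary of model fits
#'
#' Per model x feed category means of the estimated parameters, derived
#' kinetic quantities and goodness-of-fit metrics from the original fitted
#' dataset (849 curves; values as printed, i.e. cell means over curves).
#' Ships as a plain-text fixture and anchors the package's validation tests.
#'
#' @return A data.frame with 126 rows (21 models x 6 feed categories).
#' @export
gp_reference_summary <- function() {
  utils::read.csv(.gp_reference_path("reference_fit_summary.csv"),
                  stringsAsFactors = FALSE)
}

#' Published per-category selection summary
#'
#' Top/lower model sets and the average BIC values (top set, lower set, all
#' models) per feed category, with the published RPI percentages.
#'
#' @return A data.frame with 6 rows.
#' @export
gp_reference_selection <- function() {
  utils::read.csv(.gp_reference_path("reference_category_performance.csv"),
                  stringsAsFactors = FALSE)
}

#' Reference parameter presets
#'
#' Looks up the published mean parameter estimates for a model x feed
#' category cell, for use as ground truth in simulations. All 21 models and
#' six categories are available.
#'
#' @param model catalogue model name.
#' @param feed_category one of the six feed categories.
#' @return Named numeric vector of the model's parameters.
#' @examples
#' table2_presets("Burr XII", "Compound")
#' @export
table2_presets <- function(model, feed_category) {
  ref <- gp_reference_summary()
  row <- ref[ref$model == model & ref$feed_category == feed_category, ]
  if (nrow(row) != 1)
    stop(sprintf("no preset for model '%s' x category '%s'", model,
                 feed_category))
  spec <- gp_model(model)
  out <- vapply(spec$params, function(nm) row[[nm]], 0)
  names(out) <- spec$params
  out
}

#' Simulate one GP profile
#'
#' Evaluates the model curve on the time grid and adds seeded Gaussian noise
#' (sd `noise_sd` mL), truncating below at 0 (gas volumes are physical). By
#' default the t = 0 reading is pinned to exactly 0 (GP0 = 0 by definition of
#' the assay); `zero_origin = FALSE` instead records the model-implied value
#' F(0), which matters only for the four families with F(0) > 0 and is used
#' by the parameter-recovery oracles.
#'
#' @param model model name or specification.
#' @param truth named parameter vector (must be evaluable: m, r, a, p > 0).
#' @param times time grid (h), starting at 0; default [gp_times()].
#' @param noise_sd Gaussian noise sd in mL (>= 0); default 1.5, inside the
#'   published RMSE range (0.71-6.74 mL).
#' @param seed integer seed; the profile is deterministic given it.
#' @param sample_id,feed_category labels for the profile.
#' @param zero_origin pin the t = 0 volume to exactly 0 (default TRUE).
#' @return A [gp_profile()].
#' @export
simulate_profile <- function(model, truth, times = gp_times(),
                             noise_sd = 1.5, seed = 1L,
                             sample_id = "sim", feed_category = "Others",
                             zero_origin = TRUE) {
  spec <- gp_model(model)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (times[1] != 0) stop("time grid must start at 0")
  mean_curve <- gp_cdf(spec, truth, times)
  vols <- .with_seed(seed, mean_curve + stats::rnorm(length(times), 0,
                                                     noise_sd))
  vols <- pmax(vols, 0)
  if (zero_origin) vols[1] <- 0
  gp_profile(sample_id, times, vols, feed_category)
}

#' Simulation configuration
#'
#' One block per feed category: generating model, ground-truth parameters,
#' number of feeds, replicates per feed (recycled over feeds; must lie in
#' 3-7 for the default assay design), noise sd and the log-normal
#' between-feed jitter applied to m and r (sdlog; default 0.05, i.e. ~5%
#' spread between feeds of a category).
#'
#' @param categories named list; each element a list with `model`, `truth`,
#'   `n_feeds`, `replicates`, and optionally `noise_sd`, `jitter_sdlog`.
#' @param noise_sd default noise sd (mL) for blocks that do not set one.
#' @param jitter_sdlog default between-feed jitter.
#' @param times time grid.
#' @return A list of class `gp_sim_config`.
#' @export
gp_sim_config <- function(categories, noise_sd = 1.5, jitter_sdlog = 0.05,
                          times = gp_times()) {
  for (fc in names(categories)) {
    blk <- categories[[fc]]
    if (is.null(blk$model) || is.null(blk$truth) || is.null(blk$n_feeds) ||
        is.null(blk$replicates))
      stop("each category block needs model, truth, n_feeds, replicates")
    if (any(blk$replicates < 1))
      stop("replicates must be positive")
  }
  structure(list(categories = categories, noise_sd = noise_sd,
                 jitter_sdlog = jitter_sdlog, times = times),
            class = "gp_sim_config")
}

#' Default simulation configurations
#'
#' `scale = "full"` emulates the published assay structure: 849 profiles over
#' the six feed categories with 3-7 replicates per feed (Compound 19 feeds,
#' Corn 20, Processed protein 5, Legumes 25, Soft cereal 80, Others 3;
#' replicate patterns chosen so category totals mirror the study's training
#' counts). Each category is generated from the Burr XII reference preset of
#' that category. `scale = "small"` is a 36-profile miniature (2 feeds x 3
#' replicates per category) for quick runs.
#'
#' @param scale `"full"` or `"small"`.
#' @param noise_sd noise sd in mL (default 1.5).
#' @param model generating model for every category (default `"Burr XII"`).
#' @return A `gp_sim_config`.
#' @export
gp_default_config <- function(scale = c("full", "small"), noise_sd = 1.5,
                              model = "Burr XII") {
  scale <- match.arg(scale)
  design <- if (scale == "full") list(
    "Compound" = list(n_feeds = 19, replicates = c(rep(3:7, 3), 4, 5, 5, 6)),
    "Corn" = list(n_feeds = 20, replicates = 6),
    "Processed protein" = list(n_feeds = 5, replicates = 5),
    "Legumes" = list(n_feeds = 25, replicates = c(6, 5)),
    "Soft cereal" = list(n_feeds = 80, replicates = c(6, 5, 6, 6)),
    "Others" = list(n_feeds = 3, replicates = c(4, 4, 3))
  ) else {
    ds <- lapply(gp_feed_categories(),
                 function(fc) list(n_feeds = 2, replicates = 3))
    names(ds) <- gp_feed_categories()
    ds
  }
  cats <- lapply(names(design), function(fc) {
    c(design[[fc]], list(model = model,
                         truth = table2_presets(model, fc)))
  })
  names(cats) <- names(design)
  gp_sim_config(cats, noise_sd = noise_sd)
}

#' Simulate a multi-category GP dataset
#'
#' Generates `n_feeds x replicates` profiles per category. Per feed, the
#' ground-truth m and r are jittered by a log-normal factor (between-feed
#' heterogeneity); per replicate, Gaussian noise is added to the curve.
#' Deterministic given `seed`.
#'
#' @param config a [gp_sim_config()].
#' @param seed integer seed.
#' @return A long data.frame (`sample_id`, `feed_category`, `time_h`,
#'   `gp_ml`) with attribute `"truth"` recording the per-feed jittered
#'   parameters.
#' @export
simulate_dataset <- function(config, seed = 1L) {
  if (!inherits(config, "gp_sim_config")) stop("config must be gp_sim_config")
  rows <- list(); truth_rows <- list()
  counter <- 0L
  for (fc in names(config$categories)) {
    blk <- config$categories[[fc]]
    noise_sd <- blk$noise_sd %||% config$noise_sd
    jit <- blk$jitter_sdlog %||% config$jitter_sdlog
    spec <- gp_model(blk$model)
    reps <- rep(blk$replicates, length.out = blk$n_feeds)
    for (f in seq_len(blk$n_feeds)) {
      counter <- counter + 1L
      truth_f <- blk$truth
      if (jit > 0) {
        fac <- .with_seed(.gp_subseed(seed, counter),
                          stats::rlnorm(2, 0, jit))
        for (i in seq_along(intersect(c("m", "r"), names(truth_f))))
          truth_f[[intersect(c("m", "r"), names(truth_f))[i]]] <-
            truth_f[[intersect(c("m", "r"), names(truth_f))[i]]] * fac[i]
      }
      truth_rows[[counter]] <- data.frame(
        feed_category = fc, feed = f, model = spec$name,
        t(truth_f), stringsAsFactors = FALSE)
      for (r in seq_len(reps[f])) {
        counter <- counter + 1L
        id <- sprintf("%s_f%02d_r%d", gsub("[^A-Za-z]", "", fc), f, r)
        prof <- simulate_profile(spec, truth_f, times = config$times,
                                 noise_sd = noise_sd,
                                 seed = .gp_subseed(seed, counter),
                                 sample_id = id, feed_category = fc)
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = id, feed_category = fc,
          time_h = prof$times, gp_ml = prof$volumes,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- do.call(rbind, truth_rows)
  out
}
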