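# File dialects: long-format profile CSV, fit-record CSV, JSON reports and
# run manifests.

#' Read GP profiles from CSV
#'
#' Long format, header `sample_id,feed_category,time_h,gp_ml`, dot decimal.
#' Validates numeric cells, duplicate (sample, time) pairs and the t = 0
#' convention: profiles missing the t = 0 reading get a (0, 0) row imputed
#' with a warning (GP0 = 0 by definition); feed categories outside the six
#' standard labels are accepted but flagged with a warning.
#'
#' @param path CSV file path.
#' @return Long data.frame of validated profiles, sorted by sample and time.
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "feed_category", "time_h", "gp_ml")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  for (col in c("time_h", "gp_ml")) {
    v <- d[[col]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v) & v != "")
      if (length(bad))
        stop(sprintf("non-numeric %s at data line(s): %s", col,
                     paste(utils::head(bad + 1L, 5), collapse = ", ")))
      d[[col]] <- vn
    }
  }
  dup <- duplicated(d[, c("sample_id", "time_h")])
  if (any(dup))
    stop("duplicate (sample_id, time_h) at data line(s): ",
         paste(utils::head(which(dup) + 1L, 5), collapse = ", "))
  odd <- setdiff(unique(d$feed_category), gp_feed_categories())
  if (length(odd))
    warning("non-standard feed categor(ies): ", paste(odd, collapse = ", "))
  no_zero <- setdiff(unique(d$sample_id),
                     unique(d$sample_id[d$time_h == 0]))
  if (length(no_zero)) {
    warning(length(no_zero),
            " profile(s) missing the t = 0 reading; imputed as (0, 0)")
    add <- do.call(rbind, lapply(no_zero, function(id) {
      fc <- d$feed_category[d$sample_id == id][1]
      data.frame(sample_id = id, feed_category = fc, time_h = 0, gp_ml = 0,
                 stringsAsFactors = FALSE)
    }))
    d <- rbind(d, add)
  }
  d <- d[order(d$sample_id, d$time_h), need]
  rownames(d) <- NULL
  d
}

#' Write GP profiles to CSV
#'
#' @param profiles long data.frame of profiles.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  utils::write.csv(profiles, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# human-facing tables carry 6 significant digits; JSON keeps full precision
.gp_signif_df <- function(d, digits = 6) {
  num <- vapply(d, is.numeric, TRUE)
  d[num] <- lapply(d[num], signif, digits = digits)
  d
}

#' Write fit records to CSV
#'
#' Numbers serialised with 6 significant digits; absent parameters as empty
#' cells.
#'
#' @param fits fit records from [fit_all()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fits <- function(fits, path) {
  utils::write.csv(.gp_signif_df(fits), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read fit records written by [write_fits()]
#' @param path CSV path.
#' @return Fit-record data.frame.
#' @export
read_fits <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

.gp_manifest <- function(command, seed, config = NULL, inputs = NULL,
                         outputs = NULL, counts = NULL, failures = NULL) {
  list(command = command,
       package = "gpkin",
       version = as.character(utils::packageVersion("gpkin")),
       catalogue = list(n_models = length(gp_models()),
                        models = gp_models(names_only = TRUE)),
       seed = seed, config = config, inputs = inputs, outputs = outputs,
       counts = counts, failures = failures)
}

#' Write a JSON run manifest
#' @param manifest manifest list.
#' @param path output path.
#' @return `path`, invisibly.
#' @keywords internal
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Run the full pipeline
#'
#' Sequences simulation (optional), fitting, and the selection layer, writing
#' each stage's output as it completes: `profiles.csv`, `fits.csv`,
#' `report.json` (ANOVA, Tukey groupings, tree report, model sets with RPI)
#' and `manifest.json`.
#'
#' @param out_dir output directory (created if needed).
#' @param seed global seed; stage seeds are derived from it.
#' @param config a [gp_sim_config()] to simulate input, or `NULL` when
#'   `profiles` is given.
#' @param profiles long profile data.frame (alternative to `config`).
#' @param models models to fit (default all 21).
#' @param alpha Tukey level.
#' @param fit_options see [gp_fit_options()]; its seed is overridden by the
#'   derived stage seed.
#' @param verbose log stage progress to stderr.
#' @return Invisible list with `profiles`, `fits`, `report`, `manifest`.
#' @export
run_pipeline <- function(out_dir, seed = 1L, config = NULL, profiles = NULL,
                         models = "all", alpha = 0.05,
                         fit_options = gp_fit_options(), verbose = FALSE) {
  if (is.null(config) && is.null(profiles))
    stop("supply either a simulation config or profiles")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- function(stage, ...) if (verbose)
    message(sprintf("[%s] ", stage), sprintf(...))

  if (is.null(profiles)) {
    log("simulate", "generating synthetic dataset")
    profiles <- simulate_dataset(config, seed = .gp_subseed(seed, 1L))
  }
  write_profiles(profiles, file.path(out_dir, "profiles.csv"))
  n_prof <- length(unique(profiles$sample_id))
  log("simulate", "%d profiles", n_prof)

  fit_options$seed <- .gp_subseed(seed, 2L)
  fits <- fit_all(profiles, models = models, options = fit_options,
                  verbose = verbose)
  write_fits(fits, file.path(out_dir, "fits.csv"))
  fail_tally <- table(fits$failure_reason)
  log("fit", "%d records, %d failures", nrow(fits), sum(!fits$converged))

  report <- tryCatch({
    tab <- bic_table(fits)
    anova_res <- two_way_anova(tab)
    grouping <- tukey_groups(tab, alpha = alpha)
    tree <- fit_tree(tab, seed = .gp_subseed(seed, 3L))
    sets <- select_model_sets(grouping, tab)
    utils::write.csv(.gp_signif_df(tree$leaf_report),
                     file.path(out_dir, "leaf_report.csv"),
                     row.names = FALSE)
    list(anova = anova_res,
         tukey = lapply(grouping, function(g) g),
         tree = list(control = tree$control, n_splits = tree$n_splits,
                     train_r2 = tree$train_r2, train_rmse = tree$train_rmse,
                     valid_r2 = tree$valid_r2, valid_rmse = tree$valid_rmse,
                     contribution = as.list(tree$contribution),
                     leaf_report = tree$leaf_report),
         model_sets = sets)
  }, error = function(e) {
    log("select", "selection stage failed: %s", conditionMessage(e))
    list(error = conditionMessage(e))
  })
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  log("select", "report written")

  manifest <- .gp_manifest(
    command = "run", seed = seed,
    outputs = list(profiles = "profiles.csv", fits = "fits.csv",
                   report = "report.json"),
    counts = list(profiles = n_prof,
                  models = if (identical(models, "all")) 21L
                           else length(models),
                  fit_records = nrow(fits)),
    failures = as.list(fail_tally))
  write_manifest(manifest, file.path(out_dir, "manifest.json"))
  invisible(list(profiles = profiles, fits = fits, report = report,
                 manifest = manifest))
}
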