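# Selection layer: factorial ANOVA on BIC, Tukey HSD groupings with a
# compact letter display, and the relative performance improvement (RPI)
# statistic.

#' Assemble the profile-by-model BIC table
#'
#' @param fits fit records from [fit_all()].
#' @param keep_failures keep non-converged records (with NA bic)? Default
#'   drops them: the selection layer operates on converged fits only.
#' @return A data.frame with columns `sample_id`, `feed_category`, `model`,
#'   `bic`.
#' @export
bic_table <- function(fits, keep_failures = FALSE) {
  need <- c("sample_id", "feed_category", "model", "bic")
  miss <- setdiff(need, names(fits))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  out <- fits[, need]
  if (!keep_failures && "converged" %in% names(fits))
    out <- out[fits$converged & is.finite(fits$bic), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Two-way factorial ANOVA on BIC values
#'
#' Decomposes BIC into main effects of model name and feed category plus
#' their interaction, using Type II sums of squares (each main effect
#' adjusted for the other; the interaction adjusted for both), which handles
#' the unbalanced replication of the assay design.
#'
#' @param table a BIC table from [bic_table()].
#' @return A data.frame with one row per source (`model`, `feed_category`,
#'   `model:feed_category`, `residual`): `df`, `ss`, `ms`, `f`, `p`.
#' @export
two_way_anova <- function(table) {
  d <- data.frame(bic = table$bic,
                  model = factor(table$model),
                  cat = factor(table$feed_category))
  if (nlevels(d$model) < 2 || nlevels(d$cat) < 2)
    stop("need at least 2 models and 2 feed categories")
  cells <- table(d$model, d$cat)
  if (any(cells == 0))
    stop("empty model-by-category cells: interaction inestimable")
  if (!any(cells >= 2))
    stop("need at least one cell with 2 or more observations")

  rss <- function(fm) sum(stats::resid(fm)^2)
  f_m  <- stats::lm(bic ~ model, data = d)
  f_c  <- stats::lm(bic ~ cat, data = d)
  f_mc <- stats::lm(bic ~ model + cat, data = d)
  f_x  <- stats::lm(bic ~ model * cat, data = d)

  ss_model <- rss(f_c) - rss(f_mc)
  ss_cat   <- rss(f_m) - rss(f_mc)
  ss_int   <- rss(f_mc) - rss(f_x)
  ss_res   <- rss(f_x)

  df_model <- nlevels(d$model) - 1L
  df_cat   <- nlevels(d$cat) - 1L
  df_int   <- f_c$df.residual - f_x$df.residual - df_model
  df_res   <- f_x$df.residual

  ss <- c(ss_model, ss_cat, ss_int, ss_res)
  # clamp lm round-off (nested RSS differences can be O(eps) negative)
  ss[ss < 1e-10 * max(1, sum(d$bic^2))] <- 0
  src <- data.frame(
    source = c("model", "feed_category", "model:feed_category", "residual"),
    df = c(df_model, df_cat, df_int, df_res),
    ss = ss,
    stringsAsFactors = FALSE)
  src$ms <- src$ss / src$df
  ms_res <- src$ms[4]
  src$f <- c(src$ms[1:3] / ms_res, NA)
  src$p <- c(stats::pf(src$f[1:3], src$df[1:3], df_res, lower.tail = FALSE),
             NA)
  # degenerate case: constant response -> zero SS everywhere, report p = 1
  tot <- sum(src$ss)
  zero <- src$ss[1:3] <= 1e-12 * max(1, tot)
  src$f[1:3][zero & !is.finite(src$f[1:3])] <- 0
  src$p[1:3][zero] <- 1
  src
}

# Tukey-Kramer all-pairs significance matrix for one set of group means
.tukey_signif <- function(means, ns, mse, df, alpha) {
  k <- length(means)
  sig <- matrix(FALSE, k, k)
  if (k < 2 || df < 1 || !is.finite(mse) || mse <= 0) return(sig)
  qcrit <- stats::qtukey(1 - alpha, nmeans = k, df = df)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    se <- sqrt(mse / 2 * (1 / ns[i] + 1 / ns[j]))
    sig[i, j] <- sig[j, i] <- abs(means[i] - means[j]) > qcrit * se
  }
  sig
}

# insert-and-absorb compact letter display; treatments assumed ordered by
# mean (ascending); returns character vector of letter strings
.cld <- function(sig) {
  k <- nrow(sig)
  cols <- list(rep(TRUE, k))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (!sig[i, j]) next
    nxt <- list()
    for (col in cols) {
      if (col[i] && col[j]) {
        c1 <- col; c1[i] <- FALSE
        c2 <- col; c2[j] <- FALSE
        nxt <- c(nxt, list(c1, c2))
      } else nxt <- c(nxt, list(col))
    }
    # absorb columns that are subsets of another
    keep <- rep(TRUE, length(nxt))
    for (u in seq_along(nxt)) for (v in seq_along(nxt)) {
      if (u != v && keep[u] && keep[v] &&
          all(nxt[[u]] <= nxt[[v]]) && any(nxt[[u]] < nxt[[v]]))
        keep[u] <- FALSE
      else if (u < v && keep[u] && keep[v] &&
               all(nxt[[u]] == nxt[[v]]))
        keep[v] <- FALSE
    }
    cols <- nxt[keep]
  }
  # order columns by first member so letters read left-to-right down the means
  ord <- order(vapply(cols, function(col) which(col)[1], 1L))
  cols <- cols[ord]
  letters_pool <- c(letters, paste0(rep(letters, each = 26), letters))
  out <- character(k)
  for (ci in seq_along(cols))
    out[cols[[ci]]] <- paste0(out[cols[[ci]]], letters_pool[ci])
  out
}

#' Tukey HSD model groupings per feed category
#'
#' Within each feed category, compares all model pairs with the studentized
#' range statistic (Tukey-Kramer correction for unequal replication, MSE from
#' the within-category one-way model-effect fit) and assigns a compact letter
#' display by insert-and-absorb: models sharing a letter are not
#' significantly different at level `alpha`.
#'
#' @param table a BIC table from [bic_table()].
#' @param alpha familywise significance level (default 0.05).
#' @return A list with one element per feed category, each a data.frame of
#'   `model`, `mean_bic`, `n`, `letters`, ordered by mean BIC ascending
#'   (lower BIC = better fit), plus attribute `"best_letters"` (the letters
#'   of the minimum-mean model).
#' @export
tukey_groups <- function(table, alpha = 0.05) {
  out <- list()
  for (fc in unique(table$feed_category)) {
    sub <- table[table$feed_category == fc, , drop = FALSE]
    agg <- stats::aggregate(bic ~ model, data = sub,
                            FUN = function(x) c(mean(x), length(x)))
    means <- agg$bic[, 1]; ns <- agg$bic[, 2]
    ord <- order(means)
    models <- agg$model[ord]; means <- means[ord]; ns <- ns[ord]
    n_tot <- sum(ns)
    df <- n_tot - length(models)
    mse <- if (df > 0) {
      sse <- sum(unlist(lapply(models, function(mod) {
        y <- sub$bic[sub$model == mod]
        sum((y - mean(y))^2)
      })))
      sse / df
    } else NA_real_
    sig <- .tukey_signif(means, ns, mse, df, alpha)
    lets <- .cld(sig)
    g <- data.frame(model = models, mean_bic = means, n = ns,
                    letters = lets, stringsAsFactors = FALSE)
    attr(g, "best_letters") <- strsplit(lets[1], "")[[1]]
    attr(g, "worst_letters") <- strsplit(lets[length(lets)], "")[[1]]
    out[[fc]] <- g
  }
  structure(out, class = "gp_tukey", alpha = alpha)
}

#' @export
print.gp_tukey <- function(x, ...) {
  for (fc in names(x)) {
    cat("--", fc, "--\n")
    print(x[[fc]], row.names = FALSE)
  }
  invisible(x)
}

#' Relative performance improvement (RPI)
#'
#' \deqn{RPI = 100 (\bar{BIC}_{lower} - \bar{BIC}_{top}) / \bar{BIC}_{all}}
#' the percentage by which the top-performing model set outperforms the
#' lower-performing set, relative to the all-model average BIC of the feed
#' category.
#'
#' @param top_avg,lower_avg,all_avg average BIC of the top set, the lower
#'   set, and all models in the category.
#' @return RPI in percent.
#' @examples
#' compute_rpi(29.6, 58.0, 40.1)  # 70.8
#' @export
compute_rpi <- function(top_avg, lower_avg, all_avg) {
  if (any(!is.finite(all_avg)) || any(all_avg <= 0))
    stop("all-model average BIC must be positive")
  100 * (lower_avg - top_avg) / all_avg
}

#' Per-category top/lower model sets and RPI
#'
#' The top set of a feed category is the group of models sharing a compact-
#' display letter with the minimum-mean-BIC model; the lower set shares a
#' letter with the maximum-mean-BIC model. Averages are unweighted means of
#' the per-model cell means.
#'
#' @param grouping output of [tukey_groups()].
#' @param table the BIC table the grouping was computed from.
#' @return A data.frame with one row per feed category: `top_models`,
#'   `lower_models` (semicolon-separated), the three average BICs, their
#'   difference, and `rpi`.
#' @export
select_model_sets <- function(grouping, table) {
  rows <- lapply(names(grouping), function(fc) {
    g <- grouping[[fc]]
    best <- attr(g, "best_letters")
    worst <- attr(g, "worst_letters")
    has <- function(lets, set)
      vapply(strsplit(lets, ""), function(l) any(l %in% set), TRUE)
    top <- g$model[has(g$letters, best)]
    lower <- g$model[has(g$letters, worst)]
    avg_top <- mean(g$mean_bic[g$model %in% top])
    avg_lower <- mean(g$mean_bic[g$model %in% lower])
    avg_all <- mean(g$mean_bic)
    data.frame(feed_category = fc,
               top_models = paste(top, collapse = ";"),
               lower_models = paste(lower, collapse = ";"),
               bic_top = avg_top, bic_lower = avg_lower, bic_all = avg_all,
               difference = avg_lower - avg_top,
               rpi = compute_rpi(avg_top, avg_lower, avg_all),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
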