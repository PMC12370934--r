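# Regression tree on BIC with the two categorical predictors (model name,
# feed category). Squared-error CART: at each node candidate splits order the
# predictor's levels by mean response and cut the ordered sequence, which is
# the optimal subset split for a categorical predictor under squared error.
# Depth and minimum leaf size are tuned on a held-out validation split.

# best contiguous split of `x` (factor-like character) at one node
.tree_best_split <- function(x, y, min_leaf) {
  lv <- unique(x)
  if (length(lv) < 2) return(NULL)
  agg_n <- tapply(y, x, length)
  agg_s <- tapply(y, x, sum)
  ord <- names(sort(agg_s / agg_n))
  n_cum <- cumsum(agg_n[ord]); s_cum <- cumsum(agg_s[ord])
  n_tot <- n_cum[length(ord)]; s_tot <- s_cum[length(ord)]
  best <- NULL
  for (j in seq_len(length(ord) - 1)) {
    n_l <- n_cum[j]; n_r <- n_tot - n_l
    if (n_l < min_leaf || n_r < min_leaf) next
    s_l <- s_cum[j]; s_r <- s_tot - s_l
    red <- s_l^2 / n_l + s_r^2 / n_r - s_tot^2 / n_tot
    if (is.null(best) || red > best$reduction)
      best <- list(left_levels = ord[seq_len(j)], reduction = red,
                   n_left = unname(n_l), n_right = unname(n_r))
  }
  best
}

.tree_grow <- function(data, depth, max_depth, min_leaf,
                       model_set, cat_set) {
  y <- data$bic
  node <- list(n = length(y), mean = mean(y),
               dev = sum((y - mean(y))^2),
               model_set = model_set, cat_set = cat_set,
               split_var = NULL)
  if (depth >= max_depth || node$n < 2 * min_leaf || node$dev <= 1e-10)
    return(node)
  cand <- list(model = .tree_best_split(data$model, y, min_leaf),
               feed_category = .tree_best_split(data$feed_category, y,
                                                min_leaf))
  cand <- Filter(Negate(is.null), cand)
  if (!length(cand)) return(node)
  reds <- vapply(cand, `[[`, 0, "reduction")
  if (max(reds) <= 1e-10) return(node)
  var <- names(cand)[which.max(reds)]
  sp <- cand[[var]]
  left_idx <- data[[var]] %in% sp$left_levels
  node$split_var <- var
  node$left_levels <- sp$left_levels
  node$reduction <- sp$reduction
  lv_all <- if (var == "model") model_set else cat_set
  lv_left <- intersect(lv_all, sp$left_levels)
  lv_right <- setdiff(lv_all, sp$left_levels)
  if (var == "model") {
    node$left <- .tree_grow(data[left_idx, ], depth + 1, max_depth, min_leaf,
                            lv_left, cat_set)
    node$right <- .tree_grow(data[!left_idx, ], depth + 1, max_depth,
                             min_leaf, lv_right, cat_set)
  } else {
    node$left <- .tree_grow(data[left_idx, ], depth + 1, max_depth, min_leaf,
                            model_set, lv_left)
    node$right <- .tree_grow(data[!left_idx, ], depth + 1, max_depth,
                             min_leaf, model_set, lv_right)
  }
  node
}

.tree_predict_row <- function(node, model, feed_category) {
  while (!is.null(node$split_var)) {
    val <- if (node$split_var == "model") model else feed_category
    if (val %in% node$left_levels) node <- node$left
    else if (val %in% c(node$right$model_set, node$right$cat_set))
      node <- node$right
    else node <- if (node$left$n >= node$right$n) node$left else node$right
  }
  node$mean
}

.tree_predict <- function(node, data) {
  mapply(function(m, fc) .tree_predict_row(node, m, fc),
         data$model, data$feed_category, USE.NAMES = FALSE)
}

.tree_collect <- function(node, leaves = list(), splits = list()) {
  if (is.null(node$split_var)) {
    leaves[[length(leaves) + 1]] <- node
  } else {
    splits[[length(splits) + 1]] <-
      list(var = node$split_var, reduction = node$reduction)
    res <- .tree_collect(node$left, leaves, splits)
    res <- .tree_collect(node$right, res$leaves, res$splits)
    leaves <- res$leaves; splits <- res$splits
  }
  list(leaves = leaves, splits = splits)
}

.tree_metrics <- function(pred, y) {
  rss <- sum((y - pred)^2)
  tss <- sum((y - mean(y))^2)
  list(r2 = if (tss > 0) 1 - rss / tss else 1, rmse = sqrt(rss / length(y)))
}

#' Regression tree on the BIC table
#'
#' Fits a single CART regression tree predicting BIC from model name and feed
#' category. Rows are split into a training fraction and a validation
#' holdout; unless an explicit `control` is given, tree depth (3-8) and
#' minimum leaf size (5, 10, 20) are tuned by validation RMSE. Reports leaf
#' summaries (model-set x category-set, mean BIC, count) sorted by mean BIC
#' ascending, and per-predictor contribution shares (percent of total
#' split sum-of-squares reduction).
#'
#' @param table a BIC table from [bic_table()].
#' @param split_fraction training fraction (default 0.7).
#' @param seed seed for the train/validation split.
#' @param control optional list with `max_depth` and `min_leaf`, skipping the
#'   tuning grid.
#' @return An object of class `gp_tree`: the fitted tree, training and
#'   validation R2/RMSE, `n_splits`, `leaf_report`, `contribution` (named
#'   percentage vector) and the chosen `control`.
#' @export
fit_tree <- function(table, split_fraction = 0.7, seed = 1L,
                     control = NULL) {
  if (!is.numeric(split_fraction) || split_fraction <= 0 ||
      split_fraction >= 1)
    stop("split_fraction must be strictly between 0 and 1")
  if (nrow(table) < 20) stop("need at least 20 rows to fit the tree")
  d <- data.frame(model = as.character(table$model),
                  feed_category = as.character(table$feed_category),
                  bic = table$bic, stringsAsFactors = FALSE)
  idx <- .with_seed(seed,
                    sample(nrow(d), size = floor(split_fraction * nrow(d))))
  train <- d[idx, ]; valid <- d[-idx, ]
  model_set <- unique(train$model); cat_set <- unique(train$feed_category)

  grow <- function(ctl)
    .tree_grow(train, 0L, ctl$max_depth, ctl$min_leaf, model_set, cat_set)

  tuning <- NULL
  if (is.null(control)) {
    grid <- expand.grid(max_depth = 3:8, min_leaf = c(5, 10, 20))
    scores <- vapply(seq_len(nrow(grid)), function(i) {
      ctl <- as.list(grid[i, ])
      tr <- grow(ctl)
      .tree_metrics(.tree_predict(tr, valid), valid$bic)$rmse
    }, 0)
    tuning <- cbind(grid, valid_rmse = scores)
    control <- as.list(grid[which.min(scores), ])
  }
  tree <- grow(control)

  coll <- .tree_collect(tree)
  leaves <- coll$leaves; splits <- coll$splits
  leaf_report <- do.call(rbind, lapply(leaves, function(lf)
    data.frame(models = paste(sort(lf$model_set), collapse = ";"),
               categories = paste(sort(lf$cat_set), collapse = ";"),
               mean_bic = lf$mean, count = lf$n,
               stringsAsFactors = FALSE)))
  leaf_report <- leaf_report[order(leaf_report$mean_bic), ]
  rownames(leaf_report) <- NULL

  contribution <- numeric(0)
  if (length(splits)) {
    reds <- vapply(splits, `[[`, 0, "reduction")
    vars <- vapply(splits, `[[`, "", "var")
    by_var <- tapply(reds, vars, sum)
    contribution <- 100 * by_var / sum(by_var)
  }

  tr_m <- .tree_metrics(.tree_predict(tree, train), train$bic)
  va_m <- .tree_metrics(.tree_predict(tree, valid), valid$bic)

  structure(list(tree = tree, control = control, tuning = tuning,
                 split_fraction = split_fraction, seed = seed,
                 n_train = nrow(train), n_valid = nrow(valid),
                 n_splits = length(splits),
                 train_r2 = tr_m$r2, train_rmse = tr_m$rmse,
                 valid_r2 = va_m$r2, valid_rmse = va_m$rmse,
                 leaf_report = leaf_report,
                 contribution = contribution),
            class = "gp_tree")
}

#' @export
print.gp_tree <- function(x, ...) {
  cat(sprintf(
    "<gp_tree> %d splits (depth<=%d, min leaf %d); train R2=%.3f RMSE=%.2f; valid R2=%.3f RMSE=%.2f\n",
    x$n_splits, x$control$max_depth, x$control$min_leaf,
    x$train_r2, x$train_rmse, x$valid_r2, x$valid_rmse))
  if (length(x$contribution)) {
    cat("contribution shares (%):\n")
    print(round(x$contribution, 1))
  }
  cat(sprintf("%d leaves; best:\n", nrow(x$leaf_report)))
  print(utils::head(x$leaf_report, 3), row.names = FALSE)
  invisible(x)
}

#' Predict from a fitted gp_tree
#'
#' @param object a `gp_tree`.
#' @param newdata data.frame with `model` and `feed_category` columns.
#' @param ... unused.
#' @return Numeric vector of predicted BIC values (leaf means).
#' @export
predict.gp_tree <- function(object, newdata, ...) {
  .tree_predict(object$tree, newdata)
}
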