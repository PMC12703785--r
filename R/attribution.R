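#' Assemble a feature table for driver attribution
#'
#' Samples co-registered pixels, z-scores every column (scale parameters are
#' stored for back-transformation), and records a reproducible random
#' train/validation split (default 60/40). Predictors are declared
#' in two categories: climatic background (long-term means) and climatic
#' stability (trend metrics of the same variables); a missing declaration
#' defaults every predictor to "background".
#'
#' @param predictors named list of numeric matrices (one per predictor, all
#'   the same grid) or a data.frame of already-extracted samples.
#' @param response numeric matrix on the same grid (or vector matching the
#'   data.frame rows): one of the vegetation stability indices.
#' @param categories named character vector mapping predictor names to
#'   `"background"` or `"stability"`.
#' @param train_frac training fraction of the split.
#' @param max_samples cap on sampled pixels (down-sampled at random when the
#'   grid is larger).
#' @param seed RNG seed controlling sampling and split.
#' @return object of class `feature_table`: `x` (z-scored matrix), `y`
#'   (z-scored response), `split` (`"train"`/`"valid"`), `categories`,
#'   `scaling` (per-column mean/sd), `constant` (names of zero-variance
#'   predictors, retained).
#' @export
build_feature_table <- function(predictors, response,
                                categories = NULL, train_frac = 0.6,
                                max_samples = 50000L, seed = 1L) {
  if (is.data.frame(predictors)) {
    x <- as.matrix(predictors)
    y <- as.numeric(response)
  } else {
    stopifnot(is.list(predictors), length(predictors) >= 1L)
    dims <- lapply(predictors, dim)
    if (length(unique(dims)) != 1L ||
        !identical(dims[[1L]], dim(as.matrix(response))))
      stop("predictor and response layers are not co-registered")
    x <- sapply(predictors, as.vector)
    y <- as.vector(response)
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  keep <- stats::complete.cases(x) & is.finite(y)
  x <- x[keep, , drop = FALSE]; y <- y[keep]
  if (nrow(x) < 10L) stop("too few valid samples")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  if (nrow(x) > max_samples) {
    pick <- sort(sample.int(nrow(x), max_samples))
    x <- x[pick, , drop = FALSE]; y <- y[pick]
  }
  scale_col <- function(v) {
    m <- mean(v); s <- stats::sd(v)
    if (!is.finite(s) || s == 0) list(z = v * 0, mean = m, sd = 0)
    else list(z = (v - m) / s, mean = m, sd = s)
  }
  sc <- apply(x, 2L, scale_col)
  z <- sapply(sc, `[[`, "z")
  colnames(z) <- colnames(x)
  const <- names(sc)[vapply(sc, function(s) s$sd == 0, TRUE)]
  if (length(const))
    warning("constant predictor(s) retained with zero variance: ",
            paste(const, collapse = ", "))
  ysc <- scale_col(y)
  n_train <- round(train_frac * nrow(z))
  split <- rep("valid", nrow(z))
  split[sample.int(nrow(z), n_train)] <- "train"
  if (is.null(categories))
    categories <- stats::setNames(rep("background", ncol(z)), colnames(z))
  if (!all(colnames(z) %in% names(categories)))
    stop("every predictor needs a category")
  structure(list(x = z, y = ysc$z, split = split,
                 categories = categories[colnames(z)],
                 scaling = list(x = lapply(sc, function(s) s[c("mean", "sd")]),
                                y = ysc[c("mean", "sd")]),
                 constant = const),
            class = "feature_table")
}

default_gbt_params <- function() {
  list(learning_rate = 0.05, max_depth = 8L, n_estimators = 500L)
}

default_gbt_grid <- function() {
  expand.grid(learning_rate = c(0.01, 0.05, 0.1),
              max_depth = c(4L, 6L, 8L),
              n_estimators = c(300L, 500L, 700L))
}

#' Fit the gradient-boosted stability model
#'
#' Boosted regression trees (squared loss) relating a stability response to
#' the climate feature table. With `grid = NULL` the package's reference default
#' configuration is used (learning_rate 0.05, max_depth 8, n_estimators
#' 500); with `grid = "full"` (or a data.frame of candidates) the 27-point
#' grid over learning_rate {0.01, 0.05, 0.1} x max_depth {4, 6, 8} x
#' n_estimators {300, 500, 700} is searched by 5-fold cross-validated RMSE,
#' ties broken toward fewer trees then shallower depth. Performance is
#' reported as R-squared on the held-out validation split.
#'
#' @param table a [build_feature_table()] result with >= 100 training rows.
#' @param grid `NULL`, `"full"`, or a data.frame with columns
#'   `learning_rate`, `max_depth`, `n_estimators`.
#' @param n_folds cross-validation folds for the grid search.
#' @param seed RNG seed for fold assignment.
#' @return object of class `stability_model`: the fitted ensemble, chosen
#'   `params`, `r2_valid`, and (when searched) the `cv_results` table.
#' @export
fit_stability_model <- function(table, grid = NULL, n_folds = 5L, seed = 1L) {
  stopifnot(inherits(table, "feature_table"))
  tr <- table$split == "train"
  if (sum(tr) < 100L) stop("need >= 100 training rows")
  xtr <- table$x[tr, , drop = FALSE]; ytr <- table$y[tr]
  cv_results <- NULL
  if (is.null(grid)) {
    params <- default_gbt_params()
  } else {
    if (identical(grid, "full")) grid <- default_gbt_grid()
    stopifnot(is.data.frame(grid),
              all(c("learning_rate", "max_depth", "n_estimators") %in% names(grid)))
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    folds <- sample(rep_len(seq_len(n_folds), nrow(xtr)))
    rmse <- numeric(nrow(grid))
    for (g in seq_len(nrow(grid))) {
      se <- 0
      for (f in seq_len(n_folds)) {
        hold <- folds == f
        m <- .gbt_train_cpp(xtr[!hold, , drop = FALSE], ytr[!hold],
                            grid$n_estimators[g], grid$learning_rate[g],
                            grid$max_depth[g])
        pr <- .gbt_predict_cpp(m, xtr[hold, , drop = FALSE])
        se <- se + sum((pr - ytr[hold])^2)
      }
      rmse[g] <- sqrt(se / nrow(xtr))
    }
    cv_results <- cbind(grid, rmse = rmse)
    ord <- order(rmse, grid$n_estimators, grid$max_depth)
    params <- as.list(grid[ord[1L], ])
    params$max_depth <- as.integer(params$max_depth)
    params$n_estimators <- as.integer(params$n_estimators)
  }
  model <- .gbt_train_cpp(xtr, ytr, params$n_estimators,
                          params$learning_rate, params$max_depth)
  va <- table$split == "valid"
  pv <- .gbt_predict_cpp(model, table$x[va, , drop = FALSE])
  yv <- table$y[va]
  r2 <- 1 - sum((yv - pv)^2) / sum((yv - mean(yv))^2)
  structure(list(model = model, params = params, r2_valid = r2,
                 cv_results = cv_results, features = colnames(table$x)),
            class = "stability_model")
}

#' Predict from a fitted stability model
#' @param object a `stability_model`.
#' @param newdata matrix with the model's feature columns (z-scored scale).
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.stability_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata)))
    newdata <- newdata[, object$features, drop = FALSE]
  .gbt_predict_cpp(object$model, newdata)
}

#' Shapley-value attribution of the fitted model
#'
#' Exact path-dependent TreeSHAP over the ensemble: per-sample, per-feature
#' contributions that sum (with the base value) to the model prediction.
#' Importance is the mean absolute Shapley value per feature, rescaled to
#' percentages summing to 100, with sums per declared predictor category.
#'
#' @param model a [fit_stability_model()] result.
#' @param table the [build_feature_table()] the model was built from.
#' @param max_samples cap on rows explained (random subset, seeded).
#' @param seed RNG seed for the subset draw.
#' @return object of class `attribution_result`: `importance` (named
#'   percentages), `category_importance`, `shap` (matrix), `base_value`,
#'   `x` (explained rows), `r2_valid`, `params`, `categories`.
#' @export
shapley_attribution <- function(model, table, max_samples = 10000L,
                                seed = 1L) {
  stopifnot(inherits(model, "stability_model"),
            inherits(table, "feature_table"))
  if (!identical(model$features, colnames(table$x)))
    stop("feature mismatch between model and table")
  x <- table$x
  if (nrow(x) > max_samples) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    x <- x[sort(sample.int(nrow(x), max_samples)), , drop = FALSE]
  }
  sh <- .treeshap_cpp(model$model, x)
  phi <- sh$phi
  colnames(phi) <- colnames(x)
  mabs <- colMeans(abs(phi))
  tot <- sum(mabs)
  importance <- if (tot > 0) 100 * mabs / tot else mabs * 0
  cat_imp <- tapply(importance, table$categories[colnames(x)], sum)
  structure(list(importance = importance,
                 category_importance = as.vector(cat_imp) |>
                   stats::setNames(names(cat_imp)),
                 shap = phi, base_value = sh$base_value, x = x,
                 r2_valid = model$r2_valid, params = model$params,
                 categories = table$categories),
            class = "attribution_result")
}

#' Binned SHAP dependence curve
#'
#' Quantile-bins a feature and averages its Shapley values per bin, the
#' tabular equivalent of a SHAP dependence plot, with simple shape
#' descriptors (sign changes of the binned slope; monotonicity).
#'
#' @param result an [shapley_attribution()] result.
#' @param feature feature name.
#' @param bins number of quantile bins (>= 2).
#' @return data.frame (`feature_value`, `mean_shap`, `n`) with attributes
#'   `sign_changes` and `monotone` (`"increasing"`, `"decreasing"` or
#'   `"no"`).
#' @export
dependence_export <- function(result, feature, bins = 20L) {
  stopifnot(inherits(result, "attribution_result"))
  if (!feature %in% colnames(result$shap)) stop("unknown feature")
  if (bins < 2L) stop("need >= 2 bins")
  v <- result$x[, feature]
  s <- result$shap[, feature]
  br <- unique(stats::quantile(v, probs = seq(0, 1, length.out = bins + 1L)))
  if (length(br) < 3L) br <- c(min(v) - 1, mean(v), max(v) + 1)
  g <- cut(v, br, include.lowest = TRUE)
  out <- data.frame(feature_value = as.vector(tapply(v, g, mean)),
                    mean_shap = as.vector(tapply(s, g, mean)),
                    n = as.vector(tapply(s, g, length)))
  out <- out[is.finite(out$feature_value), , drop = FALSE]
  d <- diff(out$mean_shap)
  d <- d[d != 0]
  sign_changes <- if (length(d) > 1L) sum(diff(sign(d)) != 0) else 0L
  monotone <- if (length(d) == 0L) "no"
    else if (all(d > 0)) "increasing"
    else if (all(d < 0)) "decreasing" else "no"
  attr(out, "sign_changes") <- sign_changes
  attr(out, "monotone") <- monotone
  out
}

#' Export / import a feature table as CSV with a JSON schema sidecar
#'
#' The CSV holds the z-scored predictor columns, the response `y` and the
#' `split` membership; the sidecar records column categories and the
#' per-column scale parameters needed to map back to physical units.
#'
#' @param table a [build_feature_table()] result.
#' @param path CSV path (`<path>.schema.json` is written alongside).
#' @return (write) the path invisibly; (read) a `feature_table`.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  df <- as.data.frame(table$x)
  df$y <- table$y
  df$split <- table$split
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(categories = as.list(table$categories),
         scaling = table$scaling, constant = table$constant),
    paste0(path, ".schema.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  schema <- jsonlite::read_json(paste0(path, ".schema.json"),
                                simplifyVector = TRUE)
  feats <- setdiff(names(df), c("y", "split"))
  structure(list(x = as.matrix(df[feats]), y = df$y, split = df$split,
                 categories = unlist(schema$categories)[feats],
                 scaling = schema$scaling,
                 constant = schema$constant %||% character(0)),
            class = "feature_table")
}
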