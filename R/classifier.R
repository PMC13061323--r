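#' Canonical order of the 22 classification features
#'
#' Ten bands plus NBR per composite, pre first:
#' `pre_B2 ... pre_B12, pre_NBR, post_B2 ... post_B12, post_NBR`.
#' @return character vector of length 22.
#' @export
feature_names <- function() {
  c(paste0("pre_", c(band_set(), "NBR")), paste0("post_", c(band_set(), "NBR")))
}

#' Assemble the 22-feature stack from a pre/post composite pair
#'
#' Features are the ten spectral bands and the NBR of each composite. A pixel
#' is valid iff it is valid in both composites; classification and all later
#' stages ignore invalid pixels (they are unobservable that month).
#'
#' @param pre,post `burn_composite` objects on the same grid.
#' @return object of class `feature_stack`: `grid`, named list `features`
#'   (22 matrices), `valid`.
#' @export
assemble_features <- function(pre, post) {
  stopifnot(inherits(pre, "burn_composite"), inherits(post, "burn_composite"))
  check_same_grid(pre$grid, post$grid, "pre and post composites")
  feats <- c(stats::setNames(c(pre$bands, list(pre$nbr)),
                             paste0("pre_", c(band_set(), "NBR"))),
             stats::setNames(c(post$bands, list(post$nbr)),
                             paste0("post_", c(band_set(), "NBR"))))
  valid <- pre$valid & post$valid
  structure(list(grid = pre$grid, features = feats[feature_names()],
                 valid = valid),
            class = "feature_stack")
}

#' @export
print.feature_stack <- function(x, ...) {
  cat(sprintf("<feature_stack> %d features, %.1f%% valid, grid %s\n",
              length(x$features), 100 * mean(x$valid), format(x$grid)))
  invisible(x)
}

# Feature matrix (n x 22) for given pixel rows/cols of a feature stack.
extract_feature_matrix <- function(fs, rows, cols) {
  idx <- cbind(rows, cols)
  m <- vapply(fs$features, function(f) f[idx], numeric(length(rows)))
  if (length(rows) == 1L) m <- matrix(m, nrow = 1L,
                                      dimnames = list(NULL, names(fs$features)))
  m
}

#' Random-forest configuration
#'
#' Hyperparameters follow common platform defaults: 100 trees, sqrt(p)
#' candidate features per split, minimum node size 1. Class labels are 0
#' (burned) and 1 (unburned).
#'
#' @param n_trees number of trees (>= 1).
#' @param mtry candidate features per split; default `floor(sqrt(22))`.
#' @param min_leaf minimum terminal-node size.
#' @param seed integer seed controlling tree randomness.
#' @return list of class `rf_config`.
#' @export
rf_config <- function(n_trees = 100, mtry = floor(sqrt(22)), min_leaf = 1,
                      seed = 1L) {
  stopifnot(n_trees >= 1)
  structure(list(n_trees = as.integer(n_trees), mtry = as.integer(mtry),
                 min_leaf = as.integer(min_leaf), seed = as.integer(seed)),
            class = "rf_config")
}

#' Train the burned/unburned random forest
#'
#' Training spectra are extracted from the feature stack of the month each
#' point was labelled in (`points$month` selects from `feature_stacks`).
#' Deterministic for a fixed config seed.
#'
#' @param feature_stacks named list of `feature_stack` objects, names are
#'   `"YYYY-MM"` months.
#' @param points data.frame with row, col, label (0 burned / 1 unburned) and
#'   month columns, as from [sample_training_points()].
#' @param config an [rf_config()].
#' @return object of class `burn_rf` wrapping the fitted forest and the
#'   feature-order manifest.
#' @export
rf_train <- function(feature_stacks, points, config = rf_config()) {
  stopifnot(is.data.frame(points), nrow(points) > 0)
  if (length(unique(points$label)) < 2L)
    stop("training set must contain both classes", call. = FALSE)
  missing <- setdiff(unique(points$month), names(feature_stacks))
  if (length(missing))
    stop("no feature stack for training month(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  X <- matrix(NA_real_, nrow(points), 22L,
              dimnames = list(NULL, feature_names()))
  for (m in unique(points$month)) {
    i <- which(points$month == m)
    X[i, ] <- extract_feature_matrix(feature_stacks[[m]],
                                     points$row[i], points$col[i])
  }
  ok <- stats::complete.cases(X)
  if (!all(ok)) {
    if (!any(ok)) stop("all training points fall on invalid pixels", call. = FALSE)
    warning(sum(!ok), " training points on invalid pixels dropped")
    X <- X[ok, , drop = FALSE]; points <- points[ok, , drop = FALSE]
  }
  y <- factor(points$label, levels = c(0L, 1L))
  set.seed(config$seed)
  fit <- randomForest::randomForest(x = X, y = y, ntree = config$n_trees,
                                    mtry = config$mtry,
                                    nodesize = config$min_leaf)
  structure(list(forest = fit, feature_order = feature_names(),
                 config = config, n_train = nrow(X)),
            class = "burn_rf")
}

#' @export
print.burn_rf <- function(x, ...) {
  cat(sprintf("<burn_rf> %d trees, mtry %d, trained on %d points (22 features)\n",
              x$config$n_trees, x$config$mtry, x$n_train))
  invisible(x)
}

#' Classify every valid pixel of a feature stack
#'
#' Majority vote over the forest's trees. Output codes follow the training
#' labels: 0 burned, 1 unburned; invalid pixels are NA.
#'
#' @param model a `burn_rf` from [rf_train()].
#' @param fs a `feature_stack`.
#' @return integer matrix (0 / 1 / NA).
#' @export
rf_predict <- function(model, fs) {
  stopifnot(inherits(model, "burn_rf"), inherits(fs, "feature_stack"))
  if (!identical(names(fs$features), model$feature_order))
    stop("feature order does not match the trained model", call. = FALSE)
  out <- matrix(NA_integer_, fs$grid$n_rows, fs$grid$n_cols)
  idx <- which(fs$valid)
  if (!length(idx)) return(out)
  rows <- (idx - 1L) %% fs$grid$n_rows + 1L
  cols <- (idx - 1L) %/% fs$grid$n_rows + 1L
  X <- extract_feature_matrix(fs, rows, cols)
  ok <- stats::complete.cases(X)
  pred <- rep(NA_integer_, length(idx))
  if (any(ok))
    pred[ok] <- as.integer(as.character(
      stats::predict(model$forest, X[ok, , drop = FALSE])))
  out[idx] <- pred
  out
}
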