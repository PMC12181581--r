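# The fast inner predictive pipeline g: impurity-ranked feature selection
# with a single depth-capped decision tree, mean/variance scaling fitted on
# train, and L1-penalized logistic regression with a grid search over the
# regularization strength. Model selection uses the run's validation split;
# the loss is 1 - AUC on validation.

#' Inner pipeline configuration
#'
#' @param f_keep Number of features retained by the impurity selector
#'   (default 150).
#' @param m_fs Maximum depth of the selector tree (default 50).
#' @param c_grid Inverse regularization strengths for the L1 logistic model
#'   (larger = weaker penalty); default 7 log-spaced values over
#'   \[1e-3, 1e3\]. Mapped to a glmnet lambda as `1 / (n_train * C)`.
#' @param seed Integer seed (selector tie-breaks).
#' @return List of class `inner_config`.
#' @export
inner_config <- function(f_keep = 150, m_fs = 50,
                         c_grid = 10^seq(-3, 3, length.out = 7), seed = 1) {
  if (f_keep < 1 || m_fs < 1)
    stop_opticog("f_keep and m_fs must be >= 1", "opticog_config_error")
  if (!length(c_grid) || any(c_grid <= 0))
    stop_opticog("c_grid must be non-empty and positive", "opticog_config_error")
  structure(list(f_keep = as.integer(f_keep), m_fs = as.integer(m_fs),
                 c_grid = sort(c_grid), seed = as.integer(seed)),
            class = "inner_config")
}

#' Impurity-ranked feature selection
#'
#' Fits one deterministic depth-capped CART-style classification tree to all
#' features (no subsampling, all features available at every split) and
#' ranks features by their total Gini impurity reduction; returns the top
#' `f_keep` feature names. Features the tree never splits on rank after all
#' used ones, in column order.
#'
#' @param x Numeric matrix (participants x features) with column names.
#' @param y Binary labels (factor/character/0-1) with both classes present.
#' @param cfg An `inner_config`.
#' @return Character vector of selected feature names,
#'   `min(f_keep, ncol(x))` long.
#' @export
select_features_impurity <- function(x, y, cfg = inner_config()) {
  y <- factor(y)
  if (nlevels(y) < 2)
    stop_opticog("need both classes in y for feature selection",
                 "opticog_data_error")
  df <- data.frame(.y = y, x, check.names = FALSE)
  fit <- ranger::ranger(dependent.variable.name = ".y", data = df,
                        num.trees = 1, mtry = ncol(x), replace = FALSE,
                        sample.fraction = 1, max.depth = cfg$m_fs,
                        importance = "impurity", seed = cfg$seed,
                        num.threads = 1)
  imp <- fit$variable.importance[colnames(x)]
  imp[is.na(imp)] <- 0
  ord <- order(-imp, seq_along(imp))   # ties: stable column order
  colnames(x)[ord][seq_len(min(cfg$f_keep, ncol(x)))]
}

# Mean/sd scaler on selected columns (train-fitted); zero-sd -> divide by 1.
fit_column_scaler <- function(x) {
  m <- colMeans(x)
  s <- apply(x, 2, stats::sd)
  s[s == 0 | !is.finite(s)] <- 1
  list(mean = m, sd = s)
}

apply_column_scaler <- function(scaler, x) {
  sweep(sweep(x[, names(scaler$mean), drop = FALSE], 2, scaler$mean),
        2, scaler$sd, "/")
}

#' Fit the inner pipeline g
#'
#' Selects features by impurity, standardizes them (train statistics), fits
#' an L1-penalized logistic regression at every value of the regularization
#' grid, and keeps the grid value with the highest validation AUC.
#'
#' @param x_train,y_train Training features (matrix) and binary labels; the
#'   labels are the two extreme classes only.
#' @param x_val,y_val Validation features and labels used to pick the grid
#'   winner (and later to evaluate the loss).
#' @param cfg An `inner_config`.
#' @param positive Label treated as the positive class.
#' @return List of class `inner_fit`: `selected`, `scaler`, `glmnet_fit`,
#'   `lambda`, `c_value`, `val_auc`, and `predict(newx)` returning positive-
#'   class probabilities.
#' @export
fit_inner <- function(x_train, y_train, x_val, y_val, cfg = inner_config(),
                      positive = "PositiveAger") {
  y_train <- factor(y_train)
  if (nlevels(y_train) < 2 || min(table(y_train)) < 2)
    stop_opticog("degenerate training labels for the inner pipeline",
                 "opticog_data_error")
  selected <- select_features_impurity(x_train, y_train, cfg)
  scaler <- fit_column_scaler(x_train[, selected, drop = FALSE])
  xs_train <- apply_column_scaler(scaler, x_train)
  ybin <- as.numeric(as.character(y_train) == positive)
  n <- nrow(xs_train)
  lambdas <- sort(1 / (n * cfg$c_grid), decreasing = TRUE)
  fit <- glmnet::glmnet(xs_train, ybin, family = "binomial", alpha = 1,
                        lambda = lambdas, standardize = FALSE)
  xs_val <- apply_column_scaler(scaler, x_val)
  pv <- stats::predict(fit, newx = xs_val, type = "response")
  yv <- as.numeric(as.character(y_val) == positive)
  aucs <- apply(pv, 2, function(p) auc(p, yv == 1))
  best <- which.max(aucs)    # ties: strongest penalty (first = largest lambda)
  lambda_star <- fit$lambda[best]
  obj <- list(selected = selected, scaler = scaler, glmnet_fit = fit,
              lambda = lambda_star, c_value = 1 / (n * lambda_star),
              val_auc = unname(aucs[best]), positive = positive)
  obj$predict <- function(newx) {
    xs <- apply_column_scaler(scaler, newx)
    drop(stats::predict(fit, newx = xs, type = "response", s = lambda_star))
  }
  structure(obj, class = "inner_fit")
}

#' Validation loss of a fitted pipeline
#'
#' `1 - AUC` of the predicted positive-class probabilities on a validation
#' set containing both classes.
#'
#' @param model An `inner_fit` (or any object with a `$predict` function and
#'   `$positive` label).
#' @param x_val,y_val Validation features and labels.
#' @return Loss in \[0, 1\].
#' @export
evaluate_loss <- function(model, x_val, y_val) {
  yv <- as.character(y_val) == model$positive
  if (length(unique(yv)) < 2)
    stop_opticog("validation set must contain both classes",
                 "opticog_data_error")
  1 - auc(model$predict(x_val), yv)
}

#' @export
print.inner_fit <- function(x, ...) {
  nz <- sum(as.matrix(stats::coef(x$glmnet_fit, s = x$lambda))[-1, ] != 0)
  cat(sprintf(
    "inner pipeline g: %d features selected, C = %.4g, %d nonzero coefs, val AUC %.3f\n",
    length(x$selected), x$c_value, nz, x$val_auc))
  invisible(x)
}
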