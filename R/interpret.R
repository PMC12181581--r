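# Shapley-additive explanation importance for the fitted final pipeline,
# via exact tree-path attribution (the booster's predcontrib), aggregated
# by dMRI attribute or tract.

#' Shapley-value feature importance
#'
#' Computes exact per-observation tree-path Shapley attributions for a
#' fitted final pipeline. Attributions are on the model margin (log-odds)
#' scale by default; `scale = "probability"` rescales each row linearly so
#' the attributions sum to the probability shift from the base rate. Local
#' accuracy holds on the margin scale: attributions plus the bias equal the
#' model margin per observation. Importance is the mean absolute
#' attribution over observations.
#'
#' @param model A `final_fit` (fitted boosted pipeline).
#' @param features A `feature_table` whose rows are the observations to
#'   explain (typically the training set).
#' @param scale `"margin"` (default) or `"probability"`.
#' @return List of class `importance_table`: `importance` (data.frame:
#'   feature, block, attribute, tract, mean_abs_shap), `shap` (observation x
#'   feature matrix), `bias` (per-observation base value).
#' @export
shapley_importance <- function(model, features, scale = c("margin", "probability")) {
  scale <- match.arg(scale)
  miss <- setdiff(model$selected, colnames(features$x))
  if (length(miss))
    stop_opticog(paste("features missing from table:",
                       paste(utils::head(miss, 5), collapse = ", ")),
                 "opticog_schema_error")
  xs <- robust_scale(model$scaler, features$x)[, model$selected, drop = FALSE]
  contrib <- stats::predict(model$booster, xgboost::xgb.DMatrix(xs),
                            predcontrib = TRUE)
  # last column is the base value (named BIAS or (Intercept) by version)
  bias <- contrib[, ncol(contrib)]
  shap <- contrib[, -ncol(contrib), drop = FALSE]
  if (scale == "probability") {
    margin <- rowSums(shap) + bias
    delta <- stats::plogis(margin) - stats::plogis(bias)
    denom <- margin - bias
    f <- ifelse(abs(denom) < 1e-12, 0, delta / denom)
    shap <- shap * f
  }
  m <- features$meta[match(colnames(shap), features$meta$feature), ]
  imp <- data.frame(feature = colnames(shap), block = m$block,
                    attribute = m$attribute, tract = m$tract,
                    mean_abs_shap = colMeans(abs(shap)))
  imp <- imp[order(-imp$mean_abs_shap), ]
  rownames(imp) <- NULL
  structure(list(importance = imp, shap = shap, bias = bias, scale = scale),
            class = "importance_table")
}

#' @export
print.importance_table <- function(x, ...) {
  cat(sprintf("importance_table (%s scale), top features:\n", x$scale))
  print(utils::head(x$importance, 10), digits = 4)
  invisible(x)
}

#' Aggregate Shapley importance by dMRI attribute or tract
#'
#' Sums the per-feature mean absolute Shapley values of dMRI features within
#' each diffusion attribute (or tract); demographic features are reported
#' singly. Aggregation conserves the total dMRI importance exactly.
#'
#' @param tab An `importance_table`.
#' @param by `"attribute"` or `"tract"`.
#' @return data.frame with `group`, `block`, `importance`, sorted
#'   decreasing.
#' @export
aggregate_importance <- function(tab, by = c("attribute", "tract")) {
  by <- match.arg(by)
  imp <- tab$importance
  dm <- imp[imp$block == "dmri", , drop = FALSE]
  if (nrow(dm) && anyNA(dm[[by]]))
    stop_opticog("dMRI feature with missing metadata", "opticog_metadata_error")
  agg <- if (nrow(dm))
    stats::aggregate(mean_abs_shap ~ grp, data.frame(grp = dm[[by]],
                                                     mean_abs_shap = dm$mean_abs_shap),
                     FUN = sum)
  else data.frame(grp = character(0), mean_abs_shap = numeric(0))
  out <- rbind(
    data.frame(group = agg$grp, block = "dmri", importance = agg$mean_abs_shap),
    data.frame(group = imp$feature[imp$block == "demographic"],
               block = "demographic",
               importance = imp$mean_abs_shap[imp$block == "demographic"]))
  out <- out[order(-out$importance), ]
  rownames(out) <- NULL
  out
}
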