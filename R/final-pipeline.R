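# The final predictive pipeline G: robust scaling (median/IQR), tunable
# impurity feature selection, gradient-boosted trees (xgboost), and
# sequential model-based ("Bayesian") hyperparameter search with an
# expected-improvement acquisition over a random-forest surrogate. Also the
# PCA scoring baseline and the single-block (dMRI-only / demographics-only)
# baselines.

#' Fit a robust scaler
#'
#' Per-feature median and interquartile range (linear-interpolation
#' quartiles), fitted on training rows only. Zero-IQR features fall back to
#' a divisor of 1 and are flagged.
#'
#' @param x Numeric training matrix.
#' @return List of class `robust_scaler` with `median`, `iqr`,
#'   `zero_iqr` (logical flags).
#' @export
fit_robust_scaler <- function(x) {
  med <- apply(x, 2, stats::median)
  q1 <- apply(x, 2, q_linear, p = 0.25)
  q3 <- apply(x, 2, q_linear, p = 0.75)
  iqr <- q3 - q1
  zero <- iqr == 0
  iqr[zero] <- 1
  structure(list(median = med, iqr = iqr, zero_iqr = zero),
            class = "robust_scaler")
}

#' Apply a robust scaler
#'
#' `value -> (value - median) / IQR` per feature.
#'
#' @param scaler A `robust_scaler`.
#' @param x Numeric matrix with the scaler's columns.
#' @return Scaled matrix.
#' @export
robust_scale <- function(scaler, x) {
  sweep(sweep(x[, names(scaler$median), drop = FALSE], 2, scaler$median),
        2, scaler$iqr, "/")
}

#' Final pipeline search space and budget
#'
#' Bounds for the tunable steps of G: retained feature count `f_keep`,
#' selector depth `m_fs`, boosting rounds, tree depth, learning rate (log
#' scale), row/column subsampling and L2 regularization (log scale).
#'
#' @param f_keep,m_fs,nrounds,max_depth Integer ranges `c(lo, hi)`.
#' @param eta,subsample,colsample,reg_lambda Continuous ranges `c(lo, hi)`.
#' @param budget Total number of hyperparameter evaluations (>= 1).
#' @param n_init Initial Latin-hypercube design size (capped at `budget`).
#' @param nfold Cross-validation folds scoring each candidate.
#' @param seed Integer seed.
#' @return List of class `final_config`.
#' @export
final_config <- function(f_keep = c(20, 150), m_fs = c(3, 50),
                         nrounds = c(50, 500), max_depth = c(2, 8),
                         eta = c(0.01, 0.3), subsample = c(0.5, 1),
                         colsample = c(0.5, 1), reg_lambda = c(1e-3, 10),
                         budget = 50, n_init = 10, nfold = 5, seed = 1) {
  rngs <- list(f_keep = f_keep, m_fs = m_fs, nrounds = nrounds,
               max_depth = max_depth, eta = eta, subsample = subsample,
               colsample = colsample, reg_lambda = reg_lambda)
  for (nm in names(rngs)) {
    r <- rngs[[nm]]
    if (length(r) != 2 || any(r <= 0) || r[1] > r[2])
      stop_opticog(sprintf("invalid range for %s", nm), "opticog_config_error")
  }
  if (budget < 1) stop_opticog("budget must be >= 1", "opticog_config_error")
  structure(c(rngs, list(budget = as.integer(budget),
                         n_init = as.integer(min(n_init, budget)),
                         nfold = as.integer(nfold), seed = as.integer(seed))),
            class = "final_config")
}

# Map a unit-cube row to a named hyperparameter list. eta and reg_lambda are
# sampled on the log scale; integer dimensions are rounded.
unit_to_params <- function(u, cfg) {
  lin <- function(r, v) r[1] + v * (r[2] - r[1])
  logl <- function(r, v) exp(log(r[1]) + v * (log(r[2]) - log(r[1])))
  list(f_keep = as.integer(round(lin(cfg$f_keep, u[1]))),
       m_fs = as.integer(round(lin(cfg$m_fs, u[2]))),
       nrounds = as.integer(round(lin(cfg$nrounds, u[3]))),
       max_depth = as.integer(round(lin(cfg$max_depth, u[4]))),
       eta = logl(cfg$eta, u[5]),
       subsample = lin(cfg$subsample, u[6]),
       colsample = lin(cfg$colsample, u[7]),
       reg_lambda = logl(cfg$reg_lambda, u[8]))
}

# Fit one candidate G (scale -> select -> boost) on (x, y); returns a
# fitted object with a predict(newx) closure.
fit_g_once <- function(x, ybin, params, seed) {
  scaler <- fit_robust_scaler(x)
  xs <- robust_scale(scaler, x)
  sel_cfg <- inner_config(f_keep = min(params$f_keep, ncol(xs)),
                          m_fs = params$m_fs, seed = seed)
  selected <- select_features_impurity(xs, ybin, sel_cfg)
  xsel <- xs[, selected, drop = FALSE]
  bst <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", eta = params$eta,
                  max_depth = params$max_depth, subsample = params$subsample,
                  colsample_bytree = params$colsample,
                  lambda = params$reg_lambda, nthread = 1, seed = seed),
    data = xgboost::xgb.DMatrix(xsel, label = ybin),
    nrounds = params$nrounds, verbose = 0)
  obj <- list(scaler = scaler, selected = selected, booster = bst,
              params = params)
  obj$predict <- function(newx, margin = FALSE) {
    xs2 <- robust_scale(scaler, newx)[, selected, drop = FALSE]
    stats::predict(bst, xgboost::xgb.DMatrix(xs2),
                   outputmargin = margin)
  }
  structure(obj, class = "final_fit")
}

# Cross-validated AUC of one hyperparameter point.
cv_auc_g <- function(x, ybin, params, nfold, seed) {
  n <- length(ybin)
  folds <- with_local_seed(seed, sample(rep_len(seq_len(nfold), n)))
  aucs <- vapply(seq_len(nfold), function(k) {
    tr <- folds != k
    if (length(unique(ybin[!tr])) < 2 || length(unique(ybin[tr])) < 2)
      return(NA_real_)
    fit <- fit_g_once(x[tr, , drop = FALSE], ybin[tr], params, wrap_seed(seed + k))
    auc(fit$predict(x[!tr, , drop = FALSE]), ybin[!tr] == 1)
  }, numeric(1))
  mean(aucs, na.rm = TRUE)
}

#' Fit the final pipeline G with sequential model-based search
#'
#' Each evaluation fits robust scaling, impurity selection with tunable
#' `f_keep`/`m_fs`, and a gradient-boosted tree ensemble, scored by k-fold
#' cross-validated AUC on the combined train+validation extremes. The search
#' starts from a Latin-hypercube design and continues with an
#' expected-improvement acquisition over a random-forest surrogate. The
#' winner is refit on all supplied rows.
#'
#' @param x_trainval Numeric feature matrix (train + validation extremes).
#' @param y Binary labels (two extreme classes).
#' @param cfg A `final_config`.
#' @param positive Label treated as positive.
#' @return A `final_fit` with `cv_auc`, `history` (evaluated points), and a
#'   `predict(newx)` closure returning positive-class probabilities.
#' @export
fit_final <- function(x_trainval, y, cfg = final_config(),
                      positive = "PositiveAger") {
  ybin <- as.numeric(as.character(y) == positive)
  if (length(unique(ybin)) < 2)
    stop_opticog("need both extreme classes to fit the final pipeline",
                 "opticog_data_error")
  d <- 8
  n_init <- max(2, cfg$n_init)
  design <- with_local_seed(cfg$seed, lhs::maximinLHS(n_init, d))
  units <- lapply(seq_len(nrow(design)), function(i) design[i, ])
  scores <- numeric(0)
  history <- list()
  for (i in seq_along(units)) {
    if (length(scores) >= cfg$budget) break
    p <- unit_to_params(units[[i]], cfg)
    s <- cv_auc_g(x_trainval, ybin, p, cfg$nfold, wrap_seed(cfg$seed + i))
    scores <- c(scores, s)
    history[[length(history) + 1]] <- c(p, cv_auc = s)
  }
  evaluated <- do.call(rbind, lapply(units[seq_along(scores)], rbind))
  while (length(scores) < cfg$budget) {
    i <- length(scores) + 1
    cand <- with_local_seed(derive_seed(cfg$seed, paste0("cand", i)),
                            matrix(stats::runif(500 * d), ncol = d))
    ok <- is.finite(scores)
    if (sum(ok) >= 3 && stats::sd(scores[ok]) > 0) {
      sur_df <- data.frame(.s = scores[ok],
                           evaluated[ok, , drop = FALSE])
      sur <- ranger::ranger(dependent.variable.name = ".s", data = sur_df,
                            num.trees = 200, seed = wrap_seed(cfg$seed + i),
                            num.threads = 1)
      pr <- stats::predict(sur, data.frame(cand), predict.all = TRUE,
                           num.threads = 1)$predictions
      mu <- rowMeans(pr)
      sdv <- apply(pr, 1, stats::sd)
      best <- max(scores[ok])
      z <- (mu - best) / pmax(sdv, 1e-9)
      ei <- (mu - best) * stats::pnorm(z) + pmax(sdv, 1e-9) * stats::dnorm(z)
      pick <- cand[which.max(ei), ]
    } else {
      pick <- cand[1, ]
    }
    p <- unit_to_params(pick, cfg)
    s <- cv_auc_g(x_trainval, ybin, p, cfg$nfold, wrap_seed(cfg$seed + i))
    scores <- c(scores, s)
    evaluated <- rbind(evaluated, pick)
    history[[length(history) + 1]] <- c(p, cv_auc = s)
  }
  if (all(!is.finite(scores)))
    stop_opticog("all hyperparameter evaluations failed", "opticog_pipeline_error")
  best_i <- which.max(scores)
  best_params <- unit_to_params(evaluated[best_i, ], cfg)
  fit <- fit_g_once(x_trainval, ybin, best_params, cfg$seed)
  fit$cv_auc <- scores[best_i]
  fit$history <- do.call(rbind, lapply(history, function(h)
    as.data.frame(h, optional = TRUE)))
  fit$positive <- positive
  fit
}

#' @export
print.final_fit <- function(x, ...) {
  cat(sprintf("final pipeline G: %d features, depth %d, %d rounds, eta %.3f",
              length(x$selected), x$params$max_depth, x$params$nrounds,
              x$params$eta))
  if (!is.null(x$cv_auc)) cat(sprintf(" (CV AUC %.3f)", x$cv_auc))
  cat("\n")
  invisible(x)
}

#' PCA baseline cognitive scoring
#'
#' Extracts the first principal component of the standardized test channels
#' for a training population, orients it so the FI3 loading is non-negative
#' (fluid intelligence correlates positively with cognition), and maps the
#' component scores through the logistic sigmoid into (0, 1).
#'
#' @param tests_std n x 6 matrix of standardized channels
#'   (FI1, FI3, PMM1, PMM3, RT1, RT3).
#' @return List of class `pca_scorer`: `scores` in (0, 1), `loading`
#'   (oriented first-PC loading), `center`, and a `score(newx)` closure.
#' @export
pca_baseline_score <- function(tests_std) {
  if (nrow(tests_std) < 2)
    stop_opticog("need >= 2 participants for the PCA baseline",
                 "opticog_data_error")
  pc <- stats::prcomp(tests_std, center = TRUE, scale. = FALSE)
  if (pc$sdev[1] == 0)
    stop_opticog("degenerate test battery: zero variance",
                 "opticog_degenerate_error")
  loading <- pc$rotation[, 1]
  if (loading[2] < 0) loading <- -loading   # FI3 loading >= 0
  center <- pc$center
  score_fn <- function(newx) {
    stats::plogis(drop(sweep(newx, 2, center) %*% loading))
  }
  structure(list(scores = score_fn(tests_std), loading = loading,
                 center = center, score = score_fn), class = "pca_scorer")
}

#' Single-block and PCA baseline analyses
#'
#' Re-runs the full procedure with a restricted design: `"dmri_only"` and
#' `"demo_only"` keep one feature block and run OptiCS + the final pipeline
#' on it; `"pca"` replaces the optimized scoring function by the PCA
#' baseline scorer (thresholds and labels derived from its training scores)
#' and fits the final pipeline on all features.
#'
#' @param cohort Cohort list (`cognitive` + `features`).
#' @param which One of `"dmri_only"`, `"demo_only"`, `"pca"`.
#' @param split A `split_spec`.
#' @param q Labeling quantile.
#' @param inner_cfg,cans_cfg,final_cfg Stage configurations.
#' @param ddof Standardizer convention.
#' @return List with `test_auc`, `metrics` (on the test extremes), `labels`,
#'   and the stage objects (`optics` or `pca`, `final`).
#' @export
restricted_baseline <- function(cohort, which = c("dmri_only", "demo_only", "pca"),
                                split, q = 0.15, inner_cfg = inner_config(),
                                cans_cfg = cans_config(),
                                final_cfg = final_config(), ddof = 1) {
  which <- match.arg(which)
  if (which %in% c("dmri_only", "demo_only")) {
    block <- if (which == "dmri_only") "dmri" else "demographic"
    sub <- cohort
    sub$features <- subset_features(cohort$features, block = block)
    opt <- run_optics(sub, split, q, inner_cfg, cans_cfg, ddof = ddof)
    ev <- evaluate_final(sub, split, opt$model, final_cfg)
    return(c(ev, list(optics = opt, which = which)))
  }
  # PCA scoring: fixed (not optimized) parameter vector from the loading
  ctx <- loss_context(cohort, split, ddof)
  scorer <- pca_baseline_score(ctx$x_std[ctx$i_train, , drop = FALSE])
  gamma_train <- scorer$scores
  thr <- compute_thresholds(gamma_train, q)
  model <- list(score = function(x_std) scorer$score(x_std),
                lb = thr$lb, ub = thr$ub, q = q, stats = ctx$stats)
  ev <- evaluate_final(cohort, split, model, final_cfg, ctx = ctx)
  c(ev, list(pca = scorer, which = "pca"))
}

#' Label a cohort with a scoring model and fit/evaluate the final pipeline
#'
#' Scores all participants, labels them with the model's frozen thresholds,
#' trains G on the combined train+validation extremes and evaluates on the
#' test extremes.
#'
#' @param cohort Cohort list.
#' @param split A `split_spec`.
#' @param model A `scoring_model`, or any list with `lb`, `ub` and either a
#'   feasible `theta` or a `score(x_std)` function, plus `stats`.
#' @param final_cfg A `final_config`.
#' @param ctx Optional precomputed [make_loss()] context.
#' @return List with `test_auc`, `metrics`, `counts`, `labels` (per set),
#'   `final` (the fitted G), and `n_extreme` per set.
#' @export
evaluate_final <- function(cohort, split, model, final_cfg = final_config(),
                           ctx = NULL) {
  if (is.null(ctx)) {
    ctx <- loss_context(cohort, split)
    ctx$stats <- model$stats
    tt <- transform_tests(cohort$cognitive)
    ctx$x_std <- apply_standardizer(model$stats, tt)
  }
  gamma <- if (!is.null(model$theta)) compute_score(ctx$x_std, model$theta)
  else model$score(ctx$x_std)
  labels <- assign_labels(gamma, model$lb, model$ub)
  i_tv <- c(ctx$i_train, ctx$i_val)
  keep_tv <- labels[i_tv] != "NormalAger"
  keep_te <- labels[ctx$i_test] != "NormalAger"
  y_tv <- labels[i_tv][keep_tv]
  y_te <- labels[ctx$i_test][keep_te]
  fit <- fit_final(ctx$features[i_tv[keep_tv], , drop = FALSE], y_tv, final_cfg)
  p_te <- fit$predict(ctx$features[ctx$i_test[keep_te], , drop = FALSE])
  test_auc <- auc(p_te, y_te == "PositiveAger")
  pred_te <- ifelse(p_te >= 0.5, "PositiveAger", "CognitiveDecliner")
  counts <- confusion_counts(y_te, pred_te)
  list(test_auc = test_auc, metrics = classification_metrics(counts),
       counts = counts, final = fit, gamma = gamma, labels = labels,
       n_extreme = c(trainval = sum(keep_tv), test = sum(keep_te)))
}
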