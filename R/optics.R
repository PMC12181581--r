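# The OptiCS outer loop: score -> threshold -> label -> fit g -> loss,
# wrapped into a loss function over the 7-parameter scoring vector and
# minimized by CANS. Thresholds are re-derived from training scores at every
# parameter evaluation and frozen from the optimum at the end.

#' Build the OptiCS loss function over scoring parameters
#'
#' Given a cohort and a split, returns `L(theta)`: score the training set
#' with `theta`, derive `(lb, ub)` from the training scores at quantile `q`,
#' label train and validation, drop Normal-Agers, fit the inner pipeline g
#' on the training extremes and return `1 - AUC` on the validation extremes.
#' Degenerate labelings (an empty extreme class in train or validation, or a
#' single-class side) return the sentinel loss 1.0 with a warning so the
#' optimizer stays total.
#'
#' @param cohort List with `cognitive` records and a `features`
#'   `feature_table` (see [load_cohort()] / [generate_cohort()]).
#' @param split A `split_spec`.
#' @param q Labeling quantile in (0, 0.5).
#' @param inner_cfg An `inner_config`.
#' @param ddof Standardizer convention passed to [fit_standardizer()].
#' @return Function mapping a feasible 7-vector to a loss in \[0, 1\], with
#'   attribute `"context"` holding the precomputed standardized channels and
#'   index bookkeeping.
#' @export
make_loss <- function(cohort, split, q, inner_cfg = inner_config(), ddof = 1) {
  ctx <- loss_context(cohort, split, ddof)
  fn <- function(theta) {
    ev <- score_label_fit(theta, ctx, q, inner_cfg)
    ev$loss
  }
  attr(fn, "context") <- ctx
  fn
}

# Precompute everything theta-independent: transformed/standardized test
# channels and the row indices of the three sets.
loss_context <- function(cohort, split, ddof = 1) {
  cog <- cohort$cognitive
  idx <- stats::setNames(seq_len(nrow(cog)), cog$participant_id)
  i_train <- unname(idx[split$train])
  i_val <- unname(idx[split$validation])
  i_test <- unname(idx[split$test])
  if (anyNA(c(i_train, i_val, i_test)))
    stop_opticog("split contains ids absent from the cohort",
                 "opticog_config_error")
  tt <- transform_tests(cog)
  st <- fit_standardizer(tt[i_train, , drop = FALSE], ddof = ddof)
  x_std <- apply_standardizer(st, tt)
  list(x_std = x_std, stats = st, features = cohort$features$x,
       meta = cohort$features$meta,
       i_train = i_train, i_val = i_val, i_test = i_test)
}

# One full inner evaluation at a fixed theta. Returns the loss plus the
# labeling and fitted pipeline for reuse by run_optics.
score_label_fit <- function(theta, ctx, q, inner_cfg) {
  gamma_train <- compute_score(ctx$x_std[ctx$i_train, , drop = FALSE], theta)
  thr <- suppressWarnings(compute_thresholds(gamma_train, q))
  if (thr$lb == thr$ub) {
    warning("degenerate scoring: sentinel loss 1.0", call. = FALSE)
    return(list(loss = 1.0, degenerate = TRUE))
  }
  gamma_val <- compute_score(ctx$x_std[ctx$i_val, , drop = FALSE], theta)
  lab_train <- assign_labels(gamma_train, thr$lb, thr$ub)
  lab_val <- assign_labels(gamma_val, thr$lb, thr$ub)
  keep_tr <- lab_train != "NormalAger"
  keep_va <- lab_val != "NormalAger"
  y_tr <- lab_train[keep_tr]; y_va <- lab_val[keep_va]
  if (length(unique(y_tr)) < 2 || min(table(y_tr)) < 2 ||
      length(unique(y_va)) < 2) {
    warning("empty extreme class after labeling: sentinel loss 1.0",
            call. = FALSE)
    return(list(loss = 1.0, degenerate = TRUE))
  }
  x_tr <- ctx$features[ctx$i_train[keep_tr], , drop = FALSE]
  x_va <- ctx$features[ctx$i_val[keep_va], , drop = FALSE]
  fit <- fit_inner(x_tr, y_tr, x_va, y_va, inner_cfg)
  list(loss = 1 - fit$val_auc, degenerate = FALSE, thresholds = thr,
       fit = fit, labels_train = lab_train, labels_val = lab_val,
       gamma_train = gamma_train, gamma_val = gamma_val)
}

#' Run the OptiCS optimization for one quantile
#'
#' Wires [make_loss()] into [cans_optimize()], then freezes the thresholds
#' `(lb, ub)` from the optimal parameter vector's training scores.
#'
#' @inheritParams make_loss
#' @param cans_cfg A `cans_config`.
#' @param theta_init Initial 7-vector (default zeros; projected feasible).
#' @return List of class `optics_result`: `theta_star`, `lb`, `ub`,
#'   `loss_star`, `q`, `trace`, `stats` (the train-fitted standardizer),
#'   `model` (a `scoring_model`), and per-set scores/labels at the optimum.
#' @export
run_optics <- function(cohort, split, q = 0.15, inner_cfg = inner_config(),
                       cans_cfg = cans_config(), theta_init = rep(0, 7),
                       ddof = 1) {
  loss_fn <- make_loss(cohort, split, q, inner_cfg, ddof)
  ctx <- attr(loss_fn, "context")
  res <- suppressWarnings(cans_optimize(loss_fn, theta_init, cans_cfg))
  final <- suppressWarnings(score_label_fit(res$theta_star, ctx, q, inner_cfg))
  if (isTRUE(final$degenerate))
    thr <- list(lb = NA_real_, ub = NA_real_)
  else thr <- final$thresholds
  gamma_test <- compute_score(ctx$x_std[ctx$i_test, , drop = FALSE],
                              res$theta_star)
  out <- list(theta_star = res$theta_star, lb = thr$lb, ub = thr$ub,
              loss_star = res$loss_star, q = q, trace = res$trace,
              stats = ctx$stats, context = ctx, final = final,
              gamma_test = gamma_test,
              model = if (!isTRUE(final$degenerate))
                scoring_model(res$theta_star, ctx$stats, q, thr$lb, thr$ub))
  structure(out, class = "optics_result")
}

#' @export
print.optics_result <- function(x, ...) {
  cat(sprintf("OptiCS result (q = %s): loss* = %.4f\n", format(x$q), x$loss_star))
  cat("  theta*:", paste(sprintf("%.3f", x$theta_star), collapse = ", "), "\n")
  cat(sprintf("  thresholds [lb, ub] = [%.4f, %.4f]\n", x$lb, x$ub))
  invisible(x)
}

#' Sweep the labeling quantile
#'
#' Runs [run_optics()] once per quantile with an independent derived RNG
#' substream per value.
#'
#' @inheritParams run_optics
#' @param q_values Quantiles to sweep (default `c(0.10, 0.15, 0.20, 0.25)`).
#' @return Named list of `optics_result`, one per quantile.
#' @export
optics_sweep <- function(cohort, split, q_values = c(0.10, 0.15, 0.20, 0.25),
                         inner_cfg = inner_config(), cans_cfg = cans_config(),
                         theta_init = rep(0, 7), ddof = 1) {
  res <- lapply(q_values, function(qv) {
    cfg_q <- cans_cfg
    cfg_q$seed <- derive_seed(cans_cfg$seed, paste0("q", qv))
    run_optics(cohort, split, qv, inner_cfg, cfg_q, theta_init, ddof)
  })
  stats::setNames(res, paste0("q", q_values))
}
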