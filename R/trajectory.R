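# Longitudinal trajectory calculus: the linear predictor decomposes as
# theta0 + S1adj + S3adj, where the per-visit adjusted scores weight each
# visit's standardized tests by the optimal visit-specific coefficients.
# Class membership becomes a half-plane rule on S1adj + S3adj, slopes are
# per-year changes in adjusted score, and integrating the robust mean
# slope-vs-age line yields an average trajectory curve per class.

#' Per-visit adjusted scores
#'
#' `S1adj = theta1*FI1s + theta3*PMM1s + theta5*RT1s` and
#' `S3adj = theta2*FI3s + theta4*PMM3s + theta6*RT3s`, so that
#' `theta0 + S1adj + S3adj` equals the full linear predictor exactly.
#'
#' @param x_std Standardized 6-vector or n x 6 matrix
#'   (FI1, FI3, PMM1, PMM3, RT1, RT3).
#' @param theta Feasible 7-vector.
#' @return List with numeric `s1_adj` and `s3_adj`.
#' @export
adjusted_scores <- function(x_std, theta) {
  if (is.null(dim(x_std))) x_std <- matrix(x_std, nrow = 1)
  stopifnot(ncol(x_std) == 6, length(theta) == 7)
  list(s1_adj = drop(x_std[, c(1, 3, 5), drop = FALSE] %*% theta[c(2, 4, 6)]),
       s3_adj = drop(x_std[, c(2, 4, 6), drop = FALSE] %*% theta[c(3, 5, 7)]))
}

#' Class boundary constant in adjusted-score space
#'
#' Applying the logit to the labeling rule `gamma <= lb` (or `>= ub`) turns
#' it into a half-plane rule on the sum of adjusted scores:
#' `S1adj + S3adj <= c(lb)` for Cognitive Decliners and `>= c(ub)` for
#' Positive-Agers, with `c(bound) = -theta0 + log(bound / (1 - bound))`.
#' For the published model (`theta0 = -0.622`, bounds 0.004/0.986) the
#' constants are -4.9 and 4.9 at one decimal.
#'
#' @param theta0 Bias term of the scoring function.
#' @param bound Threshold in (0, 1).
#' @return The boundary constant (full precision; round for display).
#' @export
#' @examples
#' round(class_boundary_constant(-0.622, 0.004), 1)  # -4.9
#' round(class_boundary_constant(-0.622, 0.986), 1)  #  4.9
class_boundary_constant <- function(theta0, bound) {
  if (!(bound > 0 && bound < 1))
    stop_opticog("bound must lie in (0, 1)", "opticog_domain_error")
  -theta0 + log(bound / (1 - bound))
}

#' Adjusted trajectory slope
#'
#' Per-year rate of change `(S3adj - S1adj) / delta_t`.
#'
#' @param s1_adj,s3_adj Adjusted scores at the two visits.
#' @param delta_t Inter-visit interval in years (> 0).
#' @return Slope per year.
#' @export
adjusted_slope <- function(s1_adj, s3_adj, delta_t) {
  if (any(delta_t <= 0))
    stop_opticog("delta_t must be > 0", "opticog_domain_error")
  (s3_adj - s1_adj) / delta_t
}

#' Build per-participant trajectory records
#'
#' @param x_std n x 6 matrix of standardized channels.
#' @param theta Feasible 7-vector.
#' @param lb,ub Labeling thresholds on the score scale.
#' @param delta_t Inter-visit interval(s) in years (default 8).
#' @param age Optional baseline ages (carried through).
#' @return data.frame: `s1_adj`, `s3_adj`, `delta_t`, `alpha_adj`, `gamma`,
#'   `cls`, and `age` when supplied.
#' @export
trajectory_records <- function(x_std, theta, lb, ub, delta_t = 8, age = NULL) {
  adj <- adjusted_scores(x_std, theta)
  gamma <- compute_score(x_std, theta)
  out <- data.frame(s1_adj = adj$s1_adj, s3_adj = adj$s3_adj,
                    delta_t = delta_t,
                    alpha_adj = adjusted_slope(adj$s1_adj, adj$s3_adj, delta_t),
                    gamma = gamma, cls = assign_labels(gamma, lb, ub))
  if (!is.null(age)) out$age <- age
  out
}

#' Robust slope-versus-age line
#'
#' Robust (M-estimation, Huber weights) straight-line fit of mean adjusted
#' slope against baseline age, downweighting outlier age points.
#'
#' @param age Numeric ages (>= 3 points).
#' @param mean_alpha Mean adjusted slope at each age.
#' @return List with gradient `m` (per year^2) and intercept `b` (per year).
#' @export
fit_slope_age_line <- function(age, mean_alpha) {
  if (length(age) < 3)
    stop_opticog("need >= 3 age points", "opticog_data_error")
  fit <- MASS::rlm(mean_alpha ~ age, maxit = 100)
  cf <- stats::coef(fit)
  list(m = unname(cf["age"]), b = unname(cf["(Intercept)"]))
}

#' Integrate the slope line into an average trajectory curve
#'
#' The mean slope line `alpha(t) = m t + b` is the derivative of the average
#' cognitive trajectory; integrating gives
#' `C(t) = m t^2 / 2 + b t + u`, with the constant `u` solved so the curve
#' passes through the anchoring mean adjusted score at the baseline age
#' `t0` (55 years by default).
#'
#' @param m,b Slope-line gradient and intercept.
#' @param anchor_value Mean `S1adj` at `t0`.
#' @param t0 Anchor age in years (default 55).
#' @return List of class `trajectory_curve`: `m`, `b`, `u`, `t0`, and
#'   `curve(t)` / `derivative(t)` closures.
#' @export
integrate_trajectory_curve <- function(m, b, anchor_value, t0 = 55) {
  u <- anchor_value - (m * t0^2 / 2 + b * t0)
  curve <- function(t) m * t^2 / 2 + b * t + u
  structure(list(m = m, b = b, u = u, t0 = t0, curve = curve,
                 derivative = function(t) m * t + b),
            class = "trajectory_curve")
}

# Weighted Gini impurity of a hard partition defined by `groups`.
gini_impurity <- function(labels, groups) {
  n <- length(labels)
  sum(vapply(split(labels, groups), function(g) {
    p <- table(g) / length(g)
    length(g) / n * (1 - sum(p^2))
  }, numeric(1)))
}

#' One-dimensional Gini split points
#'
#' Greedy search for up to `max_splits` thresholds on a single variable
#' minimizing weighted Gini impurity of the induced partition. Candidate
#' thresholds are midpoints between consecutive sorted unique values; ties
#' break toward the smaller threshold; splitting stops when no candidate
#' strictly reduces the impurity.
#'
#' @param values Numeric values (e.g. baseline adjusted scores).
#' @param cls Class labels (2 or 3 classes).
#' @param max_splits Maximum number of thresholds (default 2, a 3-way
#'   partition).
#' @return Sorted numeric thresholds (possibly empty).
#' @export
#' @examples
#' gini_split_points(c(1, 2, 3, 10, 11, 12),
#'                   rep(c("D", "P"), each = 3))  # 6.5
gini_split_points <- function(values, cls, max_splits = 2) {
  cls <- as.character(cls)
  if (length(unique(cls)) < 2) return(numeric(0))
  uv <- sort(unique(values))
  if (length(uv) < 2) return(numeric(0))
  candidates <- (uv[-1] + uv[-length(uv)]) / 2
  thresholds <- numeric(0)
  current <- gini_impurity(cls, rep(1L, length(values)))
  for (s in seq_len(max_splits)) {
    pool <- setdiff(candidates, thresholds)
    if (!length(pool)) break
    imp <- vapply(pool, function(th) {
      grp <- findInterval(values, sort(c(thresholds, th)))
      gini_impurity(cls, grp)
    }, numeric(1))
    best <- min(imp)
    if (best >= current - 1e-12) break
    thresholds <- c(thresholds, pool[which(imp == best)[1]])
    current <- best
  }
  sort(thresholds)
}

#' Expected-slope grid over age and baseline adjusted score
#'
#' Cell `(t, s)` holds the mean adjusted slope over participants of integer
#' age `t` whose `S1adj` lies within `window` of `s`; cells matching fewer
#' than `min_n` participants are `NA`.
#'
#' @param records data.frame from [trajectory_records()] including `age`.
#' @param ages Integer grid of ages (default 55:70).
#' @param s_grid Grid of baseline adjusted scores (default range of
#'   `s1_adj` in steps of 0.25).
#' @param window Half-width of the score window (default 0.25).
#' @param min_n Minimum participants per cell (default 10).
#' @return Matrix (ages x s_grid) of mean slopes with `NA` for sparse cells.
#' @export
expected_slope_grid <- function(records, ages = 55:70, s_grid = NULL,
                                window = 0.25, min_n = 10) {
  if (is.null(s_grid)) {
    r <- range(records$s1_adj)
    s_grid <- seq(floor(r[1] / 0.25) * 0.25, ceiling(r[2] / 0.25) * 0.25,
                  by = 0.25)
  }
  out <- matrix(NA_real_, length(ages), length(s_grid),
                dimnames = list(ages, format(s_grid)))
  age_int <- round(records$age)
  for (i in seq_along(ages)) {
    in_age <- age_int == ages[i]
    for (j in seq_along(s_grid)) {
      sel <- in_age & abs(records$s1_adj - s_grid[j]) <= window
      if (sum(sel) >= min_n) out[i, j] <- mean(records$alpha_adj[sel])
    }
  }
  out
}

#' First-visit three-class decision tree
#'
#' Depth-limited classification tree predicting the cognitive class from
#' first-visit information only (demographics plus FI1/PMM1/RT1).
#'
#' @param x data.frame or matrix of first-visit features.
#' @param cls Class labels (all three classes must be present).
#' @param max_depth Tree depth (default 4).
#' @return List of class `first_visit_model`: the `rpart` `tree`, training
#'   `confusion` matrix, training `accuracy`, and a `predict(newx)` closure.
#' @export
first_visit_classifier <- function(x, cls, max_depth = 4) {
  cls <- factor(cls)
  if (nlevels(cls) < 3)
    stop_opticog("all three cognitive classes must be present",
                 "opticog_data_error")
  df <- data.frame(.cls = cls, as.data.frame(x), check.names = FALSE)
  tree <- rpart::rpart(.cls ~ ., data = df, method = "class",
                       control = rpart::rpart.control(maxdepth = max_depth,
                                                      cp = 0, xval = 0))
  pred <- predict(tree, df, type = "class")
  confusion <- table(truth = cls, predicted = pred)
  structure(list(tree = tree, confusion = confusion,
                 accuracy = mean(pred == cls),
                 predict = function(newx)
                   predict(tree, as.data.frame(newx), type = "class")),
            class = "first_visit_model")
}

#' @export
print.first_visit_model <- function(x, ...) {
  cat(sprintf("first-visit classifier: training accuracy %.3f\n", x$accuracy))
  print(x$confusion)
  invisible(x)
}
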