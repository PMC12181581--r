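# Channel order used everywhere: FI1, FI3, PMM1, PMM3, RT1, RT3.
CHANNELS <- c("fi1", "fi3", "pmm1", "pmm3", "rt1", "rt3")

#' Project a parameter vector onto the feasible sign domain
#'
#' The scoring parameter vector is `theta = (theta0, theta1, ..., theta6)`:
#' bias, then weights for FI1, FI3, PMM1, PMM3, RT1, RT3. Fluid intelligence
#' is positively related to cognition while pairs-matching errors and
#' reaction time are negatively related, so the feasible domain keeps the
#' bias free, forces the two FI weights non-negative and the four PMM/RT
#' weights non-positive. The projection maps each weight to the signed
#' absolute value and is idempotent.
#'
#' @param theta Numeric 7-vector.
#' @return Feasible numeric 7-vector.
#' @export
#' @examples
#' project_feasible(c(1, -2, 3, 4, -5, 6, -7))
project_feasible <- function(theta) {
  stopifnot(is.numeric(theta), length(theta) == 7)
  c(theta[1], abs(theta[2:3]), -abs(theta[4:7]))
}

is_feasible <- function(theta) {
  length(theta) == 7 && all(theta[2:3] >= 0) && all(theta[4:7] <= 0)
}

#' Logistic cognitive score
#'
#' `gamma = 1 / (1 + exp(-(theta0 + sum(theta[i] * x[i]))))`, evaluated on
#' standardized test channels in the order FI1, FI3, PMM1, PMM3, RT1, RT3.
#'
#' @param x_std Numeric 6-vector, or an n x 6 matrix of standardized channels.
#' @param theta Feasible numeric 7-vector (see [project_feasible()]).
#' @return Score(s) strictly inside (0, 1).
#' @export
compute_score <- function(x_std, theta) {
  stopifnot(is.numeric(theta), length(theta) == 7)
  if (is.null(dim(x_std))) x_std <- matrix(x_std, nrow = 1)
  if (ncol(x_std) != 6)
    stop_opticog("x_std must have 6 channels (FI1, FI3, PMM1, PMM3, RT1, RT3)",
                 "opticog_domain_error")
  if (!all(is.finite(x_std)) || !all(is.finite(theta)))
    stop_opticog("non-finite input to compute_score", "opticog_domain_error")
  eta <- theta[1] + drop(x_std %*% theta[2:7])
  stats::plogis(eta)
}

#' Quantile thresholds on training scores
#'
#' Lower and upper labeling bounds `lb = Q_q(scores)` and
#' `ub = Q_(1-q)(scores)` using linear-interpolation (type 7) quantiles.
#'
#' @param train_scores Numeric vector of training cognitive scores (>= 2).
#' @param q Quantile in (0, 0.5\]; the study sweeps 0.10, 0.15, 0.20, 0.25.
#'   The degenerate `q = 0.5` collapses both bounds onto the median (with a
#'   warning).
#' @return List with `lb` and `ub`, `lb <= ub`.
#' @export
compute_thresholds <- function(train_scores, q) {
  if (length(train_scores) < 2)
    stop_opticog("need >= 2 scores to compute thresholds", "opticog_data_error")
  if (!(q > 0 && q <= 0.5))
    stop_opticog("q must lie in (0, 0.5]", "opticog_config_error")
  lb <- q_linear(train_scores, q)
  ub <- q_linear(train_scores, 1 - q)
  if (lb == ub)
    warning("degenerate thresholds: lb == ub", call. = FALSE)
  list(lb = lb, ub = ub)
}

#' Assign three-class cognitive labels
#'
#' `gamma <= lb` is a `"CognitiveDecliner"`, `gamma >= ub` a
#' `"PositiveAger"`, anything strictly between a `"NormalAger"`. Both
#' boundary comparisons are inclusive; on the degenerate tie `lb == ub` the
#' Decliner branch wins.
#'
#' @param gamma Numeric score(s) in \[0, 1\].
#' @param lb,ub Thresholds with `0 <= lb <= ub <= 1`.
#' @return Character vector of class labels.
#' @export
assign_labels <- function(gamma, lb, ub) {
  if (lb > ub) stop_opticog("lb must be <= ub", "opticog_config_error")
  ifelse(gamma <= lb, "CognitiveDecliner",
         ifelse(gamma >= ub, "PositiveAger", "NormalAger"))
}

#' Construct a scoring model
#'
#' Bundles everything needed to score and label a new participant: the
#' feasible parameter vector, the per-channel standardization statistics, the
#' labeling quantile and the frozen thresholds.
#'
#' @param theta Feasible 7-vector.
#' @param stats A `standardization_stats` object (see [fit_standardizer()]).
#' @param q Labeling quantile in (0, 0.5).
#' @param lb,ub Frozen thresholds in \[0, 1\], `lb <= ub`.
#' @return Object of class `scoring_model`.
#' @export
scoring_model <- function(theta, stats, q, lb, ub) {
  if (!is_feasible(theta))
    stop_opticog("theta is not feasible", "opticog_config_error")
  if (!(lb >= 0 && lb <= ub && ub <= 1))
    stop_opticog("need 0 <= lb <= ub <= 1", "opticog_config_error")
  structure(list(theta = theta, stats = stats, q = q, lb = lb, ub = ub),
            class = "scoring_model")
}

#' @export
print.scoring_model <- function(x, ...) {
  cat("Cognitive scoring model\n")
  cat("  theta:", paste(sprintf("%.3f", x$theta), collapse = ", "), "\n")
  cat(sprintf("  q = %s, thresholds [lb, ub] = [%.3f, %.3f]\n",
              format(x$q), x$lb, x$ub))
  invisible(x)
}

#' The published optimal scoring model
#'
#' The frozen optimal model reported for the UK Biobank cohort: weights
#' `(-0.622, 1.764, 2.198, -0.349, -1.371, -0.633, -1.191)`, channel means
#' `(6.86, 6.79, 1.40, 1.41, 6.32, 6.40)` and standard deviations
#' `(1.98, 2.03, 0.62, 0.61, 0.18, 0.17)` (PMM/RT on the log scale), with
#' labeling bounds `lb = 0.004` and `ub = 0.986` at `q = 0.15`.
#'
#' @return A `scoring_model`.
#' @export
#' @examples
#' m <- published_model()
#' score_participant(m, fi1 = 9, fi3 = 10, pmm1 = 2, pmm3 = 1,
#'                   rt1 = 500, rt3 = 520)
published_model <- function() {
  stats <- structure(list(
    mean = stats::setNames(c(6.86, 6.79, 1.40, 1.41, 6.32, 6.40), CHANNELS),
    sd   = stats::setNames(c(1.98, 2.03, 0.62, 0.61, 0.18, 0.17), CHANNELS),
    ddof = NA_integer_),
    class = "standardization_stats")
  scoring_model(theta = c(-0.622, 1.764, 2.198, -0.349, -1.371, -0.633, -1.191),
                stats = stats, q = 0.15, lb = 0.004, ub = 0.986)
}

#' Score and label a participant from raw test values
#'
#' Applies the model's log transforms (PMM: `log(x + 1)`, RT: `log(x)`),
#' standardization and logistic scoring to raw test values, then labels with
#' the model's frozen thresholds.
#'
#' @param model A `scoring_model`.
#' @param fi1,fi3 Fluid intelligence correct-answer counts (0-13).
#' @param pmm1,pmm3 Pairs-matching error counts (raw, untransformed).
#' @param rt1,rt3 Mean reaction times in milliseconds (raw).
#' @return List with `gamma`, `label`, and the standardized channels `x_std`.
#' @export
score_participant <- function(model, fi1, fi3, pmm1, pmm3, rt1, rt3) {
  rec <- data.frame(fi1 = fi1, fi3 = fi3, pmm1 = pmm1, pmm3 = pmm3,
                    rt1 = rt1, rt3 = rt3)
  tt <- transform_tests(rec)
  x_std <- apply_standardizer(model$stats, tt)
  gamma <- compute_score(x_std, model$theta)
  list(gamma = gamma, label = assign_labels(gamma, model$lb, model$ub),
       x_std = x_std)
}
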