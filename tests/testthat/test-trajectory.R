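# Trajectory calculus: adjusted scores, boundaries, slopes, curves, splits.

test_that("adjusted scores decompose the linear predictor exactly", {
  th <- published_model()$theta
  adj <- adjusted_scores(c(1, 0, 0, 0, 0, 0), th)
  expect_equal(adj$s1_adj, 1.764)
  expect_equal(adj$s3_adj, 0)
  z <- adjusted_scores(rep(0, 6), th)
  expect_equal(c(z$s1_adj, z$s3_adj), c(0, 0))

  withr::with_seed(50, {
    for (i in 1:30) {
      x <- rnorm(6); t2 <- project_feasible(rnorm(7))
      a <- adjusted_scores(x, t2)
      expect_equal(t2[1] + a$s1_adj + a$s3_adj,
                   t2[1] + sum(t2[2:7] * x), tolerance = 1e-12)
    }
  })
})

test_that("boundary constants reproduce the published -4.9 / 4.9 rules", {
  expect_equal(round(class_boundary_constant(-0.622, 0.004), 1), -4.9)
  expect_equal(round(class_boundary_constant(-0.622, 0.986), 1), 4.9)
  expect_equal(class_boundary_constant(0, 0.5), 0)
  expect_error(class_boundary_constant(0, 1), class = "opticog_domain_error")
})

test_that("gamma-space labels equal the adjusted-score boundary rules", {
  withr::with_seed(51, {
    th <- project_feasible(rnorm(7))
    x <- matrix(rnorm(200 * 6), 200, 6)
    lb <- 0.1; ub <- 0.8
    gamma <- compute_score(x, th)
    lab <- assign_labels(gamma, lb, ub)
    adj <- adjusted_scores(x, th)
    s <- adj$s1_adj + adj$s3_adj
    lab2 <- ifelse(s <= class_boundary_constant(th[1], lb), "CognitiveDecliner",
                   ifelse(s >= class_boundary_constant(th[1], ub),
                          "PositiveAger", "NormalAger"))
    expect_identical(lab, lab2)
  })
})

test_that("adjusted slope is the per-year difference", {
  expect_equal(adjusted_slope(0, 4.9, 7), 0.7)
  expect_equal(adjusted_slope(1.3, 1.3, 5), 0)
  expect_equal(adjusted_slope(0, 2, 4), adjusted_slope(0, 2, 8) * 2)
  expect_error(adjusted_slope(0, 1, 0), class = "opticog_domain_error")
})

test_that("robust slope-age line resists a gross outlier", {
  age <- 55:70
  clean <- 0.02 * age - 1.5
  fit <- fit_slope_age_line(age, clean)
  expect_equal(fit$m, 0.02, tolerance = 1e-9)
  expect_equal(fit$b, -1.5, tolerance = 1e-9)

  dirty <- clean; dirty[8] <- dirty[8] + 10
  rob <- fit_slope_age_line(age, dirty)
  expect_lt(abs(rob$m - 0.02), 0.05)
  ols <- stats::lm(dirty ~ age)
  expect_gt(abs(coef(ols)["age"] - 0.02), abs(rob$m - 0.02))

  flat <- fit_slope_age_line(age, rep(0.3, 16))
  expect_equal(flat$m, 0, tolerance = 1e-12)
  expect_error(fit_slope_age_line(55:56, c(0, 1)), class = "opticog_data_error")
})

test_that("trajectory curve integrates the slope line and anchors correctly", {
  cv <- integrate_trajectory_curve(0, 0, anchor_value = 2, t0 = 55)
  expect_equal(cv$curve(70), 2)

  cv2 <- integrate_trajectory_curve(-0.01, 0.5, anchor_value = 2, t0 = 55)
  expect_equal(cv2$curve(65), 1.0)            # closed-form integral
  expect_equal(cv2$curve(55), 2)

  withr::with_seed(52, {
    for (t in runif(5, 50, 80)) {
      num <- (cv2$curve(t + 1e-6) - cv2$curve(t - 1e-6)) / 2e-6
      expect_equal(num, cv2$derivative(t), tolerance = 1e-6)
    }
  })
})

# Oracle: exhaustive search over all single thresholds.
best_single_split <- function(values, cls) {
  uv <- sort(unique(values))
  cand <- (uv[-1] + uv[-length(uv)]) / 2
  imp <- vapply(cand, function(th)
    opticog:::gini_impurity(cls, values > th), numeric(1))
  cand[which.min(imp)]
}

test_that("Gini split points match brute force and are rank-invariant", {
  v <- c(1, 2, 3, 10, 11, 12)
  cls <- rep(c("D", "P"), each = 3)
  expect_equal(gini_split_points(v, cls), 6.5)
  expect_equal(gini_split_points(v, cls)[1], best_single_split(v, cls))

  expect_length(gini_split_points(v, rep("D", 6)), 0)

  # three classes: two splits recovered
  v3 <- c(1, 2, 3, 5, 6, 7, 10, 11, 12)
  c3 <- rep(c("D", "N", "P"), each = 3)
  expect_equal(gini_split_points(v3, c3), c(4, 8.5))

  # monotone transform preserves the partition
  sp_raw <- gini_split_points(v3, c3)
  sp_tr <- gini_split_points(exp(v3 / 4), c3)
  expect_identical(findInterval(v3, sp_raw),
                   findInterval(exp(v3 / 4), sp_tr))

  withr::with_seed(53, {   # random instances vs single-split oracle
    for (i in 1:10) {
      vv <- sample(seq(0, 5, 0.5), 20, TRUE)
      cc <- sample(c("D", "P"), 20, TRUE)
      if (length(unique(cc)) < 2 || length(unique(vv)) < 2) next
      sp <- gini_split_points(vv, cc, max_splits = 1)
      if (length(sp))
        expect_equal(opticog:::gini_impurity(cc, vv > sp),
                     opticog:::gini_impurity(cc, vv > best_single_split(vv, cc)))
    }
  })
})

test_that("expected-slope grid enforces the window and minimum-count rules", {
  rec <- data.frame(age = rep(60, 12),
                    s1_adj = c(rep(0, 10), 3, 3),
                    alpha_adj = c(rep(0.1, 10), 9, 9))
  g <- expected_slope_grid(rec, ages = 60, s_grid = c(0, 3), min_n = 10)
  expect_equal(g["60", format(0)], c(`60` = 0.1), ignore_attr = TRUE)
  expect_true(is.na(g["60", format(3)]))      # only 2 participants there

  rec9 <- rec[1:9, ]
  g9 <- expected_slope_grid(rec9, ages = 60, s_grid = 0, min_n = 10)
  expect_true(is.na(g9["60", format(0)]))     # 9 < 10 -> missing

  recc <- data.frame(age = rep(c(58, 62), each = 10),
                     s1_adj = rep(0, 20), alpha_adj = rep(0.3, 20))
  gc <- expected_slope_grid(recc, ages = c(58, 62), s_grid = 0, min_n = 10)
  expect_true(all(gc == 0.3))
})

test_that("first-visit tree learns a deterministic class rule", {
  withr::with_seed(54, {
    s1 <- runif(600, -6, 6)
    cls <- ifelse(s1 < -2, "CognitiveDecliner",
                  ifelse(s1 > 2, "PositiveAger", "NormalAger"))
    x <- data.frame(fi1 = s1 + rnorm(600, 0, 0.1), age = sample(55:70, 600, TRUE))
    fit <- first_visit_classifier(x, cls)
    expect_gt(fit$accuracy, 0.95)
    cm <- fit$confusion
    expect_equal(cm["CognitiveDecliner", "PositiveAger"], 0)
    expect_equal(cm["PositiveAger", "CognitiveDecliner"], 0)
  })
  expect_error(first_visit_classifier(data.frame(a = 1:4),
                                      c("A", "B", "A", "B")),
               class = "opticog_data_error")
})
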