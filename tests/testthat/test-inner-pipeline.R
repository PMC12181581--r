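# Inner pipeline g: impurity selection, L1 logistic, validation loss.

make_xy <- function(n = 200, p = 6, seed = 2, informative = TRUE) {
  withr::with_seed(seed, {
    y <- rep(c("CognitiveDecliner", "PositiveAger"), length.out = n)
    x <- matrix(rnorm(n * p), n, p)
    if (informative) x[, 1] <- as.numeric(y == "PositiveAger")
    colnames(x) <- paste0("f", seq_len(p))
    list(x = x, y = y)
  })
}

test_that("impurity selection ranks a perfectly separating feature first", {
  d <- make_xy()
  sel <- select_features_impurity(d$x, d$y, inner_config(f_keep = 2, m_fs = 5))
  expect_equal(sel[1], "f1")
  expect_length(sel, 2)

  all_sel <- select_features_impurity(d$x, d$y, inner_config(f_keep = 99))
  expect_setequal(all_sel, colnames(d$x))

  s1 <- select_features_impurity(d$x, d$y, inner_config(f_keep = 3, seed = 4))
  s2 <- select_features_impurity(d$x, d$y, inner_config(f_keep = 3, seed = 4))
  expect_identical(s1, s2)

  expect_error(select_features_impurity(d$x, rep("A", nrow(d$x)),
                                        inner_config()),
               class = "opticog_data_error")
})

test_that("fit_inner separates two Gaussian blobs and shrinks under strong L1", {
  d <- two_blobs(n = 200, seed = 5)
  v <- two_blobs(n = 100, seed = 6)
  fit <- fit_inner(d$x, d$y, v$x, v$y, inner_config(f_keep = 10, m_fs = 5))
  expect_gt(auc(fit$predict(d$x), d$y == "PositiveAger"), 0.99)
  expect_gt(fit$val_auc, 0.95)

  # the strongest penalty in the default grid zeroes coefficients
  strong <- as.matrix(glmnet::coef.glmnet(fit$glmnet_fit,
                                          s = max(fit$glmnet_fit$lambda)))
  expect_true(any(strong[-1, ] == 0))
})

test_that("all-noise features give chance-level validation AUC", {
  d <- make_xy(n = 300, seed = 8, informative = FALSE)
  v <- make_xy(n = 200, seed = 9, informative = FALSE)
  fit <- fit_inner(d$x, d$y, v$x, v$y, inner_config(f_keep = 6, m_fs = 5))
  expect_lt(abs(fit$val_auc - 0.5), 0.1)
})

test_that("evaluate_loss is 1 - AUC, bounded, and rank-invariant", {
  fake <- structure(list(predict = function(newx) newx[, 1],
                         positive = "PositiveAger"), class = "inner_fit")
  x <- matrix(c(0.9, 0.8, 0.2, 0.1), ncol = 1)
  y_perfect <- c("PositiveAger", "PositiveAger", "CognitiveDecliner",
                 "CognitiveDecliner")
  expect_equal(evaluate_loss(fake, x, y_perfect), 0)
  expect_equal(evaluate_loss(fake, x, rev(y_perfect)), 1)

  withr::with_seed(10, {
    s <- runif(100)
    y <- sample(c("PositiveAger", "CognitiveDecliner"), 100, TRUE)
    l1 <- evaluate_loss(fake, matrix(s, ncol = 1), y)
    l2 <- evaluate_loss(fake, matrix(qlogis(s / 1.001 + 1e-4), ncol = 1), y)
    expect_equal(l1, l2)                       # monotone transform
    expect_true(l1 >= 0 && l1 <= 1)
  })
  expect_error(evaluate_loss(fake, x, rep("PositiveAger", 4)),
               class = "opticog_data_error")
})

test_that("null scores on a balanced set give loss near one half", {
  fake <- structure(list(predict = function(newx) newx[, 1],
                         positive = "PositiveAger"), class = "inner_fit")
  withr::with_seed(12, {
    s <- matrix(runif(500), ncol = 1)
    y <- rep(c("PositiveAger", "CognitiveDecliner"), 250)
    expect_lt(abs(evaluate_loss(fake, s, y) - 0.5), 0.07)
  })
})

test_that("duplicating a feature barely changes the loss", {
  d <- two_blobs(n = 200, seed = 14)
  v <- two_blobs(n = 100, seed = 15)
  f0 <- fit_inner(d$x, d$y, v$x, v$y, inner_config(f_keep = 20, m_fs = 5))
  x2 <- cbind(d$x, dup = d$x[, 1]); colnames(x2)[ncol(x2)] <- "f1_dup"
  v2 <- cbind(v$x, dup = v$x[, 1]); colnames(v2)[ncol(v2)] <- "f1_dup"
  f1 <- fit_inner(x2, d$y, v2, v$y, inner_config(f_keep = 20, m_fs = 5))
  expect_lt(abs(f1$val_auc - f0$val_auc), 0.05)
})

test_that("planted-signal cohorts yield low end-to-end loss", {
  co <- small_cohort(n = 600, seed = 20)
  loss_fn <- make_loss(co$sim, co$split, 0.15, quick_inner())
  l <- loss_fn(published_model()$theta)
  expect_lt(l, 0.2)
})
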