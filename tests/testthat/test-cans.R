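# The constrained adaptive-noise-scaling optimizer.

test_that("candidate perturbation: cardinality, zero-noise, feasibility, LLN", {
  th <- c(0.5, 1, 1, -1, -1, -1, -1)
  withr::with_seed(1, {
    cand <- perturb_candidates(th, 0, 3)
    expect_equal(dim(cand), c(3, 7))
    expect_true(all(apply(cand, 1, function(r) identical(r, th))))

    cand2 <- perturb_candidates(th, 0.5, 50)
    expect_true(all(apply(cand2, 1,
                          function(r) all(r[2:3] >= 0) && all(r[4:7] <= 0))))

    # unconstrained bias coordinate: sample mean near theta0 (CLT bound)
    big <- perturb_candidates(th, 1, 20000)
    expect_lt(abs(mean(big[, 1]) - th[1]), 3 * 1 / sqrt(20000))
  })
  expect_error(perturb_candidates(th, 0.1, 0), class = "opticog_config_error")
})

test_that("noise scale contracts on improvement and expands capped", {
  cfg <- cans_config(delta_l = 0.5, delta_u = 2, sigma_max = 1.5, sigma0 = 1)
  expect_equal(update_noise_scale(1, TRUE, cfg), 0.5)
  expect_equal(update_noise_scale(1, FALSE, cfg), 1.5)
  expect_equal(update_noise_scale(1.5, FALSE, cfg), 1.5)
})

test_that("CANS converges on a 1-D quadratic to within 0.1", {
  loss <- function(th) (th[1] - 3)^2 + sum(th[2:7]^2)
  res <- cans_optimize(loss, rep(0, 7),
                       cans_config(nc = 20, j_max = 200, delta_l = 0.9,
                                   delta_u = 1.1, sigma_max = 1, sigma0 = 0.5,
                                   seed = 7))
  expect_lt(abs(res$theta_star[1] - 3), 0.1)
})

test_that("constant loss leaves the projected initial point unchanged", {
  init <- c(1, -2, 3, 4, -5, 6, -7)
  res <- cans_optimize(function(th) 42, init, cans_config(nc = 3, j_max = 20))
  expect_equal(res$theta_star, project_feasible(init))
  expect_equal(res$loss_star, 42)
})

test_that("trace invariants: monotone best loss, sigma cap, feasibility", {
  loss <- function(th) sum((th - c(0, 1, 1, -1, -1, -1, -1))^2)
  cfg <- cans_config(nc = 5, j_max = 60, sigma_max = 0.8, sigma0 = 0.5,
                     seed = 3)
  res <- cans_optimize(loss, rnorm(7), cfg)
  expect_true(all(diff(res$trace$best_loss) <= 0))
  expect_true(all(res$trace$sigma <= cfg$sigma_max + 1e-12))
  th_cols <- as.matrix(res$trace[, paste0("theta", 0:6)])
  expect_true(all(th_cols[, 2:3] >= 0))
  expect_true(all(th_cols[, 4:7] <= 0))
})

test_that("identical config and seed reproduce the trace exactly", {
  loss <- function(th) sum(th^2) + th[1]
  cfg <- cans_config(nc = 4, j_max = 30, seed = 99)
  r1 <- cans_optimize(loss, rep(0.5, 7), cfg)
  r2 <- cans_optimize(loss, rep(0.5, 7), cfg)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$theta_star, r2$theta_star)
})

test_that("CANS matches a dense grid oracle on a 1-D unimodal loss", {
  f1 <- function(t) -exp(-(t - 1.3)^2) + 0.1 * abs(t - 1.3)
  loss <- function(th) f1(th[1])          # only the free bias coordinate
  grid_best <- min(vapply(seq(-5, 5, length.out = 1000), f1, numeric(1)))
  res <- cans_optimize(loss, rep(0, 7), cans_config(seed = 17))
  expect_lte(res$loss_star, grid_best + 1e-2)
})

test_that("non-finite losses abort with a diagnostic error", {
  expect_error(cans_optimize(function(th) NaN, rep(0, 7),
                             cans_config(nc = 2, j_max = 5)),
               class = "opticog_loss_error")
  bomb <- function(th) if (abs(th[1]) > 0.01) Inf else 0
  expect_error(cans_optimize(bomb, rep(0, 7), cans_config(nc = 5, j_max = 50)),
               class = "opticog_loss_error")
})

test_that("config invariants are enforced", {
  expect_error(cans_config(nc = 0), class = "opticog_config_error")
  expect_error(cans_config(delta_u = 0.9), class = "opticog_config_error")
  expect_error(cans_config(delta_l = 1.2), class = "opticog_config_error")
  expect_error(cans_config(sigma0 = 2, sigma_max = 1),
               class = "opticog_config_error")
})
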