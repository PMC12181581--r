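# Synthetic cohort generator and fixture writer.

test_that("generation is deterministic and complete", {
  s1 <- generate_cohort(synthetic_spec(n = 100, seed = 1, n_dmri = 20))
  s2 <- generate_cohort(synthetic_spec(n = 100, seed = 1, n_dmri = 20))
  expect_identical(s1$cognitive, s2$cognitive)
  expect_identical(s1$features$x, s2$features$x)
  expect_equal(nrow(s1$cognitive), 100)
  expect_false(anyNA(s1$features$x))
  s3 <- generate_cohort(synthetic_spec(n = 100, seed = 2, n_dmri = 20))
  expect_false(identical(s1$cognitive, s3$cognitive))
})

test_that("raw test marginals anchor to the published channel statistics", {
  sim <- generate_cohort(synthetic_spec(n = 4000, seed = 3))
  expect_lt(abs(mean(sim$cognitive$fi1) - 6.86), 3 * 1.98 / sqrt(4000))
  expect_lt(abs(mean(log(sim$cognitive$rt3)) - 6.40), 3 * 0.17 / sqrt(4000))
  expect_true(all(sim$cognitive$fi1 >= 0 & sim$cognitive$fi1 <= 13))
  expect_true(all(sim$cognitive$pmm1 >= 0))
  expect_true(all(sim$cognitive$rt1 > 0))
  expect_true(all(sim$truth$age >= 55 & sim$truth$age <= 70))
})

test_that("the noiseless limit makes the true score follow the latent trait", {
  low <- generate_cohort(synthetic_spec(n = 500, seed = 4,
                                        test_noise_sd = 1e-3))
  expect_gt(cor(low$truth$gamma_true, low$truth$z, method = "spearman"), 0.999)
  noisy <- generate_cohort(synthetic_spec(n = 500, seed = 4,
                                          test_noise_sd = 1))
  expect_lt(cor(noisy$truth$gamma_true, noisy$truth$z, method = "spearman"),
            cor(low$truth$gamma_true, low$truth$z, method = "spearman"))
})

test_that("informative dMRI features correlate with their target", {
  sim <- generate_cohort(synthetic_spec(n = 1500, seed = 5, n_dmri = 20,
                                        n_informative_dmri = 5,
                                        dmri_effect = 0.6))
  dm <- sim$features$x[, sim$features$meta$block == "dmri"]
  cors <- abs(cor(dm, sim$truth$z))
  expect_true(all(cors[1:5] > 0.45))
  expect_true(all(cors[6:20] < 0.15))

  sc <- generate_cohort(synthetic_spec(n = 1500, seed = 5, n_dmri = 10,
                                       n_informative_dmri = 5,
                                       dmri_effect = 0.6,
                                       dmri_target = "score"))
  dms <- sc$features$x[, sc$features$meta$block == "dmri"]
  eta <- qlogis(sc$truth$gamma_true)
  expect_true(all(abs(cor(dms[, 1:5], eta)) > 0.45))
})

test_that("demographic shifts follow the class-differential directions", {
  sim <- generate_cohort(synthetic_spec(n = 4000, seed = 6, demo_effect = 1))
  tr <- sim$truth
  pos <- tr$class_true == "PositiveAger"
  dec <- tr$class_true == "CognitiveDecliner"
  expect_lt(mean(tr$age[pos]), mean(tr$age[dec]))       # Positive-Agers younger
  sexm <- sim$features$x[, "sex_male"]
  expect_gt(mean(sexm[pos]), mean(sexm[dec]))           # more often male
  waist <- sim$features$x[, "waist"]
  expect_gt(mean(waist[pos]), mean(waist[dec]))         # larger waist
})

test_that("the fixture is small, deterministic and loadable", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- generate_fixture(d1); p2 <- generate_fixture(d2)
  expect_equal(length(readLines(p1[["cohort"]])), 31)   # 30 rows + header
  expect_identical(readLines(p1[["cohort"]]), readLines(p2[["cohort"]]))
  expect_identical(readLines(p1[["schema"]]), readLines(p2[["schema"]]))
  lc <- load_cohort(p1[["cohort"]], read_schema(p1[["schema"]]))
  expect_equal(lc$n_dropped, 0)
})

test_that("spec invariants reject impossible configurations", {
  expect_error(synthetic_spec(n = 5), class = "opticog_config_error")
  expect_error(synthetic_spec(n_informative_dmri = 200, n_dmri = 100),
               class = "opticog_config_error")
  expect_error(synthetic_spec(theta_true = rep(1, 7)),
               class = "opticog_config_error")
})
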