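# Ingestion, transforms, standardization, hemisphere averaging, splitting.

test_that("test transforms: natural logs for PMM/RT, FI unchanged", {
  rec <- data.frame(fi1 = 9, fi3 = 9, pmm1 = 0, pmm3 = 3, rt1 = 555.57,
                    rt3 = 600)
  tt <- transform_tests(rec)
  expect_equal(tt$pmm1, 0)                    # log(0 + 1)
  expect_equal(tt$pmm3, log(4))
  expect_equal(tt$rt1, 6.3204, tolerance = 1e-4)
  expect_equal(tt$fi3, 9)                     # FI passes through
  rec$rt1 <- 0
  expect_error(transform_tests(rec), class = "opticog_domain_error")
})

test_that("standardizer conventions and self-normalization identity", {
  two <- data.frame(fi1 = c(6, 8), fi3 = c(5, 9), pmm1 = c(0, 1),
                    pmm3 = c(1, 2), rt1 = c(6, 7), rt3 = c(6, 7))
  pop <- fit_standardizer(two, ddof = 0)
  expect_equal(unname(pop$mean["fi1"]), 7)
  expect_equal(unname(pop$sd["fi1"]), 1)      # population convention
  samp <- fit_standardizer(two, ddof = 1)
  expect_equal(unname(samp$sd["fi1"]), sqrt(2))

  withr::with_seed(4, {
    tr <- as.data.frame(matrix(rnorm(60, 5, 2), 10, 6))
    names(tr) <- c("fi1", "fi3", "pmm1", "pmm3", "rt1", "rt3")
    st <- fit_standardizer(tr)
    z <- apply_standardizer(st, tr)
    expect_true(all(abs(colMeans(z)) < 1e-9))
    expect_true(all(abs(apply(z, 2, sd) - 1) < 1e-9))
  })

  const <- two; const$fi1 <- c(3, 3)
  expect_error(fit_standardizer(const), class = "opticog_degenerate_error")
  expect_error(fit_standardizer(two[1, , drop = FALSE]),
               class = "opticog_data_error")
})

test_that("published stats give z = 0 at the published channel means", {
  m <- published_model()
  tt <- data.frame(fi1 = 6.86, fi3 = 6.79, pmm1 = 1.40, pmm3 = 1.41,
                   rt1 = 6.32, rt3 = 6.40)
  z <- apply_standardizer(m$stats, tt)
  expect_true(all(abs(z) < 1e-12))
})

test_that("hemisphere averaging: pairs averaged, midline passed, counts conserved", {
  raw <- data.frame(FA_acr_L = 0.4, FA_acr_R = 0.6, FA_scp_L = 0.2,
                    FA_scp_R = 0.4, FA_ec_L = 0.1, FA_ec_R = 0.3,
                    FA_bcc = 0.7, FA_splenium = 0.5)
  naming <- data.frame(
    column = c(NA, NA, NA, "FA_bcc", "FA_splenium"),
    left = c("FA_acr_L", "FA_scp_L", "FA_ec_L", NA, NA),
    right = c("FA_acr_R", "FA_scp_R", "FA_ec_R", NA, NA),
    attribute = "FA",
    tract = c("acr", "scp", "ec", "bcc", "splenium"))
  ft <- average_hemispheres(raw, naming)
  expect_equal(ncol(ft$x), 5)                 # 3 pairs + 2 midline
  expect_equal(unname(ft$x[1, "mean_FA_in_acr"]), 0.5)
  expect_equal(unname(ft$x[1, "mean_FA_in_bcc"]), 0.7)
  expect_true(all(ft$meta$block == "dmri"))

  bad <- naming; bad$right[1] <- "nonexistent"
  expect_error(average_hemispheres(raw, bad), class = "opticog_pairing_error")
})

test_that("cohort splitting is deterministic, disjoint, and sized per fractions", {
  ids <- as.character(1:100)
  sp <- split_cohort(ids, c(0.69, 0.155, 0.155), seed = 1)
  expect_equal(lengths(sp[c("train", "validation", "test")]),
               c(train = 69, validation = 15, test = 16))
  expect_identical(sp, split_cohort(ids, c(0.69, 0.155, 0.155), seed = 1))
  expect_false(identical(sp$train,
                         split_cohort(ids, c(0.69, 0.155, 0.155), 2)$train))
  expect_length(intersect(sp$train, sp$validation), 0)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$validation, sp$test), ids)
  # study proportions
  sp2 <- split_cohort(as.character(1:5797), c(0.689, 0.154, 0.157), seed = 3)
  expect_lt(abs(length(sp2$train) - 3996), 4)
  expect_lt(abs(length(sp2$validation) - 893), 4)
  expect_lt(abs(length(sp2$test) - 908), 4)
  expect_error(split_cohort(ids, c(0.5, 0.5, 0), 1),
               class = "opticog_config_error")
})

test_that("load_cohort validates rows and applies the complete-case filter", {
  paths <- generate_fixture(withr::local_tempdir())
  sch <- read_schema(paths[["schema"]])
  lc <- load_cohort(paths[["cohort"]], sch)
  expect_equal(nrow(lc$cognitive), 30)
  expect_equal(lc$n_dropped, 0)

  # corrupt one row: rt1 = 0 invalidates the log transform
  df <- read.csv(paths[["cohort"]], check.names = FALSE)
  df$rt1[2] <- 0
  dmri_col <- grep("^mean_", names(df), value = TRUE)[1]
  df[[dmri_col]][5] <- NA
  bad_path <- file.path(dirname(paths[["cohort"]]), "bad.csv")
  write.csv(df, bad_path, row.names = FALSE)
  expect_warning(lc2 <- load_cohort(bad_path, sch), "dropped 2")
  expect_equal(nrow(lc2$cognitive), 28)
  expect_false(df$participant_id[2] %in% lc2$cognitive$participant_id)
  expect_false(df$participant_id[5] %in% rownames(lc2$features$x))

  sch2 <- sch; sch2$cognitive$fi1 <- NULL
  expect_error(load_cohort(paths[["cohort"]], sch2),
               class = "opticog_schema_error")
})

test_that("writing then reloading a cohort round-trips the values", {
  dir <- withr::local_tempdir()
  paths <- generate_fixture(dir)
  sim <- generate_cohort(synthetic_spec(n = 30, seed = 42, n_dmri = 18,
                                        n_informative_dmri = 6))
  lc <- load_cohort(paths[["cohort"]], read_schema(paths[["schema"]]))
  expect_identical(lc$cognitive$fi1, sim$cognitive$fi1)
  expect_identical(lc$cognitive$pmm3, sim$cognitive$pmm3)
  expect_equal(lc$cognitive$rt1, sim$cognitive$rt1, tolerance = 1e-12)
  dm <- intersect(colnames(lc$features$x), colnames(sim$features$x))
  expect_equal(lc$features$x[, dm], sim$features$x[, dm], tolerance = 1e-12)
})
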