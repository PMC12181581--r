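# Synthetic cohort generator with planted ground truth. A latent cognitive
# ability z drives (i) the six standardized test channels, with signs
# matching the feasible domain (FI up, PMM/RT down), (ii) a subset of dMRI
# features, and (iii) class-differential demographic shifts. Raw test
# values are back-transformed so their marginals match the published
# channel means/sds; that anchors the simulated cohort to the study
# population without using any restricted data.

# Canonical diffusion attributes and a synthetic tract inventory (real tract
# names; the combination attribute x tract is cycled to reach n_dmri).
DMRI_ATTRIBUTES <- c("FA", "MD", "MO", "OD", "ICVF", "ISOVF", "L1", "L2", "L3")
SYNTH_TRACTS <- c("anterior_corona_radiata", "body_of_corpus_callosum",
                  "cerebral_peduncle", "cingulum_gyrus", "corticospinal_tract",
                  "external_capsule", "fornix_cres_stria_terminalis",
                  "medial_lemniscus", "posterior_limb_of_internal_capsule",
                  "sagittal_stratum", "superior_cerebellar_peduncle",
                  "superior_longitudinal_fasciculus", "tapetum",
                  "uncinate_fasciculus", "splenium_of_corpus_callosum")

#' Synthetic cohort specification
#'
#' @param n Number of participants (>= 10).
#' @param seed Integer seed.
#' @param theta_true Planted feasible 7-vector generating the true scores
#'   (default: the published optimal weights).
#' @param test_loading Loading of the latent trait on each standardized test
#'   channel (signal strength; default 0.9).
#' @param test_noise_sd Per-channel noise sd around the latent signal
#'   (default 0.35; channels are rescaled to unit marginal variance).
#' @param n_dmri Number of dMRI features (default 135).
#' @param n_informative_dmri dMRI features correlated with the latent trait
#'   (default 20).
#' @param dmri_effect Latent-trait correlation of informative dMRI features
#'   (default 0.6).
#' @param dmri_target What the informative dMRI features track:
#'   `"latent"` (default) the latent ability trait, or `"score"` the
#'   standardized linear predictor of `theta_true` (so the features carry
#'   the planted score's specific weighting of the test channels).
#' @param demo_effect Strength of class-differential demographic shifts
#'   (default 0.5; 0 removes all demographic signal).
#' @param delta_t_years Inter-visit interval in years (default 8).
#' @param age_range Baseline age range (default c(55, 70)).
#' @param q Quantile used to derive the planted true classes (default 0.15).
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n = 2000, seed = 1,
                           theta_true = c(-0.622, 1.764, 2.198, -0.349,
                                          -1.371, -0.633, -1.191),
                           test_loading = 0.9, test_noise_sd = 0.35,
                           n_dmri = 135, n_informative_dmri = 20,
                           dmri_effect = 0.6, dmri_target = c("latent", "score"),
                           demo_effect = 0.5,
                           delta_t_years = 8, age_range = c(55, 70),
                           q = 0.15) {
  if (n < 10) stop_opticog("n must be >= 10", "opticog_config_error")
  if (n_informative_dmri < 0 || n_informative_dmri > n_dmri)
    stop_opticog("need 0 <= n_informative_dmri <= n_dmri",
                 "opticog_config_error")
  if (test_noise_sd <= 0 || test_loading <= 0)
    stop_opticog("loadings and sds must be > 0", "opticog_config_error")
  if (!is_feasible(theta_true))
    stop_opticog("theta_true must be feasible", "opticog_config_error")
  dmri_target <- match.arg(dmri_target)
  structure(as.list(environment()), class = "synthetic_spec")
}

#' Generate a synthetic cohort with planted ground truth
#'
#' See the package vignette for the generative model. Returns raw cognitive
#' records (FI integer 0-13, PMM non-negative integer counts, RT in ms), a
#' feature table (one-hot demographics + dMRI), and the ground truth (latent
#' trait, true standardized channels, true score, true class).
#'
#' @param spec A `synthetic_spec`.
#' @return List with `cognitive`, `features`, `truth` (data.frame:
#'   participant_id, z, gamma_true, class_true, age, delta_t), and `spec`.
#' @export
generate_cohort <- function(spec = synthetic_spec()) {
  with_local_seed(spec$seed, {
    n <- spec$n
    ids <- sprintf("P%05d", seq_len(n))
    z <- stats::rnorm(n)

    # Standardized channels: +/- loading * z + noise, unit marginal variance.
    sgn <- c(1, 1, -1, -1, -1, -1)
    tot <- sqrt(spec$test_loading^2 + spec$test_noise_sd^2)
    x_std_true <- vapply(seq_along(CHANNELS), function(i) {
      (sgn[i] * spec$test_loading * z +
         stats::rnorm(n, 0, spec$test_noise_sd)) / tot
    }, numeric(n))
    colnames(x_std_true) <- CHANNELS

    # Back-transform to raw scales with the published channel anchors.
    pub <- published_model()$stats
    raw <- as.data.frame(sweep(sweep(x_std_true, 2, pub$sd, "*"), 2,
                               pub$mean, "+"))
    cognitive <- data.frame(
      participant_id = ids,
      fi1 = pmin(13L, pmax(0L, as.integer(round(raw$fi1)))),
      fi3 = pmin(13L, pmax(0L, as.integer(round(raw$fi3)))),
      pmm1 = pmax(0L, as.integer(round(exp(raw$pmm1) - 1))),
      pmm3 = pmax(0L, as.integer(round(exp(raw$pmm3) - 1))),
      rt1 = exp(raw$rt1), rt3 = exp(raw$rt3))

    # Planted truth on the noiseless standardized channels.
    gamma_true <- compute_score(x_std_true, spec$theta_true)
    thr <- compute_thresholds(gamma_true, spec$q)
    class_true <- assign_labels(gamma_true, thr$lb, thr$ub)

    # dMRI block: informative features = rho*target + sqrt(1-rho^2)*noise,
    # where the target is the latent trait or the standardized planted score.
    rho <- spec$dmri_effect
    target <- if (identical(spec$dmri_target, "score")) {
      eta <- spec$theta_true[1] + drop(x_std_true %*% spec$theta_true[2:7])
      as.numeric(scale(eta))
    } else z
    dmri <- matrix(stats::rnorm(n * spec$n_dmri), n, spec$n_dmri)
    if (spec$n_informative_dmri > 0) {
      k <- spec$n_informative_dmri
      dmri[, seq_len(k)] <- rho * target +
        sqrt(1 - rho^2) * dmri[, seq_len(k), drop = FALSE]
    }
    combos <- expand.grid(tract = SYNTH_TRACTS, attribute = DMRI_ATTRIBUTES,
                          stringsAsFactors = FALSE)[seq_len(spec$n_dmri), ]
    dmri_names <- sprintf("mean_%s_in_%s", combos$attribute, combos$tract)
    colnames(dmri) <- dmri_names
    dmri_meta <- data.frame(feature = dmri_names, block = "dmri",
                            attribute = combos$attribute, tract = combos$tract)

    # Demographics with class-differential shifts in the directions seen in
    # aging cohorts: Positive-Agers younger, more educated, more often male,
    # higher income, slightly larger waist.
    e <- spec$demo_effect
    age <- round(pmin(spec$age_range[2], pmax(spec$age_range[1],
                 stats::rnorm(n, 61 - 1.8 * e * z, 3.7))))
    waist <- stats::rnorm(n, 89 + 1.9 * e * z, 11.7)
    bmi <- stats::rnorm(n, 18.2 + 0.4 * e * z, 2.8)
    sex <- ifelse(stats::runif(n) < stats::plogis(0.1 + 0.6 * e * z),
                  "male", "female")
    edu_levels <- c("college", "post_secondary", "secondary", "other")
    edu_p <- function(zi) {
      w <- exp(c(0.9 * e * zi, 0.1, -0.4 * e * zi, -0.9 * e * zi))
      w / sum(w)
    }
    education <- vapply(z, function(zi)
      sample(edu_levels, 1, prob = edu_p(zi)), character(1))
    inc_levels <- c("under", "lower", "middle", "upper_middle", "upper")
    income <- vapply(z, function(zi) {
      w <- exp(seq(-1, 1, length.out = 5) * 0.8 * e * zi)
      sample(inc_levels, 1, prob = w / sum(w))
    }, character(1))
    handed <- sample(c("right", "left"), n, TRUE, prob = c(0.9, 0.1))
    skin <- sample(c("pale", "olive"), n, TRUE, prob = c(0.8, 0.2))
    tobacco <- sample(c("never", "prior", "smoker"), n, TRUE,
                      prob = c(0.62, 0.34, 0.04))
    demo <- data.frame(age = age, bmi = bmi, waist = waist, sex = sex,
                       education = education, income = income,
                       handedness = handed, skin_color = skin,
                       tobacco_use = tobacco)
    demo_enc <- encode_demographics(demo)

    x <- cbind(demo_enc$x, dmri)
    rownames(x) <- ids
    features <- feature_table(x, rbind(demo_enc$meta, dmri_meta))
    truth <- data.frame(participant_id = ids, z = z,
                        gamma_true = gamma_true, class_true = class_true,
                        age = age, delta_t = spec$delta_t_years)
    list(cognitive = cognitive, features = features, truth = truth,
         spec = spec)
  })
}

#' Write a small deterministic fixture cohort
#'
#' Writes a 30-participant synthetic cohort (fixed seed) as a cohort CSV
#' plus a JSON schema, byte-identical across runs, for use in tests and
#' examples.
#'
#' @param dir Output directory (created if needed).
#' @param n Number of participants (default 30).
#' @param seed Fixed seed (default 42).
#' @return Named character vector with the `cohort` and `schema` paths.
#' @export
generate_fixture <- function(dir = tempdir(), n = 30, seed = 42) {
  sim <- generate_cohort(synthetic_spec(n = n, seed = seed, n_dmri = 18,
                                        n_informative_dmri = 6))
  df <- cbind(sim$cognitive,
              as.data.frame(sim$features$x, check.names = FALSE))
  # format reals at full double precision, deterministically
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.15g", v))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cohort_path <- file.path(dir, "fixture_cohort.csv")
  utils::write.table(df, cohort_path, sep = ",", row.names = FALSE,
                     quote = FALSE)
  dmri_meta <- sim$features$meta[sim$features$meta$block == "dmri", ]
  schema <- list(
    cognitive = list(participant_id = "participant_id", fi1 = "fi1",
                     fi3 = "fi3", pmm1 = "pmm1", pmm3 = "pmm3",
                     rt1 = "rt1", rt3 = "rt3"),
    demographics = setdiff(colnames(sim$features$x), dmri_meta$feature),
    dmri = lapply(seq_len(nrow(dmri_meta)), function(i)
      list(column = dmri_meta$feature[i], attribute = dmri_meta$attribute[i],
           tract = dmri_meta$tract[i])))
  schema_path <- file.path(dir, "fixture_schema.json")
  jsonlite::write_json(schema, schema_path, auto_unbox = TRUE, pretty = TRUE)
  c(cohort = cohort_path, schema = schema_path)
}
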