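# Shared small fixtures, built in code at test time.

# A small cohort with informative dMRI features and a quick split.
small_cohort <- function(n = 500, seed = 11, ...) {
  sim <- generate_cohort(synthetic_spec(n = n, seed = seed, n_dmri = 30,
                                        n_informative_dmri = 10, ...))
  split <- split_cohort(sim$cognitive$participant_id, seed = seed)
  list(sim = sim, split = split)
}

# Two separable Gaussian blobs as a feature matrix + labels.
two_blobs <- function(n = 200, p = 10, sep = 4, seed = 5) {
  withr::with_seed(seed, {
    y <- rep(c("CognitiveDecliner", "PositiveAger"), each = n / 2)
    x <- matrix(rnorm(n * p), n, p)
    x[y == "PositiveAger", 1:2] <- x[y == "PositiveAger", 1:2] + sep
    colnames(x) <- paste0("f", seq_len(p))
    list(x = x, y = y)
  })
}

quick_inner <- function(seed = 1, f_keep = 25)
  inner_config(f_keep = f_keep, m_fs = 10, seed = seed)

quick_cans <- function(seed = 1, nc = 5, j = 10)
  cans_config(nc = nc, j_max = j, seed = seed)

quick_final <- function(seed = 1, budget = 5)
  final_config(budget = budget, n_init = 4, nfold = 3,
               nrounds = c(50, 150), seed = seed)
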