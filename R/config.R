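# Run configuration, manifests and the command-line dispatcher. A YAML run
# config holds one master seed plus per-stage blocks; every stage derives
# its own named RNG substream so stages are independently reproducible. The
# installed script inst/cli/opticog.R is a thin wrapper around
# opticog_main().

#' Read a run configuration
#'
#' YAML (or JSON) file with optional blocks `synthetic:`, `cans:`,
#' `inner_pipeline:`, `final_pipeline:`, `split:`, and top-level `seed`,
#' `q`, `out_dir`, `cohort`, `schema`. Missing values fall back to package
#' defaults.
#'
#' @param path Path to the config file.
#' @return Named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::fromJSON(path)
  else yaml::read_yaml(path)
  # YAML 1.1 reads the bare keys n/y as booleans; restore them
  fix_keys <- function(x) {
    if (!is.list(x)) return(x)
    nm <- names(x)
    nm[nm == "FALSE"] <- "n"; nm[nm == "TRUE"] <- "y"
    names(x) <- nm
    lapply(x, fix_keys)
  }
  cfg <- fix_keys(cfg)
  cfg$seed <- as.integer(cfg$seed %||% 1)
  cfg$q <- cfg$q %||% 0.15
  cfg$out_dir <- cfg$out_dir %||% "opticog_out"
  structure(cfg, class = "run_config")
}

config_objects <- function(cfg) {
  seed <- cfg$seed
  syn <- do.call(synthetic_spec,
                 utils::modifyList(list(seed = derive_seed(seed, "simulate")),
                                   cfg$synthetic %||% list()))
  cans <- do.call(cans_config,
                  utils::modifyList(list(seed = derive_seed(seed, "cans")),
                                    cfg$cans %||% list()))
  inner <- do.call(inner_config,
                   utils::modifyList(list(seed = derive_seed(seed, "inner")),
                                     cfg$inner_pipeline %||% list()))
  final <- do.call(final_config,
                   utils::modifyList(list(seed = derive_seed(seed, "final")),
                                     cfg$final_pipeline %||% list()))
  split_fr <- cfg$split$fractions %||% c(0.689, 0.154, 0.157)
  list(synthetic = syn, cans = cans, inner = inner, final = final,
       split_fractions = split_fr,
       split_seed = derive_seed(seed, "split"))
}

# Small deterministic content hash for manifests (djb2 over the serialized
# config), hex-encoded.
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  h <- 5381
  for (ch in utf8ToInt(as.character(s))) h <- (h * 33 + ch) %% 4294967291
  sprintf("%08x", as.integer(h %% 2147483647))
}

write_manifest <- function(cfg, dir, command) {
  jsonlite::write_json(list(command = command, config = unclass(cfg),
                            config_hash = config_hash(cfg), seed = cfg$seed,
                            package_version =
                              as.character(utils::packageVersion("opticog"))),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

load_cohort_from_config <- function(cfg) {
  if (!is.null(cfg$cohort)) {
    sch <- read_schema(cfg$schema)
    load_cohort(cfg$cohort, sch)
  } else {
    generate_cohort(config_objects(cfg)$synthetic)
  }
}

#' Command-line entry point
#'
#' Dispatches the subcommands `simulate`, `optimize`, `fit-final`, `score`,
#' `label`, `trajectory`, `evaluate` and `baseline` over a YAML run config.
#' Artifacts (CSV tables, JSON models, a manifest with the config hash,
#' seed and package version) are written under the config's `out_dir`.
#'
#' @param args Character vector: `c(command, "--config", path, ...)`;
#'   `--which` selects the baseline variant.
#' @return Integer exit status (0 on success), invisibly.
#' @export
opticog_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste("usage: opticog <simulate|optimize|fit-final|score|label|",
                 "trajectory|evaluate|baseline> --config run.yaml",
                 "[--which pca|dmri_only|demo_only]")
  cmds <- c("simulate", "optimize", "fit-final", "score", "label",
            "trajectory", "evaluate", "baseline")
  if (!length(args) || !(args[1] %in% cmds)) {
    message(usage)
    return(invisible(1L))
  }
  command <- args[1]
  get_opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) && i[1] < length(args)) args[i[1] + 1] else default
  }
  cfg_path <- get_opt("--config")
  if (is.null(cfg_path) || !file.exists(cfg_path)) {
    message("missing or unreadable --config file\n", usage)
    return(invisible(1L))
  }
  cfg <- read_run_config(cfg_path)
  obj <- config_objects(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  cohort <- load_cohort_from_config(cfg)
  split <- split_cohort(cohort$cognitive$participant_id,
                        obj$split_fractions, obj$split_seed)

  status <- 0L
  if (command == "simulate") {
    paths <- generate_fixture(cfg$out_dir, n = obj$synthetic$n,
                              seed = obj$synthetic$seed)
    if (!is.null(cohort$truth))
      utils::write.csv(cohort$truth, file.path(cfg$out_dir, "truth.csv"),
                       row.names = FALSE)
  } else if (command == "optimize") {
    res <- run_optics(cohort, split, cfg$q, obj$inner, obj$cans)
    utils::write.csv(res$trace[, c("iteration", "sigma", "best_loss")],
                     file.path(cfg$out_dir, "cans_trace.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(theta_star = res$theta_star, lb = res$lb,
                              ub = res$ub, loss_star = res$loss_star,
                              q = res$q,
                              stats = list(mean = as.list(res$stats$mean),
                                           sd = as.list(res$stats$sd))),
                         file.path(cfg$out_dir, "optics_result.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else if (command %in% c("score", "label")) {
    model <- published_model()
    tt <- transform_tests(cohort$cognitive)
    x_std <- apply_standardizer(model$stats, tt)
    gamma <- compute_score(x_std, model$theta)
    out <- data.frame(participant_id = cohort$cognitive$participant_id,
                      gamma = gamma)
    if (command == "label")
      out$label <- assign_labels(gamma, model$lb, model$ub)
    utils::write.csv(out, file.path(cfg$out_dir, paste0(command, "s.csv")),
                     row.names = FALSE)
  } else if (command %in% c("fit-final", "evaluate")) {
    opt <- run_optics(cohort, split, cfg$q, obj$inner, obj$cans)
    ev <- evaluate_final(cohort, split, opt$model, obj$final)
    tab <- data.frame(AUC = ev$test_auc,
                      Accuracy = ev$metrics$accuracy,
                      Precision = ev$metrics$precision,
                      Recall = ev$metrics$recall,
                      Specificity = ev$metrics$specificity,
                      F1 = ev$metrics$f1,
                      N = sum(ev$n_extreme))
    utils::write.csv(tab, file.path(cfg$out_dir, "metrics.csv"),
                     row.names = FALSE)
    jsonlite::write_json(as.list(tab), file.path(cfg$out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else if (command == "trajectory") {
    opt <- run_optics(cohort, split, cfg$q, obj$inner, obj$cans)
    ctx <- opt$context
    rec <- trajectory_records(ctx$x_std, opt$theta_star, opt$lb, opt$ub,
                              delta_t = obj$synthetic$delta_t_years,
                              age = cohort$truth$age)
    utils::write.csv(rec, file.path(cfg$out_dir, "trajectories.csv"),
                     row.names = FALSE)
    splits <- gini_split_points(rec$s1_adj, rec$cls)
    jsonlite::write_json(list(split_points = splits,
                              decliner_boundary =
                                class_boundary_constant(opt$theta_star[1], opt$lb),
                              positive_boundary =
                                class_boundary_constant(opt$theta_star[1], opt$ub)),
                         file.path(cfg$out_dir, "trajectory_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else if (command == "baseline") {
    which <- get_opt("--which", "pca")
    res <- restricted_baseline(cohort, which, split, cfg$q, obj$inner,
                               obj$cans, obj$final)
    jsonlite::write_json(list(which = which, test_auc = res$test_auc,
                              metrics = res$metrics),
                         file.path(cfg$out_dir, "baseline.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  write_manifest(cfg, cfg$out_dir, command)
  invisible(status)
}
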