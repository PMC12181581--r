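# Cohort ingestion, validation, transforms and splitting.
#
# A cohort is a list with:
#   $cognitive - data.frame: participant_id + the six raw test columns
#   $features  - feature_table: participant x feature matrix + metadata

#' Construct a feature table
#'
#' A participant-by-feature numeric matrix plus per-feature metadata: the
#' block (`"demographic"` or `"dmri"`) and, for dMRI features, the diffusion
#' attribute (FA, MD, MO, OD, ICVF, ISOVF, L1, L2, L3, RD) and tract name.
#'
#' @param x Numeric matrix (rows = participants, named) with column names.
#' @param meta data.frame with columns `feature`, `block`, `attribute`,
#'   `tract` (attribute/tract `NA` for demographic features), one row per
#'   column of `x`, in order.
#' @return Object of class `feature_table`.
#' @export
feature_table <- function(x, meta) {
  stopifnot(is.matrix(x), is.numeric(x), !is.null(colnames(x)))
  stopifnot(identical(colnames(x), meta$feature))
  if (anyNA(x))
    stop_opticog("feature table contains missing values", "opticog_data_error")
  bad <- meta$block == "dmri" & (is.na(meta$attribute) | is.na(meta$tract))
  if (any(bad))
    stop_opticog("every dMRI feature needs an attribute and a tract",
                 "opticog_metadata_error")
  structure(list(x = x, meta = meta), class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d participants x %d features (%d demographic, %d dMRI)\n",
              nrow(x$x), ncol(x$x), sum(x$meta$block == "demographic"),
              sum(x$meta$block == "dmri")))
  invisible(x)
}

# Subset a feature_table by row index and/or block.
subset_features <- function(ft, rows = NULL, block = NULL) {
  keep <- if (is.null(block)) rep(TRUE, ncol(ft$x)) else ft$meta$block %in% block
  x <- ft$x[, keep, drop = FALSE]
  if (!is.null(rows)) x <- x[rows, , drop = FALSE]
  feature_table(x, ft$meta[keep, , drop = FALSE])
}

#' Log-transform the raw cognitive tests
#'
#' The skewed channels are transformed with natural logarithms: PMM error
#' counts as `log(x + 1)`, reaction times as `log(x)`; fluid intelligence is
#' left unchanged.
#'
#' @param records data.frame with columns `fi1`, `fi3`, `pmm1`, `pmm3`,
#'   `rt1`, `rt3` (raw values).
#' @return data.frame with the same six columns, transformed.
#' @export
#' @examples
#' transform_tests(data.frame(fi1 = 9, fi3 = 10, pmm1 = 0, pmm3 = 1,
#'                            rt1 = 555.57, rt3 = 520))
transform_tests <- function(records) {
  miss <- setdiff(CHANNELS, names(records))
  if (length(miss))
    stop_opticog(paste("missing test columns:", paste(miss, collapse = ", ")),
                 "opticog_schema_error")
  if (any(records$rt1 <= 0) || any(records$rt3 <= 0))
    stop_opticog("reaction times must be > 0 (log undefined)",
                 "opticog_domain_error")
  if (any(records$pmm1 < 0) || any(records$pmm3 < 0))
    stop_opticog("PMM error counts must be >= 0", "opticog_domain_error")
  out <- records[CHANNELS]
  out$pmm1 <- log(records$pmm1 + 1)
  out$pmm3 <- log(records$pmm3 + 1)
  out$rt1 <- log(records$rt1)
  out$rt3 <- log(records$rt3)
  out
}

#' Fit per-channel standardization statistics
#'
#' Means and standard deviations of the six transformed test channels,
#' computed on training rows only. The sd convention is configurable:
#' `ddof = 1` (sample, default) or `ddof = 0` (population).
#'
#' @param training data.frame of transformed tests (>= 2 rows).
#' @param ddof Degrees-of-freedom correction, 1 or 0.
#' @return Object of class `standardization_stats` with named `mean` and
#'   `sd` vectors in channel order (FI1, FI3, PMM1, PMM3, RT1, RT3).
#' @export
fit_standardizer <- function(training, ddof = 1) {
  stopifnot(ddof %in% c(0, 1))
  if (nrow(training) < 2)
    stop_opticog("need >= 2 training records", "opticog_data_error")
  m <- vapply(training[CHANNELS], mean, numeric(1))
  n <- nrow(training)
  s <- vapply(training[CHANNELS], function(v) {
    sqrt(sum((v - mean(v))^2) / (n - ddof))
  }, numeric(1))
  if (any(s == 0))
    stop_opticog("zero-variance channel: cannot standardize",
                 "opticog_degenerate_error")
  structure(list(mean = m, sd = s, ddof = as.integer(ddof)),
            class = "standardization_stats")
}

#' Apply standardization statistics
#'
#' @param stats A `standardization_stats` object.
#' @param transformed data.frame of transformed tests.
#' @return n x 6 numeric matrix of standardized channels.
#' @export
apply_standardizer <- function(stats, transformed) {
  x <- as.matrix(transformed[CHANNELS])
  sweep(sweep(x, 2, stats$mean[CHANNELS]), 2, stats$sd[CHANNELS], "/")
}

#' @export
print.standardization_stats <- function(x, ...) {
  cat("standardization_stats (channels FI1, FI3, PMM1, PMM3, RT1, RT3)\n")
  print(round(rbind(mean = x$mean, sd = x$sd), 4))
  invisible(x)
}

#' Average left/right hemisphere tract columns
#'
#' Bilateral tracts appear in the input as matched left/right column pairs
#' (suffixes configurable, default `"_L"`/`"_R"`); each pair is replaced by
#' its arithmetic mean. Midline tracts appear once and pass through. Output
#' columns are named `mean_<ATTR>_in_<tract>`.
#'
#' @param raw_dmri data.frame or matrix of per-tract dMRI columns.
#' @param naming data.frame with columns `column` (for midline tracts) or
#'   `left`/`right` (for bilateral pairs; `NA` column means midline),
#'   `attribute`, `tract`.
#' @param suffixes Length-2 character: left and right suffixes (used only
#'   for error messages; pairing comes from `naming`).
#' @return A `feature_table` containing the dMRI block.
#' @export
average_hemispheres <- function(raw_dmri, naming, suffixes = c("_L", "_R")) {
  raw_dmri <- as.data.frame(raw_dmri)
  naming <- as.data.frame(naming)
  for (nm in c("column", "left", "right"))
    if (is.null(naming[[nm]])) naming[[nm]] <- NA_character_
  vals <- list(); meta <- list()
  for (i in seq_len(nrow(naming))) {
    row <- naming[i, ]
    id <- sprintf("mean_%s_in_%s", row$attribute, row$tract)
    if (!is.na(row$left) || !is.na(row$right)) {
      if (is.na(row$left) || is.na(row$right) ||
          !(row$left %in% names(raw_dmri)) || !(row$right %in% names(raw_dmri)))
        stop_opticog(sprintf("unmatched hemisphere pair for tract '%s' (%s/%s expected)",
                             row$tract, suffixes[1], suffixes[2]),
                     "opticog_pairing_error")
      v <- (raw_dmri[[row$left]] + raw_dmri[[row$right]]) / 2
    } else {
      if (!(row$column %in% names(raw_dmri)))
        stop_opticog(sprintf("missing midline column '%s'", row$column),
                     "opticog_pairing_error")
      v <- raw_dmri[[row$column]]
    }
    vals[[id]] <- v
    meta[[id]] <- data.frame(feature = id, block = "dmri",
                             attribute = row$attribute, tract = row$tract)
  }
  x <- do.call(cbind, vals)
  colnames(x) <- names(vals)
  feature_table(as.matrix(x), do.call(rbind, meta))
}

#' Split participant ids into train / validation / test
#'
#' Deterministic shuffle by seed, then allocation by fractions. Each set
#' gets the floor of its share; leftover participants are assigned by
#' largest fractional remainder, ties resolved toward the later set.
#'
#' @param ids Character vector of participant ids.
#' @param fractions Length-3 numeric (train, validation, test) summing to 1.
#' @param seed Integer seed.
#' @return List of class `split_spec` with `train`, `validation`, `test` id
#'   vectors, plus the `seed` and `fractions` used.
#' @export
#' @examples
#' split_cohort(as.character(1:100), c(0.69, 0.155, 0.155), seed = 1)
split_cohort <- function(ids, fractions = c(0.689, 0.154, 0.157), seed = 1) {
  if (length(fractions) != 3 || any(fractions <= 0))
    stop_opticog("fractions must be 3 positive values", "opticog_config_error")
  if (abs(sum(fractions) - 1) > 1e-8)
    stop_opticog("fractions must sum to 1", "opticog_config_error")
  ids <- as.character(ids)
  n <- length(ids)
  sizes <- floor(n * fractions)
  rem <- n - sum(sizes)
  if (rem > 0) {
    frac_part <- n * fractions - sizes
    # ties toward the later set: order by (fractional part, position), both desc
    who <- order(frac_part, seq_along(fractions), decreasing = TRUE)[seq_len(rem)]
    sizes[who] <- sizes[who] + 1
  }
  if (any(sizes == 0))
    stop_opticog("a split set would be empty; adjust fractions or n",
                 "opticog_config_error")
  perm <- with_local_seed(seed, sample.int(n))
  shuffled <- ids[perm]
  cut1 <- sizes[1]; cut2 <- sizes[1] + sizes[2]
  structure(list(train = shuffled[seq_len(cut1)],
                 validation = shuffled[(cut1 + 1):cut2],
                 test = shuffled[(cut2 + 1):n],
                 seed = as.integer(seed), fractions = fractions),
            class = "split_spec")
}

#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf("split_spec: train %d / validation %d / test %d (seed %d)\n",
              length(x$train), length(x$validation), length(x$test), x$seed))
  invisible(x)
}

#' Load and validate a cohort from delimited text
#'
#' Reads a CSV/TSV with header, maps columns via the schema, validates the
#' cognitive records (FI in \[0, 13\], PMM >= 0, RT > 0, both visits present)
#' and applies complete-case filtering: rows with a missing or invalid value
#' in any mapped column are dropped with a warning.
#'
#' @param path Path to the delimited file.
#' @param schema Schema list (see [read_schema()]) with components
#'   `cognitive` (named map logical -> column for `participant_id` and the
#'   six tests), `demographics` (character vector of columns; categoricals
#'   are one-hot encoded), and `dmri` (data.frame as for
#'   [average_hemispheres()]).
#' @param sep Field separator (default `","`).
#' @return List with `cognitive` (validated records), `features`
#'   (a `feature_table`), and `dropped` (ids of excluded rows).
#' @export
load_cohort <- function(path, schema, sep = ",") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  cmap <- schema$cognitive
  need <- c("participant_id", CHANNELS)
  miss <- setdiff(need, names(cmap))
  if (length(miss))
    stop_opticog(paste("schema missing cognitive mappings:",
                       paste(miss, collapse = ", ")), "opticog_schema_error")
  cols_needed <- unique(c(unlist(cmap), schema$demographics,
                          stats::na.omit(c(schema$dmri$column, schema$dmri$left,
                                           schema$dmri$right))))
  absent <- setdiff(cols_needed, names(raw))
  if (length(absent))
    stop_opticog(paste("missing mandatory columns:", paste(absent, collapse = ", ")),
                 "opticog_schema_error")

  cog <- data.frame(participant_id = as.character(raw[[cmap$participant_id]]))
  for (ch in CHANNELS) {
    v <- raw[[cmap[[ch]]]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      if (any(is.na(vn) & !is.na(v)))
        stop_opticog(sprintf("unparseable numeric in column '%s' (rows %s)",
                             cmap[[ch]],
                             paste(utils::head(which(is.na(vn) & !is.na(v)), 5),
                                   collapse = ", ")),
                     "opticog_validation_error")
      v <- vn
    }
    cog[[ch]] <- v
  }

  ok <- stats::complete.cases(cog) &
    cog$fi1 >= 0 & cog$fi1 <= 13 & cog$fi3 >= 0 & cog$fi3 <= 13 &
    cog$pmm1 >= 0 & cog$pmm3 >= 0 & cog$rt1 > 0 & cog$rt3 > 0
  ok[is.na(ok)] <- FALSE

  # complete-case across the feature columns too
  other <- raw[, setdiff(cols_needed, unlist(cmap)), drop = FALSE]
  feat_ok <- if (ncol(other)) rowSums(is.na(other)) == 0 else rep(TRUE, nrow(raw))
  keep <- ok & feat_ok
  if (any(!keep))
    warning(sprintf("dropped %d row(s) failing validation/complete-case filter",
                    sum(!keep)), call. = FALSE)

  dropped <- cog$participant_id[!keep]
  cog <- cog[keep, , drop = FALSE]
  raw <- raw[keep, , drop = FALSE]

  demo_ft <- encode_demographics(raw[, schema$demographics, drop = FALSE])
  dmri_ft <- average_hemispheres(raw, schema$dmri)
  x <- cbind(demo_ft$x, dmri_ft$x)
  rownames(x) <- cog$participant_id
  meta <- rbind(demo_ft$meta, dmri_ft$meta)
  list(cognitive = cog, features = feature_table(x, meta),
       dropped = dropped, n_dropped = length(dropped))
}

# One-hot encode character/factor demographic columns; numerics pass through.
# Dummy levels are sorted for determinism; the first level is the baseline
# and is dropped (treatment coding).
encode_demographics <- function(df) {
  cols <- list(); meta <- list()
  for (nm in names(df)) {
    v <- df[[nm]]
    if (is.numeric(v)) {
      cols[[nm]] <- v
      meta[[nm]] <- data.frame(feature = nm, block = "demographic",
                               attribute = NA_character_, tract = NA_character_)
    } else {
      lev <- sort(unique(as.character(v)))
      for (lv in lev[-1]) {
        id <- sprintf("%s_%s", nm, gsub("[^A-Za-z0-9]+", "_", lv))
        cols[[id]] <- as.numeric(v == lv)
        meta[[id]] <- data.frame(feature = id, block = "demographic",
                                 attribute = NA_character_, tract = NA_character_)
      }
    }
  }
  x <- do.call(cbind, cols)
  colnames(x) <- names(cols)
  list(x = as.matrix(x), meta = do.call(rbind, meta))
}

#' Read a schema file
#'
#' YAML or JSON schema declaring the cognitive column map, demographic
#' columns, and the dMRI attribute/tract metadata with left/right pairing.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return Schema list as required by [load_cohort()].
#' @export
read_schema <- function(path) {
  sch <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.list(sch$dmri) && !is.data.frame(sch$dmri)) {
    sch$dmri <- do.call(rbind, lapply(sch$dmri, function(e)
      data.frame(column = e$column %||% NA_character_,
                 left = e$left %||% NA_character_,
                 right = e$right %||% NA_character_,
                 attribute = e$attribute, tract = e$tract)))
  }
  sch$cognitive <- as.list(sch$cognitive)
  sch
}

#' Serialize standardization stats and a split to a JSON sidecar
#'
#' @param stats A `standardization_stats` object.
#' @param split A `split_spec`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_sidecar <- function(stats, split, path) {
  jsonlite::write_json(list(
    standardization = list(mean = as.list(stats$mean), sd = as.list(stats$sd),
                           ddof = stats$ddof),
    split = list(train = split$train, validation = split$validation,
                 test = split$test, seed = split$seed,
                 fractions = split$fractions)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
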