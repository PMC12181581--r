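#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_opticog <- function(msg, class) {
  stop(structure(class = c(class, "opticog_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Derive a named integer seed from a master seed
#'
#' One master seed spawns independent, reproducible substreams for the
#' pipeline stages (splitting, optimizing, simulating, ...). The derivation
#' is a small deterministic hash of the stream name folded into the master
#' seed, kept within the 32-bit integer range.
#'
#' @param seed Master integer seed.
#' @param stream Character stream name, e.g. `"cans"` or `"split"`.
#' @return An integer seed, deterministic in `(seed, stream)`.
#' @export
#' @examples
#' derive_seed(1, "split")
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stream))
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 131 + ch) %% 1000003L
  as.integer((abs(as.numeric(seed)) * 2654435 + h * 97 + 13) %% 2147483647)
}

# Keep any derived seed inside the 32-bit integer range.
wrap_seed <- function(seed) as.integer(abs(as.numeric(seed)) %% 2147483647)

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
with_local_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(wrap_seed(seed))
  expr
}

# Linear-interpolation (type 7) quantile, the convention used throughout.
q_linear <- function(x, p) unname(stats::quantile(x, p, type = 7, names = FALSE))
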