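# Constrained adaptive noise scaling (CANS): a simulated-annealing-style
# derivative-free search over the 7-parameter scoring vector. Each iteration
# perturbs the current best solution with iid Gaussian noise, projects the
# candidates onto the feasible sign domain, and keeps the best candidate if
# it improves the loss; the noise scale contracts on improvement and expands
# (capped) otherwise.

#' CANS optimizer configuration
#'
#' @param nc Candidates per iteration (>= 1).
#' @param j_max Total iterations.
#' @param delta_u Noise upscaling coefficient (> 1), applied when no
#'   improvement is found.
#' @param delta_l Noise downscaling coefficient in (0, 1), applied on
#'   improvement.
#' @param sigma_max Maximum noise scale (> 0).
#' @param sigma0 Initial noise scale in (0, sigma_max\].
#' @param seed Integer RNG seed; one stream per run, consumed in
#'   candidate-major order.
#' @return List of class `cans_config`.
#' @export
cans_config <- function(nc = 20, j_max = 200, delta_u = 1.1, delta_l = 0.9,
                        sigma_max = 1.0, sigma0 = 0.25, seed = 1) {
  if (nc < 1) stop_opticog("nc must be >= 1", "opticog_config_error")
  if (j_max < 0) stop_opticog("j_max must be >= 0", "opticog_config_error")
  if (delta_u <= 1) stop_opticog("delta_u must be > 1", "opticog_config_error")
  if (delta_l <= 0 || delta_l >= 1)
    stop_opticog("delta_l must lie in (0, 1)", "opticog_config_error")
  if (sigma_max <= 0) stop_opticog("sigma_max must be > 0", "opticog_config_error")
  if (sigma0 <= 0 || sigma0 > sigma_max)
    stop_opticog("sigma0 must lie in (0, sigma_max]", "opticog_config_error")
  structure(list(nc = as.integer(nc), j_max = as.integer(j_max),
                 delta_u = delta_u, delta_l = delta_l, sigma_max = sigma_max,
                 sigma0 = sigma0, seed = as.integer(seed)),
            class = "cans_config")
}

#' Generate feasible perturbed candidates
#'
#' Each candidate is `project_feasible(theta_c + eps)` with
#' `eps_i ~ iid Normal(0, sigma^2)` per coordinate, drawn from the current
#' RNG state in candidate-major order.
#'
#' @param theta_c Current best 7-vector.
#' @param sigma Noise scale (>= 0).
#' @param nc Number of candidates (>= 1).
#' @return `nc` x 7 matrix of feasible candidates.
#' @export
perturb_candidates <- function(theta_c, sigma, nc) {
  if (nc < 1) stop_opticog("nc must be >= 1", "opticog_config_error")
  if (sigma < 0) stop_opticog("sigma must be >= 0", "opticog_config_error")
  eps <- matrix(stats::rnorm(nc * 7, 0, sigma), nrow = nc, byrow = TRUE)
  t(apply(sweep(eps, 2, theta_c, "+"), 1, project_feasible))
}

#' Update the noise scale
#'
#' Contract by `delta_l` on improvement; otherwise expand by `delta_u`,
#' capped at `sigma_max`.
#'
#' @param sigma Current noise scale.
#' @param improved Logical: did this iteration improve the best loss?
#' @param cfg A `cans_config`.
#' @return Updated noise scale.
#' @export
update_noise_scale <- function(sigma, improved, cfg) {
  if (improved) sigma * cfg$delta_l else min(sigma * cfg$delta_u, cfg$sigma_max)
}

#' Run the CANS optimizer
#'
#' Minimizes `loss_fn` over feasible 7-vectors. Per iteration: draw `nc`
#' Gaussian perturbations of the current best, project them feasible,
#' evaluate all, and take the arg-min (lowest index wins ties). A strictly
#' smaller loss replaces the incumbent and contracts the noise scale;
#' otherwise the scale expands up to `sigma_max`. The best-loss sequence is
#' therefore non-increasing, and runs are reproducible given the seed.
#'
#' @param loss_fn Function: feasible 7-vector -> finite real loss.
#' @param theta_init Initial 7-vector (projected feasible if necessary).
#' @param cfg A `cans_config`.
#' @return List of class `cans_result`: `theta_star`, `loss_star`, and
#'   `trace` (data.frame: iteration, sigma, best_loss, plus the best theta
#'   per iteration as columns `theta0`..`theta6`).
#' @export
#' @examples
#' res <- cans_optimize(function(th) (th[1] - 3)^2, rep(0, 7),
#'                      cans_config(nc = 20, j_max = 200, seed = 7))
#' res$theta_star[1]
cans_optimize <- function(loss_fn, theta_init, cfg = cans_config()) {
  theta_best <- project_feasible(theta_init)
  loss_best <- loss_fn(theta_best)
  if (!is.finite(loss_best))
    stop_opticog("loss_fn returned a non-finite value at theta_init",
                 "opticog_loss_error")
  sigma <- cfg$sigma0
  tr_it <- integer(cfg$j_max); tr_sig <- tr_loss <- numeric(cfg$j_max)
  tr_theta <- matrix(NA_real_, cfg$j_max, 7,
                     dimnames = list(NULL, paste0("theta", 0:6)))
  with_local_seed(cfg$seed, {
    for (j in seq_len(cfg$j_max)) {
      cand <- perturb_candidates(theta_best, sigma, cfg$nc)
      losses <- apply(cand, 1, loss_fn)
      if (any(!is.finite(losses))) {
        bad <- which(!is.finite(losses))[1]
        stop_opticog(sprintf(
          "loss_fn returned a non-finite value at iteration %d, candidate %d",
          j, bad), "opticog_loss_error")
      }
      k <- which.min(losses)     # lowest index wins ties
      improved <- losses[k] < loss_best
      if (improved) {
        loss_best <- losses[k]
        theta_best <- cand[k, ]
      }
      sigma <- update_noise_scale(sigma, improved, cfg)
      tr_it[j] <- j; tr_sig[j] <- sigma; tr_loss[j] <- loss_best
      tr_theta[j, ] <- theta_best
    }
  })
  trace <- cbind(data.frame(iteration = tr_it, sigma = tr_sig,
                            best_loss = tr_loss), as.data.frame(tr_theta))
  structure(list(theta_star = theta_best, loss_star = loss_best, trace = trace,
                 config = cfg), class = "cans_result")
}

#' @export
print.cans_result <- function(x, ...) {
  cat(sprintf("CANS result: best loss %.5f after %d iterations\n",
              x$loss_star, nrow(x$trace)))
  cat("  theta*:", paste(sprintf("%.4f", x$theta_star), collapse = ", "), "\n")
  invisible(x)
}
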