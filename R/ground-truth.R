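#' Draw the ground truth for one synthetic subject
#'
#' Constructs, per ROI, a baseline mean pattern, a unit sensory axis `s`, a
#' unit non-sensory attention axis `a` orthogonal to `s`, and a voxel noise
#' covariance of the form "heterogeneous diagonal plus low-rank shared
#' components".  Both axes are also orthogonal to the uniform (all-ones)
#' direction, so condition and gain modulations leave the regional mean
#' response untouched; this makes the dissociation between informational
#' connectivity and mean-BOLD connectivity structural rather than
#' approximate.
#'
#' @param config A [sim_config()].
#' @param effect An [effect_params()] object.
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return An object of class `ground_truth`: per-ROI list with `mu`, `s`,
#'   `a`, `lambda`, `sigma_diag` (diagonal variances) and `sigma_load`
#'   (voxels x rank loading matrix; the noise covariance is
#'   `diag(sigma_diag) + sigma_load %*% t(sigma_load)`), plus the scalar
#'   effect parameters.
#' @export
#' @examples
#' gt <- make_ground_truth(sim_config(), effect_params(), seed = 1)
#' names(gt$roi)
make_ground_truth <- function(config, effect = effect_params(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"), inherits(effect, "effect_params"))
  v <- config$n_voxels
  # lambda entries for ROIs outside the config are ignored, so a subset of
  # the default ROI set can be simulated with the default effects
  roi <- with_seed(seed, {
    out <- vector("list", length(config$rois))
    names(out) <- config$rois
    ones <- rep(1, v) / sqrt(v)
    for (r in config$rois) {
      mu <- rnorm(v, 0, 0.5)
      # sensory axis: unit, orthogonal to the uniform direction
      s <- rnorm(v)
      s <- s - sum(s * ones) * ones
      s <- s / sqrt(sum(s^2))
      # attention axis: unit, orthogonal to both s and the uniform direction
      a <- rnorm(v)
      a <- a - sum(a * ones) * ones - sum(a * s) * s
      a <- a / sqrt(sum(a^2))
      sigma_diag <- effect$noise_scale^2 * runif(v, 0.5, 1.5)
      k <- effect$noise_rank
      sigma_load <- if (k > 0L) {
        matrix(rnorm(v * k, 0, effect$noise_scale * 0.4 / sqrt(k)), v, k)
      } else {
        matrix(0, v, 0L)
      }
      lam <- if (r %in% names(effect$lambda)) unname(effect$lambda[[r]]) else 0
      out[[r]] <- list(mu = mu, s = s, a = a, lambda = lam,
                       sigma_diag = sigma_diag, sigma_load = sigma_load)
    }
    out
  })
  structure(
    list(roi = roi, effect = effect, n_voxels = v, seed = as.integer(seed)),
    class = "ground_truth"
  )
}

#' Full noise covariance matrix of one ROI
#'
#' @param gt A [make_ground_truth()] object.
#' @param roi ROI name.
#' @return The voxel noise covariance `diag(d) + W W'` (positive definite).
#' @export
gt_noise_covariance <- function(gt, roi) {
  stopifnot(inherits(gt, "ground_truth"))
  r <- gt$roi[[roi]]
  if (is.null(r)) stop("unknown ROI: ", roi, call. = FALSE)
  diag(r$sigma_diag) + tcrossprod(r$sigma_load)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Ground truth:", length(x$roi), "ROIs x", x$n_voxels, "voxels\n")
  lam <- vapply(x$roi, `[[`, numeric(1), "lambda")
  cat("  ping gains (lambda):",
      paste(sprintf("%s=%.2f", names(lam), lam), collapse = ", "), "\n")
  cat("  beta_att =", x$effect$beta_att, " beta_sens =", x$effect$beta_sens,
      " g =", x$effect$g, "\n")
  invisible(x)
}
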