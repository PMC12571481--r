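#' @keywords internal
#' @importFrom stats rnorm runif dgamma quantile sd cor cor.test t.test
#'   setNames
#' @importFrom utils modifyList read.csv write.csv
#' @importFrom tools md5sum
"_PACKAGE"

# Deterministic child-seed derivation: one master seed, per-subject / per-run /
# per-stage children.  Mixing is done in double precision below 2^31 so the
# result is always a valid R integer seed.
child_seed <- function(seed, ...) {
  keys <- list(...)
  h <- as.double(seed) %% 2147483629
  for (k in keys) {
    if (is.character(k)) k <- sum(utf8ToInt(k) * seq_along(utf8ToInt(k)))
    for (v in as.double(k)) {
      h <- (h * 69069 + v + 13579) %% 2147483629
    }
  }
  as.integer(h)
}

# Evaluate expr with a local RNG state seeded at `seed`, restoring the caller's
# state afterwards, so library code never disturbs the user's RNG stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Fisher z-transform with clipping
#'
#' Applies `atanh()` after clipping `|r|` to `1 - 1e-6`, so self-correlations
#' and degenerate series yield large finite values rather than `Inf`.
#'
#' @param r Pearson correlation(s).
#' @return Fisher-z value(s), same shape as `r`.
#' @export
fisher_z <- function(r) {
  stopifnot(is.numeric(r))
  atanh(pmin(pmax(r, -1 + 1e-6), 1 - 1e-6))
}

stop_if_not_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a probability in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

stop_if_not_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != round(x)) {
    stop(sprintf("`%s` must be an integer >= %d", name, min), call. = FALSE)
  }
  invisible(x)
}

# Population SD (divide by n); the z-normalization convention of the package.
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
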