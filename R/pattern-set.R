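#' Trial-by-voxel pattern set
#'
#' The universal currency of the pipeline: a trials x voxels matrix of
#' response amplitudes for one ROI, with an aligned trial-metadata table.
#'
#' @param roi ROI name.
#' @param matrix Numeric matrix, one row per trial.
#' @param meta Data frame with one row per trial (columns such as `subject`,
#'   `session`, `task`, `period`, `orientation`, `run`,
#'   `trial_index_in_run`, `delay`, `correct`, `rt`).
#' @param normalization_state `"raw"` or `"znormalized"`.
#' @return An object of class `pattern_set`.
#' @export
pattern_set <- function(roi, matrix, meta, normalization_state = "raw") {
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    stop("`matrix` must be a numeric matrix", call. = FALSE)
  }
  if (!is.data.frame(meta) || nrow(meta) != nrow(matrix)) {
    stop("`meta` must be a data frame with one row per pattern row",
         call. = FALSE)
  }
  if (anyNA(matrix)) stop("pattern matrix contains missing values",
                          call. = FALSE)
  normalization_state <- match.arg(normalization_state,
                                   c("raw", "znormalized"))
  rownames(meta) <- NULL
  structure(list(roi = roi, matrix = matrix, meta = meta,
                 normalization_state = normalization_state),
            class = "pattern_set")
}

#' @export
print.pattern_set <- function(x, ...) {
  cat("Pattern set [", x$roi, "]: ", nrow(x$matrix), " trials x ",
      ncol(x$matrix), " voxels (", x$normalization_state, ")\n", sep = "")
  invisible(x)
}

#' @export
dim.pattern_set <- function(x) dim(x$matrix)

# Row subset keeping matrix and meta aligned.
subset_pattern_set <- function(ps, idx) {
  pattern_set(ps$roi, ps$matrix[idx, , drop = FALSE],
              ps$meta[idx, , drop = FALSE], ps$normalization_state)
}
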