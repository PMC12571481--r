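# Plain-text on-disk container for subject datasets and tidy outputs:
# one CSV matrix per ROI x period, CSV trial tables, JSON manifests.

#' Write a subject dataset to a directory
#'
#' Layout: `<dir>/<subject>.<session>/trials_<task>.csv` for the trial
#' tables and `pattern_<roi>_<period>.csv` for each trial-by-voxel matrix,
#' plus `dataset.json` with identifiers and subject-level parameters.  The
#' ground truth itself is not serialized (datasets on disk look like
#' ingested data).
#'
#' @param ds A [simulate_subject()] dataset.
#' @param dir Output directory (created if needed).
#' @return The dataset directory, invisibly.
#' @export
write_subject_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "subject_dataset"))
  sub_dir <- file.path(dir, paste(ds$subject, ds$session, sep = "."))
  dir.create(sub_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(ds$meta$attention,
                   file.path(sub_dir, "trials_attention.csv"),
                   row.names = FALSE)
  utils::write.csv(ds$meta$perception,
                   file.path(sub_dir, "trials_perception.csv"),
                   row.names = FALSE)
  for (roi in names(ds$patterns)) {
    for (period in names(ds$patterns[[roi]])) {
      utils::write.csv(ds$patterns[[roi]][[period]],
                       file.path(sub_dir,
                                 sprintf("pattern_%s_%s.csv", roi, period)),
                       row.names = FALSE)
    }
  }
  info <- list(subject = ds$subject, session = ds$session,
               rois = names(ds$patterns),
               n_voxels = ds$config$n_voxels,
               params = ds$params[c("propensity", "accuracy", "rt0")])
  jsonlite::write_json(info, file.path(sub_dir, "dataset.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(sub_dir)
}

#' Read a subject dataset written by [write_subject_dataset()]
#'
#' @param sub_dir The `<subject>.<session>` directory.
#' @param config The [sim_config()] the dataset was generated under.
#' @return A `subject_dataset` (without ground truth).
#' @export
read_subject_dataset <- function(sub_dir, config) {
  info <- jsonlite::read_json(file.path(sub_dir, "dataset.json"),
                              simplifyVector = TRUE)
  att <- utils::read.csv(file.path(sub_dir, "trials_attention.csv"),
                         stringsAsFactors = FALSE)
  perc <- utils::read.csv(file.path(sub_dir, "trials_perception.csv"),
                          stringsAsFactors = FALSE)
  att$onset <- as.numeric(att$onset)
  perc$onset <- as.numeric(perc$onset)
  perc$delay <- as.character(perc$delay)
  patterns <- list()
  for (roi in info$rois) {
    patterns[[roi]] <- list()
    for (period in c("preparation", "selection", "perception")) {
      f <- file.path(sub_dir, sprintf("pattern_%s_%s.csv", roi, period))
      patterns[[roi]][[period]] <- as.matrix(
        utils::read.csv(f, colClasses = "numeric"))
    }
  }
  structure(
    list(subject = info$subject, session = info$session,
         meta = list(attention = att, perception = perc),
         patterns = patterns, gt = NULL, config = config,
         params = info$params, gain = NULL),
    class = "subject_dataset"
  )
}

# Manifest of output files with md5 content hashes.
build_manifest <- function(files, root) {
  files <- sort(files)
  hashes <- unname(tools::md5sum(files))
  data.frame(file = sub(paste0("^", root, "/?"), "", files),
             md5 = hashes, stringsAsFactors = FALSE)
}
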