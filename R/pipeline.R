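# Configuration-driven orchestration: simulate -> preprocess -> decode ->
# geometry -> connect -> infer, with seeding, logging, and a hashed output
# manifest.

PIPELINE_STAGES <- c("simulate", "preprocess", "decode", "geometry",
                     "connect", "infer")

#' Build a pipeline configuration
#'
#' Bundles the simulation design, ground-truth effect parameters, and
#' analysis settings; every field is validated by the underlying
#' constructors before any stage runs.
#'
#' @param sim Named list of [sim_config()] arguments.
#' @param effect Named list of [effect_params()] arguments (`lambda` may be
#'   a named list or vector of per-ROI gains).
#' @param analysis Named list: `shrinkage`, `n_perm`, `alpha`, `q`.
#' @param seed Master seed for the run.
#' @param out_dir Output directory.
#' @return A validated object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = list(), effect = list(),
                            analysis = list(), seed = 1L,
                            out_dir = tempfile("attmvpa_run_")) {
  if (!is.null(effect$lambda)) effect$lambda <- unlist(effect$lambda)
  cfg <- list(
    sim = do.call(sim_config, c(sim, list(seed = seed))),
    effect = do.call(effect_params, effect),
    analysis = utils::modifyList(
      list(shrinkage = 0.1, n_perm = 200L, alpha = 0.05, q = 0.25),
      analysis),
    seed = as.integer(seed),
    out_dir = out_dir
  )
  a <- cfg$analysis
  stop_if_not_scalar_prob(a$alpha, "analysis$alpha")
  if (a$shrinkage < 0 || a$shrinkage > 1) {
    stop("analysis$shrinkage must lie in [0, 1]", call. = FALSE)
  }
  stop_if_not_count(a$n_perm, "analysis$n_perm")
  if (a$q <= 0 || a$q > 0.5) stop("analysis$q must lie in (0, 0.5]",
                                  call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The file may contain `sim`, `effect`, `analysis`, `seed`, and `out_dir`
#' blocks; each is validated by [pipeline_config()].
#'
#' @param path YAML file path.
#' @param out_dir Optional override of the configured output directory.
#' @param seed Optional override of the configured seed.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, out_dir = NULL, seed = NULL) {
  y <- yaml::read_yaml(path)
  known <- c("sim", "effect", "analysis", "seed", "out_dir")
  bad <- setdiff(names(y), known)
  if (length(bad)) {
    stop("unknown config block(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  pipeline_config(
    sim = if (is.null(y$sim)) list() else y$sim,
    effect = if (is.null(y$effect)) list() else y$effect,
    analysis = if (is.null(y$analysis)) list() else y$analysis,
    seed = if (!is.null(seed)) seed else if (!is.null(y$seed)) y$seed else 1L,
    out_dir = if (!is.null(out_dir)) out_dir
              else if (!is.null(y$out_dir)) y$out_dir
              else tempfile("attmvpa_run_")
  )
}

pipeline_log <- function(quiet, stage, ...) {
  if (!quiet) {
    message(sprintf("[attmvpa] %-10s %s", stage,
                    paste(..., collapse = " ")))
  }
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in order on a synthetic cohort:
#' `simulate` writes the per-subject datasets and cohort manifest;
#' `preprocess` writes the trial-filtering report; `decode`, `geometry`,
#' and `connect` write tidy CSV tables of decoding accuracies, distance
#' geometry, and connectivity; `infer` writes the group-level summary
#' (decoding significance per session x ROI x scheme x period, and the
#' inter-subject AMI-behavior correlations).  Every output file is recorded
#' in `manifest.json` with an md5 content hash; a full run with identical
#' config and seed reproduces identical hashes.
#'
#' @param config A [pipeline_config()] (or path to a YAML file).
#' @param stages Subset of
#'   `c("simulate", "preprocess", "decode", "geometry", "connect", "infer")`
#'   or `"all"`.
#' @param quiet Suppress progress messages.
#' @return The manifest data frame (file, md5), invisibly; also written to
#'   `out_dir/manifest.json`.
#' @export
run_pipeline <- function(config, stages = "all", quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  if (identical(stages, "all")) stages <- PIPELINE_STAGES
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  add <- function(f) files <<- c(files, f)

  cohort <- NULL
  results <- NULL
  get_cohort <- function() {
    if (is.null(cohort)) {
      cohort <<- simulate_cohort(config$sim, config$effect,
                                 seed = config$seed)
    }
    cohort
  }
  get_results <- function() {
    if (is.null(results)) {
      if (!"simulate" %in% stages &&
          !file.exists(file.path(out, "cohort_manifest.csv"))) {
        stop("missing upstream artifact for stage '", setdiff(
          stages, "simulate")[1], "': ",
          file.path(out, "cohort_manifest.csv"),
          " (run the 'simulate' stage first)", call. = FALSE)
      }
      results <<- analyze_cohort(get_cohort(),
                                 shrinkage = config$analysis$shrinkage)
    }
    results
  }

  if ("simulate" %in% stages) {
    coh <- get_cohort()
    pipeline_log(quiet, "simulate", nrow(coh$manifest), "subject-sessions,",
                 "seed", config$seed)
    f <- file.path(out, "cohort_manifest.csv")
    utils::write.csv(coh$manifest, f, row.names = FALSE)
    add(f)
    data_dir <- file.path(out, "datasets")
    for (ds in coh$datasets) {
      sd <- write_subject_dataset(ds, data_dir)
      add(list.files(sd, full.names = TRUE))
    }
  }
  if ("preprocess" %in% stages) {
    coh <- get_cohort()
    reports <- lapply(coh$datasets, function(ds) {
      fl <- attr(filter_trials(subject_pattern_set(
        ds, names(ds$patterns)[1], "preparation")), "filter_log")
      c(list(subject = ds$subject, session = ds$session), fl)
    })
    pipeline_log(quiet, "preprocess", length(reports),
                 "filtering reports")
    f <- file.path(out, "filter_report.json")
    jsonlite::write_json(unname(reports), f, auto_unbox = TRUE, digits = NA)
    add(f)
  }
  if ("decode" %in% stages) {
    res <- get_results()
    pipeline_log(quiet, "decode", nrow(res$decoding), "decoding rows")
    f <- file.path(out, "decoding.csv")
    utils::write.csv(res$decoding, f, row.names = FALSE)
    add(f)
  }
  if ("geometry" %in% stages) {
    res <- get_results()
    pipeline_log(quiet, "geometry", nrow(res$geometry), "geometry rows")
    f <- file.path(out, "geometry.csv")
    utils::write.csv(res$geometry, f, row.names = FALSE)
    add(f)
  }
  if ("connect" %in% stages) {
    res <- get_results()
    pipeline_log(quiet, "connect", nrow(res$ic), "ROI-pair rows")
    f1 <- file.path(out, "informational_connectivity.csv")
    utils::write.csv(res$ic, f1, row.names = FALSE)
    f2 <- file.path(out, "mean_bold_connectivity.csv")
    utils::write.csv(res$mean_bold, f2, row.names = FALSE)
    add(c(f1, f2))
  }
  if ("infer" %in% stages) {
    res <- get_results()
    summary <- decoding_group_table(res$decoding,
                                    alpha = config$analysis$alpha)
    f <- file.path(out, "group_summary.csv")
    utils::write.csv(summary, f, row.names = FALSE)
    add(f)
    # inter-subject AMI (first ROI, preparation) vs mean RT per session
    geo1 <- res$geometry[res$geometry$roi == res$geometry$roi[1], ]
    corr <- lapply(split(geo1, geo1$session), function(g) {
      sess <- g$session[1]
      beh <- res$behavior[res$behavior$session == sess, ]
      common <- intersect(g$subject, beh$subject)
      if (length(common) < 3L) return(NULL)
      nb <- neural_behavior_correlation(
        stats::setNames(g$ami[match(common, g$subject)], common),
        stats::setNames(beh$mean_rt[match(common, beh$subject)], common))
      c(list(session = sess, roi = g$roi[1]), nb)
    })
    f2 <- file.path(out, "ami_rt_correlation.json")
    jsonlite::write_json(unname(Filter(Negate(is.null), corr)), f2,
                         auto_unbox = TRUE, digits = NA)
    add(f2)
    pipeline_log(quiet, "infer", nrow(summary), "summary cells")
  }

  manifest <- build_manifest(unlist(files), out)
  jsonlite::write_json(
    list(seed = config$seed, stages = stages, files = manifest),
    file.path(out, "manifest.json"), auto_unbox = TRUE, digits = NA)
  pipeline_log(quiet, "manifest", nrow(manifest), "files hashed")
  invisible(manifest)
}
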