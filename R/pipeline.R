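default_config <- function() {
  list(
    workdir = ".",
    resume_from = NULL,
    seed = 1,
    simulate = list(preset = NULL),
    import = list(table = NULL, sample_sheet = NULL, zero_as_missing = TRUE),
    clean = list(qc_thresh = 0.2, group_thresh = 0.2, impute_k = 10,
                 normalize = "svr", min_qc = 5),
    annotate = list(library = NULL, ms2 = NULL, ppm_tol = 25, rt_tol_s = 30,
                    ms2_score_min = 0.5, levels = c(1, 2, 3), dedup = "best"),
    dam = list(group_a = NULL, group_b = NULL, test = "t", fdr_method = "BH"),
    wgcna = list(power = NULL, min_module_size = 10, merge_cut = 0.25,
                 kme_cutoff = 0.5, hub_kme = 0.8, max_rounds = 10)
  )
}

merge_config <- function(config) {
  defaults <- default_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (nm in names(config)) {
    if (is.list(defaults[[nm]]) && is.list(config[[nm]])) {
      bad <- setdiff(names(config[[nm]]), names(defaults[[nm]]))
      if (length(bad) > 0) {
        stop("unknown config key(s) under '", nm, "': ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
      defaults[[nm]][names(config[[nm]])] <- config[[nm]]
    } else {
      defaults[[nm]] <- config[[nm]]
    }
  }
  defaults
}

#' Run the full pipeline from a declarative config
#'
#' Executes import (or simulate) -> clean -> annotate -> wgcna (and, when two
#' groups are named, the differential analysis), checkpointing each stage
#' under `<workdir>/Result/` so a later run can resume. With `resume_from`
#' set, checkpoints of earlier stages are verified and reused instead of
#' recomputed; a missing or corrupt checkpoint is a hard error naming the
#' stage to rerun. Unknown config keys are rejected, and the effective
#' config (defaults plus overrides) is written next to the results.
#'
#' @param config Named list of overrides over the built-in defaults (see
#'   the vignette); unknown keys error.
#' @return List with the final `dataset`, `annotations`, `dam`, `modules`
#'   (those that ran), and `config` (the effective config).
#' @export
run_pipeline <- function(config = list()) {
  cfg <- merge_config(config)
  result_dir <- file.path(cfg$workdir, "Result")
  if (!dir.exists(result_dir)) dir.create(result_dir, recursive = TRUE)
  jsonlite::write_json(cfg, file.path(result_dir, "effective_config.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")

  stages <- c("import", "clean", "annotate", "wgcna")
  resume_at <- if (is.null(cfg$resume_from)) 1L else {
    match(cfg$resume_from, stages)
  }
  if (is.na(resume_at)) {
    stop("resume_from must be one of: ", paste(stages, collapse = ", "),
         call. = FALSE)
  }
  use_checkpoint <- function(stage) {
    path <- file.path(result_dir, paste0(stage, ".rds"))
    if (!file.exists(path)) {
      stop("cannot resume: checkpoint for stage '", stage,
           "' is missing; rerun that stage", call. = FALSE)
    }
    restore_checkpoint(path)
  }

  out <- list(config = cfg)
  lib <- NULL

  # import / simulate
  if (resume_at > 1L) {
    ds <- use_checkpoint("import")
  } else {
    if (!is.null(cfg$simulate$preset)) {
      sim <- simulate_preset(cfg$simulate$preset, seed = cfg$seed)
      ds <- sim$dataset
      out$truth <- sim$truth
    } else {
      ds <- read_peak_table(cfg$import$table, cfg$import$sample_sheet,
                            zero_as_missing = cfg$import$zero_as_missing)
    }
    stopifnot_valid(ds)
    checkpoint(ds, "import", result_dir)
  }

  # clean
  if (resume_at > 2L) {
    ds <- use_checkpoint("clean")
  } else {
    ds <- filter_noise(ds, qc_thresh = cfg$clean$qc_thresh,
                       group_thresh = cfg$clean$group_thresh)
    triage <- triage_outliers(ds)
    if (length(triage$remove) > 0) ds <- drop_samples(ds, triage$remove)
    ds <- impute_knn(ds, k = cfg$clean$impute_k)
    if (identical(cfg$clean$normalize, "svr")) {
      ds <- normalize_svr_qc(ds, min_qc = cfg$clean$min_qc)
      ds <- integrate_batches(ds)
    }
    checkpoint(ds, "clean", result_dir)
  }

  # annotate (only when a library is configured)
  annotations <- NULL
  if (resume_at > 3L) {
    annot_path <- file.path(result_dir, "annotations.csv")
    if (file.exists(annot_path)) {
      annotations <- readr::read_csv(annot_path, show_col_types = FALSE,
                                     progress = FALSE)
    }
  } else if (!is.null(cfg$annotate$library)) {
    lib <- read_library(cfg$annotate$library, cfg$annotate$ms2)
    annotations <- annotate_features(
      ds, lib, ppm_tol = cfg$annotate$ppm_tol,
      rt_tol_s = cfg$annotate$rt_tol_s,
      ms2_score_min = cfg$annotate$ms2_score_min,
      levels_allowed = cfg$annotate$levels
    )
    if (identical(cfg$annotate$dedup, "best")) {
      annotations <- deduplicate_annotations(annotations)
    }
    readr::write_csv(annotations, file.path(result_dir, "annotations.csv"),
                     progress = FALSE)
  }

  # differential analysis (optional)
  if (!is.null(cfg$dam$group_a) && !is.null(cfg$dam$group_b)) {
    out$dam <- dam_analysis(ds, cfg$dam$group_a, cfg$dam$group_b,
                            test = cfg$dam$test,
                            fdr_method = cfg$dam$fdr_method)
    readr::write_csv(out$dam, file.path(result_dir, "dam.csv"),
                     progress = FALSE)
  }

  # iterative module detection
  x <- t(log2(ds$expression + 1))
  modules <- iterative_wgcna(
    x, power = cfg$wgcna$power,
    min_module_size = cfg$wgcna$min_module_size,
    merge_cut = cfg$wgcna$merge_cut, kme_cutoff = cfg$wgcna$kme_cutoff,
    hub_kme = cfg$wgcna$hub_kme, max_rounds = cfg$wgcna$max_rounds
  )
  readr::write_csv(modules$assignments,
                   file.path(result_dir, "module_assignments.csv"),
                   progress = FALSE)
  readr::write_csv(modules$rounds, file.path(result_dir, "wgcna_rounds.csv"),
                   progress = FALSE)

  out$dataset <- ds
  out$annotations <- annotations
  out$modules <- modules
  out
}
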