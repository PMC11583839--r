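#' Assemble a metabolomics dataset
#'
#' Bundles a features-by-samples intensity matrix with sample metadata,
#' feature metadata, optional MS2 spectra, and an append-only operation log.
#' This container is the unit every pipeline stage consumes and returns, so
#' that provenance (what was filtered, imputed, normalized, with which
#' parameters) travels with the data.
#'
#' @param expression Numeric matrix, features in rows, samples in columns.
#'   Missing measurements are `NA` (never 0; a zero peak area means
#'   "not detected" and is converted at read time).
#' @param sample_info Data frame with columns `sample_id`, `class`
#'   (one of `"Subject"`, `"QC"`, `"Blank"`), `group`, `batch`,
#'   `injection_order`.
#' @param feature_info Data frame with columns `feature_id`, `mz` (Da),
#'   `rt` (seconds), `polarity` (`"pos"`/`"neg"`), optional `adduct`.
#' @param ms2 Named list mapping `feature_id` to a list of spectra as
#'   returned by [read_mgf()].
#' @param log Optional existing log tibble (used internally when rebuilding
#'   a dataset from a checkpoint).
#'
#' @return An object of class `metabo_dataset`.
#' @export
metabo_dataset <- function(expression, sample_info, feature_info,
                           ms2 = list(), log = NULL) {
  expression <- as.matrix(expression)
  storage.mode(expression) <- "double"
  sample_info <- tibble::as_tibble(sample_info)
  feature_info <- tibble::as_tibble(feature_info)
  rownames(expression) <- feature_info$feature_id
  colnames(expression) <- sample_info$sample_id
  x <- structure(
    list(
      expression = expression,
      sample_info = sample_info,
      feature_info = feature_info,
      ms2 = ms2,
      log = if (is.null(log)) empty_log() else tibble::as_tibble(log)
    ),
    class = "metabo_dataset"
  )
  x
}

empty_log <- function() {
  tibble::tibble(
    stage = character(),
    params = character(),
    n_features_in = integer(),
    n_features_out = integer(),
    n_samples_in = integer(),
    n_samples_out = integer(),
    timestamp = character()
  )
}

#' Append a log entry to a dataset
#'
#' Every pipeline operation records exactly one entry: stage name, its
#' parameters (serialized as JSON), and the feature/sample counts before and
#' after. The log is append-only.
#'
#' @param x A `metabo_dataset`.
#' @param stage Stage name.
#' @param params Named list of parameters.
#' @param before A `metabo_dataset` (or dim-like list) giving input counts;
#'   defaults to `x` itself.
#' @return `x` with one more log row.
#' @export
log_operation <- function(x, stage, params = list(), before = x) {
  entry <- tibble::tibble(
    stage = stage,
    params = as.character(jsonlite::toJSON(params, auto_unbox = TRUE)),
    n_features_in = nrow(before$expression),
    n_features_out = nrow(x$expression),
    n_samples_in = ncol(before$expression),
    n_samples_out = ncol(x$expression),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  x$log <- dplyr::bind_rows(x$log, entry)
  x
}

#' Validate a metabolomics dataset
#'
#' Report-only structural check: dimension agreement between matrix and
#' metadata, unique feature and sample ids, non-negative intensities, unique
#' injection order within batch, and availability of QC samples (several
#' stages are QC-anchored and are unavailable without them).
#'
#' @param dataset A `metabo_dataset`.
#' @return A list with `ok` (logical) and `issues`, a tibble with columns
#'   `severity` (`"error"`/`"warning"`) and `message`. The dataset is never
#'   modified.
#' @export
validate_dataset <- function(dataset) {
  issues <- list()
  add <- function(severity, message) {
    issues[[length(issues) + 1L]] <<- tibble::tibble(
      severity = severity, message = message
    )
  }
  e <- dataset$expression
  if (nrow(e) != nrow(dataset$feature_info)) {
    add("error", sprintf(
      "expression has %d rows but feature_info has %d entries",
      nrow(e), nrow(dataset$feature_info)
    ))
  }
  if (ncol(e) != nrow(dataset$sample_info)) {
    add("error", sprintf(
      "expression has %d columns but sample_info has %d entries",
      ncol(e), nrow(dataset$sample_info)
    ))
  }
  dup_f <- unique(dataset$feature_info$feature_id[
    duplicated(dataset$feature_info$feature_id)
  ])
  if (length(dup_f) > 0) {
    add("error", paste0("duplicate feature id: ", paste(dup_f, collapse = ", ")))
  }
  dup_s <- unique(dataset$sample_info$sample_id[
    duplicated(dataset$sample_info$sample_id)
  ])
  if (length(dup_s) > 0) {
    add("error", paste0("duplicate sample id: ", paste(dup_s, collapse = ", ")))
  }
  if (any(e < 0, na.rm = TRUE)) {
    add("error", sprintf("%d negative intensities", sum(e < 0, na.rm = TRUE)))
  }
  bad_class <- setdiff(unique(dataset$sample_info$class),
                       c("Subject", "QC", "Blank"))
  if (length(bad_class) > 0) {
    add("error", paste0("unknown sample class: ", paste(bad_class, collapse = ", ")))
  }
  ord <- dplyr::count(dataset$sample_info, .data$batch, .data$injection_order)
  if (any(ord$n > 1)) {
    add("error", "injection_order not unique within batch")
  }
  if (!any(dataset$sample_info$class == "QC")) {
    add("warning", "no QC samples: QC-dependent stages unavailable")
  }
  if ("mz" %in% names(dataset$feature_info) &&
      any(dataset$feature_info$mz <= 0, na.rm = TRUE)) {
    add("error", "feature mz must be positive")
  }
  issues <- if (length(issues) == 0) {
    tibble::tibble(severity = character(), message = character())
  } else {
    dplyr::bind_rows(issues)
  }
  list(ok = !any(issues$severity == "error"), issues = issues)
}

#' @export
print.metabo_dataset <- function(x, ...) {
  cls <- table(x$sample_info$class)
  cat(sprintf(
    "<metabo_dataset> %d features x %d samples (%s)\n",
    nrow(x$expression), ncol(x$expression),
    paste(sprintf("%s: %d", names(cls), as.integer(cls)), collapse = ", ")
  ))
  miss <- mean(is.na(x$expression))
  cat(sprintf("  missing: %.1f%%   MS2 spectra for %d features\n",
              100 * miss, length(x$ms2)))
  if (nrow(x$log) > 0) {
    cat(sprintf("  log: %s\n", paste(x$log$stage, collapse = " -> ")))
  }
  invisible(x)
}

#' Intensity matrix as a long tibble
#'
#' @param x A `metabo_dataset`.
#' @param ... Unused.
#' @return Tibble with one row per feature-sample pair (`feature_id`,
#'   `sample_id`, `intensity`), joined with sample class/group/batch.
#' @method tidy metabo_dataset
#' @export
tidy.metabo_dataset <- function(x, ...) {
  tibble::as_tibble(x$expression, rownames = "feature_id") |>
    tidyr::pivot_longer(-"feature_id",
                        names_to = "sample_id", values_to = "intensity") |>
    dplyr::left_join(x$sample_info, by = "sample_id")
}

#' One-row dataset summary
#'
#' @param x A `metabo_dataset`.
#' @param ... Unused.
#' @return One-row tibble with dimensions, class counts, missing fraction and
#'   log length.
#' @method glance metabo_dataset
#' @export
glance.metabo_dataset <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x$expression),
    n_samples = ncol(x$expression),
    n_qc = sum(x$sample_info$class == "QC"),
    n_subject = sum(x$sample_info$class == "Subject"),
    n_batches = dplyr::n_distinct(x$sample_info$batch),
    missing_fraction = mean(is.na(x$expression)),
    n_log_entries = nrow(x$log)
  )
}

CHECKPOINT_SCHEMA <- "metabnet/metabo_dataset/1"

#' Checkpoint a dataset to disk
#'
#' Serializes the full container (matrix, metadata, spectra, log) as a
#' versioned artifact named after the pipeline stage, so an interrupted
#' analysis can resume from the last finished step. Files whose schema id is
#' unknown are rejected on restore rather than guessed at.
#'
#' @param dataset A `metabo_dataset`.
#' @param stage Stage name; becomes the file name.
#' @param dir Directory (created if needed), conventionally
#'   `<workdir>/Result`.
#' @return The path written, invisibly usable by [restore_checkpoint()].
#' @export
checkpoint <- function(dataset, stage, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create checkpoint directory: ", dir)
  }
  path <- file.path(dir, paste0(stage, ".rds"))
  saveRDS(list(schema = CHECKPOINT_SCHEMA, stage = stage,
               payload = unclass(dataset)), path)
  path
}

#' Restore a checkpointed dataset
#'
#' @param path Path written by [checkpoint()].
#' @return The `metabo_dataset`, equal to the one checkpointed (matrix values
#'   bitwise identical, log preserved).
#' @export
restore_checkpoint <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop("corrupt checkpoint: ", path, " (", conditionMessage(e), ")",
         call. = FALSE)
  })
  if (!is.list(obj) || !identical(obj$schema, CHECKPOINT_SCHEMA)) {
    stop("corrupt checkpoint: ", path,
         " (unknown or missing schema id)", call. = FALSE)
  }
  p <- obj$payload
  metabo_dataset(p$expression, p$sample_info, p$feature_info,
                 ms2 = p$ms2, log = p$log)
}

# internal: expression submatrix for a sample class
class_matrix <- function(dataset, class) {
  ids <- dataset$sample_info$sample_id[dataset$sample_info$class == class]
  dataset$expression[, ids, drop = FALSE]
}

stopifnot_valid <- function(dataset) {
  v <- validate_dataset(dataset)
  if (!v$ok) {
    stop("invalid dataset: ",
         paste(v$issues$message[v$issues$severity == "error"], collapse = "; "),
         call. = FALSE)
  }
  invisible(dataset)
}
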