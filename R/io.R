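#' Read a peak-picking table plus sample sheet into a dataset
#'
#' The peak table is delimited text with columns `feature_id`, `mz`, `rt`,
#' then one intensity column per sample. The sample sheet maps `sample_id`
#' to `class`, `group`, `batch`, `injection_order`. The delimiter is sniffed
#' among comma, tab and semicolon (decimal point only).
#'
#' @param table Path to the peak table.
#' @param sample_sheet Path to the sample sheet.
#' @param zero_as_missing Treat intensity 0 as missing (`NA`). Default `TRUE`:
#'   a peak area of zero means the feature was not detected in that
#'   injection, and the missing-rate filters must see it as absent.
#' @param rt_unit `"auto"` (default), `"seconds"` or `"minutes"`. Under
#'   `"auto"`, a maximum RT above 120 is taken as seconds, otherwise minutes;
#'   minutes are converted so RT is always stored in seconds. The decision is
#'   logged.
#' @param polarity Polarity assigned to features lacking a `polarity` column.
#' @return A `metabo_dataset` with an `"import"` log entry.
#' @export
read_peak_table <- function(table, sample_sheet, zero_as_missing = TRUE,
                            rt_unit = c("auto", "seconds", "minutes"),
                            polarity = "pos") {
  rt_unit <- match.arg(rt_unit)
  tab <- read_delim_sniff(table)
  sheet <- read_delim_sniff(sample_sheet)

  need <- c("feature_id", "mz", "rt")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0) {
    stop("peak table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  need_sheet <- c("sample_id", "class", "group", "batch", "injection_order")
  missing_sheet <- setdiff(need_sheet, names(sheet))
  if (length(missing_sheet) > 0) {
    stop("sample sheet is missing mandatory column(s): ",
         paste(missing_sheet, collapse = ", "), call. = FALSE)
  }

  meta_cols <- intersect(c("feature_id", "mz", "rt", "polarity", "adduct"),
                         names(tab))
  sample_cols <- setdiff(names(tab), meta_cols)
  absent <- setdiff(sheet$sample_id, sample_cols)
  if (length(absent) > 0) {
    stop("sample(s) in sheet absent from peak table: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  orphan <- setdiff(sample_cols, sheet$sample_id)
  if (length(orphan) > 0) {
    warning("peak-table column(s) not in sample sheet (dropped): ",
            paste(orphan, collapse = ", "), call. = FALSE)
  }

  expr <- as.matrix(tab[, sheet$sample_id, drop = FALSE])
  storage.mode(expr) <- "double"
  if (zero_as_missing) expr[expr == 0] <- NA_real_

  rt <- tab$rt
  detected_minutes <- switch(rt_unit,
    auto = max(rt, na.rm = TRUE) <= 120,
    minutes = TRUE,
    seconds = FALSE
  )
  if (detected_minutes) rt <- rt * 60

  fi <- tibble::tibble(
    feature_id = as.character(tab$feature_id),
    mz = as.numeric(tab$mz),
    rt = as.numeric(rt),
    polarity = if ("polarity" %in% names(tab)) tab$polarity else polarity,
    adduct = if ("adduct" %in% names(tab)) tab$adduct else NA_character_
  )
  si <- tibble::tibble(
    sample_id = as.character(sheet$sample_id),
    class = as.character(sheet$class),
    group = as.character(sheet$group),
    batch = as.character(sheet$batch),
    injection_order = as.integer(sheet$injection_order)
  )
  ds <- metabo_dataset(expr, si, fi)
  log_operation(ds, "import", params = list(
    table = basename(table), zero_as_missing = zero_as_missing,
    rt_unit = if (detected_minutes) "minutes(converted)" else "seconds"
  ))
}

read_delim_sniff <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  counts <- vapply(c(",", "\t", ";"), function(d) {
    lengths(regmatches(header, gregexpr(d, header, fixed = TRUE)))
  }, integer(1))
  delim <- names(counts)[which.max(counts)]
  # base parser: correctly rounded float parsing keeps text round trips exact
  tibble::as_tibble(utils::read.table(
    path, header = TRUE, sep = delim, check.names = FALSE,
    stringsAsFactors = FALSE, strip.white = TRUE, comment.char = ""
  ))
}

#' Read MS2 spectra from an MGF file
#'
#' Parses Mascot-generic-format `BEGIN IONS`/`END IONS` blocks. The feature
#' key is `FEATURE_ID=` when present, else `TITLE=`. A feature may carry
#' several scans; all are kept. Fragment lists are returned sorted ascending
#' by m/z.
#'
#' @param file Path to the MGF file.
#' @return Named list: `feature_id` -> list of spectra. Each spectrum is a
#'   list with `precursor_mz`, `polarity`, `rt` (seconds or `NA`) and
#'   `peaks`, a two-column matrix (`mz`, `intensity`).
#' @export
read_mgf <- function(file) {
  lines <- readLines(file)
  out <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (trimws(lines[i]) == "BEGIN IONS") {
      start <- i
      key <- NULL
      title <- NULL
      pepmass <- NA_real_
      rt <- NA_real_
      charge <- ""
      peaks <- list()
      i <- i + 1L
      ended <- FALSE
      while (i <= n) {
        ln <- trimws(lines[i])
        if (ln == "END IONS") { ended <- TRUE; break }
        if (grepl("^FEATURE_ID=", ln)) {
          key <- sub("^FEATURE_ID=", "", ln)
        } else if (grepl("^TITLE=", ln)) {
          title <- sub("^TITLE=", "", ln)
        } else if (grepl("^PEPMASS=", ln)) {
          pepmass <- as.numeric(strsplit(sub("^PEPMASS=", "", ln), "\\s+")[[1]][1])
        } else if (grepl("^RTINSECONDS=", ln)) {
          rt <- as.numeric(sub("^RTINSECONDS=", "", ln))
        } else if (grepl("^CHARGE=", ln)) {
          charge <- sub("^CHARGE=", "", ln)
        } else if (grepl("^[0-9]", ln)) {
          peaks[[length(peaks) + 1L]] <- as.numeric(strsplit(ln, "\\s+")[[1]][1:2])
        }
        i <- i + 1L
      }
      if (!ended) {
        stop(sprintf("unterminated BEGIN IONS block starting at line %d", start),
             call. = FALSE)
      }
      id <- if (!is.null(key)) key else title
      if (is.null(id)) {
        warning(sprintf("MGF block at line %d has no FEATURE_ID or TITLE; skipped",
                        start), call. = FALSE)
      } else if (length(peaks) == 0) {
        warning(sprintf("MGF block '%s' has no peaks; skipped", id), call. = FALSE)
      } else {
        pk <- do.call(rbind, peaks)
        colnames(pk) <- c("mz", "intensity")
        pk <- pk[order(pk[, "mz"]), , drop = FALSE]
        spec <- list(
          precursor_mz = pepmass,
          polarity = if (grepl("-", charge, fixed = TRUE)) "neg" else "pos",
          rt = rt,
          peaks = pk
        )
        out[[id]] <- c(out[[id]], list(spec))
      }
    }
    i <- i + 1L
  }
  out
}

#' Write MS2 spectra to an MGF file
#'
#' @param ms2 Named list as produced by [read_mgf()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_mgf <- function(ms2, file) {
  con <- file(file, "w")
  on.exit(close(con))
  for (id in names(ms2)) {
    for (spec in ms2[[id]]) {
      writeLines("BEGIN IONS", con)
      writeLines(paste0("FEATURE_ID=", id), con)
      writeLines(sprintf("PEPMASS=%.10g", spec$precursor_mz), con)
      if (!is.na(spec$rt)) writeLines(sprintf("RTINSECONDS=%.10g", spec$rt), con)
      writeLines(paste0("CHARGE=1", if (identical(spec$polarity, "neg")) "-" else "+"),
                 con)
      apply(spec$peaks, 1, function(p) {
        writeLines(sprintf("%.10g %.10g", p[1], p[2]), con)
      })
      writeLines("END IONS", con)
      writeLines("", con)
    }
  }
  invisible(file)
}

#' Read a spectral library
#'
#' The MS1 table is delimited text with columns `compound_id`, `name`,
#' `formula`, `monoisotopic_mass` and optional `rt`, class labels
#' (`superclass`/`class`/`subclass`) and `pathway`. Reference MS2 spectra may
#' be supplied in MSP (NIST text) or MGF form; MSP spectra are keyed by their
#' `Name:` field, MGF spectra by `FEATURE_ID`/`TITLE`, both matched to
#' `compound_id`.
#'
#' @param ms1_table Path to the MS1 record table.
#' @param ms2_file Optional path to an MSP or MGF spectra file.
#' @return A `spectral_library`: list with `compounds` (tibble) and `ms2`
#'   (named list keyed by compound_id). Orphan spectra (ids absent from the
#'   MS1 table) are reported via warning and dropped.
#' @export
read_library <- function(ms1_table, ms2_file = NULL) {
  comp <- read_delim_sniff(ms1_table)
  need <- c("compound_id", "name", "formula", "monoisotopic_mass")
  missing_cols <- setdiff(need, names(comp))
  if (length(missing_cols) > 0) {
    stop("library MS1 table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  dup <- unique(comp$compound_id[duplicated(comp$compound_id)])
  if (length(dup) > 0) {
    stop("compound_id collision in library: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  bad <- comp$monoisotopic_mass <= 0 | is.na(comp$monoisotopic_mass)
  if (any(bad)) {
    warning(sum(bad), " library record(s) rejected: non-positive mass",
            call. = FALSE)
    comp <- comp[!bad, , drop = FALSE]
  }
  for (col in c("rt", "superclass", "class", "subclass", "pathway")) {
    if (!col %in% names(comp)) {
      comp[[col]] <- if (col == "rt") NA_real_ else NA_character_
    }
  }
  ms2 <- list()
  if (!is.null(ms2_file)) {
    first <- readLines(ms2_file, n = 50L)
    ms2 <- if (any(grepl("^BEGIN IONS", trimws(first)))) {
      read_mgf(ms2_file)
    } else {
      read_msp(ms2_file)
    }
    orphan <- setdiff(names(ms2), comp$compound_id)
    if (length(orphan) > 0) {
      warning("orphan MS2 spectra (no MS1 record): ",
              paste(orphan, collapse = ", "), call. = FALSE)
      ms2 <- ms2[setdiff(names(ms2), orphan)]
    }
  }
  structure(
    list(compounds = tibble::as_tibble(comp), ms2 = ms2),
    class = "spectral_library"
  )
}

#' @export
print.spectral_library <- function(x, ...) {
  cat(sprintf("<spectral_library> %d compounds, %d with MS2 spectra\n",
              nrow(x$compounds), length(x$ms2)))
  invisible(x)
}

#' Read MS2 spectra from an MSP (NIST text) file
#'
#' Records start at `Name:`; `PrecursorMZ:`/`PRECURSORMZ:`, optional
#' `RetentionTime:` (seconds) and `Ion_mode:` are honoured; `Num Peaks:` is
#' followed by whitespace- or semicolon-separated mz/intensity pairs.
#'
#' @param file Path.
#' @return Named list keyed by the `Name:` field, same spectrum shape as
#'   [read_mgf()].
#' @export
read_msp <- function(file) {
  lines <- readLines(file)
  out <- list()
  cur <- NULL
  flush <- function(cur) {
    if (is.null(cur) || length(cur$peaks) == 0) return(invisible(NULL))
    pk <- do.call(rbind, cur$peaks)
    colnames(pk) <- c("mz", "intensity")
    pk <- pk[order(pk[, "mz"]), , drop = FALSE]
    spec <- list(precursor_mz = cur$precursor, polarity = cur$polarity,
                 rt = cur$rt, peaks = pk)
    out[[cur$name]] <<- c(out[[cur$name]], list(spec))
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (grepl("^Name:", ln, ignore.case = TRUE)) {
      flush(cur)
      cur <- list(name = trimws(sub("^Name:", "", ln, ignore.case = TRUE)),
                  precursor = NA_real_, rt = NA_real_, polarity = "pos",
                  peaks = list())
    } else if (is.null(cur)) {
      next
    } else if (grepl("^Precursor_?MZ:", ln, ignore.case = TRUE)) {
      cur$precursor <- as.numeric(sub("^[^:]+:", "", ln))
    } else if (grepl("^RetentionTime:", ln, ignore.case = TRUE)) {
      cur$rt <- as.numeric(sub("^[^:]+:", "", ln))
    } else if (grepl("^Ion_?mode:", ln, ignore.case = TRUE)) {
      cur$polarity <- if (grepl("n", sub("^[^:]+:", "", ln), ignore.case = TRUE))
        "neg" else "pos"
    } else if (grepl("^[0-9]", ln)) {
      for (pair in strsplit(ln, ";")[[1]]) {
        v <- as.numeric(strsplit(trimws(pair), "\\s+")[[1]])
        if (length(v) >= 2 && !any(is.na(v[1:2]))) {
          cur$peaks[[length(cur$peaks) + 1L]] <- v[1:2]
        }
      }
    }
  }
  flush(cur)
  out
}

#' Export the annotated clean dataset
#'
#' Writes four re-readable files: the annotation table, the peak-area table
#' (with m/z and RT), the sample sheet, and the MS2 spectra as MGF — the
#' hand-off bundle for downstream tools.
#'
#' @param dataset A `metabo_dataset`.
#' @param annotations Annotation tibble as returned by [annotate_features()];
#'   may have zero rows.
#' @param dir Output directory (created if needed).
#' @return Manifest tibble: one row per file with `file` and `n_rows`.
#' @export
export_integrated <- function(dataset, annotations, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  annotations <- tibble::as_tibble(annotations)
  if (nrow(annotations) > 0) {
    unknown <- setdiff(annotations$feature_id, dataset$feature_info$feature_id)
    if (length(unknown) > 0) {
      stop("annotation references unknown feature(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  paths <- c(
    annotation = file.path(dir, "annotation.csv"),
    peak_area = file.path(dir, "peak_area.csv"),
    sample_info = file.path(dir, "sample_info.csv"),
    spectra = file.path(dir, "spectra.mgf")
  )
  readr::write_csv(annotations, paths["annotation"], progress = FALSE)
  peak <- dplyr::bind_cols(
    dataset$feature_info[, c("feature_id", "mz", "rt")],
    tibble::as_tibble(dataset$expression)
  )
  readr::write_csv(peak, paths["peak_area"], progress = FALSE)
  readr::write_csv(dataset$sample_info, paths["sample_info"], progress = FALSE)
  write_mgf(dataset$ms2, paths["spectra"])
  tibble::tibble(
    file = unname(paths),
    n_rows = c(nrow(annotations), nrow(peak), nrow(dataset$sample_info),
               sum(lengths(dataset$ms2)))
  )
}
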