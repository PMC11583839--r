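#' Missing-value profile of a dataset
#'
#' Computes, before any imputation, the per-feature missing rate in QC
#' samples, the per-feature missing rate within each study group (Subject
#' samples only), and the per-sample missing rate. These rates drive the
#' noise filter and the outlier-sample triage.
#'
#' @param dataset A `metabo_dataset`.
#' @return List with `feature_rates` (tibble: `feature_id`, `qc_rate`, one
#'   `group_<g>` column per group, `min_group_rate`) and `sample_rates`
#'   (tibble: `sample_id`, `class`, `rate`).
#' @export
missing_profile <- function(dataset) {
  e <- dataset$expression
  si <- dataset$sample_info
  qc <- class_matrix(dataset, "QC")
  qc_rate <- if (ncol(qc) > 0) unname(rowMeans(is.na(qc))) else rep(NA_real_, nrow(e))

  subj <- si[si$class == "Subject", , drop = FALSE]
  groups <- unique(subj$group)
  group_rates <- purrr::map(groups, function(g) {
    ids <- subj$sample_id[subj$group == g]
    if (length(ids) == 0) return(NULL)
    unname(rowMeans(is.na(e[, ids, drop = FALSE])))
  })
  names(group_rates) <- paste0("group_", groups)
  keep <- !purrr::map_lgl(group_rates, is.null)
  if (any(!keep)) {
    warning("group(s) with 0 samples excluded from missing profile",
            call. = FALSE)
  }
  group_rates <- group_rates[keep]

  feature_rates <- tibble::tibble(
    feature_id = dataset$feature_info$feature_id,
    qc_rate = qc_rate
  )
  for (nm in names(group_rates)) feature_rates[[nm]] <- group_rates[[nm]]
  feature_rates$min_group_rate <- if (length(group_rates) > 0) {
    do.call(pmin, group_rates)
  } else {
    NA_real_
  }
  sample_rates <- tibble::tibble(
    sample_id = si$sample_id,
    class = si$class,
    rate = unname(colMeans(is.na(e)))
  )
  list(feature_rates = feature_rates, sample_rates = sample_rates)
}

#' Remove noise features by missing-rate thresholds
#'
#' A feature is treated as background noise and removed when it is missing in
#' more than `qc_thresh` of the QC injections, or when its missing rate
#' exceeds `group_thresh` in every study group. The every-group rule keeps
#' group-specific metabolites: a feature fully observed in one group is
#' biology, not noise, even if absent elsewhere. Thresholds are strict
#' ("more than 20%"): a rate exactly at the threshold is retained.
#'
#' @param dataset A `metabo_dataset` with at least one QC sample and one group.
#' @param qc_thresh QC missing-rate threshold (default 0.2).
#' @param group_thresh Per-group missing-rate threshold (default 0.2).
#' @return Filtered `metabo_dataset`; retained count is logged.
#' @export
filter_noise <- function(dataset, qc_thresh = 0.2, group_thresh = 0.2) {
  if (qc_thresh < 0 || qc_thresh > 1 || group_thresh < 0 || group_thresh > 1) {
    stop("thresholds must lie in [0, 1]", call. = FALSE)
  }
  if (!any(dataset$sample_info$class == "QC")) {
    stop("filter_noise requires at least one QC sample", call. = FALSE)
  }
  prof <- missing_profile(dataset)$feature_rates
  remove <- prof$qc_rate > qc_thresh | prof$min_group_rate > group_thresh
  remove[is.na(remove)] <- FALSE
  out <- subset_features(dataset, !remove)
  log_operation(out, "filter_noise",
                params = list(qc_thresh = qc_thresh,
                              group_thresh = group_thresh,
                              removed = sum(remove)),
                before = dataset)
}

subset_features <- function(dataset, keep) {
  dataset$expression <- dataset$expression[keep, , drop = FALSE]
  dataset$feature_info <- dataset$feature_info[keep, , drop = FALSE]
  dataset$ms2 <- dataset$ms2[intersect(names(dataset$ms2),
                                       dataset$feature_info$feature_id)]
  dataset
}

subset_samples <- function(dataset, keep_ids) {
  keep <- dataset$sample_info$sample_id %in% keep_ids
  dataset$expression <- dataset$expression[, keep, drop = FALSE]
  dataset$sample_info <- dataset$sample_info[keep, , drop = FALSE]
  dataset
}

#' Triage outlier samples by missing rate
#'
#' Partitions Subject samples into `keep` (missing rate below `keep_below`),
#' `review` (borderline; needs a user decision) and `remove` (above
#' `remove_above`). Removal itself is a separate explicit call
#' ([drop_samples()]) so borderline samples are never dropped silently.
#'
#' @param dataset A `metabo_dataset` (rates computed on the current, i.e.
#'   post-noise-filter, matrix).
#' @param keep_below Samples with rate strictly below this are kept
#'   (default 0.5).
#' @param remove_above Samples with rate strictly above this are flagged for
#'   removal (default 0.8); rates in the closed interval
#'   `[keep_below, remove_above]` land in `review`.
#' @return List of character vectors `keep`, `review`, `remove` partitioning
#'   the Subject samples.
#' @export
triage_outliers <- function(dataset, keep_below = 0.5, remove_above = 0.8) {
  if (keep_below > remove_above) {
    stop("keep_below must not exceed remove_above", call. = FALSE)
  }
  rates <- missing_profile(dataset)$sample_rates
  rates <- rates[rates$class == "Subject", , drop = FALSE]
  list(
    keep = rates$sample_id[rates$rate < keep_below],
    review = rates$sample_id[rates$rate >= keep_below &
                               rates$rate <= remove_above],
    remove = rates$sample_id[rates$rate > remove_above]
  )
}

#' Drop samples by id
#'
#' @param dataset A `metabo_dataset`.
#' @param sample_ids Ids to remove (e.g. the `remove` set from
#'   [triage_outliers()]).
#' @return Filtered dataset with a log entry.
#' @export
drop_samples <- function(dataset, sample_ids) {
  out <- subset_samples(
    dataset, setdiff(dataset$sample_info$sample_id, sample_ids)
  )
  log_operation(out, "drop_samples",
                params = list(removed = length(sample_ids)), before = dataset)
}

#' K-nearest-neighbour imputation of missing intensities
#'
#' For each missing entry, the k features nearest to the target feature
#' (Euclidean distance over their shared observed samples, computed on
#' log2(x + 1) profiles and normalized by the number of shared samples) that
#' are observed in the target sample contribute their raw intensities; the
#' imputed value is their mean. Observed entries are never altered.
#'
#' @param dataset A `metabo_dataset` with no fully missing feature (filter
#'   first).
#' @param k Number of neighbours (default 10); must be smaller than the
#'   number of features.
#' @return Dataset with zero missing entries and an `"impute_knn"` log entry.
#' @export
impute_knn <- function(dataset, k = 10) {
  e <- dataset$expression
  if (k >= nrow(e)) {
    stop("k must be smaller than the number of features", call. = FALSE)
  }
  all_missing <- rowSums(!is.na(e)) == 0
  if (any(all_missing)) {
    stop(sum(all_missing), " feature(s) are 100% missing; filter them first",
         call. = FALSE)
  }
  if (!anyNA(e)) {
    return(log_operation(dataset, "impute_knn", params = list(k = k)))
  }
  le <- log2(e + 1)
  obs <- !is.na(e)
  out <- e
  todo <- which(rowSums(!obs) > 0)
  for (f in todo) {
    shared <- obs & matrix(obs[f, ], nrow(e), ncol(e), byrow = TRUE)
    diffs <- sweep(le, 2, le[f, ], "-")
    diffs[!shared] <- NA
    n_shared <- rowSums(shared)
    d <- sqrt(rowMeans(diffs^2, na.rm = TRUE))
    d[f] <- Inf
    d[n_shared == 0] <- Inf
    for (s in which(!obs[f, ])) {
      cand <- which(obs[, s] & is.finite(d))
      cand <- cand[order(d[cand])]
      nb <- utils::head(cand, k)
      if (length(nb) == 0) {
        out[f, s] <- mean(e[f, ], na.rm = TRUE)
      } else {
        out[f, s] <- mean(e[nb, s])
      }
    }
  }
  dataset$expression <- out
  log_operation(dataset, "impute_knn", params = list(k = k))
}

#' QC-anchored SVR drift normalization
#'
#' Within each batch, instrument drift is modelled per feature by a support
#' vector regression (radial kernel, cost 1, epsilon 0.1) of the QC
#' intensities against injection order. Every sample's intensity is corrected
#' by `raw * median(QC raw) / predicted(order)`, so the QC trend is flattened
#' onto its median level; predictions below `1e-6 * median(QC)` fall back to
#' the median to avoid explosive ratios.
#'
#' @param dataset Imputed `metabo_dataset` with injection order and at least
#'   `min_qc` QC samples per batch.
#' @param min_qc Minimum QC injections per batch to fit the SVR (default 5).
#' @param fallback If `TRUE`, batches with fewer than `min_qc` QC samples are
#'   corrected by median-fold-change scaling instead of erroring.
#' @return Normalized dataset with a `"normalize_svr_qc"` log entry.
#' @export
normalize_svr_qc <- function(dataset, min_qc = 5, fallback = FALSE) {
  si <- dataset$sample_info
  e <- dataset$expression
  if (anyNA(e)) {
    stop("normalize_svr_qc requires an imputed (complete) matrix", call. = FALSE)
  }
  for (b in unique(si$batch)) {
    in_batch <- si$batch == b
    qc_idx <- which(in_batch & si$class == "QC")
    if (length(qc_idx) < min_qc) {
      if (!fallback) {
        stop(sprintf(
          paste0("batch '%s' has %d QC sample(s); at least %d are needed for ",
                 "SVR normalization. Re-run with fallback = TRUE to use ",
                 "median-fold-change scaling for this batch."),
          b, length(qc_idx), min_qc
        ), call. = FALSE)
      }
      all_idx <- which(in_batch)
      med_qc <- apply(e[, qc_idx, drop = FALSE], 1, stats::median)
      fold <- apply(e[, all_idx, drop = FALSE] / med_qc, 2,
                    stats::median, na.rm = TRUE)
      e[, all_idx] <- sweep(e[, all_idx, drop = FALSE], 2, fold, "/")
      next
    }
    all_idx <- which(in_batch)
    ord_qc <- si$injection_order[qc_idx]
    ord_all <- si$injection_order[all_idx]
    for (f in seq_len(nrow(e))) {
      y <- e[f, qc_idx]
      med <- stats::median(y)
      if (med <= 0 || stats::sd(y) == 0) next
      fit <- e1071::svm(x = matrix(ord_qc, ncol = 1), y = y,
                        kernel = "radial", cost = 1, epsilon = 0.1)
      pred <- as.numeric(stats::predict(fit, matrix(ord_all, ncol = 1)))
      pred[pred < 1e-6 * med] <- med
      e[f, all_idx] <- e[f, all_idx] * med / pred
    }
  }
  dataset$expression <- e
  log_operation(dataset, "normalize_svr_qc",
                params = list(min_qc = min_qc, fallback = fallback))
}

#' Align batches on their QC medians
#'
#' Per feature, each batch is rescaled so that its QC median equals the
#' global QC median, removing residual between-batch level shifts after
#' within-batch drift correction. A single-batch dataset is returned
#' unchanged (plus a log entry).
#'
#' @param dataset A `metabo_dataset`; every batch must contain QC samples.
#' @return Batch-integrated dataset.
#' @export
integrate_batches <- function(dataset) {
  si <- dataset$sample_info
  e <- dataset$expression
  batches <- unique(si$batch)
  if (length(batches) >= 2) {
    no_qc <- batches[!purrr::map_lgl(batches, function(b) {
      any(si$batch == b & si$class == "QC")
    })]
    if (length(no_qc) > 0) {
      stop("batch(es) without QC samples: ", paste(no_qc, collapse = ", "),
           call. = FALSE)
    }
    qc_global <- e[, si$class == "QC", drop = FALSE]
    med_global <- apply(qc_global, 1, stats::median, na.rm = TRUE)
    for (b in batches) {
      qc_b <- e[, si$batch == b & si$class == "QC", drop = FALSE]
      med_b <- apply(qc_b, 1, stats::median, na.rm = TRUE)
      scale <- ifelse(med_b > 0, med_global / med_b, 1)
      e[, si$batch == b] <- e[, si$batch == b, drop = FALSE] * scale
    }
    dataset$expression <- e
  }
  log_operation(dataset, "integrate_batches",
                params = list(n_batches = length(batches)))
}

#' Relative standard deviation of QC samples
#'
#' Per-feature RSD (sd/mean) over QC injections; the median across features
#' is the standard single-number summary of technical repeatability.
#'
#' @param dataset A `metabo_dataset`.
#' @return List with `per_feature` (tibble `feature_id`, `rsd`) and `median`.
#' @export
qc_rsd <- function(dataset) {
  qc <- class_matrix(dataset, "QC")
  if (ncol(qc) < 2) stop("need at least 2 QC samples for RSD", call. = FALSE)
  m <- rowMeans(qc, na.rm = TRUE)
  s <- apply(qc, 1, stats::sd, na.rm = TRUE)
  rsd <- ifelse(m > 0, s / m, NA_real_)
  list(
    per_feature = tibble::tibble(
      feature_id = dataset$feature_info$feature_id, rsd = rsd
    ),
    median = stats::median(rsd, na.rm = TRUE)
  )
}
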