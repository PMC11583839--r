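#' Select MRM ion pairs for a pseudotargeted method
#'
#' One precursor/product transition per feature: the precursor is the
#' feature's m/z and the product is its most intense MS2 fragment lying more
#' than `precursor_margin` Da below the precursor (excluding the unfragmented
#' precursor itself); intensity ties go to the larger fragment m/z. Features
#' without a qualifying fragment are reported as unpairable.
#'
#' @param dataset A `metabo_dataset` with MS2 spectra attached.
#' @param precursor_margin Exclusion margin below the precursor in Da
#'   (default 3).
#' @return List with `pairs` (tibble: `feature_id`, `precursor_mz`,
#'   `product_mz`, `product_rank`, `rt`, `polarity`) and `unpairable`
#'   (character vector of feature ids).
#' @export
select_mrm <- function(dataset, precursor_margin = 3) {
  fi <- dataset$feature_info
  rows <- list()
  unpairable <- character()
  for (i in seq_len(nrow(fi))) {
    id <- fi$feature_id[i]
    specs <- dataset$ms2[[id]]
    if (is.null(specs) || length(specs) == 0) next
    pk <- do.call(rbind, purrr::map(specs, "peaks"))
    ok <- pk[, "mz"] < fi$mz[i] - precursor_margin
    if (!any(ok)) {
      unpairable <- c(unpairable, id)
      next
    }
    pk <- pk[ok, , drop = FALSE]
    best <- order(-pk[, "intensity"], -pk[, "mz"])[1]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      feature_id = id,
      precursor_mz = fi$mz[i],
      product_mz = unname(pk[best, "mz"]),
      product_rank = 1L,
      rt = fi$rt[i],
      polarity = fi$polarity[i]
    )
  }
  list(
    pairs = if (length(rows) > 0) dplyr::bind_rows(rows) else
      tibble::tibble(feature_id = character(), precursor_mz = numeric(),
                     product_mz = numeric(), product_rank = integer(),
                     rt = numeric(), polarity = character()),
    unpairable = unpairable
  )
}

#' Match two feature sets by precursor/product m/z and RT windows
#'
#' Every A-B pair within the rough gates is classified: `precise` when the
#' precursor differs by less than `precursor_ppm_precise` ppm (and, when both
#' sides carry a product ion, the product by less than `product_ppm` ppm)
#' with RT within `rt_tol_s`; `rough` when the precursor error lies between
#' the precise and rough windows under the same product/RT gates. An
#' A-feature counts as matched when it has one or more qualifying partners.
#' Ppm errors use set A as reference denominator.
#'
#' @param set_a,set_b Tibbles with `feature_id`, precursor m/z (`mz` or
#'   `precursor_mz`), `rt`, and optional `product_mz`.
#' @param precursor_ppm_precise Precise precursor window, ppm (default 100).
#' @param precursor_ppm_rough Rough precursor window, ppm (default 1000).
#' @param product_ppm Product-ion window, ppm (default 20).
#' @param rt_tol_s RT window, seconds (default 30).
#' @return List with `pairs` (tibble: ids, `precursor_ppm`, `product_ppm`,
#'   `rt_delta_s`, `class`) and `summary` (tibble of per-A-feature counts:
#'   `n_precise`, `n_rough`, `n_unmatched`).
#' @export
match_feature_sets <- function(set_a, set_b,
                               precursor_ppm_precise = 100,
                               precursor_ppm_rough = 1000,
                               product_ppm = 20, rt_tol_s = 30) {
  norm <- function(d) {
    d <- tibble::as_tibble(d)
    if (!"precursor_mz" %in% names(d)) d$precursor_mz <- d$mz
    if (!"product_mz" %in% names(d)) d$product_mz <- NA_real_
    d
  }
  a <- norm(set_a); b <- norm(set_b)
  if (nrow(a) == 0 || nrow(b) == 0) stop("both sets must be non-empty",
                                         call. = FALSE)
  prec_ppm <- abs(1e6 * outer(a$precursor_mz, b$precursor_mz, "-") /
                    a$precursor_mz)
  rt_d <- abs(outer(a$rt, b$rt, "-"))
  prod_ppm <- abs(1e6 * outer(a$product_mz, b$product_mz, "-") / a$product_mz)
  have_prod <- outer(!is.na(a$product_mz), !is.na(b$product_mz), "&")
  prod_ok <- !have_prod | (prod_ppm < product_ppm)
  gate <- prec_ppm < precursor_ppm_rough & rt_d < rt_tol_s & prod_ok
  idx <- which(gate, arr.ind = TRUE)
  pairs <- tibble::tibble(
    feature_a = a$feature_id[idx[, 1]],
    feature_b = b$feature_id[idx[, 2]],
    precursor_ppm = prec_ppm[idx],
    product_ppm = ifelse(have_prod[idx], prod_ppm[idx], NA_real_),
    rt_delta_s = rt_d[idx],
    class = ifelse(prec_ppm[idx] < precursor_ppm_precise, "precise", "rough")
  ) |> dplyr::arrange(.data$feature_a, .data$precursor_ppm)
  summary <- tibble::tibble(feature_a = a$feature_id) |>
    dplyr::left_join(
      pairs |> dplyr::count(.data$feature_a, .data$class) |>
        tidyr::pivot_wider(names_from = "class", values_from = "n",
                           values_fill = 0L),
      by = "feature_a"
    )
  for (col in c("precise", "rough")) {
    if (!col %in% names(summary)) summary[[col]] <- 0L
    summary[[col]][is.na(summary[[col]])] <- 0L
  }
  summary$status <- ifelse(summary$precise > 0, "precise",
                           ifelse(summary$rough > 0, "rough", "unmatched"))
  list(pairs = pairs, summary = summary)
}

#' Cross-platform consensus features
#'
#' Greedy mutual-nearest pairing of two feature sets inside joint m/z and RT
#' gates: candidate pairs are ranked by the combined normalized distance
#' `sqrt((ppm/ppm_tol)^2 + (drt/rt_tol)^2)` and accepted closest-first, each
#' feature used at most once. The consensus keeps A's ids with the matched
#' B id as cross-reference.
#'
#' @param set_a,set_b Tibbles with `feature_id`, `mz`, `rt`.
#' @param ppm m/z gate in ppm (default 30; denominator is A's m/z).
#' @param rt_tol_s RT gate in seconds (default 30).
#' @return Tibble: `feature_id` (from A), `feature_id_b`, `mz`, `rt`,
#'   `ppm_error`, `rt_delta_s`.
#' @export
cross_platform_consensus <- function(set_a, set_b, ppm = 30, rt_tol_s = 30) {
  a <- tibble::as_tibble(set_a); b <- tibble::as_tibble(set_b)
  ppm_err <- abs(1e6 * outer(a$mz, b$mz, "-") / a$mz)
  rt_d <- abs(outer(a$rt, b$rt, "-"))
  gate <- ppm_err <= ppm & rt_d <= rt_tol_s
  idx <- which(gate, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(tibble::tibble(feature_id = character(), feature_id_b = character(),
                          mz = numeric(), rt = numeric(),
                          ppm_error = numeric(), rt_delta_s = numeric()))
  }
  dist <- sqrt((ppm_err[idx] / ppm)^2 + (rt_d[idx] / rt_tol_s)^2)
  ord <- order(dist)
  used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
  rows <- list()
  for (i in ord) {
    ia <- idx[i, 1]; ib <- idx[i, 2]
    if (used_a[ia] || used_b[ib]) next
    used_a[ia] <- TRUE; used_b[ib] <- TRUE
    rows[[length(rows) + 1L]] <- tibble::tibble(
      feature_id = a$feature_id[ia], feature_id_b = b$feature_id[ib],
      mz = a$mz[ia], rt = a$rt[ia],
      ppm_error = ppm_err[idx[i, , drop = FALSE]],
      rt_delta_s = rt_d[idx[i, , drop = FALSE]]
    )
  }
  dplyr::bind_rows(rows) |> dplyr::arrange(.data$feature_id)
}
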