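PROTON_MASS <- 1.007276466

# supported adducts: mass shift (Da) and charge sign
ADDUCT_TABLE <- tibble::tibble(
  adduct = c("[M+H]+", "[M+Na]+", "[M+NH4]+", "[M-H2O+H]+",
             "[M-H]-", "[M+HCOO]-"),
  shift = c(1.007276466, 22.989218, 18.033823,
            1.007276466 - 18.010565,
            -1.007276466, 44.998201),
  charge_sign = c("pos", "pos", "pos", "pos", "neg", "neg")
)

#' Theoretical m/z of an adduct
#'
#' @param monoisotopic_mass Neutral monoisotopic mass in Da.
#' @param adduct One of `[M+H]+`, `[M+Na]+`, `[M+NH4]+`, `[M-H2O+H]+`,
#'   `[M-H]-`, `[M+HCOO]-` (all singly charged).
#' @return Theoretical m/z in Da.
#' @export
adduct_mz <- function(monoisotopic_mass, adduct) {
  i <- match(adduct, ADDUCT_TABLE$adduct)
  if (anyNA(i)) {
    stop("unsupported adduct: ",
         paste(adduct[is.na(i)], collapse = ", "), call. = FALSE)
  }
  monoisotopic_mass + ADDUCT_TABLE$shift[i]
}

#' MS1 candidate matches for one feature
#'
#' Scans the library over all supported adducts and returns the candidates
#' whose theoretical m/z lies within `ppm_tol` of the observed m/z, sorted by
#' absolute ppm error.
#'
#' @param feature One-row data frame (or list) with `mz` and `polarity`.
#' @param library A `spectral_library`.
#' @param ppm_tol Mass tolerance in ppm (default 25).
#' @param polarity_filter If `TRUE` (default) only adducts whose charge sign
#'   matches the feature's polarity are considered.
#' @return Tibble with `compound_id`, `adduct`, `mz_error_ppm`.
#' @export
match_ms1 <- function(feature, library, ppm_tol = 25, polarity_filter = TRUE) {
  adducts <- ADDUCT_TABLE
  if (polarity_filter) {
    adducts <- adducts[adducts$charge_sign == feature$polarity, , drop = FALSE]
  }
  comp <- library$compounds
  hits <- purrr::map(seq_len(nrow(adducts)), function(a) {
    theo <- comp$monoisotopic_mass + adducts$shift[a]
    ppm <- 1e6 * (feature$mz - theo) / theo
    keep <- abs(ppm) <= ppm_tol
    if (!any(keep)) return(NULL)
    tibble::tibble(
      compound_id = comp$compound_id[keep],
      adduct = adducts$adduct[a],
      mz_error_ppm = ppm[keep]
    )
  })
  out <- dplyr::bind_rows(hits)
  if (nrow(out) == 0) {
    return(tibble::tibble(compound_id = character(), adduct = character(),
                          mz_error_ppm = numeric()))
  }
  out[order(abs(out$mz_error_ppm)), ]
}

#' Fragment-spectrum similarity score
#'
#' Greedy one-to-one pairing of query and reference fragments within
#' `frag_tol_da` (closest pairs first, each fragment used once), then the
#' cosine of the square-root-intensity vectors over the union of matched and
#' unmatched fragments. Symmetric in its arguments, in \[0, 1\], and
#' invariant to uniform intensity scaling.
#'
#' @param query,reference Spectra (lists with a `peaks` matrix).
#' @param frag_tol_da Fragment m/z tolerance in Da (default 0.02).
#' @return Similarity in \[0, 1\].
#' @export
score_ms2 <- function(query, reference, frag_tol_da = 0.02) {
  q <- query$peaks
  r <- reference$peaks
  if (nrow(q) == 0 || nrow(r) == 0) return(0)
  dmat <- abs(outer(q[, "mz"], r[, "mz"], "-"))
  cand <- which(dmat <= frag_tol_da, arr.ind = TRUE)
  pairs <- matrix(integer(0), 0, 2)
  if (nrow(cand) > 0) {
    cand <- cand[order(dmat[cand]), , drop = FALSE]
    used_q <- logical(nrow(q))
    used_r <- logical(nrow(r))
    for (i in seq_len(nrow(cand))) {
      qi <- cand[i, 1]; ri <- cand[i, 2]
      if (!used_q[qi] && !used_r[ri]) {
        pairs <- rbind(pairs, c(qi, ri))
        used_q[qi] <- TRUE
        used_r[ri] <- TRUE
      }
    }
  }
  sq <- sqrt(q[, "intensity"])
  sr <- sqrt(r[, "intensity"])
  dot <- if (nrow(pairs) > 0) sum(sq[pairs[, 1]] * sr[pairs[, 2]]) else 0
  denom <- sqrt(sum(sq^2)) * sqrt(sum(sr^2))
  if (denom == 0) return(0)
  max(0, min(1, dot / denom))
}

#' Annotate features against a spectral library with MSI levels
#'
#' Per feature, every MS1 candidate within `ppm_tol` is scored on the
#' available evidence and assigned a Metabolomics Standards Initiative
#' confidence level: level 1 needs m/z, RT (library RT present and within
#' `rt_tol_s`) and an MS2 match (best fragment-cosine at least
#' `ms2_score_min`); level 2 needs m/z plus MS2; level 3 is m/z alone. The
#' composite score is a weighted mean of the evidence scores (m/z 0.25,
#' RT 0.25, MS2 0.5, renormalized over the evidence actually present).
#'
#' @param dataset Cleaned `metabo_dataset` (uses `feature_info` and `ms2`).
#' @param library A `spectral_library`.
#' @param ppm_tol MS1 tolerance in ppm (default 25).
#' @param rt_tol_s RT tolerance in seconds (default 30).
#' @param ms2_score_min Minimum fragment-cosine for MS2 evidence
#'   (default 0.5).
#' @param frag_tol_da Fragment tolerance passed to [score_ms2()].
#' @param levels_allowed Levels to keep (default `c(1, 2, 3)`).
#' @param polarity_filter Passed to [match_ms1()].
#' @return Tibble with columns `feature_id`, `mz`, `rt`, `compound_id`,
#'   `name`, `adduct`, `mz_error_ppm`, `rt_error_s`, `ms2_score`,
#'   `total_score`, `level`.
#' @export
annotate_features <- function(dataset, library, ppm_tol = 25, rt_tol_s = 30,
                              ms2_score_min = 0.5, frag_tol_da = 0.02,
                              levels_allowed = c(1, 2, 3),
                              polarity_filter = TRUE) {
  fi <- dataset$feature_info
  comp <- library$compounds
  rows <- purrr::map(seq_len(nrow(fi)), function(i) {
    feat <- fi[i, ]
    cands <- match_ms1(feat, library, ppm_tol = ppm_tol,
                       polarity_filter = polarity_filter)
    if (nrow(cands) == 0) return(NULL)
    feat_specs <- dataset$ms2[[feat$feature_id]]
    purrr::map(seq_len(nrow(cands)), function(j) {
      cid <- cands$compound_id[j]
      rec <- comp[comp$compound_id == cid, ]
      mz_score <- 1 - abs(cands$mz_error_ppm[j]) / ppm_tol

      rt_err <- NA_real_
      rt_ok <- FALSE
      if (!is.na(rec$rt)) {
        rt_err <- feat$rt - rec$rt
        rt_ok <- abs(rt_err) <= rt_tol_s
      }
      rt_score <- if (rt_ok) 1 - abs(rt_err) / rt_tol_s else NA_real_

      ms2_score <- NA_real_
      ref_specs <- library$ms2[[cid]]
      if (!is.null(feat_specs) && !is.null(ref_specs)) {
        combos <- expand.grid(q = seq_along(feat_specs),
                              r = seq_along(ref_specs))
        ms2_score <- max(purrr::map_dbl(seq_len(nrow(combos)), function(k) {
          score_ms2(feat_specs[[combos$q[k]]], ref_specs[[combos$r[k]]],
                    frag_tol_da = frag_tol_da)
        }))
      }
      ms2_ok <- !is.na(ms2_score) && ms2_score >= ms2_score_min

      level <- if (ms2_ok && rt_ok) 1L else if (ms2_ok) 2L else 3L
      w <- c(mz = 0.25, rt = 0.25, ms2 = 0.5)
      sc <- c(mz = mz_score,
              rt = if (rt_ok) rt_score else NA_real_,
              ms2 = if (ms2_ok) ms2_score else NA_real_)
      present <- !is.na(sc)
      total <- sum(w[present] * sc[present]) / sum(w[present])

      tibble::tibble(
        feature_id = feat$feature_id, mz = feat$mz, rt = feat$rt,
        compound_id = cid, name = rec$name, adduct = cands$adduct[j],
        mz_error_ppm = cands$mz_error_ppm[j],
        rt_error_s = if (rt_ok) rt_err else NA_real_,
        ms2_score = if (ms2_ok) ms2_score else NA_real_,
        total_score = total, level = level
      )
    }) |> dplyr::bind_rows()
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(
      feature_id = character(), mz = numeric(), rt = numeric(),
      compound_id = character(), name = character(), adduct = character(),
      mz_error_ppm = numeric(), rt_error_s = numeric(), ms2_score = numeric(),
      total_score = numeric(), level = integer()
    ))
  }
  out[out$level %in% levels_allowed, , drop = FALSE]
}

#' Resolve redundant annotations
#'
#' A feature can hit several library records and several features can hit the
#' same record. Under `feature_strategy = "best_total_score"` each feature
#' keeps its single best record (ties broken by higher level — i.e. smaller
#' numeric MSI level — then smaller absolute ppm error, then compound_id);
#' under `compound_strategy = "best_feature"` each compound likewise keeps
#' its best-scoring feature. The defaults mirror common practice: one record
#' per feature, all features per compound preserved.
#'
#' @param annotations Annotation tibble from [annotate_features()].
#' @param feature_strategy `"best_total_score"` or `"keep_all"`.
#' @param compound_strategy `"keep_all"`, `"best_feature"` or `"first"`.
#' @return Filtered annotation tibble.
#' @export
deduplicate_annotations <- function(annotations,
                                    feature_strategy = c("best_total_score",
                                                         "keep_all"),
                                    compound_strategy = c("keep_all",
                                                          "best_feature",
                                                          "first")) {
  feature_strategy <- match.arg(feature_strategy)
  compound_strategy <- match.arg(compound_strategy)
  ann <- tibble::as_tibble(annotations)
  if (nrow(ann) == 0) return(ann)
  rank_order <- function(d) {
    order(-d$total_score, d$level, abs(d$mz_error_ppm), d$compound_id)
  }
  if (feature_strategy == "best_total_score") {
    ann <- ann |>
      dplyr::group_by(.data$feature_id) |>
      dplyr::group_modify(function(d, key) d[rank_order(d)[1], , drop = FALSE]) |>
      dplyr::ungroup()
  }
  if (compound_strategy == "best_feature") {
    ann <- ann |>
      dplyr::group_by(.data$compound_id) |>
      dplyr::group_modify(function(d, key) {
        d[order(-d$total_score, d$level, abs(d$mz_error_ppm),
                d$feature_id)[1], , drop = FALSE]
      }) |>
      dplyr::ungroup()
  } else if (compound_strategy == "first") {
    ann <- ann |>
      dplyr::group_by(.data$compound_id) |>
      dplyr::slice(1) |>
      dplyr::ungroup()
  }
  dplyr::arrange(ann, .data$feature_id, .data$compound_id)
}
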