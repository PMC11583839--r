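#' Simulate a multi-batch LC-MS feature table with known truth
#'
#' Generates the statistical structure the pipeline assumes, with full ground
#' truth: log-normal baseline intensities; planted co-accumulation modules
#' whose members share a latent factor (expected within-module Pearson
#' correlation approximately `within_cor`); pooled-QC injections every
#' `qc_every` positions carrying the mean profile plus technical noise;
#' per-batch multiplicative drift `1 + drift_slope * injection_order`;
#' and missingness that is part completely-at-random (`mcar_rate`) and part
#' intensity-dependent (logistic in -log intensity, strength `mnar_coef`) —
#' the low-abundance dropout that dominates real LC-MS tables. Optional
#' per-group log2 effects are planted on random features for differential
#' testing.
#'
#' @param n_features Total features.
#' @param n_samples Subject samples (QC injections are added on top).
#' @param n_groups Number of study groups (default 2).
#' @param n_batches Number of batches (default 1).
#' @param n_modules Planted modules (default 0).
#' @param module_size Members per module.
#' @param within_cor Target within-module correlation (default 0.9).
#' @param qc_every One QC injection every this many positions (default 10).
#' @param drift_slope Per-injection multiplicative drift (default 0).
#' @param mcar_rate Completely-at-random missing rate (default 0).
#' @param mnar_coef Strength of intensity-dependent missingness (default 0).
#' @param n_effect_features Features given a group effect (default 0).
#' @param effect_log2 Log2 effect size for planted group effects (default 1).
#' @param qc_noise_sd Log2-scale technical noise of QC injections
#'   (default 0.05).
#' @param batch_sd Standard deviation of per-feature, per-batch log2 offsets
#'   (default 0; the systematic level shift between batches that
#'   [integrate_batches()] removes).
#' @param seed Random seed governing all draws.
#' @return List with `dataset` (a `metabo_dataset`) and `truth` (list:
#'   `module_labels` tibble, `effect_table` tibble, `drift_slope`,
#'   `missing` settings).
#' @export
simulate_dataset <- function(n_features = 200, n_samples = 60, n_groups = 2,
                             n_batches = 1, n_modules = 0, module_size = 40,
                             within_cor = 0.9, qc_every = 10,
                             drift_slope = 0, mcar_rate = 0, mnar_coef = 0,
                             n_effect_features = 0, effect_log2 = 1,
                             qc_noise_sd = 0.05, batch_sd = 0, seed = 1) {
  if (n_modules * module_size > n_features) {
    stop("n_modules * module_size exceeds n_features", call. = FALSE)
  }
  set.seed(seed)

  # ---- log2-scale subject profiles -------------------------------------
  base_mean <- stats::runif(n_features, 14, 20)   # log2 of ~1.6e4..1e6
  amp <- stats::runif(n_features, 0.6, 1.2)       # per-feature dynamic range
  z <- matrix(stats::rnorm(n_features * n_samples), n_features, n_samples)
  module_labels <- rep("noise", n_features)
  if (n_modules > 0) {
    w <- sqrt(within_cor)
    for (m in seq_len(n_modules)) {
      idx <- ((m - 1) * module_size + 1):(m * module_size)
      latent <- stats::rnorm(n_samples)
      z[idx, ] <- w * matrix(latent, module_size, n_samples, byrow = TRUE) +
        sqrt(1 - within_cor) * z[idx, ]
      module_labels[idx] <- paste0("planted_", m)
    }
  }
  log2_expr <- base_mean + amp * z

  groups <- paste0("G", ((seq_len(n_samples) - 1) %% n_groups) + 1)
  effect_table <- tibble::tibble(feature_id = character(), group = character(),
                                 log2_effect = numeric())
  if (n_effect_features > 0) {
    eff_idx <- sample.int(n_features, n_effect_features)
    eff_group <- paste0("G", 1)
    log2_expr[eff_idx, groups == eff_group] <-
      log2_expr[eff_idx, groups == eff_group] + effect_log2
    effect_table <- tibble::tibble(
      feature_id = paste0("F", sprintf("%04d", eff_idx)),
      group = eff_group, log2_effect = effect_log2
    )
  }

  feature_ids <- paste0("F", sprintf("%04d", seq_len(n_features)))
  qc_profile <- rowMeans(log2_expr)

  # ---- interleave QC injections, assign batches ------------------------
  n_qc <- max(2, floor(n_samples / qc_every))
  total <- n_samples + n_qc
  qc_pos <- round(seq(1, total, length.out = n_qc))
  is_qc <- seq_len(total) %in% qc_pos
  batch_of <- paste0("B", ceiling(seq_len(total) / (total / n_batches)))

  expr <- matrix(NA_real_, n_features, total)
  sample_ids <- character(total)
  cls <- ifelse(is_qc, "QC", "Subject")
  grp <- character(total)
  s_i <- 0L; q_i <- 0L
  for (j in seq_len(total)) {
    if (is_qc[j]) {
      q_i <- q_i + 1L
      sample_ids[j] <- paste0("QC", sprintf("%02d", q_i))
      grp[j] <- "QC"
      expr[, j] <- qc_profile + stats::rnorm(n_features, sd = qc_noise_sd)
    } else {
      s_i <- s_i + 1L
      sample_ids[j] <- paste0("S", sprintf("%03d", s_i))
      grp[j] <- groups[s_i]
      expr[, j] <- log2_expr[, s_i]
    }
  }

  raw <- 2^expr
  inj <- integer(total)
  batches <- unique(batch_of)
  for (bi in seq_along(batches)) {
    in_b <- batch_of == batches[bi]
    inj[in_b] <- seq_len(sum(in_b))
    if (drift_slope != 0) {
      raw[, in_b] <- sweep(raw[, in_b, drop = FALSE], 2,
                           1 + drift_slope * inj[in_b], "*")
    }
    if (batch_sd > 0 && bi > 1) {
      offset <- 2^stats::rnorm(n_features, sd = batch_sd)
      raw[, in_b] <- raw[, in_b, drop = FALSE] * offset
    }
  }

  # ---- missingness: MCAR + logistic MNAR in -log intensity -------------
  if (mcar_rate > 0 || mnar_coef > 0) {
    li <- log(raw)
    med <- stats::median(li)
    p_mnar <- if (mnar_coef > 0) stats::plogis(mnar_coef * (med - li) - 2) else 0
    p_miss <- pmin(0.95, mcar_rate + p_mnar)
    mask <- matrix(stats::runif(length(raw)) < p_miss,
                   nrow(raw), ncol(raw))
    mask[, cls == "QC"] <- mask[, cls == "QC"] &
      (matrix(stats::runif(length(raw)), nrow(raw))[, cls == "QC"] < 0.5)
    raw[mask] <- NA_real_
  }

  si <- tibble::tibble(
    sample_id = sample_ids, class = cls, group = grp,
    batch = batch_of, injection_order = inj
  )
  fi <- tibble::tibble(
    feature_id = feature_ids,
    mz = round(stats::runif(n_features, 85, 1200), 4),
    rt = round(stats::runif(n_features, 30, 1020), 1),
    polarity = sample(c("pos", "neg"), n_features, replace = TRUE),
    adduct = NA_character_
  )
  ds <- metabo_dataset(raw, si, fi)
  ds <- log_operation(ds, "simulate", params = list(seed = seed))
  list(
    dataset = ds,
    truth = list(
      module_labels = tibble::tibble(feature_id = feature_ids,
                                     module = module_labels),
      effect_table = effect_table,
      drift_slope = drift_slope,
      missing = list(mcar_rate = mcar_rate, mnar_coef = mnar_coef)
    )
  )
}

#' Simulate a toy spectral library with planted annotation truth
#'
#' For `n_annotatable` randomly chosen features, a library record is planted
#' whose evidence matches a chosen MSI level: level 1 records carry the exact
#' neutral mass, a matching RT and a matching MS2 spectrum (which is also
#' attached to the feature); level 2 records match mass and MS2 but carry no
#' RT; level 3 records match mass only. `n_decoys` additional records are
#' placed at least 50 ppm away from every feature so they can never match at
#' typical tolerances.
#'
#' @param dataset A `metabo_dataset` (features get MS2 spectra attached for
#'   levels 1-2; the modified dataset is returned).
#' @param n_annotatable Features to plant annotations for.
#' @param level_probs Probabilities of planting level 1/2/3 (default equal).
#' @param n_decoys Decoy records (default 50).
#' @param seed Random seed.
#' @return List with `library` (a `spectral_library`), `truth` (tibble:
#'   `feature_id`, `compound_id`, `level`) and `dataset` (with spectra
#'   attached).
#' @export
simulate_library <- function(dataset, n_annotatable = 50,
                             level_probs = c(1, 1, 1) / 3, n_decoys = 50,
                             seed = 1) {
  set.seed(seed)
  fi <- dataset$feature_info
  if (n_annotatable > nrow(fi)) {
    stop("n_annotatable exceeds the number of features", call. = FALSE)
  }
  chosen <- if (n_annotatable > 0) sample.int(nrow(fi), n_annotatable)
            else integer(0)
  levels <- if (n_annotatable > 0)
    sample(1:3, n_annotatable, replace = TRUE, prob = level_probs)
  else integer(0)

  make_spectrum <- function(precursor, polarity) {
    n_frag <- sample(4:8, 1)
    frag_mz <- sort(stats::runif(n_frag, 50, max(60, precursor - 10)))
    list(
      precursor_mz = precursor, polarity = polarity, rt = NA_real_,
      peaks = cbind(mz = frag_mz,
                    intensity = stats::runif(n_frag, 0.05, 1))
    )
  }

  comp_rows <- list()
  ms2 <- list()
  truth_rows <- list()
  for (i in seq_along(chosen)) {
    f <- chosen[i]
    cid <- paste0("CPD", sprintf("%04d", i))
    adduct <- if (fi$polarity[f] == "pos") "[M+H]+" else "[M-H]-"
    shift <- ADDUCT_TABLE$shift[ADDUCT_TABLE$adduct == adduct]
    mass <- fi$mz[f] - shift
    lv <- levels[i]
    rt <- if (lv == 1) fi$rt[f] + stats::runif(1, -5, 5) else NA_real_
    if (lv <= 2) {
      spec <- make_spectrum(fi$mz[f], fi$polarity[f])
      dataset$ms2[[fi$feature_id[f]]] <- list(spec)
      ref <- spec
      ref$peaks[, "intensity"] <- ref$peaks[, "intensity"] *
        stats::runif(nrow(ref$peaks), 0.8, 1.2)
      ms2[[cid]] <- list(ref)
    }
    comp_rows[[i]] <- tibble::tibble(
      compound_id = cid, name = paste0("Compound ", i),
      formula = "unknown", monoisotopic_mass = mass, rt = rt,
      superclass = sample(c("Lipids", "Phenylpropanoids", "Organic acids",
                            "Alkaloids"), 1),
      class = NA_character_, subclass = NA_character_,
      pathway = NA_character_
    )
    truth_rows[[i]] <- tibble::tibble(
      feature_id = fi$feature_id[f], compound_id = cid, level = lv
    )
  }

  # decoys: ≥ 50 ppm from every feature m/z under either common adduct
  decoy_rows <- list()
  d_i <- 0L
  while (d_i < n_decoys) {
    mass <- stats::runif(1, 80, 1200)
    safe <- all(vapply(c("[M+H]+", "[M-H]-"), function(a) {
      theo <- adduct_mz(mass, a)
      all(abs(1e6 * (fi$mz - theo) / theo) >= 50)
    }, logical(1)))
    if (!safe) next
    d_i <- d_i + 1L
    decoy_rows[[d_i]] <- tibble::tibble(
      compound_id = paste0("DECOY", sprintf("%04d", d_i)),
      name = paste0("Decoy ", d_i), formula = "unknown",
      monoisotopic_mass = mass, rt = NA_real_,
      superclass = "Decoys", class = NA_character_,
      subclass = NA_character_, pathway = NA_character_
    )
  }

  compounds <- dplyr::bind_rows(c(comp_rows, decoy_rows))
  if (nrow(compounds) == 0) {
    compounds <- tibble::tibble(
      compound_id = character(), name = character(), formula = character(),
      monoisotopic_mass = numeric(), rt = numeric(), superclass = character(),
      class = character(), subclass = character(), pathway = character()
    )
  }
  lib <- structure(list(compounds = compounds, ms2 = ms2),
                   class = "spectral_library")
  list(
    library = lib,
    truth = dplyr::bind_rows(truth_rows),
    dataset = dataset
  )
}

#' Named simulation presets
#'
#' Three ready-made study designs used throughout the tests and examples:
#' \describe{
#'   \item{`"fbox-like"`}{A large mutant-panel design: 2,583 features over
#'     206 subject samples in 20 groups and 3 batches, 12 planted
#'     co-accumulation modules of 114 features (within-module correlation
#'     0.9), pooled QC every 10 injections, mild drift (0.005/injection),
#'     batch offsets, and mixed MCAR/MNAR missingness.}
#'   \item{`"drift-3batch"`}{A complete (no-missing) 300-feature, 90-sample
#'     table over 3 batches with strong drift (0.02/injection), per-batch
#'     level shifts and dense QC coverage — the drift-correction and batch
#'     integration test bed.}
#'   \item{`"planted-modules"`}{5 modules of 40 features (within-module
#'     correlation 0.9) plus 100 uncorrelated noise features across 100
#'     samples, complete matrix — the module-recovery test bed.}
#' }
#'
#' @param name Preset name.
#' @param seed Random seed.
#' @return As [simulate_dataset()]: list with `dataset` and `truth`.
#' @export
simulate_preset <- function(name = c("fbox-like", "drift-3batch",
                                     "planted-modules"), seed = 1) {
  name <- match.arg(name)
  switch(name,
    "fbox-like" = simulate_dataset(
      n_features = 2583, n_samples = 206, n_groups = 20, n_batches = 3,
      n_modules = 12, module_size = 114, within_cor = 0.9, qc_every = 10,
      drift_slope = 0.005, mcar_rate = 0.02, mnar_coef = 1,
      n_effect_features = 100, effect_log2 = 1, batch_sd = 0.2, seed = seed
    ),
    "drift-3batch" = simulate_dataset(
      n_features = 300, n_samples = 90, n_groups = 3, n_batches = 3,
      n_modules = 0, qc_every = 5, drift_slope = 0.02, mcar_rate = 0,
      mnar_coef = 0, batch_sd = 0.3, seed = seed
    ),
    "planted-modules" = simulate_dataset(
      n_features = 300, n_samples = 100, n_groups = 2, n_batches = 1,
      n_modules = 5, module_size = 40, within_cor = 0.9, qc_every = 10,
      drift_slope = 0, mcar_rate = 0, mnar_coef = 0, seed = seed
    )
  )
}
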