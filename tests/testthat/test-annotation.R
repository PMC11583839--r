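test_that("adduct m/z arithmetic is standard", {
  expect_equal(adduct_mz(180.0634, "[M+H]+"), 181.0707, tolerance = 1e-4)
  # [M+H]+ and [M-H]- differ by exactly two proton masses
  M <- 300.1234
  expect_equal(adduct_mz(M, "[M+H]+") - adduct_mz(M, "[M-H]-"),
               2 * 1.007276466, tolerance = 1e-9)
  expect_error(adduct_mz(100, "[2M+H]+"), "unsupported adduct")
})

test_that("MS1 matching equals an exhaustive scan over records and adducts", {
  set.seed(21)
  lib <- structure(list(
    compounds = tibble::tibble(
      compound_id = paste0("C", 1:200),
      name = paste0("cpd", 1:200),
      formula = "unknown",
      monoisotopic_mass = runif(200, 100, 900),
      rt = NA_real_, superclass = NA_character_, class = NA_character_,
      subclass = NA_character_, pathway = NA_character_
    ),
    ms2 = list()
  ), class = "spectral_library")

  feat <- list(mz = 350.25, polarity = "pos")
  got <- match_ms1(feat, lib, ppm_tol = 500, polarity_filter = TRUE)

  # brute force over all records x positive adducts
  adducts <- c("[M+H]+", "[M+Na]+", "[M+NH4]+", "[M-H2O+H]+")
  expected <- list()
  for (a in adducts) {
    theo <- adduct_mz(lib$compounds$monoisotopic_mass, a)
    ppm <- 1e6 * (feat$mz - theo) / theo
    hit <- which(abs(ppm) <= 500)
    for (h in hit) {
      expected[[length(expected) + 1L]] <-
        list(id = lib$compounds$compound_id[h], adduct = a, ppm = ppm[h])
    }
  }
  expect_equal(nrow(got), length(expected))
  key_got <- sort(paste(got$compound_id, got$adduct))
  key_exp <- sort(vapply(expected, function(e) paste(e$id, e$adduct), ""))
  expect_equal(key_got, key_exp)
  # sorted by absolute error
  expect_true(all(diff(abs(got$mz_error_ppm)) >= 0))

  # degenerate tolerance: only exact matches survive
  exact_mass <- feat$mz - 1.007276466
  lib$compounds$monoisotopic_mass[1] <- exact_mass
  hit0 <- match_ms1(feat, lib, ppm_tol = 0)
  expect_equal(hit0$compound_id, "C1")
  expect_equal(hit0$mz_error_ppm, 0, tolerance = 1e-9)
})

test_that("candidate count is monotone in the ppm tolerance", {
  set.seed(31)
  lib <- structure(list(
    compounds = tibble::tibble(
      compound_id = paste0("C", 1:100), name = "x", formula = "x",
      monoisotopic_mass = runif(100, 100, 500), rt = NA_real_,
      superclass = NA_character_, class = NA_character_,
      subclass = NA_character_, pathway = NA_character_
    ), ms2 = list()
  ), class = "spectral_library")
  feat <- list(mz = 250.1, polarity = "pos")
  counts <- sapply(c(1, 10, 100, 1000, 1e4), function(tol) {
    nrow(match_ms1(feat, lib, ppm_tol = tol))
  })
  expect_true(all(diff(counts) >= 0))
})

test_that("fragment cosine matches hand arithmetic and its invariants", {
  s1 <- spectrum(c(100, 150), c(1.0, 0.5))
  s2 <- spectrum(100, 1.0)
  # sqrt intensities: q = (1, sqrt(.5)), r = (1); matched dot = 1
  expect_equal(score_ms2(s1, s2), 1 / sqrt(1.5), tolerance = 1e-12)

  expect_equal(score_ms2(s1, s1), 1.0)                      # identity
  s3 <- spectrum(c(400, 500), c(1, 1))
  expect_equal(score_ms2(s1, s3), 0.0)                      # disjoint

  # symmetry and scale invariance
  set.seed(12)
  a <- spectrum(sort(runif(6, 50, 300)), runif(6))
  b <- spectrum(sort(runif(5, 50, 300)), runif(5))
  expect_equal(score_ms2(a, b), score_ms2(b, a), tolerance = 1e-12)
  b10 <- b; b10$peaks[, "intensity"] <- b10$peaks[, "intensity"] * 10
  expect_equal(score_ms2(a, b), score_ms2(a, b10), tolerance = 1e-12)
  expect_gte(score_ms2(a, b), 0)
  expect_lte(score_ms2(a, b), 1)
})

planted_fixture <- function() {
  # 5 features, 5 compounds with planted evidence tiers:
  # F1 level 1 (mz+rt+ms2), F2 level 2 (mz+ms2), F3 level 3 (mz only),
  # F4/F5 no match (decoy masses far away)
  fi <- tibble::tibble(
    feature_id = paste0("F", 1:5),
    mz = c(181.0707, 255.2330, 301.1400, 449.1078, 609.1461),
    rt = c(120, 240, 360, 480, 600),
    polarity = "pos", adduct = NA_character_
  )
  si <- tibble::tibble(sample_id = c("S1", "QC1"),
                       class = c("Subject", "QC"), group = c("A", "QC"),
                       batch = "B1", injection_order = 1:2)
  ds <- metabo_dataset(matrix(1000, 5, 2), si, fi)
  spec1 <- spectrum(c(80.05, 120.2, 163.06), c(1, 0.4, 0.7),
                    precursor = 181.0707)
  spec2 <- spectrum(c(97.1, 140.3), c(1, 0.2), precursor = 255.2330)
  ds$ms2 <- list(F1 = list(spec1), F2 = list(spec2))

  comp <- tibble::tibble(
    compound_id = paste0("C", 1:5),
    name = paste0("cpd", 1:5), formula = "unknown",
    monoisotopic_mass = c(181.0707, 255.2330, 301.1400, 600.0, 700.0) -
      1.007276466,
    rt = c(118, NA, NA, NA, NA),
    superclass = NA_character_, class = NA_character_,
    subclass = NA_character_, pathway = NA_character_
  )
  lib <- structure(
    list(compounds = comp, ms2 = list(C1 = list(spec1), C2 = list(spec2))),
    class = "spectral_library"
  )
  list(ds = ds, lib = lib)
}

test_that("MSI levels follow the planted evidence tiers exactly", {
  fx <- planted_fixture()
  ann <- annotate_features(fx$ds, fx$lib, ppm_tol = 25)
  ann <- deduplicate_annotations(ann)
  expect_equal(ann$level[ann$feature_id == "F1"], 1L)
  expect_equal(ann$level[ann$feature_id == "F2"], 2L)
  expect_equal(ann$level[ann$feature_id == "F3"], 3L)
  expect_false(any(c("F4", "F5") %in% ann$feature_id))
  # level filtering
  ann23 <- annotate_features(fx$ds, fx$lib, levels_allowed = c(2, 3))
  expect_false(any(ann23$level == 1))
})

test_that("level assignment is monotone in evidence", {
  fx <- planted_fixture()
  # removing the feature's MS2 spectrum can only demote, never promote
  with_ms2 <- deduplicate_annotations(annotate_features(fx$ds, fx$lib))
  no_ms2 <- fx$ds
  no_ms2$ms2 <- list()
  without <- deduplicate_annotations(annotate_features(no_ms2, fx$lib))
  shared <- intersect(with_ms2$feature_id, without$feature_id)
  for (f in shared) {
    expect_lte(with_ms2$level[with_ms2$feature_id == f],
               without$level[without$feature_id == f])
  }
})

test_that("deduplication keeps the best record with deterministic tie-breaks", {
  rows <- tibble::tibble(
    feature_id = c("F1", "F1", "F2", "F2"),
    mz = 200, rt = 100,
    compound_id = c("C1", "C2", "C4", "C3"),
    name = "x", adduct = "[M+H]+",
    mz_error_ppm = c(5, 1, -3, 3),
    rt_error_s = NA_real_, ms2_score = NA_real_,
    total_score = c(0.9, 0.7, 0.5, 0.5),
    level = c(3L, 3L, 3L, 3L)
  )
  out <- deduplicate_annotations(rows)
  expect_equal(out$total_score[out$feature_id == "F1"], 0.9)
  # F2 tie at equal score and level: smaller |ppm| wins (both are 3)
  # |-3| == |3| -> falls to lexicographic compound_id
  expect_equal(out$compound_id[out$feature_id == "F2"], "C3")
  # permutation invariance
  out2 <- deduplicate_annotations(rows[c(4, 2, 3, 1), ])
  expect_equal(out, out2)
  expect_equal(nrow(deduplicate_annotations(rows[0, ])), 0)
})
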