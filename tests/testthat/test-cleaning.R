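test_that("missing rates match a direct count/denominator recount", {
  set.seed(7)
  ds <- toy_dataset(n_features = 30, n_samples = 16, n_qc = 4)
  mask <- matrix(runif(30 * 16) < 0.3, 30, 16)
  ds$expression[mask] <- NA_real_
  prof <- missing_profile(ds)

  si <- ds$sample_info
  qc_ids <- si$sample_id[si$class == "QC"]
  for (f in sample(1:30, 10)) {
    expect_equal(prof$feature_rates$qc_rate[f],
                 mean(is.na(ds$expression[f, qc_ids])))
    for (g in c("A", "B")) {
      ids <- si$sample_id[si$class == "Subject" & si$group == g]
      expect_equal(prof$feature_rates[[paste0("group_", g)]][f],
                   mean(is.na(ds$expression[f, ids])))
    }
  }
  expect_equal(prof$sample_rates$rate, unname(colMeans(is.na(ds$expression))))

  # fully observed dataset has all-zero rates
  clean <- toy_dataset(n_features = 8, n_samples = 8, n_qc = 2)
  p2 <- missing_profile(clean)
  expect_true(all(p2$feature_rates$qc_rate == 0))
  expect_true(all(p2$sample_rates$rate == 0))
})

test_that("noise filter applies the QC-or-every-group rule with strict thresholds", {
  ds <- toy_dataset(n_features = 4, n_samples = 10, n_qc = 4)
  si <- ds$sample_info
  qc_ids <- si$sample_id[si$class == "QC"]
  a_ids <- si$sample_id[si$group == "A"]
  b_ids <- si$sample_id[si$group == "B"]

  ds$expression["F1", qc_ids[1:2]] <- NA     # qc_rate 0.5 -> removed
  ds$expression["F2", b_ids] <- NA           # fully missing in B only -> kept
  ds$expression["F3", c(a_ids, b_ids)] <- NA # missing in every group -> removed
  # F4: qc_rate exactly at the threshold is retained (strict >)
  ds4 <- ds
  ds4$expression["F4", qc_ids[1]] <- NA      # 1/4 = 0.25 > 0.2 -> removed
  out <- filter_noise(ds4)
  expect_setequal(out$feature_info$feature_id, "F2")

  out2 <- filter_noise(ds4, qc_thresh = 0.25)   # 0.25 not > 0.25 -> F4 kept
  expect_true("F4" %in% out2$feature_info$feature_id)

  expect_error(filter_noise(ds, qc_thresh = 1.2), "0, 1")
})

test_that("noise filter is monotone in its thresholds", {
  set.seed(11)
  ds <- toy_dataset(n_features = 60, n_samples = 20, n_qc = 5)
  ds$expression[matrix(runif(60 * 20) < 0.25, 60, 20)] <- NA_real_
  counts <- sapply(c(0.1, 0.2, 0.4, 0.8), function(th) {
    nrow(filter_noise(ds, qc_thresh = th, group_thresh = th)$expression)
  })
  expect_true(all(diff(counts) >= 0))
})

test_that("outlier triage partitions Subject samples at the documented boundaries", {
  ds <- toy_dataset(n_features = 10, n_samples = 5, n_qc = 2)
  # engineer per-sample missing rates 0.1, 0.5, 0.9 on subjects S1..S3
  ds$expression[1, "S1"] <- NA
  ds$expression[1:5, "S2"] <- NA
  ds$expression[1:9, "S3"] <- NA
  tri <- triage_outliers(ds)
  expect_equal(tri$keep, "S1")
  expect_equal(tri$review, "S2")   # boundary 0.5 falls in the closed interval
  expect_equal(tri$remove, "S3")
  expect_setequal(c(tri$keep, tri$review, tri$remove),
                  ds$sample_info$sample_id[ds$sample_info$class == "Subject"])

  clean <- toy_dataset()
  tri2 <- triage_outliers(clean)
  expect_length(tri2$review, 0)
  expect_length(tri2$remove, 0)
  expect_error(triage_outliers(ds, keep_below = 0.9, remove_above = 0.5),
               "keep_below")
})

test_that("KNN imputation reproduces a hand-computed neighbour mean", {
  # 4 features x 3 samples; F1 missing in S3
  expr <- matrix(c(
    10, 12, NA,
    10, 12, 14,
    11, 13, 15,
    40, 10, 80
  ), nrow = 4, byrow = TRUE)
  expr <- 2^expr - 1   # so log2(x+1) recovers the values above
  si <- tibble::tibble(
    sample_id = c("S1", "S2", "S3"), class = "Subject",
    group = "A", batch = "B1", injection_order = 1:3
  )
  fi <- tibble::tibble(feature_id = paste0("F", 1:4),
                       mz = 100 + 1:4, rt = 1:4 * 10,
                       polarity = "pos", adduct = NA_character_)
  ds <- metabo_dataset(expr, si, fi)
  out <- impute_knn(ds, k = 2)
  # log2 distances over shared samples S1,S2: F2 is 0, F3 is 1, F4 dominates;
  # imputed value = mean of F2 and F3 raw values in S3
  expected <- mean(c(2^14 - 1, 2^15 - 1))
  expect_equal(out$expression[1, 3], expected)
  # observed values untouched
  obs <- !is.na(ds$expression)
  expect_identical(out$expression[obs], ds$expression[obs])
  expect_false(anyNA(out$expression))
})

test_that("imputation is the identity on complete data and validates k", {
  ds <- toy_dataset()
  out <- impute_knn(ds, k = 3)
  expect_identical(out$expression, ds$expression)
  expect_error(impute_knn(ds, k = 10), "smaller than")
})

test_that("KNN beats per-feature mean imputation on correlated data", {
  sim <- simulate_dataset(n_features = 120, n_samples = 60, n_modules = 3,
                          module_size = 40, within_cor = 0.9, seed = 5)
  ds <- sim$dataset
  truth <- ds$expression
  set.seed(99)
  mask <- matrix(runif(length(truth)) < 0.1, nrow(truth), ncol(truth))
  # keep every feature partially observed
  mask[, 1] <- FALSE
  ds$expression[mask] <- NA_real_
  out <- impute_knn(ds, k = 10)
  rel_err <- abs(out$expression[mask] - truth[mask]) / truth[mask]

  mean_imp <- ds$expression
  fmeans <- rowMeans(mean_imp, na.rm = TRUE)
  idx <- which(mask, arr.ind = TRUE)
  rel_err_mean <- abs(fmeans[idx[, 1]] - truth[mask]) / truth[mask]
  expect_lt(median(rel_err), median(rel_err_mean))
})

test_that("SVR normalization is near-identity without drift and removes drift", {
  # drift-free: corrected stays within 1% of raw
  flat <- simulate_dataset(n_features = 40, n_samples = 40, qc_every = 5,
                           drift_slope = 0, qc_noise_sd = 0.002, seed = 3)
  ds <- flat$dataset
  out <- normalize_svr_qc(ds)
  rel <- abs(out$expression - ds$expression) / ds$expression
  expect_lt(max(rel), 0.01)

  # monotone drift: median QC RSD strictly decreases
  drift <- simulate_dataset(n_features = 60, n_samples = 60, qc_every = 5,
                            drift_slope = 0.02, seed = 4)
  before <- qc_rsd(drift$dataset)$median
  corr <- normalize_svr_qc(drift$dataset)
  after <- qc_rsd(corr)$median
  expect_lt(after, before)
})

test_that("SVR normalization refuses sparse QC unless the fallback is requested", {
  ds <- toy_dataset(n_features = 10, n_samples = 8, n_qc = 2)
  expect_error(normalize_svr_qc(ds), "fallback")
  out <- normalize_svr_qc(ds, fallback = TRUE)
  expect_s3_class(out, "metabo_dataset")
})

test_that("batch integration equalizes per-feature QC medians", {
  ds <- toy_dataset(n_features = 6, n_samples = 12, n_qc = 4)
  ds$sample_info$batch <- rep(c("B1", "B2"), each = 6)
  ds$sample_info$injection_order <- rep(1:6, 2)
  ds$sample_info$class[c(5, 6, 11, 12)] <- "QC"
  ds$sample_info$class[1:4] <- "Subject"
  ds$sample_info$class[7:10] <- "Subject"
  # plant a 2x offset on feature 1 in batch 2
  b2 <- ds$sample_info$sample_id[ds$sample_info$batch == "B2"]
  ds$expression[1, b2] <- ds$expression[1, b2] * 2
  out <- integrate_batches(ds)
  si <- out$sample_info
  for (f in 1:2) {
    meds <- sapply(c("B1", "B2"), function(b) {
      ids <- si$sample_id[si$batch == b & si$class == "QC"]
      median(out$expression[f, ids])
    })
    expect_equal(meds[["B1"]], meds[["B2"]])
  }
  # single-batch input is a no-op
  one <- toy_dataset()
  expect_identical(integrate_batches(one)$expression, one$expression)
})

test_that("full cleaning on the drifted preset reduces QC RSD and batch structure", {
  sim <- simulate_preset("drift-3batch", seed = 2)
  ds <- sim$dataset
  before_rsd <- qc_rsd(ds)$median
  ds2 <- integrate_batches(normalize_svr_qc(ds))
  expect_lt(qc_rsd(ds2)$median, before_rsd)
})
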