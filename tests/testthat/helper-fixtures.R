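# Small fixture builders shared across test files.

toy_dataset <- function(n_features = 10, n_samples = 6, n_qc = 2,
                        missing = NULL, seed = 42) {
  set.seed(seed)
  n_subj <- n_samples - n_qc
  expr <- matrix(2^stats::rnorm(n_features * n_samples, mean = 16, sd = 1),
                 n_features, n_samples)
  if (!is.null(missing)) expr[missing] <- NA_real_
  si <- tibble::tibble(
    sample_id = c(paste0("S", seq_len(n_subj)),
                  if (n_qc > 0) paste0("QC", seq_len(n_qc)) else character(0)),
    class = c(rep("Subject", n_subj), rep("QC", n_qc)),
    group = c(rep(c("A", "B"), length.out = n_subj), rep("QC", n_qc)),
    batch = "B1",
    injection_order = seq_len(n_samples)
  )
  fi <- tibble::tibble(
    feature_id = paste0("F", seq_len(n_features)),
    mz = round(stats::runif(n_features, 100, 900), 4),
    rt = round(stats::runif(n_features, 60, 600), 1),
    polarity = "pos",
    adduct = NA_character_
  )
  metabo_dataset(expr, si, fi)
}

spectrum <- function(mz, intensity, precursor = max(mz) + 50,
                     polarity = "pos", rt = NA_real_) {
  o <- order(mz)
  list(precursor_mz = precursor, polarity = polarity, rt = rt,
       peaks = cbind(mz = mz[o], intensity = intensity[o]))
}

write_lines_tmp <- function(lines, ext = ".csv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
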