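#' Differential accumulation analysis between two groups
#'
#' Per feature: a Welch t-test (or Wilcoxon rank-sum test) on log2(x + 1)
#' intensities, Benjamini-Hochberg (or Bonferroni/BY) adjustment across all
#' features, the log2 ratio of raw group means, and a PLS-DA variable
#' importance (VIP) computed by NIPALS on the unit-variance-scaled log2 data
#' of the two compared groups.
#'
#' Zero-variance features get p = 1 and are flagged rather than erroring:
#' a constant feature carries no between-group evidence.
#'
#' @param dataset Imputed `metabo_dataset`.
#' @param group_a,group_b Group labels (Subject samples only).
#' @param test `"t"` (Welch) or `"wilcoxon"`.
#' @param fdr_method `"BH"` (default), `"bonferroni"` or `"BY"`.
#' @param pls_components Number of PLS components for the VIP (default 2).
#' @return Tibble with one row per feature: `feature_id`, `mean_a`, `mean_b`,
#'   `log2_fc`, `p_value`, `fdr`, `vip`, `flag`.
#' @export
dam_analysis <- function(dataset, group_a, group_b,
                         test = c("t", "wilcoxon"),
                         fdr_method = c("BH", "bonferroni", "BY"),
                         pls_components = 2) {
  test <- match.arg(test)
  fdr_method <- match.arg(fdr_method)
  si <- dataset$sample_info
  a_ids <- si$sample_id[si$class == "Subject" & si$group == group_a]
  b_ids <- si$sample_id[si$class == "Subject" & si$group == group_b]
  if (length(a_ids) == 0) stop("group not found: ", group_a, call. = FALSE)
  if (length(b_ids) == 0) stop("group not found: ", group_b, call. = FALSE)
  if (length(a_ids) < 3 || length(b_ids) < 3) {
    warning("fewer than 3 samples in a group; p-values will be unstable",
            call. = FALSE)
  }
  e <- dataset$expression
  if (anyNA(e)) stop("dam_analysis requires an imputed matrix", call. = FALSE)
  xa <- e[, a_ids, drop = FALSE]
  xb <- e[, b_ids, drop = FALSE]
  la <- log2(xa + 1)
  lb <- log2(xb + 1)

  if (test == "t") {
    p <- welch_t_rows(la, lb)
  } else {
    p <- vapply(seq_len(nrow(la)), function(f) {
      if (stats::sd(c(la[f, ], lb[f, ])) == 0) return(1)
      stats::wilcox.test(la[f, ], lb[f, ], exact = NULL)$p.value
    }, numeric(1))
  }
  flag <- ifelse(
    apply(la, 1, stats::sd) == 0 & apply(lb, 1, stats::sd) == 0 &
      rowMeans(la) == rowMeans(lb),
    "zero_variance", ""
  )
  p[flag == "zero_variance"] <- 1

  mean_a <- rowMeans(xa)
  mean_b <- rowMeans(xb)
  log2_fc <- log2(mean_a / mean_b)

  vip <- pls_vip(cbind(la, lb),
                 c(rep(1, length(a_ids)), rep(0, length(b_ids))),
                 ncomp = pls_components)

  tibble::tibble(
    feature_id = dataset$feature_info$feature_id,
    mean_a = unname(mean_a), mean_b = unname(mean_b),
    log2_fc = unname(log2_fc),
    p_value = unname(p),
    fdr = unname(stats::p.adjust(p, method = fdr_method)),
    vip = unname(vip), flag = unname(flag)
  )
}

# vectorized Welch t-test over matrix rows (unequal variances,
# Welch-Satterthwaite df); cross-checked against stats::t.test in tests
welch_t_rows <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  p[!is.finite(t)] <- 1
  p
}

#' PLS-DA variable importance in projection
#'
#' NIPALS PLS1 regression of a group indicator on the unit-variance-scaled
#' feature matrix; VIP_j = sqrt(p * sum_a(ssy_a w_ja^2) / sum_a(ssy_a)) with
#' normalized loading weights, so the mean squared VIP over features is 1.
#'
#' @param x Matrix features x samples (log scale).
#' @param y Numeric group indicator per sample.
#' @param ncomp Number of components (default 2).
#' @return Numeric VIP per feature (row of `x`).
#' @export
pls_vip <- function(x, y, ncomp = 2) {
  X <- t(x)                               # samples x features
  keep <- apply(X, 2, stats::sd) > 0
  Xs <- scale(X[, keep, drop = FALSE])
  yc <- as.numeric(scale(y, scale = FALSE))
  n <- nrow(Xs); p <- ncol(Xs)
  ncomp <- min(ncomp, p, n - 1)
  W <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp)
  ssy <- numeric(ncomp)
  Xd <- Xs; yd <- yc
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { ncomp <- a - 1L; break }
    w <- w / nw
    t_a <- Xd %*% w
    tt <- sum(t_a^2)
    p_a <- crossprod(Xd, t_a) / tt
    q_a <- sum(yd * t_a) / tt
    Xd <- Xd - t_a %*% t(p_a)
    yd <- yd - q_a * t_a
    W[, a] <- w
    Tm[, a] <- t_a
    ssy[a] <- q_a^2 * tt
  }
  if (ncomp == 0) return(rep(1, nrow(x)))
  W <- W[, seq_len(ncomp), drop = FALSE]
  ssy <- ssy[seq_len(ncomp)]
  vip_kept <- sqrt(p * as.numeric(W^2 %*% ssy) / sum(ssy))
  out <- rep(NA_real_, nrow(x))
  out[keep] <- vip_kept
  out[!keep] <- 0
  out
}

#' Select differentially accumulated metabolites
#'
#' Applies the three standard criteria — absolute fold change, FDR, VIP — and
#' returns per-criterion membership plus all intersection counts (ready for
#' an UpSet-style summary).
#'
#' @param rows Tibble from [dam_analysis()].
#' @param fc_min Minimum fold change (linear scale; default 2 means
#'   |log2 FC| >= 1).
#' @param fdr_max FDR ceiling (default 0.05).
#' @param vip_min VIP floor (default 1).
#' @return List with `membership` (tibble: `feature_id`, logical `fc`, `fdr`,
#'   `vip`, `selected` = all three) and `intersections` (tibble of pattern
#'   counts).
#' @export
select_dam <- function(rows, fc_min = 2, fdr_max = 0.05, vip_min = 1) {
  rows <- tibble::as_tibble(rows)
  if (nrow(rows) == 0) {
    return(list(
      membership = tibble::tibble(feature_id = character(), fc = logical(),
                                  fdr = logical(), vip = logical(),
                                  selected = logical()),
      intersections = tibble::tibble(fc = logical(), fdr = logical(),
                                     vip = logical(), n = integer())
    ))
  }
  membership <- tibble::tibble(
    feature_id = rows$feature_id,
    fc = abs(rows$log2_fc) >= log2(fc_min),
    fdr = rows$fdr <= fdr_max,
    vip = rows$vip >= vip_min
  )
  membership$selected <- membership$fc & membership$fdr & membership$vip
  intersections <- membership |>
    dplyr::count(.data$fc, .data$fdr, .data$vip, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n))
  list(membership = membership, intersections = intersections)
}

#' Hypergeometric enrichment over term sets
#'
#' Upper-tail hypergeometric test P(X >= k) for each term (chemical class or
#' pathway): population `N = |universe|`, term successes
#' `n = |term ∩ universe|`, draws `m = |selected|`, overlap `k`. BH
#' adjustment across terms; `ratio = k/n` is the dot-size statistic used in
#' enrichment plots.
#'
#' @param selected Character vector of selected ids (subset of `universe`).
#' @param term_map Named list: term -> character vector of member ids.
#' @param universe Character vector of all eligible ids.
#' @param term_labels Optional named character vector of display labels.
#' @return Tibble: `term_id`, `term_label`, `k`, `n`, `m`, `N`, `ratio`,
#'   `p_value`, `fdr`, sorted by p-value.
#' @export
enrich_terms <- function(selected, term_map, universe, term_labels = NULL) {
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  universe <- unique(universe)
  selected <- intersect(unique(selected), universe)
  N <- length(universe)
  m <- length(selected)
  rows <- purrr::imap(term_map, function(members, term) {
    members <- intersect(unique(members), universe)
    n <- length(members)
    if (n == 0) return(NULL)
    k <- length(intersect(members, selected))
    p <- stats::phyper(k - 1, n, N - n, m, lower.tail = FALSE)
    tibble::tibble(
      term_id = term,
      term_label = if (!is.null(term_labels) && term %in% names(term_labels))
        term_labels[[term]] else term,
      k = k, n = n, m = m, N = N,
      ratio = k / n, p_value = p
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(term_id = character(), term_label = character(),
                          k = integer(), n = integer(), m = integer(),
                          N = integer(), ratio = numeric(),
                          p_value = numeric(), fdr = numeric()))
  }
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  dplyr::arrange(out, .data$p_value)
}
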