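#' Soft-threshold power selection by scale-free fit
#'
#' For each candidate power, the weighted connectivity of every feature is
#' `k_i = sum_{u != i} |cor(x_i, x_u)|^beta` (or the signed analogue), and
#' the scale-free topology fit is the signed R^2 of the regression of
#' log10 frequency on log10 mean connectivity over 10 bins (negative slope
#' counts positively). The chosen power is the smallest one whose signed R^2
#' reaches `rsq_cut`, else the argmax.
#'
#' @param x Matrix samples x features, no missing values.
#' @param powers Candidate integer powers (default 1:20).
#' @param rsq_cut Signed R^2 target (default 0.8).
#' @param network_type `"unsigned"` (default) or `"signed"`.
#' @return List with `power` and `fit` (tibble: `power`, `rsq_signed`,
#'   `mean_k`, `median_k`, `max_k`).
#' @export
pick_soft_threshold <- function(x, powers = 1:20, rsq_cut = 0.8,
                                network_type = c("unsigned", "signed")) {
  network_type <- match.arg(network_type)
  if (nrow(x) < 15) {
    warning("fewer than 15 samples; soft-threshold fit may be unstable",
            call. = FALSE)
  }
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant feature(s) removed before correlation",
            call. = FALSE)
    x <- x[, sds > 0, drop = FALSE]
  }
  cors <- stats::cor(x)
  base <- if (network_type == "unsigned") abs(cors) else (1 + cors) / 2
  diag(base) <- 0
  fit <- purrr::map(powers, function(beta) {
    k <- colSums(base^beta)
    tibble::tibble(
      power = beta,
      rsq_signed = scale_free_rsq(k),
      mean_k = mean(k), median_k = stats::median(k), max_k = max(k)
    )
  }) |> dplyr::bind_rows()
  hit <- which(fit$rsq_signed >= rsq_cut)
  power <- if (length(hit) > 0) {
    fit$power[hit[1]]
  } else {
    fit$power[which.max(fit$rsq_signed)]
  }
  list(power = power, fit = fit)
}

# signed scale-free topology fit index over 10 log-spaced connectivity bins
scale_free_rsq <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(k) < n_bins) return(NA_real_)
  cuts <- cut(k, breaks = n_bins)
  dk <- tapply(k, cuts, mean)
  pk <- tapply(k, cuts, length) / length(k)
  keep <- !is.na(dk) & dk > 0 & !is.na(pk) & pk > 0
  if (sum(keep) < 3) return(NA_real_)
  lx <- log10(dk[keep]); ly <- log10(pk[keep])
  f <- stats::lm(ly ~ lx)
  r2 <- summary(f)$r.squared
  -sign(stats::coef(f)[2]) * r2
}

#' Topological overlap matrix
#'
#' Adjacency `a_ij = |cor|^beta` (unsigned) or `((1 + cor)/2)^beta` (signed);
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' unit diagonal. Symmetric with entries in \[0, 1\]; two features overlap
#' strongly when they are directly connected and share neighbours.
#'
#' @param x Matrix samples x features, complete.
#' @param beta Soft-threshold power.
#' @param network_type `"unsigned"` or `"signed"`.
#' @return Features x features TOM matrix.
#' @export
tom_matrix <- function(x, beta, network_type = c("unsigned", "signed")) {
  network_type <- match.arg(network_type)
  if (ncol(x) < 3) stop("need at least 3 features for TOM", call. = FALSE)
  cors <- stats::cor(x)
  a <- if (network_type == "unsigned") abs(cors)^beta else ((1 + cors) / 2)^beta
  diag(a) <- 0
  k <- rowSums(a)
  num <- a %*% a + a
  minK <- outer(k, k, pmin)
  tom <- num / (minK + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Eigenmetabolite of a module
#'
#' The first principal component of the module's standardized (per-feature
#' z-scored) submatrix, extracted via singular value decomposition and
#' sign-flipped so that its mean correlation with the member profiles is
#' positive. It summarizes the module's accumulation pattern across samples.
#'
#' @param x Matrix samples x features restricted to one module's members.
#' @return Numeric vector, one value per sample.
#' @export
eigenmetabolite <- function(x) {
  xs <- scale(x)
  xs[is.na(xs)] <- 0
  sv <- svd(xs, nu = 1, nv = 0)
  me <- sv$u[, 1]
  if (mean(stats::cor(me, x), na.rm = TRUE) < 0) me <- -me
  me
}

#' Detect modules from a TOM
#'
#' Average-linkage hierarchical clustering on dissimilarity `1 - TOM`, static
#' tree cut at 0.995 of the maximum merge height; clusters smaller than
#' `min_module_size` become `"grey"` (unassigned). Eigenmetabolites are
#' computed per module and modules whose eigenmetabolites correlate above
#' `1 - merge_cut` are merged (and their eigenmetabolites recomputed) until
#' stable. Modules are labelled `"M1"`, `"M2"`, ... in decreasing size order.
#'
#' @param tom TOM matrix from [tom_matrix()].
#' @param x Matrix samples x features aligned with `tom` columns.
#' @param min_module_size Minimum module size (default 10).
#' @param merge_cut Eigenmetabolite dissimilarity below which modules merge
#'   (default 0.25, i.e. correlation above 0.75).
#' @param cut_height_frac Fraction of the maximum merge height for the static
#'   cut (default 0.995).
#' @return List with `assignments` (named character vector feature ->
#'   module), `eigenmetabolites` (matrix samples x modules).
#' @export
detect_modules <- function(tom, x, min_module_size = 10, merge_cut = 0.25,
                           cut_height_frac = 0.995) {
  d <- stats::as.dist(1 - tom)
  tree <- stats::hclust(d, method = "average")
  # guard against tiny floating-point inversions in the merge heights
  if (is.unsorted(tree$height)) tree$height <- cummax(tree$height)
  h <- cut_height_frac * max(tree$height)
  cl <- stats::cutree(tree, h = h)
  sizes <- table(cl)
  keep_cl <- names(sizes)[sizes >= min_module_size]
  labels <- ifelse(cl %in% as.integer(keep_cl), as.character(cl), "grey")
  names(labels) <- colnames(tom)

  if (all(labels == "grey")) {
    warning("no module reached min_module_size; all features grey",
            call. = FALSE)
    return(list(
      assignments = labels,
      eigenmetabolites = matrix(numeric(0), nrow = nrow(x), ncol = 0)
    ))
  }

  compute_mes <- function(labels) {
    mods <- setdiff(unique(labels), "grey")
    me <- vapply(mods, function(m) {
      eigenmetabolite(x[, labels == m, drop = FALSE])
    }, numeric(nrow(x)))
    colnames(me) <- mods
    me
  }

  # merge close modules until no eigenmetabolite pair exceeds 1 - merge_cut
  repeat {
    me <- compute_mes(labels)
    mods <- colnames(me)
    if (length(mods) < 2) break
    cc <- stats::cor(me)
    diag(cc) <- -Inf
    top <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    if (cc[top[1], top[2]] <= 1 - merge_cut) break
    labels[labels == mods[top[2]]] <- mods[top[1]]
  }

  me <- compute_mes(labels)
  mods <- names(sort(table(labels[labels != "grey"]), decreasing = TRUE))
  new_names <- stats::setNames(paste0("M", seq_along(mods)), mods)
  labels[labels != "grey"] <- new_names[labels[labels != "grey"]]
  me <- me[, mods, drop = FALSE]
  colnames(me) <- new_names[mods]
  list(assignments = labels, eigenmetabolites = me)
}

#' Module membership (kME)
#'
#' Pearson correlation of each feature's profile with each module
#' eigenmetabolite; the own-module kME measures how central a feature is in
#' its module.
#'
#' @param x Matrix samples x features.
#' @param eigenmetabolites Matrix samples x modules.
#' @return Matrix features x modules of correlations in \[-1, 1\].
#' @export
compute_kme <- function(x, eigenmetabolites) {
  kme <- stats::cor(x, eigenmetabolites)
  rownames(kme) <- colnames(x)
  kme
}

#' Iterative weighted-correlation-network module detection
#'
#' Round r: build the TOM on the current feature set (the soft-threshold
#' power is selected in round 1 and then held fixed), detect modules, compute
#' kME, and drop every feature that is unassigned (grey) or whose own-module
#' kME falls below `kme_cutoff`. Iteration stops when a round drops no
#' feature or `max_rounds` is reached, leaving only features that cluster
#' consistently into co-accumulation modules.
#'
#' @param x Matrix samples x features (cleaned, imputed; log scale
#'   recommended).
#' @param power Soft-threshold power, or `NULL` to select via
#'   [pick_soft_threshold()].
#' @param network_type `"unsigned"` (default) or `"signed"`.
#' @param min_module_size Minimum module size (default 10).
#' @param merge_cut Module-merge dissimilarity cut (default 0.25).
#' @param kme_cutoff Own-module kME below which a feature is dropped between
#'   rounds (default 0.5).
#' @param hub_kme kME above which a member counts as a hub (default 0.8,
#'   strict inequality).
#' @param max_rounds Iteration cap (default 10).
#' @return A `metabo_modules` object: list with `assignments` (tibble
#'   `feature_id`, `module`, `kme`, `is_hub`), `kme` (matrix kept features x
#'   modules), `eigenmetabolites` (samples x modules), `edges` (tibble of
#'   within-module TOM edges), `rounds` (per-round counts tibble), `power`,
#'   `converged`, `params`.
#' @export
iterative_wgcna <- function(x, power = NULL,
                            network_type = c("unsigned", "signed"),
                            min_module_size = 10, merge_cut = 0.25,
                            kme_cutoff = 0.5, hub_kme = 0.8,
                            max_rounds = 10) {
  network_type <- match.arg(network_type)
  stopifnot(is.matrix(x), !anyNA(x))
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) x <- x[, sds > 0, drop = FALSE]
  if (nrow(x) < 30) {
    warning("fewer than 30 samples; module detection is most reliable at ",
            "larger sample sizes", call. = FALSE)
  }
  if (is.null(power)) {
    power <- pick_soft_threshold(x, network_type = network_type)$power
  }

  current <- x
  rounds <- list()
  converged <- FALSE
  det <- NULL
  kme <- NULL
  tom <- NULL
  for (r in seq_len(max_rounds)) {
    if (ncol(current) < max(3, min_module_size)) {
      det <- list(assignments = stats::setNames(
        rep("grey", ncol(current)), colnames(current)
      ), eigenmetabolites = matrix(numeric(0), nrow(current), 0))
      rounds[[r]] <- tibble::tibble(round = r, n_input = ncol(current),
                                    n_assigned = 0L, n_dropped = ncol(current))
      current <- current[, 0, drop = FALSE]
      converged <- TRUE
      break
    }
    tom <- tom_matrix(current, beta = power, network_type = network_type)
    det <- suppressWarnings(
      detect_modules(tom, current, min_module_size = min_module_size,
                     merge_cut = merge_cut)
    )
    lab <- det$assignments
    if (ncol(det$eigenmetabolites) == 0) {
      rounds[[r]] <- tibble::tibble(round = r, n_input = ncol(current),
                                    n_assigned = 0L, n_dropped = ncol(current))
      current <- current[, 0, drop = FALSE]
      converged <- TRUE
      break
    }
    kme <- compute_kme(current, det$eigenmetabolites)
    own_kme <- vapply(seq_along(lab), function(i) {
      if (lab[i] == "grey") return(NA_real_)
      kme[i, lab[i]]
    }, numeric(1))
    drop <- lab == "grey" | (!is.na(own_kme) & own_kme < kme_cutoff)
    rounds[[r]] <- tibble::tibble(
      round = r, n_input = ncol(current),
      n_assigned = sum(lab != "grey"), n_dropped = sum(drop)
    )
    if (!any(drop)) { converged <- TRUE; break }
    current <- current[, !drop, drop = FALSE]
  }
  rounds <- dplyr::bind_rows(rounds)

  if (ncol(current) == 0 || ncol(det$eigenmetabolites) == 0) {
    res <- list(
      assignments = tibble::tibble(feature_id = character(),
                                   module = character(), kme = numeric(),
                                   is_hub = logical()),
      kme = matrix(numeric(0), 0, 0),
      eigenmetabolites = matrix(numeric(0), nrow(x), 0),
      edges = tibble::tibble(source = character(), target = character(),
                             module = character(), weight = numeric()),
      rounds = rounds, power = power, converged = converged,
      params = list(network_type = network_type,
                    min_module_size = min_module_size, merge_cut = merge_cut,
                    kme_cutoff = kme_cutoff, hub_kme = hub_kme)
    )
    class(res) <- "metabo_modules"
    return(res)
  }

  lab <- det$assignments
  keep <- lab != "grey"          # grey survivors only when max_rounds hit
  current <- current[, keep, drop = FALSE]
  tom <- tom[keep, keep, drop = FALSE]
  lab <- lab[keep]
  kme <- compute_kme(current, det$eigenmetabolites)
  own_kme <- vapply(seq_along(lab), function(i) kme[i, lab[i]], numeric(1))
  assignments <- tibble::tibble(
    feature_id = colnames(current),
    module = unname(lab),
    kme = own_kme,
    is_hub = own_kme > hub_kme
  )
  edges <- purrr::map(setdiff(unique(lab), "grey"), function(m) {
    idx <- which(lab == m)
    if (length(idx) < 2) return(NULL)
    pairs <- utils::combn(idx, 2)
    tibble::tibble(
      source = colnames(current)[pairs[1, ]],
      target = colnames(current)[pairs[2, ]],
      module = m,
      weight = tom[cbind(pairs[1, ], pairs[2, ])]
    )
  }) |> dplyr::bind_rows()

  res <- list(
    assignments = assignments, kme = kme,
    eigenmetabolites = det$eigenmetabolites,
    edges = edges, rounds = rounds, power = power, converged = converged,
    params = list(network_type = network_type,
                  min_module_size = min_module_size, merge_cut = merge_cut,
                  kme_cutoff = kme_cutoff, hub_kme = hub_kme)
  )
  class(res) <- "metabo_modules"
  res
}

#' @export
print.metabo_modules <- function(x, ...) {
  n_mod <- ncol(x$eigenmetabolites)
  cat(sprintf(
    "<metabo_modules> %d features in %d modules after %d round(s)%s\n",
    nrow(x$assignments), n_mod, nrow(x$rounds),
    if (x$converged) "" else " (not converged)"
  ))
  if (n_mod > 0) {
    sz <- sort(table(x$assignments$module), decreasing = TRUE)
    cat("  sizes:", paste(sprintf("%s=%d", names(sz), sz), collapse = " "), "\n")
  }
  invisible(x)
}

#' Per-feature module table
#'
#' @param x A `metabo_modules` object.
#' @param ... Unused.
#' @return Tibble: `feature_id`, `module`, `kme`, `is_hub`.
#' @method tidy metabo_modules
#' @export
tidy.metabo_modules <- function(x, ...) x$assignments

#' One-row module-detection summary
#'
#' @param x A `metabo_modules` object.
#' @param ... Unused.
#' @return One-row tibble with module count, assigned/hub feature counts,
#'   rounds run, power and convergence flag.
#' @method glance metabo_modules
#' @export
glance.metabo_modules <- function(x, ...) {
  tibble::tibble(
    n_modules = ncol(x$eigenmetabolites),
    n_assigned = nrow(x$assignments),
    n_hubs = sum(x$assignments$is_hub),
    n_rounds = nrow(x$rounds),
    n_input = if (nrow(x$rounds) > 0) x$rounds$n_input[1] else 0L,
    power = x$power,
    converged = x$converged
  )
}

#' Hub metabolites per module
#'
#' Members whose own-module kME strictly exceeds `hub_kme`, per module,
#' sorted by decreasing kME (ties by feature_id).
#'
#' @param result A `metabo_modules` object.
#' @param hub_kme kME threshold (default 0.8, strict).
#' @return Tibble: `module`, `feature_id`, `kme`.
#' @export
hub_metabolites <- function(result, hub_kme = 0.8) {
  a <- result$assignments
  a[a$kme > hub_kme, c("module", "feature_id", "kme")] |>
    dplyr::arrange(.data$module, dplyr::desc(.data$kme), .data$feature_id)
}

#' Export a module's co-accumulation network
#'
#' Edge and node tables for one module, importable into Cytoscape or Gephi:
#' edges carry the TOM weight (filtered at `weight_min`), nodes carry kME and
#' the hub flag. Ordering is deterministic.
#'
#' @param result A `metabo_modules` object.
#' @param module Module label (e.g. `"M1"`).
#' @param weight_min Minimum TOM weight for an edge (default 0).
#' @return List with `edges` (`source`, `target`, `weight`) and `nodes`
#'   (`feature_id`, `kme`, `is_hub`).
#' @export
export_network <- function(result, module, weight_min = 0) {
  a <- result$assignments
  if (!module %in% a$module) stop("no such module: ", module, call. = FALSE)
  nodes <- a[a$module == module, c("feature_id", "kme", "is_hub")] |>
    dplyr::arrange(.data$feature_id)
  edges <- result$edges[result$edges$module == module &
                          result$edges$weight >= weight_min,
                        c("source", "target", "weight")] |>
    dplyr::arrange(.data$source, .data$target)
  list(edges = edges, nodes = nodes)
}
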