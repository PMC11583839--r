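brute_force_tom <- function(x, beta) {
  a <- abs(cor(x))^beta
  diag(a) <- 0
  n <- ncol(a)
  k <- rowSums(a)
  tom <- matrix(0, n, n)
  for (i in 1:n) {
    for (j in 1:n) {
      if (i == j) { tom[i, j] <- 1; next }
      l <- 0
      for (u in 1:n) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
      tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  tom
}

test_that("TOM equals the O(n^3) brute-force oracle and its limits", {
  set.seed(14)
  x <- matrix(rnorm(20 * 5), 20, 5)
  for (beta in c(1, 6)) {
    tom <- tom_matrix(x, beta)
    expect_equal(unname(tom), brute_force_tom(x, beta), tolerance = 1e-10)
  }
  x8 <- matrix(rnorm(25 * 8), 25, 8)
  tom8 <- tom_matrix(x8, 6)
  expect_equal(unname(tom8), brute_force_tom(x8, 6), tolerance = 1e-10)
  expect_true(isSymmetric(tom8))
  expect_true(all(tom8 >= 0 & tom8 <= 1 + 1e-12))

  # three identical profiles -> all-ones TOM
  base <- rnorm(15)
  ident <- cbind(base, base, base)
  expect_equal(unname(tom_matrix(ident, 6)), matrix(1, 3, 3),
               tolerance = 1e-10)

  # independent profiles at large beta -> off-diagonal TOM near 0
  big <- matrix(rnorm(200 * 10), 200, 10)
  tomb <- tom_matrix(big, 20)
  expect_lt(max(tomb[upper.tri(tomb)]), 0.05)

  expect_error(tom_matrix(matrix(rnorm(10), 5, 2), 6), "3 features")
})

test_that("soft-threshold grid behaves: connectivity decreases, degenerate grid works", {
  set.seed(15)
  x <- matrix(rnorm(40 * 60), 40, 60)
  st <- pick_soft_threshold(x, powers = 1:10)
  expect_true(all(diff(st$fit$mean_k) < 0))
  st1 <- pick_soft_threshold(x, powers = 1)
  expect_equal(st1$power, 1)
  expect_equal(nrow(st1$fit), 1)
})

test_that("soft threshold reaches scale-free fit on hub-structured data", {
  # single latent factor with power-law-like loadings: k_i ~ u_i^beta,
  # whose log-log frequency curve is linear, i.e. scale-free topology
  set.seed(6)
  n <- 200; p <- 400
  u <- runif(p, 0.15, 1)
  latent <- rnorm(n)
  x <- sapply(u, function(w) sqrt(w) * latent + sqrt(1 - w) * rnorm(n))
  st <- pick_soft_threshold(x)
  expect_gte(max(st$fit$rsq_signed, na.rm = TRUE), 0.8)
  chosen <- st$fit$rsq_signed[st$fit$power == st$power]
  expect_gte(chosen, 0.8)
})

test_that("eigenmetabolite matches the direct first principal component", {
  set.seed(16)
  x <- matrix(rnorm(30 * 12), 30, 12)
  me <- eigenmetabolite(x)
  pc1 <- prcomp(x, scale. = TRUE)$x[, 1]
  expect_gt(abs(cor(me, pc1)), 0.999)
  # invariant to reordering of features in the module
  me_perm <- eigenmetabolite(x[, sample(12)])
  expect_equal(abs(cor(me, me_perm)), 1, tolerance = 1e-10)
})

test_that("kME is the plain correlation with the eigenmetabolite", {
  set.seed(18)
  x <- matrix(rnorm(25 * 8), 25, 8)
  colnames(x) <- paste0("F", 1:8)
  me <- cbind(M1 = eigenmetabolite(x[, 1:4]), M2 = eigenmetabolite(x[, 5:8]))
  kme <- compute_kme(x, me)
  for (f in 1:8) for (m in 1:2) {
    expect_equal(kme[f, m], cor(x[, f], me[, m]), tolerance = 1e-12)
  }
  # a feature equal to the eigenmetabolite has kME 1; negated, -1
  x2 <- cbind(x, exact = me[, "M1"], anti = -me[, "M1"])
  kme2 <- compute_kme(x2, me)
  expect_equal(kme2["exact", "M1"], 1, tolerance = 1e-12)
  expect_equal(kme2["anti", "M1"], -1, tolerance = 1e-12)
})

test_that("two planted blocks are recovered exactly with no grey features", {
  set.seed(19)
  n <- 60
  lat1 <- rnorm(n); lat2 <- rnorm(n)
  w <- sqrt(0.9)
  x <- cbind(
    sapply(1:20, function(i) w * lat1 + sqrt(0.1) * rnorm(n)),
    sapply(1:20, function(i) w * lat2 + sqrt(0.1) * rnorm(n))
  )
  colnames(x) <- paste0("F", 1:40)
  tom <- tom_matrix(x, 6)
  det <- detect_modules(tom, x, min_module_size = 10)
  expect_equal(ncol(det$eigenmetabolites), 2)
  expect_false(any(det$assignments == "grey"))
  expect_equal(length(unique(det$assignments[1:20])), 1)
  expect_equal(length(unique(det$assignments[21:40])), 1)

  # min_module_size above n -> everything grey
  expect_warning(all_grey <- detect_modules(tom, x, min_module_size = 50),
                 "grey")
  expect_true(all(all_grey$assignments == "grey"))
})

test_that("iterative clustering drops unstructured data entirely", {
  set.seed(20)
  x <- matrix(rnorm(50 * 80), 50, 80)
  colnames(x) <- paste0("F", 1:80)
  res <- suppressWarnings(iterative_wgcna(x, power = 6))
  expect_true(res$converged)
  expect_equal(nrow(res$assignments), 0)
  expect_equal(ncol(res$eigenmetabolites), 0)
})

test_that("iterative clustering recovers planted modules and drops noise", {
  sim <- simulate_preset("planted-modules", seed = 1)
  ds <- sim$dataset
  x <- t(log2(ds$expression + 1))
  res <- iterative_wgcna(x)
  expect_true(res$converged)
  g <- glance(res)
  expect_equal(g$n_modules, 5)

  truth <- sim$truth$module_labels
  assigned <- res$assignments
  merged <- merge(assigned, truth, by = "feature_id")
  planted <- merged[merged$module.y != "noise", ]
  # each planted module maps to exactly one detected module
  tab <- table(planted$module.y, planted$module.x)
  expect_true(all(apply(tab > 0, 1, sum) == 1))
  # invariants: own-module kME above the cutoff, module sizes respected
  expect_true(all(assigned$kme >= res$params$kme_cutoff))
  expect_true(all(table(assigned$module) >= res$params$min_module_size))
  expect_true(all(res$edges$weight >= 0 & res$edges$weight <= 1))
  # feature count decreases across rounds until convergence
  expect_true(all(diff(res$rounds$n_input) <= 0))
})

test_that("raising the kME cutoff never increases the assigned count", {
  sim <- simulate_dataset(n_features = 120, n_samples = 60, n_modules = 2,
                          module_size = 30, within_cor = 0.7, seed = 23)
  x <- t(log2(sim$dataset$expression + 1))
  counts <- sapply(c(0.3, 0.5, 0.7, 0.9), function(cutoff) {
    nrow(suppressWarnings(
      iterative_wgcna(x, power = 6, kme_cutoff = cutoff)
    )$assignments)
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("hub screening uses a strict threshold and stable ordering", {
  sim <- simulate_preset("planted-modules", seed = 2)
  x <- t(log2(sim$dataset$expression + 1))
  res <- iterative_wgcna(x)
  hubs <- hub_metabolites(res, hub_kme = 0.8)
  expect_true(all(hubs$kme > 0.8))
  # exact boundary value is excluded
  fake <- res
  fake$assignments$kme[1] <- 0.8
  h2 <- hub_metabolites(fake, hub_kme = 0.8)
  expect_false(fake$assignments$feature_id[1] %in% h2$feature_id)
  # per-module descending kME
  for (m in unique(hubs$module)) {
    expect_true(all(diff(hubs$kme[hubs$module == m]) <= 0))
  }
})

test_that("network export filters by weight and matches the TOM", {
  sim <- simulate_preset("planted-modules", seed = 3)
  x <- t(log2(sim$dataset$expression + 1))
  res <- iterative_wgcna(x)
  m1 <- res$assignments$module[1]
  net_all <- export_network(res, m1, weight_min = 0)
  n_m <- sum(res$assignments$module == m1)
  expect_equal(nrow(net_all$edges), choose(n_m, 2))
  expect_equal(nrow(net_all$nodes), n_m)

  net_none <- export_network(res, m1, weight_min = 1.1)
  expect_equal(nrow(net_none$edges), 0)
  expect_equal(nrow(net_none$nodes), n_m)

  # edge weights are the TOM entries of the final feature set
  ids <- res$assignments$feature_id[res$assignments$module == m1]
  xm <- x[, res$assignments$feature_id, drop = FALSE]
  tom <- tom_matrix(xm, res$power)
  for (i in sample(nrow(net_all$edges), 10)) {
    e <- net_all$edges[i, ]
    expect_equal(e$weight, tom[e$source, e$target], tolerance = 1e-12)
  }
  expect_error(export_network(res, "no-such-module"), "no such module")
})
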