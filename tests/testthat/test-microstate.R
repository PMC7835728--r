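test_that("GFP matches its defining formula", {
  rec <- eeg_recording(cbind(c(3, 3, 3, 3), c(1, -1, 1, -1) + 2, c(1, 2, 3, 4)), 100)
  g <- compute_gfp(rec)$gfp
  expect_equal(g[1], 0)
  expect_equal(g[2], 1)
  expect_equal(g[3], sqrt(1.25))
})

test_that("GFP peak detection: strict maxima, plateau-first, no endpoints", {
  expect_equal(find_gfp_peaks(c(1, 3, 2, 5, 4)), c(2, 4))
  expect_warning(p <- find_gfp_peaks(c(1, 2, 3, 4, 5)), class = "msvalid_empty_result")
  expect_length(p, 0)
  expect_equal(find_gfp_peaks(c(1, 4, 4, 1)), 2)
  expect_equal(find_gfp_peaks(c(5, 4, 4, 5, 1)), 4)  # interior plateau is a valley here
  expect_error(find_gfp_peaks(c(1, 2)), class = "msvalid_invalid_argument")
})

test_that("modified k-means recovers degenerate and orthogonal generators exactly", {
  u <- c(2, -1, -1, 0)
  flips <- rep(c(1, -1), 5)
  X <- outer(flips, u)
  fit <- modified_kmeans(X, 1, n_restarts = 5, seed = 1)
  expect_equal(fit$gev, 1, tolerance = 1e-9)
  expect_equal(abs(spatial_correlation(fit$templates$maps[1, ], u)), 1, tolerance = 1e-9)

  v <- c(0, 1, -1, 0)  # orthogonal to u after average reference
  X2 <- rbind(outer(rep(c(1, -1), 5), u), outer(rep(c(1, -1), 5), v))
  fit2 <- modified_kmeans(X2, 2, n_restarts = 20, seed = 2)
  expect_equal(fit2$gev, 1, tolerance = 1e-9)
  cr <- abs(cbind(
    apply(fit2$templates$maps, 1, spatial_correlation, v = u),
    apply(fit2$templates$maps, 1, spatial_correlation, v = v)
  ))
  expect_equal(sort(apply(cr, 2, max)), c(1, 1), tolerance = 1e-9)
  # one pure cluster per generator
  expect_equal(length(unique(fit2$assignments[1:10])), 1)
  expect_equal(length(unique(fit2$assignments[11:20])), 1)
})

test_that("k-means with restarts attains the exhaustive-partition optimum", {
  set.seed(5)
  for (case in list(list(P = 12, k = 2, n = 6), list(P = 9, k = 3, n = 8))) {
    base <- t(sapply(seq_len(case$k), function(i) random_zero_mean_map(case$n)))
    X <- base[rep(seq_len(case$k), length.out = case$P), ] +
      0.25 * matrix(rnorm(case$P * case$n), case$P)
    X <- X - rowMeans(X)
    fit <- modified_kmeans(X, case$k, n_restarts = 50, seed = 3)
    expect_equal(fit$gev, oracle_best_gev(X, case$k), tolerance = 1e-9)
  }
})

test_that("clustering is polarity-invariant and assignment is scale-invariant", {
  set.seed(6)
  X <- matrix(rnorm(20 * 8), 20)
  X <- X - rowMeans(X)
  fit <- modified_kmeans(X, 3, n_restarts = 20, seed = 4)
  # flipping any subset of map signs changes nothing observable
  flip <- sample(c(-1, 1), 20, TRUE)
  fit2 <- modified_kmeans(X * flip, 3, n_restarts = 20, seed = 4)
  expect_identical(fit$assignments, fit2$assignments)
  expect_equal(fit$gev, fit2$gev, tolerance = 1e-9)
  for (j in 1:3) {
    expect_equal(abs(spatial_correlation(fit$templates$maps[j, ],
                                         fit2$templates$maps[j, ])), 1,
                 tolerance = 1e-9)
  }
  # scaling a map by c > 0 leaves its assignment to fixed templates unchanged
  Tm <- msvalid:::template_maps_unit_norm(fit$templates)
  assign_against <- function(M) max.col((M %*% t(Tm))^2, ties.method = "first")
  scale <- runif(20, 0.1, 10)
  expect_identical(assign_against(X), assign_against(X * scale))
})

test_that("KL criterion finds the true model order", {
  # maps drawn exactly from 4 well-separated templates, random sign/scale
  tpl <- generate_template_set(24, 4, seed = 12)
  set.seed(13)
  idx <- rep(1:4, each = 15)
  X <- tpl$maps[idx, ] * sample(c(-1, 1), 60, TRUE) * runif(60, 0.5, 2)
  sel <- select_k_kl(X, k_min = 1, k_max = 8, n_restarts = 20, seed = 5)
  expect_identical(sel$k_opt, 4L)
  # dispersion is non-increasing and GEV non-decreasing in k
  expect_true(all(diff(sel$dispersion_curve) <= 1e-9))
  expect_true(all(diff(sel$gev_curve) >= -1e-9))

  # 2 orthogonal templates + small noise: k = 2 in >= 9/10 seeds
  u <- random_zero_mean_map(16)
  v <- random_zero_mean_map(16)
  v <- v - u * sum(u * v) / sum(u * u)
  wins <- 0
  for (s in 1:10) {
    set.seed(s)
    Y <- rbind(outer(sample(c(-1, 1), 20, TRUE), u),
               outer(sample(c(-1, 1), 20, TRUE), v)) +
      0.15 * matrix(rnorm(40 * 16), 40)
    k2 <- select_k_kl(Y, k_min = 1, k_max = 6, n_restarts = 15, seed = s)$k_opt
    wins <- wins + (k2 == 2L)
  }
  expect_gte(wins, 9)
})

test_that("explained variance follows the GFP-weighted correlation formula", {
  tpl <- generate_template_set(16, 3, seed = 14)
  # perfect fit up to sign/scale
  X <- tpl$maps[c(1, 2, 3, 1), ] * c(-2, 1, 3, 0.5)
  expect_equal(explained_variance(tpl, X), 1, tolerance = 1e-12)

  # orthogonal maps explain nothing (4 channels, hand-built)
  tpl2 <- ms_template_set(rbind(c(1, -1, 1, -1)), normalize = TRUE)
  expect_equal(explained_variance(tpl2, rbind(c(1, 1, -1, -1))), 0, tolerance = 1e-12)

  # 2 peaks, gfp {1, 2}, correlations {1, 0.5} -> GEV = 2/5
  u <- c(1, -1, 1, -1) / 1  # unit GFP
  w <- c(1, -1, -1, 1)      # orthogonal to u, zero mean
  tpl3 <- ms_template_set(rbind(u), normalize = TRUE)
  m1 <- u                                   # gfp 1, corr 1
  m2 <- 2 * (0.5 * u + sqrt(0.75) * w)      # gfp 2, corr 0.5
  expect_equal(explained_variance(tpl3, rbind(m1, m2)), 0.4, tolerance = 1e-12)
})

test_that("group-template aggregation undoes permutations and sign flips", {
  base <- generate_template_set(24, 4, seed = 9)
  same <- build_group_templates(list(base, base, base))
  cr <- abs(same$maps %*% t(base$maps)) / 24
  expect_equal(apply(cr, 2, max), rep(1, 4), tolerance = 1e-9)

  set.seed(4)
  sets <- lapply(1:6, function(i) {
    p <- sample(4)
    s <- sample(c(-1, 1), 4, TRUE)
    ms_template_set(base$maps[p, ] * s)
  })
  g <- build_group_templates(sets)
  cr <- abs(g$maps %*% t(base$maps)) / 24
  expect_equal(apply(cr, 2, max), rep(1, 4), tolerance = 1e-9)

  expect_error(build_group_templates(list(base, ms_template_set(base$maps[1:3, ]))),
               class = "msvalid_invalid_argument")
})

test_that("two discordant subgroups each dominate their own global template", {
  u1 <- random_zero_mean_map(12)
  u2 <- random_zero_mean_map(12)
  u2 <- u2 - u1 * sum(u1 * u2) / sum(u1 * u1)
  mk <- function(m, eps, seed) {
    set.seed(seed)
    ms_template_set(rbind(m + eps * random_zero_mean_map(12),
                          10 * random_zero_mean_map(12)))
  }
  sets <- c(lapply(1:3, function(i) mk(u1, 0.05, i)),
            lapply(4:6, function(i) mk(u2, 0.05, i)))
  g <- build_group_templates(sets)
  cr1 <- max(abs(apply(g$maps, 1, spatial_correlation, v = u1)))
  cr2 <- max(abs(apply(g$maps, 1, spatial_correlation, v = u2)))
  expect_gte(cr1, 0.9)
  expect_gte(cr2, 0.9)
})
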