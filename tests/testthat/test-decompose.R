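test_that("extended Infomax separates a 3-channel super-Gaussian mixture", {
  set.seed(42)
  n <- 5000
  S <- rbind(rexp(n) * sample(c(-1, 1), n, TRUE),
             rexp(n) * sample(c(-1, 1), n, TRUE))
  A <- matrix(c(1, 0.5, 0.3, 0.2, 1, 0.7), 3, 2)
  X <- A %*% S + 0.05 * matrix(rnorm(3 * n), 3)
  dec <- decompose_ica(eeg_recording(X, 250), n_ics = 2, seed = 1)
  cr <- abs(stats::cor(t(dec$sources), t(S)))
  expect_gte(min(apply(cr, 2, max)), 0.95)
  # deterministic
  dec2 <- decompose_ica(eeg_recording(X, 250), n_ics = 2, seed = 1)
  expect_identical(dec$sources, dec2$sources)
})

test_that("decomposition reconstructs its PCA projection; full rank is exact", {
  set.seed(7)
  X <- matrix(rnorm(6 * 2000), 6) + rexp(6 * 2000) * 0.3
  rec <- eeg_recording(X, 250)
  dec <- decompose_ica(rec, n_ics = 6, seed = 1, on_nonconvergence = "warn")
  recon <- dec$mixing %*% dec$sources + dec$center
  expect_lt(norm(recon - X, "F") / norm(X, "F"), 1e-6)

  dec3 <- decompose_ica(rec, n_ics = 3, seed = 1, on_nonconvergence = "warn")
  Xc <- X - rowMeans(X)
  eg <- eigen(tcrossprod(Xc) / ncol(X), symmetric = TRUE)
  proj <- eg$vectors[, 1:3] %*% crossprod(eg$vectors[, 1:3], Xc) + rowMeans(X)
  recon3 <- dec3$mixing %*% dec3$sources + dec3$center
  expect_lt(norm(recon3 - proj, "F") / norm(proj, "F"), 1e-9)

  expect_error(decompose_ica(rec, n_ics = 7), class = "msvalid_invalid_argument")
})

test_that("component removal is exact algebra on a constructed mixture", {
  set.seed(9)
  n <- 1000
  S <- rbind(rnorm(n), rnorm(n), exp(-((seq_len(n) - 500) / 30)^2))  # source 3 = blink pulse
  A <- matrix(rnorm(12), 4, 3)
  dec <- manual_decomposition(A, S)

  none <- remove_ics_and_reproject(dec, integer(0))
  expect_lt(norm(none$data - A %*% S, "F") / norm(A %*% S, "F"), 1e-9)

  no_blink <- remove_ics_and_reproject(dec, 3)
  clean <- A[, 1:2] %*% S[1:2, ]
  expect_lt(norm(no_blink$data - clean, "F") / max(norm(clean, "F"), 1), 1e-9)

  # null mixing column: removal changes nothing
  A0 <- A
  A0[, 2] <- 0
  dec0 <- manual_decomposition(A0, S)
  expect_lt(max(abs(remove_ics_and_reproject(dec0, 2)$data -
                    remove_ics_and_reproject(dec0, integer(0))$data)), 1e-12)

  expect_error(remove_ics_and_reproject(dec, 1:3), class = "msvalid_empty_model")
  expect_equal(max(abs(remove_ics_and_reproject(dec, 1:3, allow_empty = TRUE)$data)), 0)
})

test_that("removal is linear in the retained set", {
  set.seed(10)
  dec <- manual_decomposition(matrix(rnorm(24), 6, 4), matrix(rnorm(4 * 500), 4))
  r0 <- remove_ics_and_reproject(dec, integer(0))$data
  rA <- remove_ics_and_reproject(dec, 1)$data
  rB <- remove_ics_and_reproject(dec, c(3, 4))$data
  rAB <- remove_ics_and_reproject(dec, c(1, 3, 4))$data
  expect_lt(max(abs(r0 - rA - rB + rAB)), 1e-9 * max(abs(r0)))
})

test_that("McNemar statistic matches hand values and its invariances", {
  # b = 6, c = 2: chi2 = (4 - 1)^2 / 8
  a <- c(rep(1, 6), rep(0, 2), rep(1, 10), rep(0, 10))
  b <- c(rep(0, 6), rep(1, 2), rep(1, 10), rep(0, 10))
  res <- mcnemar_compare(a, b)
  expect_equal(res$chi2, 1.125)
  expect_equal(res[c("b", "c")], list(b = 6L, c = 2L))
  # agrees with the standard implementation
  ref <- stats::mcnemar.test(table(factor(a, 0:1), factor(b, 0:1)), correct = TRUE)
  expect_equal(res$chi2, unname(ref$statistic))
  expect_equal(res$p, ref$p.value)

  # b = 5, c = 5: over-corrected statistic 0.1, by the stated formula
  a2 <- c(rep(1, 5), rep(0, 5))
  b2 <- c(rep(0, 5), rep(1, 5))
  expect_equal(mcnemar_compare(a2, b2)$chi2, 0.1)

  # symmetric in (b, c); invariant to concordant pairs
  expect_equal(mcnemar_compare(b, a)$chi2, res$chi2)
  expect_equal(mcnemar_compare(c(a, 1, 0), c(b, 1, 0))$chi2, res$chi2)

  expect_error(mcnemar_compare(c(1, 0, 1), c(1, 0, 1)), class = "msvalid_undefined_test")
})

test_that("injected rank-1 artifacts are identifiable as components", {
  hits <- logical(10)
  for (s in 1:10) {
    tpl <- generate_template_set(16, 3, seed = 300 + s)
    cfg <- generator_config(n_channels = 16, duration = 16, k_true = 3, seed = 320 + s)
    syn <- synthesize_eeg(tpl, generate_label_sequence(cfg), cfg)
    art <- inject_artifacts(syn$recording,
                            list(eyeblink = list(amplitude = 60, rate = 0.25),
                                 cardiac = list(amplitude = 40, rate = 1)),
                            seed = 340 + s)
    dec <- decompose_ica(average_reference(art$recording), n_ics = 8,
                         seed = s, on_nonconvergence = "warn")
    cr <- abs(stats::cor(t(dec$sources), t(art$ground_truth$sources)))
    hits[s] <- all(apply(cr, 2, max) >= 0.9)
    if (s == 1) {
      labs <- label_ics_from_ground_truth(dec, art$ground_truth, threshold = 0.8)
      expect_gte(sum(labs$eye), 1)
      expect_gte(sum(labs$cardiac), 1)
      expect_setequal(flagged_ics(labs),
                      unique(c(which(labs$eye == 1), which(labs$cardiac == 1))))
    }
  }
  expect_true(all(hits))
})
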