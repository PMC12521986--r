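# evoked-to-total power ratio of a linear projection w on an epoch set
proj_snr <- function(ep, train_idx, w) {
  ns <- dim(ep$data)[3]
  labs <- ep$labels[train_idx]
  P <- apply(ep$data[train_idx[labs == "IMAGERY"], , , drop = FALSE],
             c(2, 3), mean)
  Cs <- tcrossprod(P) / ns
  Cx <- matrix(0, dim(ep$data)[2], dim(ep$data)[2])
  for (i in train_idx) {
    X <- matrix(ep$data[i, , ], dim(ep$data)[2], ns)
    Cx <- Cx + tcrossprod(X) / ns
  }
  Cx <- Cx / length(train_idx)
  as.numeric((w %*% Cs %*% w) / (w %*% Cx %*% w))
}

test_that("prototypes are exact class means of the training subset only", {
  ep <- null_epochs(n_trials = 8, n_ch = 3, ns = 10, seed = 2)
  # all IMAGERY trials identical to a template
  template <- matrix(seq_len(30), 3, 10)
  for (i in which(ep$labels == "IMAGERY")) ep$data[i, , ] <- template
  pro <- compute_prototypes(ep)
  expect_equal(pro$IMAGERY, template)

  # two-trial average
  ep2 <- null_epochs(n_trials = 4, n_ch = 2, ns = 5, seed = 3)
  pro2 <- compute_prototypes(ep2, train_idx = 1:4)
  expect_equal(pro2$NO_IMAGERY,
               (matrix(ep2$data[2, , ], 2, 5) + matrix(ep2$data[4, , ], 2, 5)) / 2)

  # non-training trials are irrelevant
  pro_a <- compute_prototypes(ep2, train_idx = 1:3)
  ep2$data[4, , ] <- 1e6
  pro_b <- compute_prototypes(ep2, train_idx = 1:3)
  expect_identical(pro_a$IMAGERY, pro_b$IMAGERY)
  expect_identical(pro_a$NO_IMAGERY, pro_b$NO_IMAGERY)

  expect_error(compute_prototypes(ep2, train_idx = c(1, 3)), "absent")
})

test_that("xDAWN returns the requested filter counts", {
  ep <- patterned_epochs(seed = 4)
  for (f in c(2, 4, 6)) {
    xd <- fit_xdawn(ep, f = f)
    expect_equal(dim(xd$filters$IMAGERY), c(f, 8))
    expect_equal(dim(xd$filters$NO_IMAGERY), c(f, 8))
  }
})

test_that("the leading xDAWN filter beats every channel and random projections", {
  ep <- patterned_epochs(n_ch = 8, snr = 1.5, seed = 7)
  train <- seq_len(dim(ep$data)[1])
  xd <- fit_xdawn(ep, train, f = 2)
  w1 <- xd$filters$IMAGERY[1, ]
  snr_filter <- proj_snr(ep, train, w1)
  # exhaustive channel comparison
  for (ch in 1:8) {
    e <- rep(0, 8); e[ch] <- 1
    expect_gte(snr_filter, proj_snr(ep, train, e))
  }
  # brute-force random projection oracle
  withr::with_seed(99, {
    best_random <- max(vapply(seq_len(10000), function(i) {
      w <- rnorm(8); proj_snr(ep, train, w / sqrt(sum(w^2)))
    }, 0))
  })
  expect_gte(snr_filter, best_random)
})

test_that("augmented covariances are SPD with the expected dimension", {
  for (chrom in c("HBO", "HBR", "BOTH")) {
    ep <- cached_epochs("RESPONSIVE", chrom)
    pro <- compute_prototypes(ep, 1:48)
    xd <- fit_xdawn(ep, 1:48, f = 4)
    spd <- augment_and_covary(ep, pro, xd)
    expect_equal(dim(spd$matrices)[1:2], c(16, 16))
    for (i in c(1, 25, 60)) {
      S <- spd$matrices[, , i]
      expect_lt(max(abs(S - t(S))), 1e-12)
      expect_gt(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), 0)
    }
    expect_true(all(spd$rho >= 0 & spd$rho <= 1))
  }
})

test_that("OAS shrinkage preserves the trace of the sample covariance", {
  withr::with_seed(5, {
    for (rep in 1:5) {
      X <- matrix(rnorm(12 * 40), 12, 40)
      res <- oas_cov(X)
      Xc <- X - rowMeans(X)
      S <- tcrossprod(Xc) / ncol(X)
      expect_equal(sum(diag(res$sigma)), sum(diag(S)), tolerance = 1e-10)
      expect_gte(res$rho, 0); expect_lte(res$rho, 1)
    }
  })
})

test_that("OAS shrinkage intensity decreases with sample length on average", {
  # anisotropic truth: with a spherical truth the identity target is
  # exact and rho stays near 1 at any n, so use distinct variances
  withr::with_seed(6, {
    sds <- sqrt(seq(0.2, 4, length.out = 10))
    rho_at <- function(n) mean(vapply(1:20, function(i)
      oas_cov(sds * matrix(rnorm(10 * n), 10, n))$rho, 0))
    rhos <- vapply(c(15, 60, 400), rho_at, 0)
    expect_true(all(diff(rhos) < 0))
  })
})

test_that("the fused decoding pipeline matches the composed module functions", {
  ep <- cached_epochs("RESPONSIVE", "HBO")
  train <- c(2:25, 31:55)
  y01 <- as.integer(ep$labels == "IMAGERY")
  pf <- nirsaware:::pipeline_features_cpp(aperm(ep$data, c(2, 3, 1)),
                                          train, y01, 4L)
  pro <- compute_prototypes(ep, train)
  xd <- fit_xdawn(ep, train, 4)
  spd <- augment_and_covary(ep, pro, xd)
  ref <- frechet_mean(spd$matrices[, , train])
  feats <- tangent_map(spd$matrices, ref)
  expect_equal(pf$features, feats, tolerance = 1e-8)
  expect_equal(pf$reference, as.matrix(ref), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("training-fold fits are blind to test-fold data", {
  ep <- cached_epochs("RESPONSIVE", "HBO")
  train <- 1:40
  test <- 41:60
  y01 <- as.integer(ep$labels == "IMAGERY")
  cube <- aperm(ep$data, c(2, 3, 1))
  pf1 <- nirsaware:::pipeline_features_cpp(cube, train, y01, 2L)
  # corrupt test-fold labels and data
  y_bad <- y01; y_bad[test] <- 1L - y_bad[test]
  cube_bad <- cube; cube_bad[, , test] <- cube_bad[, , test] * 5 + 1
  pf2 <- nirsaware:::pipeline_features_cpp(cube_bad, train, y_bad, 2L)
  expect_identical(pf1$features[train, ], pf2$features[train, ])
  expect_identical(pf1$reference, pf2$reference)
})

test_that("between-class separation on null data shrinks towards the dispersion", {
  # with no real class difference, classDis falls as trial count grows
  cd_at <- function(n_trials, seed) {
    ep <- null_epochs(n_trials = n_trials, n_ch = 6, ns = 40, seed = seed)
    pro <- compute_prototypes(ep)
    xd <- fit_xdawn(ep, f = 2)
    class_distinctiveness(augment_and_covary(ep, pro, xd))
  }
  withr::with_seed(10, {
    small <- mean(vapply(1:6, function(s) cd_at(12, s), 0))
    large <- mean(vapply(1:6, function(s) cd_at(96, s + 100), 0))
  })
  expect_lt(large, small)
})
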