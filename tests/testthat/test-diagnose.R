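fake_perm <- function(chrom, p) {
  structure(list(chromophore = chrom, observed_accuracy = 0.8,
                 null_accuracies = rep(0.5, 10), p_value = p,
                 n_perm = 250, n_done = 250, curtailed = FALSE,
                 best = list(f = 2, C = 1)),
            class = "nirs_perm")
}

test_that("the empirical p-value respects its formula bounds", {
  ep <- null_epochs(n_trials = 20, n_ch = 5, ns = 25, seed = 41)
  pr_hi <- permutation_pvalue(ep, n_perm = 9, seed = 1, observed = 1.000001,
                              f_grid = 2, C_grid = 1)
  expect_equal(pr_hi$p_value, 1 / 10)
  pr_lo <- permutation_pvalue(ep, n_perm = 9, seed = 1, observed = 0,
                              f_grid = 2, C_grid = 1)
  expect_equal(pr_lo$p_value, 1)
  expect_error(permutation_pvalue(ep, n_perm = 0), "at least 1")
})

test_that("with 250 permutations the smallest attainable p is 1/251", {
  expect_lt(abs(1 / (1 + 250) - 0.00398), 1e-5)
  ep <- null_epochs(n_trials = 20, n_ch = 5, ns = 25, seed = 42)
  pr <- permutation_pvalue(ep, n_perm = 19, seed = 2, f_grid = 2, C_grid = 1)
  expect_gte(pr$p_value, 1 / 20)
  expect_lte(pr$p_value, 1)
})

test_that("the observed statistic equals the grid-search selection", {
  ep <- cached_epochs("UNRESPONSIVE", "HBO")
  gs <- grid_search(ep, seed = 5)
  pr <- permutation_pvalue(ep, n_perm = 3, seed = 5)
  expect_equal(pr$observed_accuracy, gs$best_accuracy)
})

test_that("permutation null is reproducible under a seed", {
  ep <- null_epochs(n_trials = 20, n_ch = 5, ns = 25, seed = 43)
  p1 <- permutation_pvalue(ep, n_perm = 11, seed = 7, f_grid = 2, C_grid = 1)
  p2 <- permutation_pvalue(ep, n_perm = 11, seed = 7, f_grid = 2, C_grid = 1)
  expect_identical(p1$null_accuracies, p2$null_accuracies)
  expect_identical(p1$p_value, p2$p_value)
})

test_that("sequential curtailment never changes the decision at alpha", {
  for (s in 44:46) {
    ep <- null_epochs(n_trials = 20, n_ch = 5, ns = 25, seed = s)
    full <- permutation_pvalue(ep, n_perm = 39, seed = s,
                               f_grid = 2, C_grid = c(1, 10))
    curt <- permutation_pvalue(ep, n_perm = 39, seed = s, alpha_stop = 0.05,
                               f_grid = 2, C_grid = c(1, 10))
    expect_identical(full$p_value < 0.05, curt$p_value < 0.05)
    expect_lte(curt$n_done, full$n_done)
    if (curt$curtailed) expect_gte(curt$p_value, 0.05)
  }
})

test_that("permutation p-values are calibrated under the null", {
  n_rep <- 200
  pvals <- vapply(seq_len(n_rep), function(r) {
    ep <- null_epochs(n_trials = 20, n_ch = 5, ns = 25, seed = 1000 + r)
    permutation_pvalue(ep, n_perm = 39, seed = r,
                       f_grid = 2, C_grid = c(1, 10, 100, 1000))$p_value
  }, 0)
  expect_lte(mean(pvals < 0.05), 0.075)
  # validity across a grid of thresholds, with Monte-Carlo tolerance
  for (a in c(0.1, 0.25, 0.5))
    expect_lte(mean(pvals <= a), a + 3 * sqrt(a * (1 - a) / n_rep))
})

test_that("the minimum-p rule decides responsiveness strictly below alpha", {
  r <- decide_responsiveness(list(fake_perm("HBO", 0.2),
                                  fake_perm("HBR", 0.03),
                                  fake_perm("BOTH", 0.6)))
  expect_equal(r$label, "RESPONSIVE")
  expect_equal(r$p_min, 0.03)

  r2 <- decide_responsiveness(list(fake_perm("HBO", 0.5),
                                   fake_perm("HBR", 0.5),
                                   fake_perm("BOTH", 0.5)))
  expect_equal(r2$label, "UNRESPONSIVE")

  # boundary: p exactly alpha is not significant
  r3 <- decide_responsiveness(list(fake_perm("HBO", 0.05),
                                   fake_perm("HBR", 0.05),
                                   fake_perm("BOTH", 0.05)))
  expect_equal(r3$label, "UNRESPONSIVE")

  expect_error(decide_responsiveness(list(fake_perm("HBO", 0.5),
                                          fake_perm("HBR", 0.5))),
               "exactly one result")
  expect_error(decide_responsiveness(list(fake_perm("HBO", 0.5),
                                          fake_perm("HBO", 0.5),
                                          fake_perm("BOTH", 0.5))),
               "exactly one result")
})

test_that("class distinctiveness matches its closed forms", {
  # identical class multisets: distance between centres is zero
  m <- array(NA_real_, c(2, 2, 6))
  set <- list(diag(c(1, 2)), diag(c(2, 1)), diag(c(1.5, 1.5)))
  for (i in 1:3) { m[, , i] <- set[[i]]; m[, , i + 3] <- set[[i]] }
  labs <- factor(rep(c("IMAGERY", "NO_IMAGERY"), each = 3),
                 levels = c("IMAGERY", "NO_IMAGERY"))
  expect_equal(class_distinctiveness(list(matrices = m, labels = labs)), 0,
               tolerance = 1e-6)

  # 1-d closed form: A = {1, e^2}, B = {e^4, e^6} gives classDis = 4
  m1 <- array(c(1, exp(2), exp(4), exp(6)), c(1, 1, 4))
  labs1 <- factor(c("IMAGERY", "IMAGERY", "NO_IMAGERY", "NO_IMAGERY"),
                  levels = c("IMAGERY", "NO_IMAGERY"))
  expect_equal(class_distinctiveness(list(matrices = m1, labels = labs1)), 4,
               tolerance = 1e-6)

  # a class with a single matrix has undefined dispersion
  m2 <- m1[, , 1:3, drop = FALSE]
  labs2 <- factor(c("IMAGERY", "IMAGERY", "NO_IMAGERY"),
                  levels = c("IMAGERY", "NO_IMAGERY"))
  expect_error(class_distinctiveness(list(matrices = m2, labels = labs2)),
               "fewer than 2")
})

test_that("class distinctiveness grows with the evoked amplitude", {
  cd <- vapply(c(0.2, 0.5, 1.0), function(amp) {
    runs <- simulate_dataset("RESPONSIVE", seed = 21,
                             evoked_amplitude_hbo = amp)
    hb <- lapply(runs, preprocess_run)
    ep <- pool_epochs(lapply(hb, make_epochs, chromophore = "BOTH"))
    pro <- compute_prototypes(ep)
    xd <- fit_xdawn(ep, f = 4)
    class_distinctiveness(augment_and_covary(ep, pro, xd))
  }, 0)
  expect_true(all(diff(cd) > 0))
})

test_that("a diagnosis reports three chromophores, one label, and serialises", {
  runs <- simulate_dataset("RESPONSIVE", seed = 31)
  dg <- run_full_diagnosis(runs, config = list(n_perm = 19, seed = 31,
                                               early_stop = TRUE))
  expect_setequal(names(dg$chromophores), c("HBO", "HBR", "BOTH"))
  expect_true(dg$label %in% c("RESPONSIVE", "UNRESPONSIVE"))
  expect_equal(dg$p_min, min(dg$p_values))
  td <- tidy(dg)
  expect_equal(nrow(td), 3)
  path <- file.path(withr::local_tempdir(), "report.json")
  write_diagnosis(dg, path)
  rep <- jsonlite::read_json(path)
  expect_equal(rep$label, dg$label)
  expect_length(rep$chromophores, 3)
})
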