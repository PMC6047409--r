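test_that("Poisson-case exact p follows the doubled conditional binomial", {
  # perfectly balanced split is the mode: two-sided p is 1
  expect_equal(nb_exact_pvalue(5, 5, 3, 3, phi = 0), 1)
  # extreme split (0, 10) with equal groups: p = 2 * 0.5^10
  expect_equal(nb_exact_pvalue(0, 10, 3, 3, phi = 0), 2 * 0.5^10)
  # no information in an all-zero window
  expect_equal(nb_exact_pvalue(0, 0, 3, 3, phi = 0), 1)
  # unequal group sizes shift the null success probability to na/(na+nb)
  expect_equal(nb_exact_pvalue(3, 9, 1, 3, phi = 0),
               oracle_binomial_p(3, 12, 1 / 4))
})

test_that("phi = 0 matches exhaustive conditional-binomial enumeration", {
  # spot grid here (the full totals <= 50 sweep runs in the acceptance suite)
  for (na in c(2, 3, 5)) for (nb in c(2, 5)) {
    pr <- na / (na + nb)
    for (t in c(1, 7, 20)) {
      for (ya in 0:t) {
        expect_equal(nb_exact_pvalue(ya, t - ya, na, nb, phi = 0),
                     oracle_binomial_p(ya, t, pr), tolerance = 1e-12)
      }
    }
  }
})

test_that("overdispersed exact p matches brute-force NB split enumeration", {
  # frozen oracle value for phi = 0.5, split (2, 20), 3 vs 3 samples
  expect_equal(nb_exact_pvalue(2, 20, 3, 3, phi = 0.5), 0.0164427711702,
               tolerance = 1e-9)
  for (case in list(c(0, 15, 2, 2, 0.2), c(8, 9, 3, 4, 0.8),
                    c(30, 5, 5, 2, 0.05))) {
    expect_equal(
      nb_exact_pvalue(case[1], case[2], case[3], case[4], case[5]),
      oracle_nb_split_p(case[1], case[1] + case[2], case[3], case[4], case[5]),
      tolerance = 1e-10
    )
  }
  expect_error(nb_exact_pvalue(1, 2, 3, 3, phi = -1), "dispersion")
})

test_that("exact test p-values are invariant to group-label exchange", {
  for (phi in c(0, 0.3)) {
    for (case in list(c(3, 12, 2, 4), c(0, 9, 3, 3), c(25, 11, 5, 3))) {
      expect_equal(
        nb_exact_pvalue(case[1], case[2], case[3], case[4], phi),
        nb_exact_pvalue(case[2], case[1], case[4], case[3], phi)
      )
    }
  }
  # and at the table level the fold change negates
  exp <- make_experiment(matrix(rpois(40, 100), 10, 4))
  cfg <- test_config(dispersion = 0.1)
  ab <- nb_exact_test(exp, "ctrl", "treat", cfg)
  ba <- nb_exact_test(exp, "treat", "ctrl", cfg)
  expect_equal(ab$p_value, ba$p_value)
  expect_equal(ab$log2_fc, -ba$log2_fc)
})

test_that("the exact test agrees with the edgeR implementation it mirrors", {
  skip_if_not_installed("edgeR")
  set.seed(8)
  m <- matrix(rnbinom(52 * 6, size = 10, mu = 200), 52, 6)
  phi <- 0.1
  exp <- make_experiment(m, treatments = rep(c("ctrl", "treat"), each = 3))
  mine <- nb_exact_test(exp, "ctrl", "treat", test_config(dispersion = phi))
  # independent route: edgeR's exact test with the same fixed common
  # dispersion, equal library sizes and the minimum-likelihood rejection
  # region
  dge <- edgeR::DGEList(counts = m, group = rep(c("a", "b"), each = 3),
                        lib.size = rep(1e6, 6))
  et <- edgeR::exactTest(dge, dispersion = phi, rejection.region = "smallp")
  expect_equal(mine$p_value, et$table$PValue, tolerance = 1e-6)
})

test_that("common dispersion is recovered by the moment estimator", {
  # Poisson data: dispersion near zero
  set.seed(31)
  pois <- make_experiment(matrix(rpois(52 * 20, 300), 52, 20),
                          treatments = rep(c("ctrl", "treat"), each = 10))
  expect_lte(estimate_common_dispersion(pois), 0.05)

  # genuinely NB data with phi = 0.2 and means >= 100
  set.seed(32)
  nb <- make_experiment(
    matrix(rnbinom(52 * 20, size = 1 / 0.2, mu = rep(sample(100:1000, 52), 20)),
           52, 20),
    treatments = rep(c("ctrl", "treat"), each = 10)
  )
  phi_hat <- estimate_common_dispersion(nb)
  expect_gte(phi_hat, 0.1)
  expect_lte(phi_hat, 0.3)

  # constant windows have zero variance
  flat <- make_experiment(matrix(100, 10, 4))
  expect_equal(estimate_common_dispersion(flat), 0)

  # no replication anywhere is an instructive error
  single <- make_experiment(matrix(1:10, 5, 2), treatments = c("a", "b"))
  expect_error(estimate_common_dispersion(single), "dispersion")
})
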