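test_that("library size factors are totals over their geometric mean", {
  exp <- make_experiment(cbind(c(40, 60), c(150, 250)))
  f <- library_size_factors(exp)
  expect_equal(unname(f$factors), c(0.5, 2.0))

  exp3 <- make_experiment(cbind(c(40, 60), c(40, 60), c(350, 450)),
                          treatments = c("a", "b", "c"))
  f3 <- library_size_factors(exp3)
  expect_equal(unname(f3$factors), c(0.5, 0.5, 4.0))

  eq <- library_size_factors(make_experiment(cbind(c(30, 70), c(60, 40))))
  expect_equal(unname(eq$factors), c(1, 1))

  zero <- make_experiment(cbind(c(0, 0), c(1, 2)))
  expect_error(library_size_factors(zero), "zero total")
})

test_that("an advisory is raised for low-count library-size normalization", {
  low <- make_experiment(matrix(5, 4, 2))
  expect_message(library_size_factors(low), "advisory")
})

test_that("gof is the Pearson statistic on library-size-scaled counts", {
  # equal library sizes: scaling is a no-op and the formula is direct
  exp <- make_experiment(cbind(c(10, 10, 40), c(20, 10, 30), c(30, 10, 20)),
                         treatments = c("a", "b", "c"))
  g <- gof_stats(exp)
  expect_equal(g$gof[1], (100 + 0 + 100) / 20)   # counts 10,20,30 about mean 20
  expect_equal(g$gof[2], 0)                      # constant window
  expect_equal(g$rank[2], 1L)

  # all-zero window gets Inf and is never selected
  exp0 <- make_experiment(cbind(c(10, 0, 40), c(20, 0, 30), c(30, 0, 20)),
                          treatments = c("a", "b", "c"))
  g0 <- gof_stats(exp0, quantile = 1)
  expect_equal(g0$gof[2], Inf)
  expect_false(g0$selected[2])
  expect_true(all(g0$selected[c(1, 3)]))

  expect_error(gof_stats(make_experiment(cbind(c(1, 2)), treatments = "a")),
               "2 samples")
})

test_that("gof ordering and selection are invariant to per-sample rescaling", {
  set.seed(21)
  m <- matrix(rpois(52 * 4, 200), 52, 4)
  exp <- make_experiment(m)
  exact <- new_experiment(exp$windows, exp$samples, sweep(m, 2, c(3, 1, 0.5, 2), "*"))
  g0 <- gof_stats(exp, quantile = 0.25)
  g1 <- gof_stats(exact, quantile = 0.25)
  # library-size scaling removes the per-sample distortion, leaving only a
  # global scale: GoF values stay exactly proportional, so ranks and the
  # selected window set are unchanged
  expect_equal(g1$rank, g0$rank)
  expect_equal(g1$selected, g0$selected)
  ratio <- g1$gof / g0$gof
  expect_equal(ratio, rep(ratio[1], length(ratio)), tolerance = 1e-9)
})

test_that("gof_factors selects stable windows and recovers scale distortions", {
  set.seed(7)
  # 13 windows identical across samples, 39 noisy: the stable 13 dominate
  # selection at the default quantile and factors stay at 1
  stable <- matrix(100, 13, 4)
  noisy <- matrix(rpois(39 * 4, 80) + rep(sample(0:200, 39), 4), 39, 4)
  noisy <- noisy + matrix(rpois(39 * 4, 100), 39, 4)   # real inter-sample noise
  exp <- make_experiment(rbind(stable, noisy))
  nf <- gof_factors(exp, quantile = 0.25)
  expect_true(all(sprintf("win_%02d", 1:13) %in% nf$windows_used))
  expect_equal(unname(nf$factors), rep(1, 4), tolerance = 0.05)

  # multiplying one sample by 3 multiplies its factor by ~3 (after centering)
  m <- matrix(rpois(20 * 3, 150), 20, 3)
  base_f <- gof_factors(make_experiment(m, treatments = c("a", "b", "c")))$factors
  m2 <- m; m2[, 2] <- m[, 2] * 3
  f2 <- gof_factors(make_experiment(m2, treatments = c("a", "b", "c")))$factors
  expect_equal(unname(f2[2] / base_f[2]), 3 / 3^(1 / 3), tolerance = 1e-9)

  # quantile 1 uses every finite-gof window
  nf_all <- gof_factors(exp, quantile = 1)
  expect_length(nf_all$windows_used, 52)
})

test_that("control-window factors follow the nominated windows", {
  # controls identical across samples -> factors 1
  m <- rbind(c(50, 50), c(10, 90), c(30, 70))
  exp <- make_experiment(m)
  exp$windows$target_class <- c("control", "on_target", "on_target")
  nf <- control_window_factors(exp)
  expect_equal(unname(nf$factors), c(1, 1))
  expect_equal(nf$method, "control_windows")

  # single control window with counts (10, 20) -> centred (1/sqrt2, sqrt2)
  exp2 <- make_experiment(rbind(c(10, 20), c(99, 1)))
  nf2 <- control_window_factors(exp2, controls = "win_01")
  expect_equal(unname(nf2$factors), c(1 / sqrt(2), sqrt(2)))

  expect_error(control_window_factors(exp2, controls = "win_99"), "win_99")
  expect_error(control_window_factors(make_experiment(m)), "no windows")
})

test_that("control factors equal gof factors when the selections coincide", {
  set.seed(13)
  m <- matrix(rpois(40 * 3, 300), 40, 3)
  exp <- make_experiment(m, treatments = c("a", "b", "c"))
  nf_gof <- gof_factors(exp, quantile = 0.25)
  nf_ctrl <- control_window_factors(exp, controls = nf_gof$windows_used)
  expect_equal(nf_ctrl$factors, nf_gof$factors)
})

test_that("every method yields centred factors (product 1)", {
  set.seed(5)
  m <- matrix(rpois(30 * 4, 120), 30, 4)
  exp <- make_experiment(m)
  for (nf in list(library_size_factors(exp), gof_factors(exp),
                  control_window_factors(exp, controls = rownames(exp$counts)[1:5]),
                  custom_factors(exp, setNames(c(2, 1, 1, 4), colnames(exp$counts))))) {
    expect_equal(prod(nf$factors), 1, tolerance = 1e-9)
    expect_true(all(nf$factors > 0))
  }
})

test_that("apply_factors adds a normalized layer without touching counts", {
  exp <- make_experiment(matrix(c(10, 20, 30, 40), 2, 2))
  ones <- new_norm_factors(setNames(c(1, 1), colnames(exp$counts)), "custom")
  e1 <- apply_factors(exp, ones)
  expect_equal(e1$layers$normalized, exp$counts + 0)   # identity factors

  halve <- new_norm_factors(setNames(c(2, 0.5), colnames(exp$counts)), "custom")
  e2 <- apply_factors(exp, halve)
  expect_equal(e2$layers$normalized[, 1], exp$counts[, 1] / 2)
  expect_equal(e2$counts, exp$counts)
  expect_warning(apply_factors(e2, halve), "overwriting")

  bad <- new_norm_factors(c(x = 1, y = 1), "custom")
  expect_error(apply_factors(exp, bad), "match")
})
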