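test_that("polarization follows the intensity-ratio formula", {
  expect_equal(polarization(100, 100), 0)
  expect_equal(polarization(300, 100), 0.5)
  expect_equal(polarization(250, 0), 1)
  expect_error(polarization(0, 0), "both intensities are zero")
  expect_error(polarization(-1, 5), "non-negative")
  # antisymmetric under swapping the two intensities
  set.seed(1)
  fa <- runif(20, 1, 500); fb <- runif(20, 1, 500)
  expect_equal(polarization(fa, fb), -polarization(fb, fa))
  expect_true(all(abs(polarization(fa, fb)) <= 1))
})

test_that("noiseless competition curves are recovered to high precision", {
  cv <- make_competition_curve(1e-8, min = 50, max = 300, hill = 1, seed = 1)
  fit <- fit_competition(cv)
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)["log_ic50"]), -8, tolerance = 1e-4)
  expect_equal(unname(coef(fit)["min"]), 50, tolerance = 1e-3)
  expect_equal(unname(coef(fit)["max"]), 300, tolerance = 1e-3)

  # four-parameter mode frees and recovers the hill slope
  cv2 <- make_competition_curve(5e-9, hill = 1.4, seed = 2)
  fit4 <- fit_competition(cv2, mode = "four_param")
  expect_true(fit4$converged)
  expect_equal(unname(coef(fit4)["hill"]), 1.4, tolerance = 1e-3)
  expect_equal(unname(coef(fit4)["log_ic50"]), log10(5e-9), tolerance = 1e-4)
})

test_that("the fitted competition model is monotone decreasing", {
  cv <- make_competition_curve(1e-8, noise_sd = 0.02, seed = 3)
  fit <- fit_competition(cv)
  grid <- 10^seq(-11, -5, length.out = 100)
  expect_true(all(diff(predict(fit, grid)) < 0))
})

test_that("degenerate inputs are flagged, not fatal", {
  flat <- competition_curve(10^seq(-11, -5, length.out = 12), rep(100, 12))
  fit <- fit_competition(flat)
  expect_false(fit$converged)
  expect_error(fit_competition(
    competition_curve(10^c(-9, -8, -7, -6, -5), c(5, 4, 3, 2, 1))[1:3, ]),
    "at least")
  expect_error(competition_curve(c(0, 1e-8, 1e-7, 1e-6, 1e-5), 1:5),
               "strictly positive")
})

test_that("competition fit methods behave like a classic model object", {
  cv <- make_competition_curve(1e-8, noise_sd = 0.03, seed = 4)
  fit <- fit_competition(cv)
  expect_named(coef(fit), c("min", "max", "log_ic50", "hill"))
  expect_equal(length(residuals(fit)), 12L)
  expect_equal(fitted(fit) + residuals(fit), cv$p)
  expect_equal(dim(vcov(fit)), c(3L, 3L))
  s <- summary(fit)
  expect_s3_class(s, "summary.competition_fit")
  expect_gt(s$ic50, 0)
  sims <- simulate(fit, nsim = 3, seed = 9)
  expect_equal(dim(sims), c(12L, 3L))
  expect_identical(sims, simulate(fit, nsim = 3, seed = 9))
  expect_output(print(fit), "IC50")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("noisy replicate fits recover the IC50 within a few percent", {
  curves <- make_competition_curve(1e-8, noise_sd = 0.03, n_replicates = 60,
                                   seed = 5)
  ic50s <- vapply(curves, function(cv) {
    f <- fit_competition(cv)
    10^unname(coef(f)["log_ic50"])
  }, 0)
  expect_lt(abs(median(ic50s) - 1e-8) / 1e-8, 0.05)
})

test_that("noiseless Boltzmann melts recover Tm and the midpoint property", {
  for (tm in c(59.5, 61.5, 65.8)) {
    fit <- fit_melt(make_melt_curve(tm, slope_width = 2, seed = 1))
    expect_true(fit$converged)
    expect_lt(abs(unname(coef(fit)["tm"]) - tm), 0.01)
    # signal at the fitted midpoint equals the baseline average
    cf <- coef(fit)
    expect_equal(unname(predict(fit, unname(cf["tm"]))),
                 unname((cf["folded"] + cf["unfolded"]) / 2),
                 tolerance = 1e-6)
  }
})

test_that("melt fits on noisy data stay within half a degree", {
  curves <- make_melt_curve(59.5, noise_sd = 0.02, n_replicates = 40,
                            seed = 6)
  tms <- vapply(curves, function(cv) unname(coef(fit_melt(cv))["tm"]), 0)
  expect_lt(abs(median(tms) - 59.5), 0.5)
})

test_that("non-sigmoidal melt data is flagged rather than crashing", {
  flat <- melt_curve(seq(25, 90, by = 5), rep(-10, 14))
  fit <- fit_melt(flat)
  expect_false(fit$converged)
  expect_error(melt_curve(c(30, 29, 31, 32, 33, 34, 35, 36), 1:8),
               "increasing")
  expect_error(melt_curve(seq(25, 130, by = 15), 1:8), "0, 120")
})

test_that("affinity tables validate units and values", {
  expect_error(affinity_table("r", "l", -1, 1, "nM"), "positive")
  expect_error(affinity_table("r", "l", 1, 1, "furlongs"), "unresolvable")
  tab <- affinity_table(c("a", "a"), c("x", "y"), c(10, 2), c(1, 0.5),
                        c("nM", "uM"))
  expect_equal(tab$ic50_molar, c(1e-8, 2e-6))
})

test_that("fold changes and the SE-interval rule match hand arithmetic", {
  tab <- read_affinity_table(
    system.file("extdata", "affinity_table_published.tsv",
                package = "erdesign"))
  fc <- fold_change(tab, "wt", "M421F")
  ee2 <- fc[fc$ligand == "17a-ethinylestradiol", ]
  expect_equal(ee2$fold, 2.1 / 12, tolerance = 1e-12)
  expect_equal(ee2$direction, "improved")
  tam <- fc[fc$ligand == "tamoxifen", ]
  expect_equal(tam$direction, "ns")  # 47 +/- 14 overlaps 55 +/- 40
  # self-comparison: all folds one, nothing significant
  self <- fold_change(tab, "wt", "wt")
  expect_true(all(self$fold == 1))
  expect_true(all(self$direction == "ns"))
})

test_that("fold change is reciprocal under receptor exchange", {
  tab <- read_affinity_table(
    system.file("extdata", "affinity_table_published.tsv",
                package = "erdesign"))
  fwd <- fold_change(tab, "wt", "M421I")
  rev <- fold_change(tab, "M421I", "wt")
  rev <- rev[match(fwd$ligand, rev$ligand), ]
  expect_equal(fwd$fold, 1 / rev$fold)
  flip <- c(improved = "worsened", worsened = "improved", ns = "ns")
  expect_equal(unname(flip[fwd$direction]), rev$direction)
})
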