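test_that("local-linear mean curve is exact on affine data and constants", {
  set.seed(1)
  age <- runif(300, 0, 20)
  snap <- data.frame(age_h = age, size_au = 10 + 5 * age)
  mc <- mean_size_vs_age(snap, bandwidth = 1, n_boot = 0)
  interior <- mc$age_h > 2 & mc$age_h < 18
  expect_equal(mc$estimate[interior], 10 + 5 * mc$age_h[interior],
               tolerance = 1e-8)
  # constant data give a flat curve
  snap2 <- data.frame(age_h = age, size_au = rep(100, 300))
  mc2 <- mean_size_vs_age(snap2, bandwidth = 1, n_boot = 30)
  expect_equal(mc2$estimate, rep(100, nrow(mc2)), tolerance = 1e-10)
  expect_equal(mc2$ci_hi - mc2$ci_lo, rep(0, nrow(mc2)), tolerance = 1e-10)
  # variance of deterministic size = f(age) is ~0 everywhere
  vc <- var_size_vs_age(snap, bandwidth = 1, n_boot = 0)
  expect_lt(max(vc$estimate), 1e-10)
})

test_that("variance curve recovers cohort-wise population variances", {
  snap <- data.frame(age_h = rep(c(0, 1), each = 2),
                     size_au = c(8, 12, 11, 11))
  vc <- var_size_vs_age(snap, bandwidth = 0.02, n_boot = 0,
                        grid = c(0, 1), min_cells = 2L)
  expect_equal(vc$estimate, c(4, 0), tolerance = 1e-8)
})

test_that("a too-small bandwidth with an empty grid point errors", {
  snap <- data.frame(age_h = c(rep(0, 30), rep(10, 30)),
                     size_au = rnorm(60, 100))
  expect_error(mean_size_vs_age(snap, bandwidth = 0.01,
                                grid = c(0, 5, 10), n_boot = 0),
               "kernel mass")
})

test_that("variance decomposition is an algebraic identity on any data", {
  set.seed(7)
  for (i in 1:25) {
    n <- sample(5:500, 1)
    s1 <- rlnorm(n, 4, 0.6)
    ds <- rnorm(n, 10, 4) - 0.2 * s1
    vd <- variance_decomposition(s1, s1 + ds)
    expect_lt(abs(vd$residual) / max(abs(vd$delta_var), 1e-12), 1e-10)
    # a variance drop forces a negative size-growth covariance
    if (vd$delta_var < 0) expect_lt(vd$cov_s1_ds, 0)
  }
})

test_that("paired Gcv reproduces hand arithmetic and sign conventions", {
  g <- gcv_paired(c(8, 12), c(11, 11))
  expect_equal(g$delta_var, -4)
  expect_equal(g$delta_mean, 1)
  expect_equal(g$gcv, -2)
  # zero variance change gives Gcv = 0 by convention
  expect_equal(gcv_paired(c(9, 11), c(10.5, 12.5))$gcv, 0)
  # size-independent increments: Gcv equals the increment CV
  set.seed(11)
  s1 <- rlnorm(40000, 4.6, 0.0001)
  ds <- rnorm(40000, 10, 2)
  expect_equal(gcv_paired(s1, s1 + ds)$gcv, 0.2, tolerance = 0.01)
})

test_that("gcv_vs_age differences the curves and respects conventions", {
  grid <- seq(0, 10, by = 0.5)
  mk <- function(est, kind) structure(
    data.frame(age_h = grid, estimate = est, ci_lo = NA, ci_hi = NA,
               n_eff = 100),
    kind = kind, boot = NULL, boot_id = "x",
    class = c("age_curve", "data.frame"))
  mc <- mk(100 + 2 * grid, "mean")
  vc <- mk(50 + 0 * grid, "variance")
  g <- gcv_vs_age(mc, vc, lag = 2.5)
  expect_equal(g$gcv, rep(0, nrow(g))) # flat variance
  expect_equal(g$delta_mean, rep(5, nrow(g)))
  # sign(gcv) equals sign(delta_var) wherever the mean increases
  vc2 <- mk(50 + sin(grid), "variance")
  g2 <- gcv_vs_age(mc, vc2, lag = 2.5)
  ok <- !is.na(g2$gcv) & g2$delta_var != 0
  expect_true(all(sign(g2$gcv[ok]) == sign(g2$delta_var[ok])))
  # suppressed where the mean does not increase
  mc2 <- mk(100 - 2 * grid, "mean")
  g3 <- gcv_vs_age(mc2, vc2, lag = 2.5)
  expect_true(all(is.na(g3$gcv)))
  expect_error(gcv_vs_age(mc, vc, lag = 0.3), "multiple")
  expect_error(gcv_vs_age(mc, vc, lag = -1), "multiple")
})

test_that("estimators are invariant to row order of the snapshot", {
  snap <- sizer_run()$snapshot
  perm <- sample(nrow(snap))
  c1 <- size_age_curves(snap, n_boot = 0)
  c2 <- size_age_curves(snap[perm, ], n_boot = 0)
  expect_equal(c1$mean$estimate, c2$mean$estimate)
  expect_equal(c1$var$estimate, c2$var$estimate)
  expect_equal(checkpoint_contrast(snap)$p_value,
               checkpoint_contrast(snap[perm, ])$p_value)
  expect_equal(doubling_ratio(snap), doubling_ratio(snap[perm, ]))
})

test_that("checkpoint contrast detects a sizer and stays calibrated on a timer", {
  snap <- sizer_run()$snapshot
  ck <- checkpoint_contrast(snap)
  expect_lt(ck$p_value, 0.01)
  expect_gt(ck$contrast, 0)
  # post-G1 cells are larger in (nearly) every qualifying bin
  expect_gt(mean(ck$bins$mean_postg1 > ck$bins$mean_g1), 0.9)
  # timer null: rejections at alpha = 0.01 stay near the nominal rate
  rej <- 0L
  for (i in 1:20) {
    cfg <- scenario_config("null_timer", seed = 300 + i)
    s <- simulate_population(cfg, 24, 500, record = "snapshot")$snapshot
    p <- checkpoint_contrast(s)$p_value
    rej <- rej + (p < 0.01)
  }
  expect_lte(rej, 3L)
  expect_error(checkpoint_contrast(snap[snap$phase == "G1", ]),
               "both G1 and post-G1")
})

test_that("doubling ratio is 2 on constructed data and near 2 at steady state", {
  snap <- data.frame(age_h = c(rep(0.5, 20), rep(15, 20)),
                     size_au = c(rep(100, 20), rep(200, 20)),
                     phase = c(rep("G1", 20), rep("M", 20)))
  expect_equal(doubling_ratio(snap), 2)
  expect_equal(doubling_ratio(sizer_run()$snapshot), 2, tolerance = 0.06)
  expect_error(doubling_ratio(snap[snap$phase == "G1", ]), "mitotic")
})

test_that("size variability is the normalized MAD and is scale invariant", {
  x <- c(1, 2, 3, 4, 100)
  expect_equal(size_variability(x), 1 / 3)
  expect_equal(size_variability(17.3 * x), 1 / 3)
  expect_error(size_variability(c(-5, -1, 1)), "positive")
  # disabling feedback mid-run (radicicol-like) raises size variability
  on <- feedback_run()$snapshot
  cfg_off <- scenario_config("feedback_dips", seed = 42)
  cfg_off$feedback_windows$strength <- 0
  off <- simulate_population(cfg_off, 24, 1400, record = "snapshot")$snapshot
  expect_gt(size_variability(off$size_au), size_variability(on$size_au))
})

test_that("bootstrap bands for the mean curve have near-nominal coverage", {
  # fixed truth: linear mean with heteroscedastic noise; 60 Monte-Carlo
  # replicates of n = 600, nominal 90% pointwise coverage at three ages
  set.seed(99)
  truth <- function(a) 100 + 4 * a
  grid <- c(5, 10, 15)
  hits <- 0L; total <- 0L
  for (i in 1:60) {
    age <- runif(600, 0, 20)
    snap <- data.frame(age_h = age,
                       size_au = truth(age) + rnorm(600, 0, 5 + age))
    mc <- mean_size_vs_age(snap, bandwidth = 1.5, n_boot = 80, grid = grid)
    hits <- hits + sum(mc$ci_lo <= truth(grid) & truth(grid) <= mc$ci_hi)
    total <- total + length(grid)
  }
  cover <- hits / total
  expect_gt(cover, 0.85 - 0.05)
  expect_lt(cover, 0.98)
})
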