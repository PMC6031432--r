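test_that("growth increments follow the configured model and feedback", {
  cfg <- exact_config(growth_model = "linear", base_rate = 5,
                      feedback_windows = data.frame(age_lo = 0, age_hi = 100,
                                                    strength = 0))
  # feedback off reduces to the constant rate
  expect_equal(growth_increment(100, age = 1, dt = 1, config = cfg), 5)
  # at the target size the feedback multiplier is the identity for any beta
  cfg1 <- exact_config(growth_model = "linear", base_rate = 5,
                       target_size = 200,
                       feedback_windows = data.frame(age_lo = 0,
                                                     age_hi = 100,
                                                     strength = 3))
  expect_equal(growth_increment(200, age = 1, dt = 1, config = cfg1), 5)
  # beta = 1 at twice the target size halves the rate
  cfg2 <- exact_config(growth_model = "linear", base_rate = 5,
                       target_size = 200,
                       feedback_windows = data.frame(age_lo = 0,
                                                     age_hi = 100,
                                                     strength = 1))
  expect_equal(growth_increment(400, age = 1, dt = 1, config = cfg2), 2.5)
  # outside a window the strength is treated as zero
  cfg3 <- exact_config(growth_model = "linear", base_rate = 5,
                       target_size = 200,
                       feedback_windows = data.frame(age_lo = 4, age_hi = 7,
                                                     strength = 1))
  expect_equal(growth_increment(400, age = 2, dt = 1, config = cfg3), 5)
  expect_error(growth_increment(100, 1, dt = 0, config = cfg),
               "positive")
})

test_that("exponential and poisson growth models behave as configured", {
  cfge <- exact_config(growth_model = "exponential", base_rate = 0.05)
  expect_equal(growth_increment(100, 1, dt = 1, config = cfge), 5)
  cfgp <- exact_config(growth_model = "poisson", base_rate = 2)
  set.seed(1)
  ds <- growth_increment(rep(100, 5000), 1, dt = 1, config = cfgp)
  expect_true(all(ds >= 0), info = "poisson increments are non-negative")
  expect_true(all(ds == round(ds)))
  expect_equal(mean(ds), 2, tolerance = 0.05)
})

test_that("G1 exit rules fire at the documented times", {
  # sizer with threshold already satisfied exits at the minimum duration
  cfg <- exact_config(g1_exit_rule = "sizer", sizer_threshold = 50,
                      g1_min_duration = 2, base_rate = 5)
  st <- cell_state(1L, birth_time = 0, size = 100, config = cfg)
  st1 <- advance_phase(st, now = 1, config = cfg)
  expect_identical(st1$phase, "G1")
  st2 <- advance_phase(st, now = 2, config = cfg)
  expect_identical(st2$phase, "postG1")
  expect_equal(st2$g1_exit_time, 2)

  # sizer with linear noiseless growth: 100 + 5a = 150 at a = 10
  cfg2 <- exact_config(g1_exit_rule = "sizer", sizer_threshold = 150,
                       g1_min_duration = 0, base_rate = 5)
  st <- cell_state(1L, 0, 100, cfg2)
  for (step in seq(0.25, 12, by = 0.25)) {
    st$size <- st$size + growth_increment(st$size, step - 0.25, 0.25, cfg2)
    st <- advance_phase(st, now = step, config = cfg2)
    if (st$phase != "G1") break
  }
  expect_equal(st$g1_exit_time, 10)

  # degenerate timer gives every cell the same G1 length
  cfg3 <- exact_config(g1_exit_rule = "timer", timer_mean = 8, timer_sd = 0)
  durs <- vapply(1:5, function(i)
    cell_state(i, 0, 100, cfg3)$g1_dur, numeric(1))
  expect_true(all(durs == 8))
})

test_that("division conserves mass and splits by the drawn fraction", {
  cfg <- exact_config()
  st <- cell_state(1L, 0, 200, cfg)
  st$phase <- "M"
  st$divide_flag <- TRUE
  st$m_entry_time <- 20
  st$m_dur <- 1
  d <- divide_cell(st, cfg)
  expect_equal(d[[1]]$size, 100) # symmetric split when sd = 0
  expect_equal(d[[1]]$size + d[[2]]$size, 200)
  expect_identical(d[[1]]$phase, "G1")
  expect_error(divide_cell(cell_state(2L, 0, 100, cfg), cfg),
               "not flagged in mitosis")
})

test_that("measurement is the identity when all noise is off", {
  cfg <- exact_config(nucleus_scale = 2, nucleus_exponent = 1)
  st <- cell_state(1L, 0, 50, cfg)
  m <- measure_cell(st, cfg)
  expect_equal(m$observed_size, 50)
  expect_equal(m$observed_nucleus, 100)
})

test_that("perturbation rescales rates only after onset", {
  cfg <- exact_config(base_rate = 5,
                      perturbation = list(onset = 10, growth_scale = 0.4,
                                          cycle_scale = 0.5))
  expect_equal(apply_perturbation(cfg, 5)$growth_scale, 1)
  expect_equal(apply_perturbation(cfg, 10)$growth_scale, 0.4)
  expect_equal(apply_perturbation(cfg, 12)$duration_scale, 2)
  expect_equal(growth_increment(100, 1, 1, cfg, now = 12), 2)
  expect_error(sim_config(perturbation = list(onset = 1, growth_scale = 0,
                                              cycle_scale = 1)),
               "positive")
  # infinite onset is a no-op: identical dynamics for the same seed
  a <- simulate_population(exact_config(seed = 9), 6, 20)
  b <- simulate_population(
    exact_config(seed = 9, perturbation = list(onset = Inf,
                                               growth_scale = 0.4,
                                               cycle_scale = 0.5)), 6, 20)
  expect_identical(a$snapshot, b$snapshot)
})

test_that("a noiseless timer population doubles synchronously", {
  cfg <- exact_config(g1_exit_rule = "timer", timer_mean = 10,
                      postg1_mean = 9, mitosis_duration = 1, base_rate = 5,
                      founder_size_mean = 100, seed = 3)
  res <- simulate_population(cfg, 40, 1)
  expect_equal(nrow(res$snapshot), 4) # two synchronous doublings
  expect_equal(res$mean_cycle_h, 20)
  # duration 0 returns exactly the founders
  res0 <- simulate_population(cfg, 0, 7)
  expect_equal(nrow(res0$snapshot), 7)
  expect_true(all(res0$snapshot$age_h == 0))
})

test_that("mass is conserved at every division in a stochastic run", {
  res <- sizer_run()
  ev <- res$tracks$events
  divided <- ev$cell_id[!is.na(ev$division_time)]
  kids <- split(ev$cell_id, ev$parent_id)
  # reconstruct each mother's size at division from her daughters' births
  # is not possible from events alone; instead check the simulator's scalar
  # division operator over many draws
  cfg <- sim_config(division_fraction_sd = 0.15, seed = 1)
  set.seed(1)
  for (s in c(80, 123.4, 200)) {
    st <- cell_state(1L, 0, s, cfg)
    st$phase <- "M"; st$divide_flag <- TRUE
    st$m_entry_time <- 0; st$m_dur <- 1
    d <- divide_cell(st, cfg)
    expect_identical(d[[1]]$size + d[[2]]$size, s)
    expect_true(d[[1]]$size / s > 0.2 && d[[1]]$size / s < 0.8)
  }
  # every divided mother has exactly two daughters
  expect_true(all(lengths(kids[as.character(divided)]) == 2L))
})

test_that("identical config and seed give identical output tables", {
  cfg <- scenario_config("sizer", seed = 77)
  a <- simulate_population(cfg, 12, 80)
  b <- simulate_population(cfg, 12, 80)
  expect_identical(a$snapshot, b$snapshot)
  expect_identical(a$tracks, b$tracks)
  expect_identical(a$bulk, b$bulk)
})

test_that("steady snapshot age distribution decays like 2a*exp(-alpha*t)", {
  res <- timer_run()
  age <- res$snapshot$age_h
  alpha <- log(2) / 20
  # compare empirical age-bin frequencies with the analytic steady density
  br <- seq(0, 18, by = 3)
  emp <- as.numeric(table(cut(age[age < 18], br))) / sum(age < 18)
  dens <- function(a) 2 * alpha * exp(-alpha * a)
  theor <- vapply(seq_len(length(br) - 1), function(i)
    integrate(dens, br[i], br[i + 1])$value, numeric(1))
  theor <- theor / sum(theor)
  expect_lt(max(abs(emp - theor)), 0.05)
  # monotonically decreasing occupancy with age
  expect_true(all(diff(emp) < 0))
})

test_that("feedback tightens the steady-state size distribution", {
  cfg_off <- scenario_config("feedback_dips", seed = 5)
  cfg_off$feedback_windows$strength <- 0
  snap_on <- feedback_run()$snapshot
  snap_off <- simulate_population(cfg_off, 24, 1400,
                                  record = "snapshot")$snapshot
  cv <- function(x) sd(x) / mean(x)
  expect_gt(nrow(snap_on), 2000)
  expect_lt(cv(snap_on$size_au), cv(snap_off$size_au))
})
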