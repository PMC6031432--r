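make_toy_tracks <- function() {
  # three cells sampled every 0.25 h from birth
  grid <- seq(0, 6, by = 0.25)
  samples <- do.call(rbind, lapply(1:3, function(id)
    data.frame(cell_id = id, t_h = grid + (id - 1),
               nucleus_au = 100 + 2 * grid)))
  events <- data.frame(cell_id = 1:3, birth_time = 0:2,
                       g1_exit_time = c(4, 5, NA),
                       m_entry_time = c(5.5, NA, NA),
                       division_time = c(6, NA, NA))
  list(samples = samples, events = events)
}

test_that("track preprocessing trims birth flattening and mitosis", {
  tr <- make_toy_tracks()
  pp <- preprocess_tracks(tr)
  s1 <- pp$samples[pp$samples$cell_id == 1, ]
  # samples at ages 0..1 h (five samples) removed from the head
  expect_equal(min(s1$t_h), 1.25)
  # samples at/after mitosis onset removed from the tail
  expect_lt(max(s1$t_h), 5.5)
  # a track with no early samples keeps its head
  tr2 <- tr
  tr2$samples <- tr$samples[tr$samples$t_h - rep(0:2, each = 25)[
    seq_len(nrow(tr$samples))] >= 2, ]
  s2 <- preprocess_tracks(tr)$samples
  expect_true(all(s2$t_h[s2$cell_id == 2] - 1 >= 1.25))
  # too-short tracks are excluded with a logged reason
  tr3 <- tr
  tr3$samples <- tr3$samples[!(tr3$samples$cell_id == 3 &
                                 tr3$samples$t_h > 3.5), ]
  pp3 <- preprocess_tracks(tr3)
  expect_true(3 %in% attr(pp3, "excluded")$cell_id ||
                sum(pp3$samples$cell_id == 3) >= 3)
})

test_that("G1 duration is the exit-birth difference and validates order", {
  ev <- data.frame(cell_id = 1:2, birth_time = c(10, 0),
                   g1_exit_time = c(21, NA))
  d <- g1_duration(ev)
  expect_equal(unname(d[1]), 11)
  expect_true(is.na(d[2]))
  ev$g1_exit_time[2] <- -1
  expect_error(g1_duration(ev), "precedes birth")
})

test_that("sizer tracks couple birth size to G1 length; timer tracks do not", {
  rep_s <- birth_size_g1_correlation(sizer_run()$tracks, n_perm = 500,
                                     seed = 3)
  expect_gt(rep_s$n, 500)
  expect_lt(rep_s$r, -0.3)
  expect_lt(rep_s$perm_p, 0.01)
  expect_lt(rep_s$slope, 0)
  rep_t <- birth_size_g1_correlation(timer_run()$tracks, n_perm = 500,
                                     seed = 3)
  expect_lt(abs(rep_t$r), 0.08)
  expect_gt(rep_t$perm_p, 0.05)
  # the permutation null is centred on zero
  expect_lt(abs(mean(rep_s$null_distribution)),
            3 / sqrt(length(rep_s$null_distribution)))
  # reported permutation p equals the null-exceedance fraction by definition
  expect_equal(rep_s$perm_p,
               mean(abs(rep_s$null_distribution) >= abs(rep_s$r)))
})

test_that("sizer G1 lengths are right-skewed relative to timer lengths", {
  skew <- function(x) mean(((x - mean(x)) / sd(x))^3)
  g1_s <- g1_duration(sizer_run()$tracks$events)
  g1_t <- g1_duration(timer_run()$tracks$events)
  expect_gt(skew(g1_s[!is.na(g1_s)]), skew(g1_t[!is.na(g1_t)]))
})

test_that("track statistics are invariant to reordering and unit rescaling", {
  tr <- sizer_run()$tracks
  perm <- sample(nrow(tr$samples))
  tr2 <- list(samples = tr$samples[perm, ], events = tr$events)
  r1 <- birth_size_g1_correlation(tr, n_perm = 50, seed = 5)
  r2 <- birth_size_g1_correlation(tr2, n_perm = 50, seed = 5)
  expect_equal(r1$r, r2$r)
  expect_equal(r1$n, r2$n)
  # affine rescaling of nucleus units: r unchanged, slope scales
  tr3 <- tr
  tr3$samples$nucleus_au <- tr3$samples$nucleus_au * 3.5
  r3 <- birth_size_g1_correlation(tr3, n_perm = 50, seed = 5)
  expect_equal(r3$r, r1$r, tolerance = 1e-12)
  expect_equal(r3$slope, r1$slope / 3.5, tolerance = 1e-9)
})

test_that("|r| grows as the sizer threshold gets sharper", {
  # sharpness = how deterministically size sets the G1 exit: lower growth
  # noise and rate heterogeneity make the size threshold bind more tightly
  settings <- list(c(4, 0.7), c(1.34, 0.25), c(0.3, 0.05))
  rs <- vapply(settings, function(p) {
    cfg <- scenario_config("sizer", seed = 8)
    cfg$growth_noise_cv <- p[1]
    cfg$rate_cv <- p[2]
    res <- simulate_population(cfg, 36, 400, record = "tracks")
    birth_size_g1_correlation(res$tracks, n_perm = 10, seed = 1)$r
  }, numeric(1))
  expect_true(all(diff(abs(rs)) > 0))
  expect_true(all(rs < 0))
})

test_that("age-resolved lagged correlation localizes the feedback windows", {
  res <- cached_sim("feedback_tracks", function()
    simulate_population(scenario_config("feedback_dips", seed = 14), 30, 700,
                        record = "tracks"))
  ar <- growth_vs_size_by_age(res$tracks, lag = 2.5, age_step = 1)
  # windows (4,7) and (11,15): lagged detection regions (1.5,7), (8.5,15);
  # only ages 7-8 are untouched by either window after the lag shift
  in1 <- ar$age_h >= 2 & ar$age_h <= 6.5
  in2 <- ar$age_h >= 10 & ar$age_h <= 14.5
  out <- ar$age_h >= 7 & ar$age_h <= 8
  expect_lt(min(ar$r[in1], na.rm = TRUE), -0.15)
  expect_lt(min(ar$r[in2], na.rm = TRUE), -0.15)
  expect_gt(mean(ar$r[out], na.rm = TRUE), -0.05)
  # beta = 0: no coupling at any age
  res0 <- cached_sim("timer_tracks_ar", function()
    simulate_population(scenario_config("null_timer", seed = 14), 30, 700,
                        record = "tracks"))
  ar0 <- growth_vs_size_by_age(res0$tracks, lag = 2.5, age_step = 1)
  expect_gt(min(ar0$r, na.rm = TRUE), -0.3)
  expect_lt(abs(mean(ar0$r, na.rm = TRUE)), 0.05)
  # sparse ages are flagged undefined, not zero-filled
  expect_true(all(is.na(ar0$r[!ar0$defined])))
  expect_error(growth_vs_size_by_age(res0$tracks, lag = 0.37), "grid")
})

test_that("extreme deciles converge under feedback and diverge under exponential growth", {
  res <- cached_sim("strong_feedback_tracks", function()
    simulate_population(scenario_config("strong_feedback", seed = 14), 30,
                        700, record = "tracks"))
  dc <- extreme_decile_convergence(res$tracks, sort_age = 10, k = 10)
  expect_lt(dc$gap_ratio, 1)
  cfge <- sim_config(growth_model = "exponential", base_rate = log(2) / 21,
                     g1_exit_rule = "timer", timer_mean = 10,
                     postg1_mean = 10, growth_noise_cv = 0,
                     founder_init = "steady", seed = 6)
  rese <- simulate_population(cfge, 30, 700, record = "tracks")
  dce <- extreme_decile_convergence(rese$tracks, sort_age = 10, k = 10)
  expect_gt(dce$gap_ratio, 1)
  # symmetric constructed fixture: identical groups keep a unit gap ratio
  grid <- seq(0, 16, by = 0.25)
  sizes <- rep(c(90, 110), each = 10)
  samples <- do.call(rbind, lapply(1:20, function(id)
    data.frame(cell_id = id, t_h = grid, nucleus_au = sizes[id] + 2 * grid)))
  events <- data.frame(cell_id = 1:20, birth_time = 0,
                       g1_exit_time = NA, m_entry_time = NA,
                       division_time = NA)
  dcf <- extreme_decile_convergence(list(samples = samples, events = events),
                                    sort_age = 10, k = 10)
  expect_equal(dcf$gap_ratio, 1)
})
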