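#' Default growth-feedback windows
#'
#' Two age windows in which the growth rate carries the size correction
#' `(target_size / size)^strength`, one in mid G1 and one around the
#' G1/S-to-G2 transition. Two windows are the default because unperturbed
#' populations show two distinct periods of negative size-growth coupling
#' per cycle.
#'
#' @param strength feedback exponent applied in both windows.
#' @return data frame with `age_lo`, `age_hi`, `strength`.
#' @export
default_feedback_windows <- function(strength = 1.5) {
  data.frame(age_lo = c(4, 11), age_hi = c(7, 15), strength = strength)
}

#' Scenario configurations
#'
#' Named simulation regimes mirroring the experiment classes the analyses
#' are designed for:
#'
#' * `null_timer` — timer G1 exit, no feedback: size plays no role anywhere;
#'   the null for checkpoint and birth-size/G1-length analyses.
#' * `sizer` — sizer G1 exit plus the default feedback windows: the full
#'   homeostatic regime.
#' * `feedback_dips` — timer G1 exit with two feedback windows: growth-rate
#'   regulation without a checkpoint, isolating the negative Gcv excursions.
#' * `strong_feedback` — timer G1 exit with one feedback window spanning the
#'   whole cycle: continuous size-dependent growth regulation, the regime in
#'   which initially extreme cells visibly converge in size.
#' * `rapamycin_like` — sizer regime with an acute growth-rate inhibition
#'   (g = 0.4) switched on at `onset`; the cycle compensates by lengthening.
#' * `sns_like` — sizer regime with an acute cell-cycle slow-down (c = 0.5)
#'   at `onset`; growth per cycle compensates via the size threshold.
#'
#' @param scenario scenario name.
#' @param seed master seed.
#' @param onset perturbation onset for the drug-like scenarios, hours.
#' @return a [sim_config()].
#' @export
scenario_config <- function(scenario = c("null_timer", "sizer",
                                         "feedback_dips", "strong_feedback",
                                         "rapamycin_like", "sns_like"),
                            seed = 1L, onset = 12) {
  scenario <- match.arg(scenario)
  switch(scenario,
    null_timer = sim_config(
      g1_exit_rule = "timer", timer_mean = 10, timer_sd = 1.5,
      postg1_mean = 9, postg1_sd = 1, feedback_windows = NULL,
      base_rate = 5, founder_size_mean = 100,
      founder_init = "steady", seed = seed),
    sizer = sim_config(
      g1_exit_rule = "sizer", feedback_windows = default_feedback_windows(),
      founder_init = "steady", seed = seed),
    feedback_dips = sim_config(
      g1_exit_rule = "timer", timer_mean = 10, timer_sd = 1.5,
      postg1_mean = 9, postg1_sd = 1,
      feedback_windows = data.frame(age_lo = c(4, 11), age_hi = c(7, 15),
                                    strength = c(3, 4)),
      base_rate = 5, founder_size_mean = 100, target_size = 140,
      founder_init = "steady", seed = seed),
    strong_feedback = sim_config(
      g1_exit_rule = "timer", timer_mean = 10, timer_sd = 1.5,
      postg1_mean = 9, postg1_sd = 1,
      feedback_windows = data.frame(age_lo = 0, age_hi = 30, strength = 2),
      base_rate = 5, founder_size_mean = 100, target_size = 140,
      founder_init = "steady", seed = seed),
    rapamycin_like = sim_config(
      g1_exit_rule = "sizer", feedback_windows = default_feedback_windows(),
      perturbation = list(onset = onset, growth_scale = 0.4,
                          cycle_scale = 1),
      founder_init = "steady", seed = seed),
    sns_like = sim_config(
      g1_exit_rule = "sizer", feedback_windows = default_feedback_windows(),
      perturbation = list(onset = onset, growth_scale = 1,
                          cycle_scale = 0.5),
      founder_init = "steady", seed = seed))
}

#' A perfectly compensating condition panel
#'
#' Constructs a panel of conditions whose growth rates and cycle lengths
#' satisfy `v = C_TS / tau` exactly, the perfect-compensation limit in which
#' every condition has the same target size and the log-log correlation of
#' `v` with `tau` is exactly -1.
#'
#' @param n_conditions number of perturbed conditions.
#' @param target_size the common `C_TS = v * tau` (size units).
#' @param tau_range range of cycle lengths, hours.
#' @param control control label.
#' @return data frame with `condition`, `tau_h`, `v`.
#' @export
perfect_compensation_panel <- function(n_conditions = 10L,
                                       target_size = log(2) * 200,
                                       tau_range = c(12, 48),
                                       control = "control") {
  tau <- seq(tau_range[1], tau_range[2], length.out = n_conditions)
  rbind(
    data.frame(condition = control, tau_h = 21, v = target_size / 21),
    data.frame(condition = sprintf("cond%02d", seq_len(n_conditions)),
               tau_h = tau, v = target_size / tau))
}

#' Generate an on-disk fixture dataset
#'
#' Simulates (or constructs) a named scenario and writes its tables as CSV
#' together with a JSON run manifest. Deterministic for a given
#' `(scenario, seed)`.
#'
#' @param scenario one of the [scenario_config()] names or
#'   `"perfect_compensation_panel"`.
#' @param seed master seed.
#' @param dir output directory (created if needed).
#' @param duration,n_founders simulation extent; defaults chosen per
#'   scenario.
#' @return invisible list of written paths.
#' @export
make_fixtures <- function(scenario, seed = 1L, dir = tempdir(),
                          duration = NULL, n_founders = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  if (scenario == "perfect_compensation_panel") {
    panel <- perfect_compensation_panel()
    p <- file.path(dir, "panel.csv")
    utils::write.csv(panel, p, row.names = FALSE, quote = FALSE)
    manifest <- run_manifest(list(scenario = scenario), seed)
    paths <- list(panel = p)
  } else {
    cfg <- scenario_config(scenario, seed = seed)
    if (is.null(duration))
      duration <- if (grepl("_like$", scenario)) 72 else 36
    if (is.null(n_founders))
      n_founders <- if (grepl("_like$", scenario)) 300 else 500
    res <- simulate_population(cfg, duration, n_founders,
                               condition = scenario)
    paths$snapshot <- file.path(dir, "snapshot.csv")
    write_snapshot(res$snapshot, paths$snapshot)
    write_tracks(res$tracks, file.path(dir, "tracks"))
    paths$tracks <- file.path(dir, "tracks")
    paths$bulk <- file.path(dir, "bulk.csv")
    write_bulk(res$bulk, paths$bulk)
    manifest <- run_manifest(cfg, seed)
  }
  mpath <- file.path(dir, "manifest.json")
  writeLines(jsonlite::toJSON(unclass(manifest), auto_unbox = TRUE,
                              pretty = TRUE), mpath)
  paths$manifest <- mpath
  invisible(paths)
}
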