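#' Simulation configuration for the growth-and-division model
#'
#' Builds and validates the parameter set for [simulate_population()]. The
#' model follows single cells through G1, post-G1 (S/G2 pooled) and mitosis,
#' growing them in discrete time steps of `sampling_interval` hours, and
#' divides them into two daughters. Size sensing enters in two independent
#' places:
#'
#' * the **G1 exit rule** (`g1_exit_rule`): `"sizer"` exits G1 at the first
#'   sample time at which size reaches `sizer_threshold` and age exceeds
#'   `g1_min_duration`; `"timer"` exits after a drawn duration independent of
#'   size; `"adder"` exits once `adder_increment` size units have been added
#'   since birth;
#' * **growth-rate feedback** (`feedback_windows`): inside each age window the
#'   instantaneous growth rate is multiplied by `(target_size / size)^strength`,
#'   so undersized cells grow faster and oversized cells slower. Outside all
#'   windows the strength is treated as zero.
#'
#' @param growth_model one of `"linear"` (rate in size units/h), `"exponential"`
#'   (`base_rate` is a per-hour fraction; rate is `base_rate * size`) or
#'   `"poisson"` (integer size increments drawn as Poisson with mean
#'   `rate * dt`, giving intrinsically stochastic growth).
#' @param base_rate baseline growth rate, size units per hour (linear,
#'   poisson) or per-hour fraction (exponential).
#' @param target_size size the feedback corrects towards (size units).
#' @param feedback_windows data frame with columns `age_lo`, `age_hi`
#'   (hours) and `strength` (>= 0); windows must be ordered and
#'   non-overlapping. `NULL` disables feedback.
#' @param g1_exit_rule `"sizer"`, `"timer"` or `"adder"`.
#' @param sizer_threshold G1 exit size threshold (size units, sizer rule).
#' @param g1_min_duration minimum time in G1 (hours, sizer rule).
#' @param timer_mean,timer_sd mean and sd of the drawn G1 duration (hours,
#'   timer rule).
#' @param adder_increment size added in G1 before exit (adder rule).
#' @param postg1_mean,postg1_sd mean and sd of the pooled S/G2 duration (hours).
#' @param mitosis_duration duration of mitosis (hours).
#' @param division_fraction_sd sd of the division fraction `f` around 0.5;
#'   `f` is truncated to (0.2, 0.8) so both daughters are viable. Daughter
#'   sizes are `f * S` and `(1 - f) * S`, conserving mass exactly.
#' @param growth_noise_cv short-term growth-rate fluctuation for the
#'   `"linear"` and `"exponential"` models: a mean-one gamma multiplier with
#'   this CV is redrawn every `growth_noise_block` hours and scales the
#'   increments inside the block, so increments stay non-negative and the CV
#'   of growth accumulated over a lag of `k` blocks decays as
#'   `growth_noise_cv / sqrt(k)`. The default (1.34 per 1.25 h block) gives
#'   growth over 2.5 h a CV near 1, the value expected if mass accretion is
#'   Poisson-like; set 0 for deterministic growth. Ignored by the
#'   `"poisson"` model, whose stochasticity is the Poisson draw itself.
#' @param growth_noise_block correlation time of the growth-rate
#'   fluctuations, hours; rate fluctuations are constant within a block and
#'   independent across blocks and cells.
#' @param rate_cv coefficient of variation of a per-cell, lifetime-persistent
#'   lognormal growth-rate multiplier (mean 1). This is the heritable-free
#'   growth-rate heterogeneity that makes cohorts of identically sized cells
#'   diverge in size; set to 0 for perfectly uniform growth rates.
#' @param size_noise_cv CV of the multiplicative measurement noise on
#'   observed cell size (stain intensity proxy).
#' @param nucleus_scale,nucleus_exponent the expected nucleus size is
#'   `nucleus_scale * size^nucleus_exponent`.
#' @param nucleus_noise_cv per-cell nucleus offset: each cell's nucleus size
#'   is displaced from the size trend by an additive offset drawn at birth
#'   (sd = `nucleus_noise_cv` times the expected newborn nucleus size) and
#'   held fixed for the cell's lifetime. This is the biological imperfection
#'   of the nucleus as a size proxy: it dominates the cross-sectional
#'   scatter between stain intensity and nucleus size, while leaving a
#'   cell's nucleus *growth* an undistorted readout of its size growth.
#' @param track_jitter_cv CV of the small per-observation measurement jitter
#'   added every time the nucleus is imaged.
#' @param perturbation list with `onset` (hours; `Inf` for none),
#'   `growth_scale` (g > 0) and `cycle_scale` (c > 0). From `onset` onwards
#'   growth rates are multiplied by `g` and all cycle-phase mean durations by
#'   `1/c`; sizer thresholds are unchanged. This emulates acute addition of a
#'   growth inhibitor (g < 1) and/or a cell-cycle inhibitor (c < 1).
#' @param founder_size_mean,founder_size_cv lognormal birth-size distribution
#'   of the founding cells (defaults: `target_size / 1.4`, CV 0.12).
#' @param founder_init `"newborn"` starts all founders at age 0 in G1;
#'   `"steady"` draws founder ages from the steady-state exponential age
#'   distribution of a proliferating population (density `2 a e^(-a t)`) so
#'   snapshots reach a stationary age structure after a short burn-in.
#' @param sampling_interval simulation/observation time step (hours).
#' @param seed integer master seed; all stochastic draws derive from it.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$g1_exit_rule
#' @export
sim_config <- function(growth_model = c("linear", "exponential", "poisson"),
                       base_rate = 3,
                       target_size = 200,
                       feedback_windows = NULL,
                       g1_exit_rule = c("sizer", "timer", "adder"),
                       sizer_threshold = 150,
                       g1_min_duration = 3,
                       timer_mean = 10,
                       timer_sd = 1.5,
                       adder_increment = 50,
                       postg1_mean = 10,
                       postg1_sd = 1,
                       mitosis_duration = 1,
                       division_fraction_sd = 0.1,
                       growth_noise_cv = 1.34,
                       growth_noise_block = 1.25,
                       rate_cv = 0.25,
                       size_noise_cv = 0.05,
                       nucleus_scale = 1,
                       nucleus_exponent = 1,
                       nucleus_noise_cv = 0.35,
                       track_jitter_cv = 0.02,
                       perturbation = list(onset = Inf, growth_scale = 1,
                                           cycle_scale = 1),
                       founder_size_mean = NULL,
                       founder_size_cv = 0.12,
                       founder_init = c("newborn", "steady"),
                       sampling_interval = 0.25,
                       seed = 1L) {
  growth_model <- match.arg(growth_model)
  g1_exit_rule <- match.arg(g1_exit_rule)
  founder_init <- match.arg(founder_init)
  if (is.null(founder_size_mean)) founder_size_mean <- target_size / 1.4
  if (is.null(feedback_windows)) {
    feedback_windows <- data.frame(age_lo = numeric(0), age_hi = numeric(0),
                                   strength = numeric(0))
  }
  feedback_windows <- as.data.frame(feedback_windows)
  stopifnot(all(c("age_lo", "age_hi", "strength") %in% names(feedback_windows)))
  pert <- utils::modifyList(list(onset = Inf, growth_scale = 1,
                                 cycle_scale = 1), as.list(perturbation))

  cfg <- structure(list(
    growth_model = growth_model, base_rate = base_rate,
    target_size = target_size, feedback_windows = feedback_windows,
    g1_exit_rule = g1_exit_rule, sizer_threshold = sizer_threshold,
    g1_min_duration = g1_min_duration, timer_mean = timer_mean,
    timer_sd = timer_sd, adder_increment = adder_increment,
    postg1_mean = postg1_mean, postg1_sd = postg1_sd,
    mitosis_duration = mitosis_duration,
    division_fraction_sd = division_fraction_sd,
    growth_noise_cv = growth_noise_cv,
    growth_noise_block = growth_noise_block, rate_cv = rate_cv,
    size_noise_cv = size_noise_cv, nucleus_scale = nucleus_scale,
    nucleus_exponent = nucleus_exponent, nucleus_noise_cv = nucleus_noise_cv,
    track_jitter_cv = track_jitter_cv, perturbation = pert,
    founder_size_mean = founder_size_mean, founder_size_cv = founder_size_cv,
    founder_init = founder_init, sampling_interval = sampling_interval,
    seed = as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param x a `sim_config` object.
#' @export
validate_sim_config <- function(x) {
  stopifnot(inherits(x, "sim_config"))
  pos <- c("base_rate", "target_size", "sizer_threshold", "timer_mean",
           "adder_increment", "postg1_mean", "mitosis_duration",
           "founder_size_mean", "sampling_interval", "growth_noise_block")
  for (f in pos) {
    if (!is.numeric(x[[f]]) || length(x[[f]]) != 1L || x[[f]] <= 0)
      stop("`", f, "` must be a single strictly positive number",
           call. = FALSE)
  }
  nonneg <- c("g1_min_duration", "timer_sd", "postg1_sd",
              "division_fraction_sd", "growth_noise_cv", "rate_cv",
              "size_noise_cv",
              "nucleus_noise_cv", "track_jitter_cv", "founder_size_cv")
  for (f in nonneg) {
    if (!is.numeric(x[[f]]) || length(x[[f]]) != 1L || x[[f]] < 0)
      stop("`", f, "` must be a single non-negative number", call. = FALSE)
  }
  w <- x$feedback_windows
  if (nrow(w)) {
    if (any(w$strength < 0)) stop("feedback strengths must be >= 0",
                                  call. = FALSE)
    if (any(w$age_hi <= w$age_lo))
      stop("feedback windows must have age_hi > age_lo", call. = FALSE)
    if (is.unsorted(w$age_lo, strictly = TRUE) ||
        any(w$age_lo[-1] < w$age_hi[-nrow(w)]))
      stop("feedback windows must be ordered and non-overlapping",
           call. = FALSE)
  }
  p <- x$perturbation
  if (p$growth_scale <= 0 || p$cycle_scale <= 0)
    stop("perturbation scales must be strictly positive", call. = FALSE)
  if (p$onset < 0) stop("perturbation onset must be >= 0", call. = FALSE)
  x
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  growth model :", x$growth_model, "(base rate", x$base_rate, ")\n")
  cat("  G1 exit rule :", x$g1_exit_rule, "\n")
  cat("  target size  :", x$target_size, "\n")
  if (nrow(x$feedback_windows)) {
    cat("  feedback     :",
        paste(sprintf("[%g, %g]h beta=%g", x$feedback_windows$age_lo,
                      x$feedback_windows$age_hi, x$feedback_windows$strength),
              collapse = ", "), "\n")
  } else cat("  feedback     : none\n")
  if (is.finite(x$perturbation$onset)) {
    cat("  perturbation : onset", x$perturbation$onset, "h, g =",
        x$perturbation$growth_scale, ", c =", x$perturbation$cycle_scale, "\n")
  }
  cat("  step         :", x$sampling_interval, "h, seed", x$seed, "\n")
  invisible(x)
}

#' Effective rate scalings under an acute perturbation
#'
#' Returns the multiplicative scalings in force at time `now`: growth rates
#' are multiplied by `growth_scale` and cycle-phase mean durations by
#' `1/cycle_scale` once `now >= onset`; before onset both scalings are 1.
#'
#' @param config a [sim_config()].
#' @param now simulation time in hours (>= 0).
#' @return list with `growth_scale` and `duration_scale`.
#' @examples
#' cfg <- sim_config(perturbation = list(onset = 12, growth_scale = 0.4,
#'                                       cycle_scale = 1))
#' apply_perturbation(cfg, 6)$growth_scale   # 1
#' apply_perturbation(cfg, 20)$growth_scale  # 0.4
#' @export
apply_perturbation <- function(config, now) {
  stopifnot(inherits(config, "sim_config"), now >= 0)
  p <- config$perturbation
  if (now >= p$onset) {
    list(growth_scale = p$growth_scale, duration_scale = 1 / p$cycle_scale)
  } else {
    list(growth_scale = 1, duration_scale = 1)
  }
}

# feedback strength at given ages: 0 outside all windows
feedback_strength <- function(age, config) {
  beta <- numeric(length(age))
  w <- config$feedback_windows
  if (nrow(w)) {
    for (i in seq_len(nrow(w))) {
      inside <- age >= w$age_lo[i] & age < w$age_hi[i]
      beta[inside] <- w$strength[i]
    }
  }
  beta
}

# derive an independent substream seed (< 2^31) from a master seed and a label
substream_seed <- function(master, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.double(master) * 48271 + h * 16807) %% 2147483647)
}
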