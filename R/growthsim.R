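# truncated normal draws; draw count depends only on n so RNG use is
# reproducible regardless of truncation bounds
rtnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (n == 0L) return(numeric(0))
  if (all(sd == 0)) {
    runif(n) # keep stream advancement uniform
    return(pmin(pmax(rep_len(mean, n), lo), hi))
  }
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(plo + runif(n) * (phi - plo), mean, sd)
}

# per-cell additive nucleus offset, drawn at birth: zero-mean, sd equal to
# cv times the expected nucleus size of the newborn, truncated so the
# nucleus stays positive
draw_nucleus_offset <- function(birth_size, config) {
  ref <- config$nucleus_scale * birth_size^config$nucleus_exponent
  rtnorm(length(birth_size), 0, config$nucleus_noise_cv * ref,
         lo = -0.8 * ref)
}

# lognormal multiplier with mean 1 and coefficient of variation cv
rlnorm_mean1 <- function(n, cv) {
  if (cv == 0) {
    runif(n)
    return(rep(1, n))
  }
  sdlog <- sqrt(log1p(cv^2))
  qlnorm(runif(n), meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Growth increment over one time step
#'
#' Computes the size gained by one or more cells over `dt` hours. Inside a
#' feedback window the instantaneous rate carries the multiplicative
#' correction `(target_size / size)^strength`; outside all windows the
#' correction is absent. For the `"linear"` and `"poisson"` models the
#' baseline rate is `base_rate` size units per hour; for `"exponential"` it
#' is `base_rate * size`. The `"poisson"` model draws an integer increment
#' from a Poisson distribution with mean `rate * dt` and is the stochastic
#' growth mode; the other two are deterministic given the per-cell rate
#' multiplier.
#'
#' @param size current cell size(s), size units.
#' @param age current cell age(s) in hours (time since last division); used
#'   only to locate the feedback windows.
#' @param dt time step, hours (> 0).
#' @param config a [sim_config()].
#' @param now simulation time, hours; controls the perturbation scaling.
#' @param rate_factor per-cell growth-rate multiplier(s) (default 1).
#' @param noise_factor optional pre-drawn growth-noise multiplier(s); when
#'   `NULL` and `growth_noise_cv > 0` a fresh mean-one gamma multiplier is
#'   drawn per cell for this call (one noise block). The population
#'   simulator passes its block-persistent multipliers here.
#' @return vector of size increments (>= 0 for linear/poisson).
#' @examples
#' cfg <- sim_config(growth_model = "linear", base_rate = 5, rate_cv = 0)
#' growth_increment(100, age = 1, dt = 1, config = cfg)  # 5
#' @export
growth_increment <- function(size, age, dt, config, now = 0, rate_factor = 1,
                             noise_factor = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("`dt` must be a single positive number", call. = FALSE)
  beta <- feedback_strength(age, config)
  corr <- (config$target_size / size)^beta
  g <- apply_perturbation(config, now)$growth_scale
  base <- config$base_rate * g * rate_factor
  mean_ds <- switch(config$growth_model,
    linear = base * corr * dt,
    exponential = base * size * corr * dt,
    poisson = return(rpois(length(size), base * corr * dt)),
    stop("unknown growth model", call. = FALSE)
  )
  if (!is.null(noise_factor)) return(mean_ds * noise_factor)
  cv <- config$growth_noise_cv
  if (cv > 0) {
    mean_ds * rgamma(length(mean_ds), shape = 1 / cv^2, scale = cv^2)
  } else {
    mean_ds
  }
}

# mean-one gamma growth-noise multipliers
draw_growth_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  rgamma(n, shape = 1 / cv^2, scale = cv^2)
}

#' Construct a single-cell state
#'
#' A `cell_state` carries a cell's identity, lineage, birth time and size,
#' current size and phase, and its (pending) G1-exit and division times. It
#' is the unit the scalar operations [advance_phase()], [divide_cell()] and
#' [measure_cell()] act on; [simulate_population()] uses the same rules in
#' vectorised form.
#'
#' @param cell_id,parent_id identifiers (`parent_id` `NA` for founders).
#' @param birth_time hours.
#' @param size current size (> 0), size units.
#' @param phase `"G1"`, `"postG1"` or `"M"`.
#' @param config a [sim_config()]; supplies the drawn per-cell quantities
#'   (timer G1 duration, growth-rate multiplier, nucleus deviation).
#' @param birth_size size at birth (defaults to `size`).
#' @return object of class `cell_state`.
#' @export
cell_state <- function(cell_id, birth_time, size, config,
                       parent_id = NA_integer_, phase = "G1",
                       birth_size = size) {
  stopifnot(size > 0, phase %in% c("G1", "postG1", "M"))
  dscale <- apply_perturbation(config, max(birth_time, 0))$duration_scale
  g1_dur <- if (config$g1_exit_rule == "timer") {
    rtnorm(1L, config$timer_mean * dscale, config$timer_sd,
           lo = config$sampling_interval)
  } else NA_real_
  structure(list(
    cell_id = cell_id, parent_id = parent_id, birth_time = birth_time,
    birth_size = birth_size, size = size, phase = phase,
    g1_exit_time = NA_real_, m_entry_time = NA_real_,
    division_time = NA_real_, g1_dur = g1_dur, postg1_dur = NA_real_,
    m_dur = NA_real_,
    rate_factor = rlnorm_mean1(1L, config$rate_cv),
    nucleus_offset = draw_nucleus_offset(birth_size, config),
    divide_flag = FALSE
  ), class = "cell_state")
}

#' Advance the cell-cycle phase of a single cell
#'
#' Applies the configured G1 exit rule and the downstream phase clocks at
#' sample time `now`. Under the sizer rule G1 ends at the first sample time
#' at which size has reached `sizer_threshold` *and* age has reached
#' `g1_min_duration`; under the timer rule after a drawn duration; under the
#' adder rule once `adder_increment` size units have been added since birth.
#' Post-G1 lasts a drawn duration, then mitosis lasts `mitosis_duration`,
#' after which the cell is flagged for division (`divide_flag`).
#'
#' @param state a [cell_state()].
#' @param now current sample time, hours.
#' @param config a [sim_config()].
#' @return the updated `cell_state`.
#' @export
advance_phase <- function(state, now, config) {
  stopifnot(inherits(state, "cell_state"), now >= state$birth_time)
  dscale <- apply_perturbation(config, now)$duration_scale
  age <- now - state$birth_time
  if (state$phase == "G1") {
    exit <- switch(config$g1_exit_rule,
      sizer = state$size >= config$sizer_threshold &&
        age >= config$g1_min_duration - 1e-9,
      timer = age >= state$g1_dur - 1e-9,
      adder = (state$size - state$birth_size) >= config$adder_increment)
    if (exit) {
      state$phase <- "postG1"
      state$g1_exit_time <- now
      state$postg1_dur <- rtnorm(1L, config$postg1_mean * dscale,
                                 config$postg1_sd,
                                 lo = config$sampling_interval)
    }
  } else if (state$phase == "postG1") {
    if (now - state$g1_exit_time >= state$postg1_dur - 1e-9) {
      state$phase <- "M"
      state$m_entry_time <- now
      state$m_dur <- config$mitosis_duration * dscale
    }
  } else if (state$phase == "M") {
    if (now - state$m_entry_time >= state$m_dur - 1e-9) {
      state$divide_flag <- TRUE
    }
  }
  state
}

#' Divide a mitotic cell into two daughters
#'
#' The division fraction `f` is drawn from a Normal(0.5,
#' `division_fraction_sd`) truncated to (0.2, 0.8); daughters receive
#' `f * S` and `(1 - f) * S`, so their sizes sum to the mother size exactly.
#' Both daughters start in G1 at age 0.
#'
#' @param state a [cell_state()] in mitosis with `divide_flag` set.
#' @param config a [sim_config()].
#' @param now division time, hours (defaults to the mother's flag time).
#' @param ids integer ids for the daughters.
#' @return list of two `cell_state` daughters.
#' @export
divide_cell <- function(state, config, now = state$m_entry_time + state$m_dur,
                        ids = state$cell_id * 2L + c(0L, 1L)) {
  if (!inherits(state, "cell_state") || state$phase != "M" ||
      !isTRUE(state$divide_flag))
    stop("cannot divide a cell that is not flagged in mitosis", call. = FALSE)
  f <- rtnorm(1L, 0.5, config$division_fraction_sd, lo = 0.2, hi = 0.8)
  s1 <- f * state$size
  d1 <- cell_state(ids[1], now, s1, config, parent_id = state$cell_id)
  d2 <- cell_state(ids[2], now, state$size - s1, config,
                   parent_id = state$cell_id)
  list(d1, d2)
}

#' Measure a cell's size and nucleus size
#'
#' Observed size is the true size with multiplicative zero-mean noise of CV
#' `size_noise_cv` (the stain-intensity measurement). The observed nucleus
#' size is `nucleus_scale * size^nucleus_exponent` plus the cell's
#' persistent additive offset (drawn at birth, see [sim_config()]), times a
#' small per-observation jitter (CV `track_jitter_cv`). With all noise CVs
#' zero the measurement is the identity.
#'
#' @param state a [cell_state()].
#' @param config a [sim_config()].
#' @return list with `observed_size` and `observed_nucleus`.
#' @export
measure_cell <- function(state, config) {
  stopifnot(inherits(state, "cell_state"))
  eps1 <- rtnorm(1L, 0, config$size_noise_cv, lo = -0.9)
  jit <- rtnorm(1L, 0, config$track_jitter_cv, lo = -0.9)
  list(
    observed_size = state$size * (1 + eps1),
    observed_nucleus = (config$nucleus_scale *
                          state$size^config$nucleus_exponent +
                          state$nucleus_offset) * (1 + jit)
  )
}

# evaluate RNG-consuming expr under a named substream, preserving the
# surrounding stream; `state` is NULL on first use
with_stream <- function(state, seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  if (is.null(state)) set.seed(seed) else assign(".Random.seed", state,
                                                 envir = globalenv())
  value <- force(expr)
  new_state <- get(".Random.seed", envir = globalenv())
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  list(value = value, state = new_state)
}

#' Simulate a proliferating population
#'
#' Runs the discrete-time growth-and-division model for `duration` hours at
#' steps of `sampling_interval`, starting from `n_founders` founder cells,
#' and returns the three measurement modalities derived from one lineage
#' history: an end-point fixed **snapshot** (per-cell age, observed size,
#' observed nucleus size, phase), time-lapse **tracks** (per-cell nucleus
#' size series plus a per-cell event table with birth, G1-exit, mitosis-entry
#' and division times) and a **bulk** series (cell count and mean size per
#' sample time). Identical `(config, duration, n_founders)` give identical
#' output; measurement draws use a separate random substream so recording
#' observers does not perturb the dynamics.
#'
#' @param config a [sim_config()].
#' @param duration hours (>= 0); should be a multiple of the sampling
#'   interval.
#' @param n_founders number of founder cells (>= 1).
#' @param record character subset of `c("snapshot", "tracks", "bulk")`.
#' @param condition label stored in the bulk series.
#' @return object of class `sim_result`: list with elements `snapshot`
#'   (data frame: `cell_id`, `age_h`, `size_au`, `nucleus_au`, `phase`),
#'   `tracks` (list of `samples` and `events` data frames), `bulk`
#'   (data frame: `condition`, `t_h`, `n_cells`, `mean_size_au`), and the
#'   realized mean cycle length of completed cycles (`mean_cycle_h`).
#' @examples
#' cfg <- sim_config(seed = 7, founder_init = "steady")
#' res <- simulate_population(cfg, duration = 12, n_founders = 50)
#' head(res$snapshot)
#' @export
simulate_population <- function(config, duration, n_founders,
                                record = c("snapshot", "tracks", "bulk"),
                                condition = "sim") {
  validate_sim_config(config)
  stopifnot(duration >= 0, n_founders >= 1)
  record <- match.arg(record, several.ok = TRUE)
  dt <- config$sampling_interval
  n_steps <- as.integer(floor(duration / dt + 1e-9))
  set.seed(substream_seed(config$seed, "simulate"))
  meas_state <- NULL
  meas_seed <- substream_seed(config$seed, "measure")

  n0 <- as.integer(n_founders)
  # per-cell state vectors (grown as daughters are born)
  birth_size <- rlnorm_mean1(n0, config$founder_size_cv) *
    config$founder_size_mean
  rate_f <- rlnorm_mean1(n0, config$rate_cv)
  nuc_off <- draw_nucleus_offset(birth_size, config)
  id <- seq_len(n0)
  parent <- rep(NA_integer_, n0)
  phase <- rep(1L, n0) # 1 G1, 2 postG1, 3 M
  g1_exit <- m_entry <- division <- rep(NA_real_, n0)
  g1_dur <- postg1_dur <- m_dur <- rep(NA_real_, n0)
  birth_time <- rep(0, n0)
  size <- birth_size
  alive <- rep(TRUE, n0)

  draw_g1_dur <- function(n, at) {
    ds <- apply_perturbation(config, max(at, 0))$duration_scale
    rtnorm(n, config$timer_mean * ds, config$timer_sd, lo = dt)
  }
  if (config$g1_exit_rule == "timer") g1_dur <- draw_g1_dur(n0, 0)

  if (config$founder_init == "steady") {
    # approximate stationary age structure: ages from 2*alpha*exp(-alpha*a),
    # sizes grown deterministically from birth, phases assigned from the
    # per-cell expected phase boundaries; a short burn-in completes the job
    g1_est <- switch(config$g1_exit_rule,
      sizer = pmax(config$g1_min_duration,
                   switch(config$growth_model,
                     exponential = log(pmax(config$sizer_threshold /
                                              birth_size, 1.0001)) /
                       (config$base_rate * rate_f),
                     pmax(config$sizer_threshold - birth_size, 0.01) /
                       (config$base_rate * rate_f))),
      timer = g1_dur,
      adder = config$adder_increment /
        (config$base_rate * rate_f *
           (if (config$growth_model == "exponential") birth_size else 1)))
    tau_bar <- mean(g1_est) + config$postg1_mean + config$mitosis_duration
    alpha <- log(2) / tau_bar
    ages <- -log(1 - runif(n0) / 2) / alpha
    post_dur0 <- rtnorm(n0, config$postg1_mean, config$postg1_sd, lo = dt)
    total <- g1_est + post_dur0 + config$mitosis_duration
    ages <- pmin(ages, total - dt / 2)
    birth_time <- -ages
    size <- if (config$growth_model == "exponential") {
      birth_size * exp(config$base_rate * rate_f * ages)
    } else {
      birth_size + config$base_rate * rate_f * ages
    }
    in_post <- ages >= g1_est & ages < g1_est + post_dur0
    in_m <- ages >= g1_est + post_dur0
    phase[in_post] <- 2L
    phase[in_m] <- 3L
    g1_exit[in_post | in_m] <- (birth_time + g1_est)[in_post | in_m]
    postg1_dur[in_post | in_m] <- post_dur0[in_post | in_m]
    m_entry[in_m] <- (birth_time + g1_est + post_dur0)[in_m]
    m_dur[in_m] <- config$mitosis_duration
  }

  noise_f <- draw_growth_noise(length(id), config$growth_noise_cv)
  last_block <- 0L
  want_tracks <- "tracks" %in% record
  want_bulk <- "bulk" %in% record
  trk_t <- trk_id <- trk_nuc <- vector("list", n_steps + 1L)
  bulk_t <- bulk_n <- bulk_s <- numeric(n_steps + 1L)

  record_at <- function(t, step_idx) {
    ia <- which(alive)
    if (want_bulk) {
      bulk_t[step_idx] <<- t
      bulk_n[step_idx] <<- length(ia)
      bulk_s[step_idx] <<- mean(size[ia])
    }
    if (want_tracks) {
      r <- with_stream(meas_state, meas_seed, {
        jit <- rtnorm(length(ia), 0, config$track_jitter_cv, lo = -0.9)
        (config$nucleus_scale * size[ia]^config$nucleus_exponent +
           nuc_off[ia]) * (1 + jit)
      })
      meas_state <<- r$state
      trk_t[[step_idx]] <<- rep(t, length(ia))
      trk_id[[step_idx]] <<- id[ia]
      trk_nuc[[step_idx]] <<- r$value
    }
  }

  for (s in seq_len(n_steps + 1L)) {
    t_prev <- (s - 1L) * dt
    record_at(t_prev, s)
    if (s > n_steps) break
    t_new <- s * dt
    ia <- which(alive)
    blk <- as.integer(floor(t_prev / config$growth_noise_block + 1e-9))
    if (blk != last_block) {
      noise_f <- draw_growth_noise(length(id), config$growth_noise_cv)
      last_block <- blk
    }
    age_prev <- t_prev - birth_time[ia]
    size[ia] <- size[ia] + growth_increment(size[ia], age_prev, dt, config,
                                            now = t_prev,
                                            rate_factor = rate_f[ia],
                                            noise_factor = noise_f[ia])
    dscale <- apply_perturbation(config, t_new)$duration_scale
    # G1 exits
    ig1 <- ia[phase[ia] == 1L]
    if (length(ig1)) {
      age_new <- t_new - birth_time[ig1]
      exit <- switch(config$g1_exit_rule,
        sizer = size[ig1] >= config$sizer_threshold &
          age_new >= config$g1_min_duration - 1e-9,
        timer = age_new >= g1_dur[ig1] - 1e-9,
        adder = (size[ig1] - birth_size[ig1]) >= config$adder_increment)
      ex <- ig1[exit]
      if (length(ex)) {
        phase[ex] <- 2L
        g1_exit[ex] <- t_new
        postg1_dur[ex] <- rtnorm(length(ex), config$postg1_mean * dscale,
                                 config$postg1_sd, lo = dt)
      }
    }
    # postG1 -> M
    ip <- ia[phase[ia] == 2L]
    if (length(ip)) {
      toM <- ip[t_new - g1_exit[ip] >= postg1_dur[ip] - 1e-9]
      if (length(toM)) {
        phase[toM] <- 3L
        m_entry[toM] <- t_new
        m_dur[toM] <- config$mitosis_duration * dscale
      }
    }
    # divisions
    im <- ia[phase[ia] == 3L]
    if (length(im)) {
      dv <- im[t_new - m_entry[im] >= m_dur[im] - 1e-9]
      nd <- length(dv)
      if (nd) {
        division[dv] <- t_new
        alive[dv] <- FALSE
        f <- rtnorm(nd, 0.5, config$division_fraction_sd, lo = 0.2, hi = 0.8)
        s1 <- f * size[dv]
        s2 <- size[dv] - s1
        nmax <- length(id)
        new_id <- nmax + seq_len(2L * nd)
        nb_size <- c(s1, s2)
        id <- c(id, new_id)
        parent <- c(parent, rep(id[dv], 2L))
        birth_time <- c(birth_time, rep(t_new, 2L * nd))
        birth_size <- c(birth_size, nb_size)
        size <- c(size, nb_size)
        phase <- c(phase, rep(1L, 2L * nd))
        g1_exit <- c(g1_exit, rep(NA_real_, 2L * nd))
        m_entry <- c(m_entry, rep(NA_real_, 2L * nd))
        division <- c(division, rep(NA_real_, 2L * nd))
        postg1_dur <- c(postg1_dur, rep(NA_real_, 2L * nd))
        m_dur <- c(m_dur, rep(NA_real_, 2L * nd))
        g1_dur <- c(g1_dur, if (config$g1_exit_rule == "timer")
          draw_g1_dur(2L * nd, t_new) else rep(NA_real_, 2L * nd))
        rate_f <- c(rate_f, rlnorm_mean1(2L * nd, config$rate_cv))
        noise_f <- c(noise_f, draw_growth_noise(2L * nd,
                                                config$growth_noise_cv))
        nuc_off <- c(nuc_off, draw_nucleus_offset(nb_size, config))
        alive <- c(alive, rep(TRUE, 2L * nd))
      }
    }
  }

  out <- list(config = config, duration = duration, n_founders = n0)
  if ("snapshot" %in% record) {
    ia <- which(alive)
    r <- with_stream(meas_state, meas_seed, {
      eps1 <- rtnorm(length(ia), 0, config$size_noise_cv, lo = -0.9)
      jit <- rtnorm(length(ia), 0, config$track_jitter_cv, lo = -0.9)
      list(size = size[ia] * (1 + eps1),
           nuc = (config$nucleus_scale * size[ia]^config$nucleus_exponent +
                    nuc_off[ia]) * (1 + jit))
    })
    meas_state <- r$state
    out$snapshot <- data.frame(
      cell_id = id[ia],
      age_h = duration - birth_time[ia],
      size_au = r$value$size,
      nucleus_au = r$value$nuc,
      phase = c("G1", "postG1", "M")[phase[ia]]
    )
  }
  if (want_tracks) {
    out$tracks <- list(
      samples = data.frame(cell_id = unlist(trk_id), t_h = unlist(trk_t),
                           nucleus_au = unlist(trk_nuc)),
      events = data.frame(cell_id = id, parent_id = parent,
                          birth_time = birth_time, g1_exit_time = g1_exit,
                          m_entry_time = m_entry, division_time = division)
    )
  }
  if (want_bulk) {
    out$bulk <- bulk_series(condition, bulk_t, bulk_n, bulk_s)
  }
  cyc <- division - birth_time
  out$mean_cycle_h <- if (any(!is.na(cyc))) mean(cyc, na.rm = TRUE) else NA_real_
  class(out) <- "sim_result"
  out
}

#' @export
print.sim_result <- function(x, ...) {
  cat("<sim_result>", x$n_founders, "founders,", x$duration, "h\n")
  if (!is.null(x$snapshot))
    cat("  snapshot:", nrow(x$snapshot), "cells\n")
  if (!is.null(x$tracks))
    cat("  tracks  :", nrow(x$tracks$events), "cells,",
        nrow(x$tracks$samples), "samples\n")
  if (!is.null(x$bulk))
    cat("  bulk    :", nrow(x$bulk), "time points\n")
  if (!is.na(x$mean_cycle_h))
    cat("  realized mean cycle:", round(x$mean_cycle_h, 2), "h\n")
  invisible(x)
}

#' Assemble a bulk time series
#'
#' @param condition condition label.
#' @param t_h sample times, hours (increasing).
#' @param n_cells cell counts (>= 1).
#' @param mean_size_au mean cell size per time point.
#' @return data frame of class `bulk_series` with the derived bulk mass
#'   `mass_au = n_cells * mean_size_au`.
#' @export
bulk_series <- function(condition, t_h, n_cells, mean_size_au) {
  stopifnot(length(t_h) == length(n_cells),
            length(t_h) == length(mean_size_au),
            !is.unsorted(t_h), all(n_cells >= 1))
  structure(data.frame(condition = condition, t_h = t_h, n_cells = n_cells,
                       mean_size_au = mean_size_au,
                       mass_au = n_cells * mean_size_au),
            class = c("bulk_series", "data.frame"))
}
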