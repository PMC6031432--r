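#' Cell-cycle length from a proliferation curve
#'
#' Fits `N_t = N_0 * exp(alpha * t)` by least squares on the log scale and
#' reports the population growth exponent `alpha` and the cell-cycle length
#' `tau = ln(2) / alpha`. A non-positive slope (non-proliferating or
#' arrested condition) yields `tau = Inf` with a flag rather than an error,
#' so such conditions survive panel assembly.
#'
#' @param times sample times, hours (>= 3 points).
#' @param counts cell counts (>= 1).
#' @return object of class `cycle_fit`: list with `alpha` (per hour), `tau_h`,
#'   `r_squared`, `n`, `arrested` flag and the fitted `lm` object.
#' @examples
#' fit_cycle_length(c(0, 20, 40), c(100, 200, 400))$tau_h # 20
#' @export
fit_cycle_length <- function(times, counts) {
  stopifnot(length(times) == length(counts))
  if (length(times) < 3L) stop("need at least 3 time points", call. = FALSE)
  if (any(counts < 1)) stop("cell counts must be >= 1", call. = FALSE)
  fit <- lm(log(counts) ~ times)
  alpha <- unname(coef(fit)[2L])
  arrested <- alpha <= 0
  tss <- sum((log(counts) - mean(log(counts)))^2)
  r2 <- if (tss > 0) 1 - sum(resid(fit)^2) / tss else NA_real_
  structure(list(
    alpha = alpha,
    tau_h = if (arrested) Inf else log(2) / alpha,
    r_squared = r2,
    n = length(times), arrested = arrested, fit = fit
  ), class = "cycle_fit")
}

#' @export
print.cycle_fit <- function(x, ...) {
  cat("<cycle_fit> alpha =", signif(x$alpha, 4), "per h, tau =",
      if (is.finite(x$tau_h)) paste(signif(x$tau_h, 4), "h") else
        "Inf (arrested)",
      ", R2 =", signif(x$r_squared, 3), "\n")
  invisible(x)
}

#' Average per-cell growth rate from bulk mass accumulation
#'
#' Estimates the mean single-cell growth rate `v = (1/N_t) dM_t/dt`, where
#' the bulk mass is `M_t = N_t * mean_size_t`. The default estimator fits
#' `ln M` linearly in time within the window (robust to count noise) and
#' evaluates `v` at the window midpoint `t*` as `alpha_M * M(t*) / N(t*)`,
#' with `M` from the fit and `N` interpolated on the log scale. A
#' finite-difference mode averages pointwise `dM/dt / N` instead.
#'
#' @param series a [bulk_series()] (or data frame with `t_h`, `n_cells`,
#'   `mean_size_au`).
#' @param window numeric length-2 `(t_lo, t_hi)` in hours; default spans the
#'   series.
#' @param method `"exponential"` (default) or `"finite_difference"`.
#' @return object of class `bulk_growth_rate`: list with `v` (size units per
#'   hour), `t_star`, `alpha_m`, `n`, `method`.
#' @export
growth_rate_bulk <- function(series, window = NULL,
                             method = c("exponential", "finite_difference")) {
  method <- match.arg(method)
  stopifnot(all(c("t_h", "n_cells", "mean_size_au") %in% names(series)))
  if (is.null(window)) window <- range(series$t_h)
  sel <- series$t_h >= window[1] - 1e-9 & series$t_h <= window[2] + 1e-9
  s <- series[sel, , drop = FALSE]
  if (nrow(s) < 3L) stop("need at least 3 points in the window",
                         call. = FALSE)
  m <- s$n_cells * s$mean_size_au
  if (any(m <= 0)) stop("non-positive bulk mass", call. = FALSE)
  t_star <- mean(range(s$t_h))
  if (method == "exponential") {
    fit <- lm(log(m) ~ t_h, data = s)
    alpha_m <- unname(coef(fit)[2L])
    m_star <- exp(unname(predict(fit, data.frame(t_h = t_star))))
    n_star <- exp(approx(s$t_h, log(s$n_cells), xout = t_star)$y)
    v <- alpha_m * m_star / n_star
  } else {
    dm <- diff(m) / diff(s$t_h)
    n_mid <- (head(s$n_cells, -1) + tail(s$n_cells, -1)) / 2
    v <- mean(dm / n_mid)
    alpha_m <- NA_real_
  }
  structure(list(v = v, t_star = t_star, alpha_m = alpha_m, n = nrow(s),
                 method = method),
            class = "bulk_growth_rate")
}

#' Segment a drug time course into early and late stages
#'
#' Finds the time at which the mean cell size stabilizes after a
#' perturbation: a grid search over candidate break points fits the mean
#' size linearly in time before the break and as a constant after it, and
#' picks the break minimizing the total squared error. When the search is
#' degenerate (the series is flat, so no transient exists) the break falls
#' back to `fallback` hours and is flagged.
#'
#' @param series a bulk series with `t_h` and `mean_size_au` (>= 6 size
#'   points).
#' @param fallback break used for degenerate series, hours (default 24).
#' @param min_points minimum points on each side of a candidate break.
#' @return list with `stage_break` (hours), `degenerate` flag and the
#'   search table `sse` (`break_h`, `sse`).
#' @export
segment_stages <- function(series, fallback = 24, min_points = 3L) {
  stopifnot(all(c("t_h", "mean_size_au") %in% names(series)))
  t <- series$t_h
  y <- series$mean_size_au
  if (length(t) < 6L) stop("need at least 6 size time points", call. = FALSE)
  cand <- t[seq.int(min_points, length(t) - min_points)]
  sse <- vapply(cand, function(b) {
    e <- t <= b + 1e-9
    fit <- lm(y[e] ~ t[e])
    sum(resid(fit)^2) + sum((y[!e] - mean(y[!e]))^2)
  }, numeric(1))
  null_sse <- sum((y - mean(y))^2)
  best <- which.min(sse)
  degenerate <- null_sse < 1e-12 ||
    (null_sse - min(sse)) / max(null_sse, 1e-300) < 1e-6
  list(stage_break = if (degenerate) fallback else cand[best],
       degenerate = degenerate,
       sse = data.frame(break_h = cand, sse = sse))
}

#' Early/late kinetics of one condition
#'
#' Splits a bulk time course at `stage_break` and estimates the cell-cycle
#' length ([fit_cycle_length()]) and mean growth rate ([growth_rate_bulk()])
#' independently in each stage, together with the late-stage stabilized mean
#' size and the target size `C_TS = v * tau` per stage. `alpha * tau =
#' ln(2)` holds exactly by construction.
#'
#' @param series a [bulk_series()] for one condition.
#' @param stage_break break between early and late stages, hours; `NULL`
#'   runs [segment_stages()].
#' @param condition label; defaults to the series' condition.
#' @return object of class `compensation_estimate`: list with `tau_early_h`,
#'   `tau_late_h`, `v_early`, `v_late`, `alpha_early`, `alpha_late`,
#'   `c_ts_early`, `c_ts_late`, `mean_size_late`, `stage_break_h`.
#' @export
stagewise_estimates <- function(series, stage_break = NULL,
                                condition = NULL) {
  stopifnot(all(c("t_h", "n_cells", "mean_size_au") %in% names(series)))
  if (is.null(condition))
    condition <- if ("condition" %in% names(series))
      as.character(series$condition[1]) else "condition"
  if (is.null(stage_break)) stage_break <- segment_stages(series)$stage_break
  early <- series[series$t_h <= stage_break + 1e-9, , drop = FALSE]
  late <- series[series$t_h >= stage_break - 1e-9, , drop = FALSE]
  if (nrow(early) < 3L || nrow(late) < 3L)
    stop("each stage needs at least 3 points", call. = FALSE)
  fe <- fit_cycle_length(early$t_h, early$n_cells)
  fl <- fit_cycle_length(late$t_h, late$n_cells)
  ve <- growth_rate_bulk(early)$v
  vl <- growth_rate_bulk(late)$v
  structure(list(
    condition = condition,
    tau_early_h = fe$tau_h, tau_late_h = fl$tau_h,
    alpha_early = fe$alpha, alpha_late = fl$alpha,
    v_early = ve, v_late = vl,
    c_ts_early = ve * fe$tau_h, c_ts_late = vl * fl$tau_h,
    mean_size_late = mean(late$mean_size_au),
    stage_break_h = stage_break
  ), class = "compensation_estimate")
}

#' @export
print.compensation_estimate <- function(x, ...) {
  cat("<compensation_estimate>", x$condition, "(break at",
      x$stage_break_h, "h)\n")
  cat(sprintf("  early: tau = %.2f h, v = %.3f, v*tau = %.1f\n",
              x$tau_early_h, x$v_early, x$c_ts_early))
  cat(sprintf("  late : tau = %.2f h, v = %.3f, v*tau = %.1f\n",
              x$tau_late_h, x$v_late, x$c_ts_late))
  invisible(x)
}

#' Target-size panel across conditions
#'
#' Normalizes per-condition growth rates `v` and cell-cycle lengths `tau` to
#' the control, computes the target size `C_TS = v * tau` and its fold
#' change, flags conditions whose fold change leaves a tolerance band, and
#' reports the Pearson correlation between `log(v)` and `log(tau)` over a
#' caller-selected subset of conditions (the compensation correlation; a
#' value near -1 means conditions slide along an iso-size contour
#' `v = C / tau`).
#'
#' @param estimates data frame with columns `condition`, `tau_h`, `v` (one
#'   row per condition or replicate), or a list of `compensation_estimate`
#'   objects (their late-stage values are used).
#' @param control control condition label; multiple control rows are
#'   averaged before normalization.
#' @param subset conditions entering the log-log correlation (default: all
#'   non-control conditions).
#' @param band flag threshold on `|C_TS fold change - 1|` (default 0.25).
#' @return object of class `condition_panel`: list with the per-condition
#'   `table` (fold changes, flags), `loglog_r`, `loglog_p`, `control`.
#' @export
target_size_panel <- function(estimates, control, subset = NULL,
                              band = 0.25) {
  if (is.list(estimates) && !is.data.frame(estimates) &&
      all(vapply(estimates, inherits, logical(1), "compensation_estimate"))) {
    estimates <- do.call(rbind, lapply(estimates, function(e)
      data.frame(condition = e$condition, tau_h = e$tau_late_h,
                 v = e$v_late)))
  }
  stopifnot(is.data.frame(estimates),
            all(c("condition", "tau_h", "v") %in% names(estimates)))
  if (!control %in% estimates$condition)
    stop("control condition `", control, "` not present", call. = FALSE)
  if (any(estimates$v <= 0) || any(estimates$tau_h <= 0))
    stop("growth rates and cycle lengths must be positive", call. = FALSE)
  agg <- aggregate(cbind(tau_h, v) ~ condition, data = estimates, FUN = mean)
  ctl <- agg[agg$condition == control, ]
  tab <- data.frame(
    condition = agg$condition,
    tau_fold = agg$tau_h / ctl$tau_h,
    v_fold = agg$v / ctl$v)
  tab$c_ts = agg$v * agg$tau_h
  tab$c_ts_fold <- tab$v_fold * tab$tau_fold
  tab$size_flag <- abs(tab$c_ts_fold - 1) > band
  tab <- tab[order(tab$condition != control, tab$condition), , drop = FALSE]
  rownames(tab) <- NULL
  if (is.null(subset)) subset <- setdiff(agg$condition, control)
  sub <- agg[agg$condition %in% subset, , drop = FALSE]
  loglog_r <- loglog_p <- NA_real_
  if (nrow(sub) >= 3L && sd(log(sub$v)) > 0 && sd(log(sub$tau_h)) > 0) {
    ct <- cor.test(log(sub$v), log(sub$tau_h))
    loglog_r <- unname(ct$estimate)
    loglog_p <- ct$p.value
  }
  structure(list(table = tab, loglog_r = loglog_r, loglog_p = loglog_p,
                 control = control, band = band, subset = subset),
            class = "condition_panel")
}

#' @export
print.condition_panel <- function(x, ...) {
  cat("<condition_panel> control =", x$control, "\n")
  print(x$table, digits = 3)
  if (is.finite(x$loglog_r))
    cat("  log(v) vs log(tau): r =", signif(x$loglog_r, 3), ", p =",
        format.pval(x$loglog_p), "over", length(x$subset), "conditions\n")
  else cat("  log-log correlation undefined for this panel\n")
  invisible(x)
}
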