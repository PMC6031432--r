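# local-linear Gaussian-kernel regression of y on x evaluated at grid points;
# returns the fitted value and an effective count (kernel mass / K(0))
ll_fit <- function(x, y, grid, bandwidth) {
  D <- outer(grid, x, "-") # grid - x
  W <- dnorm(D / bandwidth)
  S0 <- rowSums(W)
  if (any(S0 < length(x) * 1e-12))
    stop("bandwidth too small: a grid point has zero kernel mass",
         call. = FALSE)
  S1 <- rowSums(W * D)
  S2 <- rowSums(W * D^2)
  T0 <- W %*% y
  T1 <- (W * D) %*% y
  den <- S0 * S2 - S1^2
  est <- ifelse(abs(den) > 1e-300, (S2 * T0 - S1 * T1) / den, T0 / S0)
  list(estimate = as.numeric(est), n_eff = S0 / dnorm(0))
}

silverman_bw <- function(x) {
  0.9 * min(sd(x), IQR(x) / 1.34) * length(x)^(-1 / 5)
}

# default grid avoids the post-mitotic first 1.25 h (cells re-spread after
# division, and the boundary bias of the local-linear fit is largest there)
# and the sparse, division-depleted oldest ages (upper decile), where lagged
# differences of the curves are dominated by censoring and edge effects
default_age_grid <- function(age, step = 0.5) {
  lo <- max(ceiling(1.25 / step) * step,
            ceiling(quantile(age, 0.005) / step) * step)
  hi <- floor(quantile(age, 0.90) / step) * step
  seq(lo, hi, by = step)
}

# mean curve and (optionally) variance curve on one grid, with a joint
# cell-level bootstrap so downstream differencing (Gcv) can pair replicates;
# residuals for the variance stage are taken around the mean fit evaluated
# over the full age range of the data (not just the reporting grid), so
# cells outside the grid do not leak spurious residual variance inward
age_curve_engine <- function(age, size, grid, bandwidth, n_boot, want_var,
                             var_bandwidth = bandwidth) {
  step <- if (length(grid) > 1L) min(diff(grid)) else bandwidth
  egrid <- sort(unique(c(grid, seq(min(age), max(age), by = step),
                         max(age))))
  keep <- match(grid, egrid)
  fit_once <- function(a, s) {
    m <- ll_fit(a, s, egrid, bandwidth)
    out <- list(mean = m$estimate[keep], n_eff = m$n_eff[keep])
    if (want_var) {
      mhat <- approx(egrid, m$estimate, xout = a, rule = 2)$y
      r2 <- (s - mhat)^2
      out$var <- ll_fit(a, r2, grid, var_bandwidth)$estimate
    }
    out
  }
  point <- fit_once(age, size)
  boot_mean <- boot_var <- NULL
  if (n_boot > 0) {
    n <- length(age)
    boot_mean <- matrix(NA_real_, length(grid), n_boot)
    if (want_var) boot_var <- matrix(NA_real_, length(grid), n_boot)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      fb <- fit_once(age[idx], size[idx])
      boot_mean[, b] <- fb$mean
      if (want_var) boot_var[, b] <- fb$var
    }
  }
  list(point = point, boot_mean = boot_mean, boot_var = boot_var)
}

make_age_curve <- function(grid, est, boot, ci_level, n_eff, kind,
                           boot_id, clip_zero = FALSE) {
  clipped <- FALSE
  if (clip_zero && any(est < 0)) {
    clipped <- TRUE
    est <- pmax(est, 0)
  }
  ci_lo <- ci_hi <- rep(NA_real_, length(grid))
  if (!is.null(boot)) {
    if (clip_zero) boot <- pmax(boot, 0)
    qs <- apply(boot, 1L, quantile,
                probs = c((1 - ci_level) / 2, 1 - (1 - ci_level) / 2),
                names = FALSE)
    ci_lo <- pmin(qs[1L, ], est)
    ci_hi <- pmax(qs[2L, ], est)
  }
  structure(
    data.frame(age_h = grid, estimate = est, ci_lo = ci_lo, ci_hi = ci_hi,
               n_eff = n_eff),
    kind = kind, ci_level = ci_level, boot = boot, boot_id = boot_id,
    clipped = clipped,
    class = c("age_curve", "data.frame"))
}

check_snapshot <- function(snapshot, min_n = 50L) {
  stopifnot(is.data.frame(snapshot),
            all(c("age_h", "size_au") %in% names(snapshot)))
  if (nrow(snapshot) == 0L) stop("empty snapshot", call. = FALSE)
  if (nrow(snapshot) < min_n)
    stop("snapshot needs at least ", min_n, " cells", call. = FALSE)
  invisible(snapshot)
}

#' Age-resolved mean and variance of cell size from a snapshot
#'
#' `size_age_curves()` estimates the mean size and the size variance as
#' smooth functions of cell age from a fixed-population snapshot, by
#' local-linear Gaussian-kernel regression. The variance function is the
#' two-stage estimator: squared residuals around the fitted mean curve are
#' themselves regressed on age; negative point estimates are clipped to zero
#' with a warning. Confidence bands come from a cell-level bootstrap
#' (resampling rows with replacement, percentile method); the two curves
#' share bootstrap resamples so that [gcv_vs_age()] can difference them
#' jointly. `mean_size_vs_age()` and `var_size_vs_age()` are single-curve
#' conveniences.
#'
#' @param snapshot data frame with columns `age_h` and `size_au` (>= 50
#'   rows).
#' @param bandwidth kernel bandwidth in hours; `NULL` uses Silverman's rule
#'   on the age distribution.
#' @param n_boot bootstrap replicates (0 disables the bands).
#' @param ci_mean,ci_var,ci_level nominal coverage of the percentile bands
#'   (defaults 0.90 for the mean and 0.70 for the variance curve).
#' @param grid evaluation grid in hours (uniform spacing); default spans the
#'   central 99% of ages at 0.5 h spacing.
#' @param seed integer seed for the bootstrap resamples.
#' @param min_cells minimum snapshot size accepted (default 50; lower it
#'   only for constructed toy inputs).
#' @param var_bandwidth bandwidth for the variance stage (defaults to
#'   `1.25 * bandwidth`, since squared residuals are noisier than the sizes
#'   themselves); widen it to smooth harder at the cost of blurring
#'   short-lived variance dips.
#' @return `size_age_curves()`: list with `mean` and `var`, each an
#'   `age_curve` data frame (`age_h`, `estimate`, `ci_lo`, `ci_hi`,
#'   `n_eff`). The single-curve functions return one `age_curve`.
#' @examples
#' snap <- data.frame(age_h = runif(200, 0, 20),
#'                    size_au = 100 + 5 * runif(200, 0, 20))
#' mc <- mean_size_vs_age(snap, bandwidth = 1, n_boot = 20)
#' head(mc)
#' @export
size_age_curves <- function(snapshot, bandwidth = 1, n_boot = 200,
                            ci_mean = 0.90, ci_var = 0.70, grid = NULL,
                            seed = NULL, min_cells = 50L,
                            var_bandwidth = NULL) {
  check_snapshot(snapshot, min_n = min_cells)
  age <- snapshot$age_h
  size <- snapshot$size_au
  if (is.null(bandwidth)) bandwidth <- silverman_bw(age)
  if (is.null(var_bandwidth)) var_bandwidth <- 1.25 * bandwidth
  stopifnot(bandwidth > 0, var_bandwidth > 0)
  if (is.null(grid)) grid <- default_age_grid(age)
  if (!is.null(seed)) set.seed(seed)
  eng <- age_curve_engine(age, size, grid, bandwidth, n_boot,
                          want_var = TRUE, var_bandwidth = var_bandwidth)
  boot_id <- paste0("b", sample.int(.Machine$integer.max, 1L))
  mc <- make_age_curve(grid, eng$point$mean, eng$boot_mean, ci_mean,
                       eng$point$n_eff, "mean", boot_id)
  vc <- make_age_curve(grid, eng$point$var, eng$boot_var, ci_var,
                       eng$point$n_eff, "variance", boot_id,
                       clip_zero = TRUE)
  if (attr(vc, "clipped"))
    warning("negative variance point estimates clipped to 0", call. = FALSE)
  list(mean = mc, var = vc)
}

#' @rdname size_age_curves
#' @export
mean_size_vs_age <- function(snapshot, bandwidth = 1, n_boot = 200,
                             ci_level = 0.90, grid = NULL, seed = NULL,
                             min_cells = 50L) {
  check_snapshot(snapshot, min_n = min_cells)
  age <- snapshot$age_h
  size <- snapshot$size_au
  if (is.null(bandwidth)) bandwidth <- silverman_bw(age)
  stopifnot(bandwidth > 0)
  if (is.null(grid)) grid <- default_age_grid(age)
  if (!is.null(seed)) set.seed(seed)
  eng <- age_curve_engine(age, size, grid, bandwidth, n_boot,
                          want_var = FALSE)
  make_age_curve(grid, eng$point$mean, eng$boot_mean, ci_level,
                 eng$point$n_eff, "mean",
                 paste0("b", sample.int(.Machine$integer.max, 1L)))
}

#' @rdname size_age_curves
#' @export
var_size_vs_age <- function(snapshot, bandwidth = 1, n_boot = 200,
                            ci_level = 0.70, grid = NULL, seed = NULL,
                            min_cells = 50L, var_bandwidth = NULL) {
  curves <- size_age_curves(snapshot, bandwidth, n_boot, ci_var = ci_level,
                            grid = grid, seed = seed, min_cells = min_cells,
                            var_bandwidth = var_bandwidth)
  curves$var
}

#' Variance decomposition of paired sizes
#'
#' For paired per-cell sizes before (`s1`) and after (`s2 = s1 + ds`) a
#' growth interval, the change in variance decomposes algebraically as
#' `Var(S2) - Var(S1) = Var(dS) + 2 Cov(S1, dS)`. The decomposition holds
#' for any data; a negative variance change therefore implies a negative
#' size-growth covariance. Population (divide-by-n) variance conventions
#' are used throughout.
#'
#' @param s1,s2 numeric vectors of equal length: sizes at the start and end
#'   of the interval, paired by cell.
#' @return list with `var_s1`, `var_s2`, `delta_var`, `var_ds`, `cov_s1_ds`
#'   and `residual` (`delta_var - var_ds - 2 * cov_s1_ds`, zero to floating
#'   tolerance).
#' @export
variance_decomposition <- function(s1, s2) {
  stopifnot(length(s1) == length(s2), length(s1) >= 2)
  n <- length(s1)
  pvar <- function(x) mean((x - mean(x))^2)
  ds <- s2 - s1
  cov_p <- mean((s1 - mean(s1)) * (ds - mean(ds)))
  out <- list(var_s1 = pvar(s1), var_s2 = pvar(s2),
              delta_var = pvar(s2) - pvar(s1),
              var_ds = pvar(ds), cov_s1_ds = cov_p)
  out$residual <- out$delta_var - out$var_ds - 2 * cov_p
  out
}

gcv_value <- function(delta_var, delta_mean) {
  out <- sign(delta_var) * sqrt(abs(delta_var)) / delta_mean
  out[!is.na(delta_mean) & delta_mean <= 0] <- NA_real_
  out
}

#' Coefficient of growth-rate variation for a paired cohort
#'
#' Computes `Gcv = sign(dVar) * sqrt(|dVar|) / (mean2 - mean1)` from paired
#' start/end sizes of one cohort. When growth increments are independent of
#' size, `Gcv` equals the coefficient of variation of the increments; a
#' negative value diagnoses negative size-growth coupling (variance
#' shrinking while the mean grows). Returns 0 when the variance change is
#' exactly zero, and `NA` when the mean has not increased.
#'
#' @inheritParams variance_decomposition
#' @return list with the decomposition components plus `delta_mean` and
#'   `gcv`.
#' @examples
#' gcv_paired(c(8, 12), c(11, 11))$gcv # -2
#' @export
gcv_paired <- function(s1, s2) {
  vd <- variance_decomposition(s1, s2)
  vd$delta_mean <- mean(s2) - mean(s1)
  vd$gcv <- gcv_value(vd$delta_var, vd$delta_mean)
  vd
}

#' Age-resolved coefficient of growth-rate variation (Gcv)
#'
#' Differences the age-resolved variance and mean curves over an age lag
#' and forms the signed, normalized statistic
#' `Gcv(a) = sign(dVar) * sqrt(|dVar|) / (mean(a + lag) - mean(a))`, where
#' `dVar = Var(a + lag) - Var(a)`. Negative values mark ages at which cells
#' become more uniform in size while still growing, the signature of
#' size-dependent growth-rate regulation. Evaluation is suppressed (NA)
#' where the mean change is not positive. Confidence bands difference the
#' paired bootstrap replicates of the two curves (default nominal coverage
#' 0.50).
#'
#' @param mean_curve,var_curve `age_curve` objects on the same grid,
#'   produced together by [size_age_curves()] so their bootstrap replicates
#'   are paired.
#' @param lag age lag in hours; must be a positive multiple of the grid
#'   spacing (default 2.5).
#' @param ci_level nominal coverage of the percentile band.
#' @return data frame of class `gcv_curve` with columns `age_h` (start age),
#'   `delta_var`, `delta_mean`, `gcv`, `ci_lo`, `ci_hi`, and attribute
#'   `lag`.
#' @export
gcv_vs_age <- function(mean_curve, var_curve, lag = 2.5, ci_level = 0.50) {
  stopifnot(inherits(mean_curve, "age_curve"), inherits(var_curve, "age_curve"))
  grid <- mean_curve$age_h
  if (!isTRUE(all.equal(grid, var_curve$age_h)))
    stop("mean and variance curves must share one age grid", call. = FALSE)
  step <- diff(grid[1:2])
  k <- lag / step
  if (lag <= 0 || abs(k - round(k)) > 1e-8)
    stop("`lag` must be a positive multiple of the grid spacing",
         call. = FALSE)
  k <- as.integer(round(k))
  if (k >= length(grid)) stop("`lag` exceeds the grid span", call. = FALSE)
  i <- seq_len(length(grid) - k)
  dv <- var_curve$estimate[i + k] - var_curve$estimate[i]
  dm <- mean_curve$estimate[i + k] - mean_curve$estimate[i]
  gcv <- gcv_value(dv, dm)
  ci_lo <- ci_hi <- rep(NA_real_, length(i))
  bm <- attr(mean_curve, "boot", exact = TRUE)
  bv <- attr(var_curve, "boot", exact = TRUE)
  if (!is.null(bm) && !is.null(bv)) {
    if (!identical(attr(mean_curve, "boot_id"), attr(var_curve, "boot_id")))
      warning("curves carry unpaired bootstrap replicates; the Gcv band ",
              "treats them as paired", call. = FALSE)
    dvb <- bv[i + k, , drop = FALSE] - bv[i, , drop = FALSE]
    dmb <- bm[i + k, , drop = FALSE] - bm[i, , drop = FALSE]
    gb <- gcv_value(dvb, dmb)
    qs <- apply(gb, 1L, function(z) {
      z <- z[is.finite(z)]
      if (length(z) < 2L) return(c(NA_real_, NA_real_))
      quantile(z, probs = c((1 - ci_level) / 2, 1 - (1 - ci_level) / 2),
               names = FALSE)
    })
    ci_lo <- qs[1L, ]
    ci_hi <- qs[2L, ]
  }
  structure(
    data.frame(age_h = grid[i], delta_var = dv, delta_mean = dm, gcv = gcv,
               ci_lo = ci_lo, ci_hi = ci_hi),
    lag = lag, ci_level = ci_level,
    class = c("gcv_curve", "data.frame"))
}

#' Locate negative Gcv excursions
#'
#' Identifies contiguous runs of grid points at which the Gcv estimate is
#' negative (and, if `require_ci`, at which the upper confidence bound is
#' below zero as well).
#'
#' @param gcv a `gcv_curve` from [gcv_vs_age()].
#' @param require_ci if `TRUE`, only count points whose entire band lies
#'   below zero.
#' @param min_run minimum number of consecutive negative grid points for a
#'   run to count as an excursion (default 2, suppressing single-point
#'   noise).
#' @return data frame with one row per excursion: `start_h`, `end_h`,
#'   `min_gcv`.
#' @export
gcv_excursions <- function(gcv, require_ci = FALSE, min_run = 2L) {
  stopifnot(inherits(gcv, "gcv_curve"))
  neg <- !is.na(gcv$gcv) & gcv$gcv < 0
  if (require_ci) neg <- neg & !is.na(gcv$ci_hi) & gcv$ci_hi < 0
  if (!any(neg)) {
    return(data.frame(start_h = numeric(0), end_h = numeric(0),
                      min_gcv = numeric(0)))
  }
  r <- rle(neg)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= min_run)
  if (!length(keep)) {
    return(data.frame(start_h = numeric(0), end_h = numeric(0),
                      min_gcv = numeric(0)))
  }
  data.frame(
    start_h = gcv$age_h[starts[keep]],
    end_h = gcv$age_h[ends[keep]],
    min_gcv = vapply(keep, function(j)
      min(gcv$gcv[starts[j]:ends[j]]), numeric(1)))
}

#' Size contrast between G1 and post-G1 cells of the same age
#'
#' Bins cells by age, and within each bin containing at least `min_bin_n`
#' cells of each phase computes the mean size of G1 and post-G1 cells
#' (mitotic cells count as post-G1). The global test is a Welch two-sample
#' t-test of age-detrended sizes (size minus the bin-wise all-cell mean)
#' pooled over the qualifying bins. A positive contrast with a small p-value
#' indicates that cells which have passed the G1/S transition are larger
#' than G1 cells of the same age, the signature of a G1 size checkpoint.
#' `plateau_flag` reports whether the G1 mean-size curve has stopped rising
#' over the older qualifying bins (its slope is not significantly positive).
#'
#' @param snapshot data frame with `age_h`, `size_au` and `phase`.
#' @param age_bin_width bin width in hours (default 1.5).
#' @param min_bin_n minimum cells of each phase per qualifying bin.
#' @return object of class `checkpoint_result`: list with the per-bin table
#'   (`bins`), `t_statistic`, `p_value`, `contrast` (pooled post-G1 minus G1
#'   detrended mean) and `plateau_flag`.
#' @export
checkpoint_contrast <- function(snapshot, age_bin_width = 1.5,
                                min_bin_n = 10L) {
  check_snapshot(snapshot, min_n = 2L)
  stopifnot("phase" %in% names(snapshot))
  g1 <- snapshot$phase == "G1"
  if (!any(g1) || all(g1))
    stop("snapshot must contain both G1 and post-G1 cells", call. = FALSE)
  bin <- floor(snapshot$age_h / age_bin_width)
  tab <- table(bin, factor(ifelse(g1, "G1", "postG1"),
                           levels = c("G1", "postG1")))
  ok_bins <- as.numeric(rownames(tab))[tab[, "G1"] >= min_bin_n &
                                         tab[, "postG1"] >= min_bin_n]
  if (length(ok_bins) < 2L)
    stop("fewer than 2 age bins contain ", min_bin_n,
         " cells of each phase", call. = FALSE)
  keep <- bin %in% ok_bins
  kb <- bin[keep]
  ks <- snapshot$size_au[keep]
  kg1 <- g1[keep]
  bin_all_mean <- tapply(ks, kb, mean)
  detr <- ks - bin_all_mean[as.character(kb)]
  tt <- t.test(detr[!kg1], detr[kg1])
  bins <- data.frame(
    age_mid = (ok_bins + 0.5) * age_bin_width,
    mean_g1 = as.numeric(tapply(ks[kg1], kb[kg1], mean)[as.character(ok_bins)]),
    mean_postg1 = as.numeric(tapply(ks[!kg1], kb[!kg1],
                                    mean)[as.character(ok_bins)]),
    n_g1 = as.numeric(tab[as.character(ok_bins), "G1"]),
    n_postg1 = as.numeric(tab[as.character(ok_bins), "postG1"]))
  # plateau: slope of G1 mean size over the later half of qualifying bins
  nb <- nrow(bins)
  tail_idx <- seq.int(max(1L, nb - max(2L, ceiling(nb / 2)) + 1L), nb)
  plateau <- NA
  if (length(tail_idx) >= 3L) {
    fit <- lm(mean_g1 ~ age_mid, data = bins[tail_idx, ])
    ci <- confint(fit, "age_mid", level = 0.95)
    plateau <- ci[1] <= 0 # slope not significantly positive
  }
  structure(list(bins = bins, t_statistic = unname(tt$statistic),
                 p_value = tt$p.value,
                 contrast = mean(detr[!kg1]) - mean(detr[kg1]),
                 plateau_flag = plateau),
            class = "checkpoint_result")
}

#' @export
print.checkpoint_result <- function(x, ...) {
  cat("<checkpoint_result>", nrow(x$bins), "qualifying age bins\n")
  cat("  post-G1 minus G1 (age-detrended):", signif(x$contrast, 4), "\n")
  cat("  Welch t =", signif(x$t_statistic, 4), ", p =",
      format.pval(x$p_value), "\n")
  cat("  G1 plateau flag:", x$plateau_flag, "\n")
  invisible(x)
}

#' Mitotic-to-newborn size ratio
#'
#' Mean size of mitotic cells divided by the mean size of newborn cells
#' (age at most `newborn_window` hours). In a steady exponentially growing
#' population cells double in size per cycle, so the ratio is close to 2.
#'
#' @param snapshot data frame with `age_h`, `size_au` and `phase`.
#' @param newborn_window age cut-off for the newborn group, hours.
#' @return the ratio (dimensionless).
#' @export
doubling_ratio <- function(snapshot, newborn_window = 1.5) {
  check_snapshot(snapshot, min_n = 2L)
  stopifnot("phase" %in% names(snapshot))
  m <- snapshot$size_au[snapshot$phase == "M"]
  nb <- snapshot$size_au[snapshot$age_h <= newborn_window]
  if (!length(m)) stop("no mitotic cells in snapshot", call. = FALSE)
  if (!length(nb)) stop("no newborn cells in snapshot", call. = FALSE)
  mean(m) / mean(nb)
}

#' Robust size variability (normalized MAD)
#'
#' Median absolute deviation from the median, divided by the median, with no
#' consistency constant. A robust, dimensionless and scale-invariant
#' dispersion measure for cell-size distributions.
#'
#' @param sizes numeric vector of at least 2 positive values.
#' @return dimensionless variability.
#' @examples
#' size_variability(c(1, 2, 3, 4, 100)) # 1/3
#' @export
size_variability <- function(sizes) {
  stopifnot(is.numeric(sizes), length(sizes) >= 2L)
  med <- median(sizes)
  if (med <= 0) stop("median size must be positive", call. = FALSE)
  median(abs(sizes - med)) / med
}
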