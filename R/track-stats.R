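as_tracks <- function(tracks) {
  stopifnot(is.list(tracks), all(c("samples", "events") %in% names(tracks)))
  stopifnot(all(c("cell_id", "t_h", "nucleus_au") %in%
                  names(tracks$samples)),
            all(c("cell_id", "birth_time") %in% names(tracks$events)))
  tracks
}

#' Trim time-lapse tracks for analysis
#'
#' Removes, per cell, samples taken less than `trim` hours after birth (the
#' nucleus flattens and changes apparent size just after mitosis) and
#' samples at or after the onset of mitosis (nuclear envelope breakdown).
#' Cells with fewer than `min_samples` samples after trimming are excluded;
#' the exclusions and their reasons are attached as attribute `excluded`.
#'
#' @param tracks list with `samples` (`cell_id`, `t_h`, `nucleus_au`) and
#'   `events` (`cell_id`, `birth_time`, and optionally `g1_exit_time`,
#'   `m_entry_time`, `division_time`), as produced by
#'   [simulate_population()].
#' @param trim hours removed from the start of every track (default 1.25).
#' @param min_samples minimum retained samples per track.
#' @return the tracks list with trimmed `samples`; excluded cells are
#'   reported in `attr(, "excluded")`.
#' @export
preprocess_tracks <- function(tracks, trim = 1.25, min_samples = 3L) {
  tracks <- as_tracks(tracks)
  ev <- tracks$events
  sm <- tracks$samples
  birth <- ev$birth_time[match(sm$cell_id, ev$cell_id)]
  keep <- (sm$t_h - birth) >= trim - 1e-9
  if ("m_entry_time" %in% names(ev)) {
    mend <- ev$m_entry_time[match(sm$cell_id, ev$cell_id)]
    keep <- keep & (is.na(mend) | sm$t_h < mend - 1e-9)
  }
  sm <- sm[keep, , drop = FALSE]
  cnt <- table(sm$cell_id)
  short <- setdiff(ev$cell_id, as.numeric(names(cnt)[cnt >= min_samples]))
  sm <- sm[!(sm$cell_id %in% short), , drop = FALSE]
  excluded <- data.frame(cell_id = short,
                         reason = rep("fewer than min_samples after trimming",
                                      length(short)))
  out <- list(samples = sm[order(sm$cell_id, sm$t_h), , drop = FALSE],
              events = ev)
  attr(out, "excluded") <- excluded
  attr(out, "trim") <- trim
  out
}

#' G1 duration of tracked cells
#'
#' @param events per-cell events data frame with `birth_time` and
#'   `g1_exit_time`.
#' @return numeric vector (hours) named by `cell_id`; errors if any exit
#'   precedes birth. Cells with a pending (missing) exit get `NA`.
#' @export
g1_duration <- function(events) {
  stopifnot(all(c("cell_id", "birth_time", "g1_exit_time") %in%
                  names(events)))
  d <- events$g1_exit_time - events$birth_time
  if (any(d < 0, na.rm = TRUE))
    stop("G1 exit precedes birth for some cells", call. = FALSE)
  stats::setNames(d, events$cell_id)
}

#' Birth size versus G1 length, with a permutation null
#'
#' Correlates each cell's nucleus size at its first retained sample
#' (approximately `trim` hours after birth, the operational "size at birth")
#' with its G1 duration. Cells whose G1 exit precedes the first retained
#' sample, or whose track does not start at birth, are excluded. Reports the
#' Pearson correlation with the two-sided p-value from the Student-t
#' transform, the least-squares slope of G1 length on birth size, and a
#' permutation null distribution obtained by shuffling the G1 durations
#' against the sizes.
#'
#' @param tracks tracks list (see [preprocess_tracks()]; preprocessing is
#'   applied if not already done).
#' @param n_perm number of permutations.
#' @param seed integer seed for the permutations.
#' @param trim passed to [preprocess_tracks()].
#' @param min_tracks minimum usable tracks (default 20).
#' @return object of class `correlation_report`: list with `r`, `p_value`,
#'   `perm_p` (fraction of `|null r| >= |r|`), `n`, `slope`,
#'   `null_distribution`, and the analysis table `data`.
#' @export
birth_size_g1_correlation <- function(tracks, n_perm = 1000L, seed = 1L,
                                      trim = 1.25, min_tracks = 20L) {
  if (is.null(attr(tracks, "trim")))
    tracks <- preprocess_tracks(tracks, trim = trim)
  ev <- tracks$events
  sm <- tracks$samples
  stopifnot("g1_exit_time" %in% names(ev))
  first <- sm[!duplicated(sm$cell_id), , drop = FALSE]
  i <- match(first$cell_id, ev$cell_id)
  birth <- ev$birth_time[i]
  exit <- ev$g1_exit_time[i]
  dt_grid <- min(diff(sort(unique(sm$t_h))))
  # track must start at birth (first retained sample right after the trim)
  # and G1 exit must come at or after that sample
  usable <- !is.na(exit) & exit >= first$t_h &
    (first$t_h - birth) <= trim + dt_grid + 1e-9
  x <- first$nucleus_au[usable]
  y <- (exit - birth)[usable]
  n <- length(x)
  if (n < min_tracks)
    stop("only ", n, " usable tracks; need at least ", min_tracks,
         call. = FALSE)
  ct <- cor.test(x, y)
  r <- unname(ct$estimate)
  set.seed(substream_seed(seed, "permutation"))
  null_r <- vapply(seq_len(n_perm),
                   function(b) cor(x, y[sample.int(n)]), numeric(1))
  structure(list(
    r = r, p_value = ct$p.value,
    perm_p = mean(abs(null_r) >= abs(r)),
    n = n, slope = unname(coef(lm(y ~ x))[2L]),
    null_distribution = null_r,
    data = data.frame(cell_id = first$cell_id[usable], birth_size_au = x,
                      g1_length_h = y)
  ), class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat("<correlation_report> n =", x$n, "tracks\n")
  cat("  Pearson r =", signif(x$r, 3), ", p =", format.pval(x$p_value),
      "(t transform)\n")
  cat("  permutation p =", signif(x$perm_p, 3), "(",
      length(x$null_distribution), "shuffles )\n")
  cat("  slope =", signif(x$slope, 3), "h per size unit\n")
  invisible(x)
}

# per-cell nucleus value at a given age on the sampling grid (exact match)
nucleus_at_age <- function(sm, birth, age, tol = 1e-6) {
  a <- sm$t_h - birth[match(sm$cell_id, names(birth))]
  hit <- abs(a - age) < tol
  stats::setNames(sm$nucleus_au[hit], sm$cell_id[hit])
}

#' Age-resolved correlation of size with subsequent growth
#'
#' For each age on a grid, correlates the nucleus size of cells alive at
#' that age with their nucleus growth over the following `lag` hours
#' (`nucleus(a + lag) - nucleus(a)`), across cells. Negative values mark
#' ages at which large cells grow less than small cells. Ages with fewer
#' than `min_n` cells are reported as `NA` and flagged.
#'
#' @param tracks tracks list (preprocessed if needed).
#' @param lag lag in hours; must be a multiple of the sampling interval.
#' @param age_step grid spacing in hours (default the sampling interval).
#' @param min_n minimum cells per age (default 20).
#' @return data frame of class `age_resolved_correlation`: `age_h`, `r`,
#'   `n`, `defined`.
#' @export
growth_vs_size_by_age <- function(tracks, lag = 2.5, age_step = NULL,
                                  min_n = 20L) {
  if (is.null(attr(tracks, "trim"))) tracks <- preprocess_tracks(tracks)
  sm <- tracks$samples
  ev <- tracks$events
  birth <- stats::setNames(ev$birth_time, ev$cell_id)
  age <- sm$t_h - ev$birth_time[match(sm$cell_id, ev$cell_id)]
  dt_grid <- min(diff(sort(unique(sm$t_h))))
  if (is.null(age_step)) age_step <- dt_grid * 2
  k <- lag / dt_grid
  if (abs(k - round(k)) > 1e-8)
    stop("`lag` is not representable on the sampling grid", call. = FALSE)
  ages <- seq(ceiling(min(age) / age_step) * age_step,
              max(age) - lag, by = age_step)
  key <- paste(sm$cell_id, round(age / dt_grid))
  val <- stats::setNames(sm$nucleus_au, key)
  res <- lapply(ages, function(a) {
    ids <- sm$cell_id[abs(age - a) < 1e-6]
    k1 <- paste(ids, round(a / dt_grid))
    k2 <- paste(ids, round((a + lag) / dt_grid))
    ok <- k2 %in% key
    n <- sum(ok)
    if (n < min_n) return(c(NA_real_, n))
    x <- val[k1[ok]]
    g <- val[k2[ok]] - x
    if (sd(x) == 0 || sd(g) == 0) return(c(NA_real_, n))
    c(cor(x, g), n)
  })
  m <- do.call(rbind, res)
  structure(data.frame(age_h = ages, r = m[, 1L], n = m[, 2L],
                       defined = !is.na(m[, 1L])),
            lag = lag,
            class = c("age_resolved_correlation", "data.frame"))
}

#' Convergence of extreme size deciles
#'
#' Sorts tracked cells by nucleus size at `sort_age` hours after birth,
#' takes the `k` largest and `k` smallest, and follows the two group-mean
#' trajectories to the last age at which all selected cells are still
#' observed. The `gap_ratio` is the large-minus-small group gap at that last
#' common age divided by the gap at `sort_age`: values below 1 indicate
#' convergence (size-dependent growth), values above 1 divergence (e.g.
#' exponential growth). Ties in the selection are broken by cell id.
#'
#' @param tracks tracks list (preprocessed if needed).
#' @param sort_age age at which cells are ranked, hours (default 10).
#' @param k group size (default 10).
#' @param ref_age minimum age through which eligible cells must remain
#'   observed (default `sort_age + 5`), so the trajectories have room to
#'   converge or diverge.
#' @return list with `trajectories` (data frame `age_h`, `mean_large`,
#'   `mean_small`), `gap_ratio`, `sort_age`, `last_common_age`.
#' @export
extreme_decile_convergence <- function(tracks, sort_age = 10, k = 10L,
                                       ref_age = sort_age + 5) {
  if (is.null(attr(tracks, "trim"))) tracks <- preprocess_tracks(tracks)
  sm <- tracks$samples
  ev <- tracks$events
  birth <- ev$birth_time[match(sm$cell_id, ev$cell_id)]
  age <- sm$t_h - birth
  all_max_age <- tapply(age, sm$cell_id, max)
  eligible <- as.numeric(names(all_max_age)[all_max_age >= ref_age - 1e-6])
  at <- abs(age - sort_age) < 1e-6 & sm$cell_id %in% eligible
  ids <- sm$cell_id[at]
  vals <- sm$nucleus_au[at]
  if (length(ids) < 2L * k)
    stop("fewer than 2k tracks observed at sort_age", call. = FALSE)
  ord <- order(vals, ids)
  small <- ids[ord[seq_len(k)]]
  large <- ids[ord[seq.int(length(ord) - k + 1L, length(ord))]]
  sel <- c(small, large)
  max_age <- tapply(age[sm$cell_id %in% sel], sm$cell_id[sm$cell_id %in% sel],
                    max)
  last_common <- min(max_age[as.character(sel)])
  dt_grid <- min(diff(sort(unique(sm$t_h))))
  grid <- seq(sort_age, last_common, by = dt_grid)
  gmean <- function(group, a) {
    hit <- sm$cell_id %in% group & abs(age - a) < 1e-6
    mean(sm$nucleus_au[hit])
  }
  traj <- data.frame(
    age_h = grid,
    mean_large = vapply(grid, function(a) gmean(large, a), numeric(1)),
    mean_small = vapply(grid, function(a) gmean(small, a), numeric(1)))
  gap0 <- traj$mean_large[1L] - traj$mean_small[1L]
  gap1 <- traj$mean_large[nrow(traj)] - traj$mean_small[nrow(traj)]
  list(trajectories = traj, gap_ratio = gap1 / gap0, sort_age = sort_age,
       last_common_age = last_common)
}
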