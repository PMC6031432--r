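# canonical columns per table kind
canonical_columns <- list(
  snapshot = c("cell_id", "age_h", "size_au", "nucleus_au", "phase"),
  track_samples = c("cell_id", "t_h", "nucleus_au"),
  track_events = c("cell_id", "birth_time", "g1_exit_time", "m_entry_time",
                   "division_time"),
  bulk = c("condition", "t_h", "n_cells", "mean_size_au")
)

#' Read a measurement table with column mapping and validation
#'
#' Reads a delimited text table (comma separator, header row, `.` decimal)
#' and coerces it to the canonical column vocabulary of the requested kind.
#' `mapping` renames source columns (e.g. deposited files using
#' `"cell age"`, `"total SE-A647 intensity"`, `"nucleus size"`) to the
#' canonical names: a named character vector `c(canonical = "source name")`.
#' Rows violating basic invariants (negative ages, non-positive sizes,
#' counts below 1) are dropped and counted in attribute `dropped`. When a
#' snapshot has no `phase` column but has a phase-marker intensity column
#' (canonical `phase_marker_au`), phases are called from the marker with
#' [phase_from_marker()].
#'
#' @param path file path.
#' @param kind `"snapshot"`, `"bulk"`, `"track_samples"` or
#'   `"track_events"`.
#' @param mapping optional named character vector mapping canonical names to
#'   source column names.
#' @return validated data frame with canonical columns; attribute `dropped`
#'   counts removed rows.
#' @export
load_table <- function(path, kind = c("snapshot", "bulk", "track_samples",
                                      "track_events"),
                       mapping = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!is.null(mapping)) {
    for (canon in names(mapping)) {
      src <- mapping[[canon]]
      if (!src %in% names(df))
        stop("mapped column `", src, "` absent from ", path, call. = FALSE)
      names(df)[names(df) == src] <- canon
    }
  }
  need <- canonical_columns[[kind]]
  optional <- c("nucleus_au", "phase", "g1_exit_time", "m_entry_time",
                "division_time")
  if (kind == "snapshot" && !"cell_id" %in% names(df)) {
    df$cell_id <- seq_len(nrow(df)) # deposited tables carry no cell ids
  }
  missing <- setdiff(setdiff(need, optional), names(df))
  if (kind == "snapshot" && !"phase" %in% names(df) &&
      "phase_marker_au" %in% names(df)) {
    df$phase <- phase_from_marker(df$phase_marker_au)
  }
  if (length(missing))
    stop("missing required columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  n0 <- nrow(df)
  ok <- rep(TRUE, n0)
  if ("age_h" %in% names(df)) ok <- ok & is.finite(df$age_h) & df$age_h >= 0
  if ("size_au" %in% names(df))
    ok <- ok & is.finite(df$size_au) & df$size_au > 0
  if ("n_cells" %in% names(df))
    ok <- ok & is.finite(df$n_cells) & df$n_cells >= 1
  if ("mean_size_au" %in% names(df))
    ok <- ok & is.finite(df$mean_size_au) & df$mean_size_au > 0
  df <- df[ok, intersect(c(need, "phase_marker_au"), names(df)),
           drop = FALSE]
  if (!nrow(df)) stop("no valid rows after validation: ", path,
                      call. = FALSE)
  if (n0 - nrow(df) > 0)
    message(n0 - nrow(df), " invalid row(s) dropped from ", basename(path))
  attr(df, "dropped") <- n0 - nrow(df)
  df
}

#' Call cell-cycle phase from a reporter intensity
#'
#' Two-class threshold (Otsu's criterion, maximizing the between-class
#' variance of a 256-bin histogram) on the log reporter intensity; cells
#' above the threshold are called `"postG1"`, cells below `"G1"`. Used when
#' a snapshot table carries a post-G1 reporter intensity instead of an
#' explicit phase label.
#'
#' @param marker positive reporter intensities.
#' @return character vector of `"G1"` / `"postG1"` calls.
#' @export
phase_from_marker <- function(marker) {
  stopifnot(all(marker > 0))
  x <- log(marker)
  thr <- otsu_threshold(x)
  ifelse(x > thr, "postG1", "G1")
}

# Otsu threshold on a numeric vector via a fixed 256-bin histogram
otsu_threshold <- function(x, n_bins = 256L) {
  h <- hist(x, breaks = seq(min(x), max(x), length.out = n_bins + 1L),
            plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- -Inf
  mids[which.max(between)]
}

#' Write simulation outputs as delimited text
#'
#' Writers for the three measurement modalities, in the package's CSV
#' dialect (UTF-8, header row, comma separator, `.` decimal).
#'
#' @param x table to write (`snapshot` data frame, `tracks` list, or bulk
#'   series).
#' @param path output file (for tracks, a stem producing
#'   `<stem>_samples.csv` and `<stem>_events.csv`).
#' @return the written path(s), invisibly.
#' @export
write_snapshot <- function(x, path) {
  utils::write.csv(x[, canonical_columns$snapshot], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_snapshot
#' @export
write_tracks <- function(x, path) {
  p1 <- paste0(path, "_samples.csv")
  p2 <- paste0(path, "_events.csv")
  utils::write.csv(x$samples, p1, row.names = FALSE, quote = FALSE)
  utils::write.csv(x$events, p2, row.names = FALSE, quote = FALSE)
  invisible(c(p1, p2))
}

#' @rdname write_snapshot
#' @export
write_bulk <- function(x, path) {
  utils::write.csv(as.data.frame(x)[, canonical_columns$bulk], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read tracks written by [write_tracks()]
#'
#' @param path the stem used when writing.
#' @param mapping optional column mapping (see [load_table()]).
#' @return tracks list with `samples` and `events`.
#' @export
read_tracks <- function(path, mapping = NULL) {
  list(samples = load_table(paste0(path, "_samples.csv"), "track_samples",
                            mapping),
       events = load_table(paste0(path, "_events.csv"), "track_events",
                           mapping))
}

# small stable content hash (polynomial rolling hash over the serialized
# object's bytes; collision resistance adequate for manifest bookkeeping)
content_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  h <- 5381
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run manifest for reproducibility
#'
#' Records the package version, a content hash of the configuration, the
#' master seed and digests of any input files, so a run can be reproduced
#' byte-for-byte.
#'
#' @param config a [sim_config()] or any serializable configuration object.
#' @param seed master seed used.
#' @param inputs character vector of input file paths (optional).
#' @return list of class `run_manifest`.
#' @export
run_manifest <- function(config, seed, inputs = character(0)) {
  digests <- vapply(inputs, function(p)
    content_hash(readBin(p, "raw", file.info(p)$size)), character(1))
  structure(list(
    package_version = as.character(utils::packageVersion("cellsizer")),
    config_hash = content_hash(unclass(config)),
    master_seed = as.integer(seed),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    input_digests = as.list(digests)
  ), class = "run_manifest")
}

#' Aggregate analysis outputs into one JSON report
#'
#' Serializes a named list of analysis results (statistics, ratios, seeds)
#' to JSON with stable key order. Curve data frames are included as column
#' lists; S3 result objects are flattened to their numeric fields.
#'
#' @param results named list of analysis outputs.
#' @param path optional file to write; when `NULL` the JSON string is
#'   returned.
#' @return the JSON string, invisibly when written to file.
#' @export
report_json <- function(results, path = NULL) {
  if (!length(results)) stop("no analysis outputs to report", call. = FALSE)
  stopifnot(!is.null(names(results)), all(nzchar(names(results))))
  flatten <- function(x) {
    if (inherits(x, "lm")) return(NULL)
    if (is.data.frame(x)) return(as.list(x))
    if (is.list(x)) {
      x <- lapply(x, flatten)
      return(x[!vapply(x, is.null, logical(1))])
    }
    x
  }
  out <- lapply(results[order(names(results))], flatten)
  js <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Read or write a simulation configuration as YAML
#'
#' Flat key-value serialization of a [sim_config()]; feedback windows are
#' stored as parallel lists, the perturbation as nested keys.
#'
#' @param config a `sim_config`.
#' @param path YAML file path.
#' @return `write_sim_config()` returns the path invisibly;
#'   `read_sim_config()` returns a validated `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  x <- unclass(config)
  x$feedback_windows <- as.list(as.data.frame(x$feedback_windows))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$feedback_windows <- if (length(x$feedback_windows$age_lo))
    as.data.frame(x$feedback_windows) else NULL
  do.call(sim_config, x)
}
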