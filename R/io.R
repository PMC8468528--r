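## Plain-text session I/O: wrench CSV, stride-label CSV, geometry JSON and
## calibration-sample CSV. Every file written carries a one-line metadata
## header (# key=value ...) recording the seed and config hash for
## provenance; readers skip it transparently.

meta_header <- function(meta) {
  if (is.null(meta) || !length(meta)) {
    return(NULL)
  }
  paste0("# ", paste(sprintf("%s=%s", names(meta), unlist(meta)), collapse = " "))
}

write_csv_meta <- function(df, path, meta = NULL) {
  hdr <- meta_header(meta)
  if (!is.null(hdr)) {
    writeLines(hdr, path)
    data.table::fwrite(df, path, append = TRUE, col.names = TRUE)
  } else {
    data.table::fwrite(df, path)
  }
  invisible(path)
}

read_csv_meta <- function(path) {
  first <- readLines(path, n = 1)
  if (!length(first)) stop(sprintf("empty file: %s", path))
  skip <- if (startsWith(first, "#")) 1L else 0L
  df <- as.data.frame(data.table::fread(path, skip = skip))
  if (!nrow(df)) stop(sprintf("no data rows in %s", path))
  attr(df, "meta_skip") <- skip
  df
}

#' Deterministic hash of a configuration object
#'
#' MD5 of the serialized object; recorded in output-file headers so artifacts
#' can be traced to the exact configuration and seed that produced them.
#'
#' @param x any R object.
#' @return 32-character hex string.
#' @export
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(serialize(x, NULL, version = 2), f)
  unname(tools::md5sum(f))
}

#' Write / read a wrench-series session CSV
#'
#' Columns: `time_s, fx_n, fy_n, fz_n, mx_nm, my_nm, mz_nm`. The reader
#' validates timestamps and rejects non-monotonic rows, naming the first
#' offending file row.
#'
#' @param series a `wrench_series`.
#' @param path file path.
#' @param meta named list written into the `#` header line (e.g. seed, hash).
#' @return `write_session_csv`: the path, invisibly. `read_session_csv`: a
#'   `wrench_series` (frame `"load_cell"` unless the header says otherwise).
#' @export
write_session_csv <- function(series, path, meta = NULL) {
  stopifnot(inherits(series, "wrench_series"))
  df <- data.frame(
    time_s = series$time,
    fx_n = series$force[, 1], fy_n = series$force[, 2], fz_n = series$force[, 3],
    mx_nm = series$moment[, 1], my_nm = series$moment[, 2], mz_nm = series$moment[, 3]
  )
  write_csv_meta(df, path, c(meta, list(frame = series$frame)))
}

#' @rdname write_session_csv
#' @export
read_session_csv <- function(path) {
  df <- read_csv_meta(path)
  need <- c("time_s", "fx_n", "fy_n", "fz_n", "mx_nm", "my_nm", "mz_nm")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  bad <- which(diff(df$time_s) <= 0)
  if (length(bad)) {
    # file row: +1 header, +meta line if present, +1 for the second row of the pair
    stop(sprintf(
      "non-monotonic timestamp at file row %d",
      bad[1] + 2L + attr(df, "meta_skip")
    ))
  }
  first <- readLines(path, n = 1)
  frame <- if (grepl("frame=shank", first)) "shank" else "load_cell"
  wrench_series(df$time_s, as.matrix(df[, c("fx_n", "fy_n", "fz_n")]),
    as.matrix(df[, c("mx_nm", "my_nm", "mz_nm")]),
    frame = frame
  )
}

#' Write / read ground-truth stride labels
#'
#' Columns: `stride_id, mode, stiffness_code, transition_flag, hs_time_s,
#' to_time_s`.
#'
#' @param truth data.frame of stride ground truth (as in a `gait_session`).
#' @param path file path.
#' @param meta named list for the header line.
#' @return the path / the labels data.frame.
#' @export
write_labels_csv <- function(truth, path, meta = NULL) {
  df <- data.frame(
    stride_id = truth$stride_id,
    mode = truth$mode,
    stiffness_code = truth$stiffness_code,
    transition_flag = as.integer(truth$transition),
    hs_time_s = truth$hs_time_s,
    to_time_s = truth$to_time_s
  )
  write_csv_meta(df, path, meta)
}

#' @rdname write_labels_csv
#' @export
read_labels_csv <- function(path) {
  df <- read_csv_meta(path)
  df$transition <- as.logical(df$transition_flag)
  df
}

#' Expand stride-level labels to per-sample labels
#'
#' Assigns each sample time the mode of the stride whose stance covers it;
#' swing samples take the mode of the upcoming stride (the label a controller
#' would be preparing for). Transition flags propagate to stance samples.
#'
#' @param labels stride-level labels (`mode`, `hs_time_s`, `to_time_s`,
#'   `transition`).
#' @param times sample times to label.
#' @return data.frame `time`, `mode`, `transition`.
#' @export
labels_to_samples <- function(labels, times) {
  labels <- labels[order(labels$hs_time_s), , drop = FALSE]
  idx <- findInterval(times, labels$hs_time_s)
  nxt <- pmin(idx + 1L, nrow(labels))
  in_stance <- idx >= 1 & times <= labels$to_time_s[pmax(idx, 1L)]
  pick <- ifelse(in_stance, pmax(idx, 1L), nxt)
  pick[idx < 1] <- 1L
  data.frame(
    time = times,
    mode = labels$mode[pick],
    transition = in_stance & labels$transition[pmax(idx, 1L)],
    stringsAsFactors = FALSE
  )
}

#' Write / read subject geometry JSON
#'
#' The rotation is stored row-major (9 numbers); offsets in meters; foot
#' length and body weight as scalars. Reading validates and re-projects the
#' rotation, and errors on any missing field.
#'
#' @param geometry a `subject_geometry`.
#' @param path file path.
#' @param meta optional named list stored under `$meta`.
#' @return the path / a `subject_geometry`.
#' @export
write_geometry_json <- function(geometry, path, meta = NULL) {
  stopifnot(inherits(geometry, "subject_geometry"))
  obj <- list(
    rotation_lc_to_shank_row_major = as.numeric(t(geometry$rotation_lc_to_shank)),
    r_ankle_to_lc_m = geometry$r_ankle_to_lc,
    r_knee_to_lc_m = geometry$r_knee_to_lc,
    foot_length_m = geometry$foot_length,
    body_weight_n = geometry$body_weight
  )
  if (!is.null(meta)) obj$meta <- meta
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_geometry_json
#' @export
read_geometry_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c(
    "rotation_lc_to_shank_row_major", "r_ankle_to_lc_m", "r_knee_to_lc_m",
    "foot_length_m", "body_weight_n"
  )
  miss <- setdiff(need, names(obj))
  if (length(miss)) {
    stop(sprintf("geometry file missing field(s): %s", paste(miss, collapse = ", ")))
  }
  R <- matrix(obj$rotation_lc_to_shank_row_major, 3, 3, byrow = TRUE)
  subject_geometry(
    project_rotation(R), obj$r_ankle_to_lc_m, obj$r_knee_to_lc_m,
    obj$foot_length_m, obj$body_weight_n
  )
}

#' Write / read calibration samples CSV
#'
#' One row per paired sample: the 9 row-major rotation entries
#' (`r11 ... r33`), then ankle and knee offset components
#' (`ankle_x ... knee_z`), in meters.
#'
#' @param trial list from [generate_calibration_trial()].
#' @param path file path.
#' @param meta named list for the header line.
#' @return the path / a list shaped like a calibration trial.
#' @export
write_calibration_csv <- function(trial, path, meta = NULL) {
  Rflat <- t(vapply(trial$rotations, function(R) as.numeric(t(R)), numeric(9)))
  df <- as.data.frame(cbind(Rflat, trial$ankle_offsets, trial$knee_offsets))
  names(df) <- c(
    paste0("r", rep(1:3, each = 3), rep(1:3, 3)),
    paste0("ankle_", c("x", "y", "z")), paste0("knee_", c("x", "y", "z"))
  )
  write_csv_meta(df, path, meta)
}

#' @rdname write_calibration_csv
#' @export
read_calibration_csv <- function(path) {
  df <- read_csv_meta(path)
  rot_cols <- paste0("r", rep(1:3, each = 3), rep(1:3, 3))
  rotations <- lapply(seq_len(nrow(df)), function(i) {
    matrix(as.numeric(df[i, rot_cols]), 3, 3, byrow = TRUE)
  })
  list(
    rotations = rotations,
    ankle_offsets = as.matrix(df[, paste0("ankle_", c("x", "y", "z"))]),
    knee_offsets = as.matrix(df[, paste0("knee_", c("x", "y", "z"))])
  )
}

#' Read a full recorded session
#'
#' Loads and validates the wrench stream, stride labels, and subject geometry
#' for one trial.
#'
#' @param session_path wrench CSV path.
#' @param labels_path stride-label CSV path.
#' @param geometry_path geometry JSON path.
#' @return list with `series`, `labels`, `geometry`.
#' @export
read_session <- function(session_path, labels_path, geometry_path) {
  list(
    series = read_session_csv(session_path),
    labels = read_labels_csv(labels_path),
    geometry = read_geometry_json(geometry_path)
  )
}
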